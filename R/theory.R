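check_tfbm_params <- function(n, x, m) {
  if (n <= 0 || m < n) stop("invalid TFBM parameters: need 0 < n <= m",
                            call. = FALSE)
  if (x < 0) stop("invalid TFBM parameters: x must be >= 0", call. = FALSE)
  if (x > 0 && n == m)
    stop("invalid TFBM parameters: turnover (x > 0) requires n < m",
         call. = FALSE)
  invisible(TRUE)
}

#' Fragile-persistence probability P(l) under TFBM
#'
#' The probability that a site fragile at time 0 is still fragile after l
#' 2-breaks, when each 2-break retires x of the n fragile sites (each with
#' probability x/n) and activates x of the m - n solid ones (probability
#' x/(m - n)).  The closed form
#' `P(l) = ((m-n)/m) (1 - x m / (n (m-n)))^l + n/m`
#' solves the two-state Markov recurrence
#' `P(l+1) = P(l) (1 - x/n) + (1 - P(l)) x/(m-n)` with `P(0) = 1`, and
#' decays towards the stationary fraction n/m.
#'
#' @param l Vector of non-negative step counts.
#' @param n Number of fragile sites.
#' @param x Turnover rate per 2-break.
#' @param m Total number of breakable sites.
#' @return `P(l)`, vectorized over `l`.
#' @examples
#' persistence_probability(0:3, n = 900, x = 1, m = 2000)
#' @export
persistence_probability <- function(l, n, x, m) {
  check_tfbm_params(n, x, m)
  if (x == 0) return(rep(1, length(l)))
  (m - n) / m * (1 - x * m / (n * (m - n)))^l + n / m
}

#' Theoretical multispecies breakpoint reuse R(l) under TFBM
#'
#' The expected number of vertices shared by two 2-breaks separated by l
#' rearrangements: the first uses 4 vertices, each still fragile after l
#' steps with probability P(l), and a random 2-break hits a given fragile
#' vertex with probability 2/n, giving
#' `R(l) = (8/n) P(l) = 8 (m-n) / (n m) (1 - x m/(n (m-n)))^l + 8/m`.
#' With x = 0 the curve is flat at 8/n (the FBM/RBM signature).
#'
#' @inheritParams persistence_probability
#' @return `R(l)`, vectorized over `l`.
#' @examples
#' theoretical_R(0, n = 900, x = 1, m = 2000)  # 8/900
#' @export
theoretical_R <- function(l, n, x, m) {
  8 / n * persistence_probability(l, n, x, m)
}

#' Linear approximation of R(l)
#'
#' For `x m l / (n (m - n))` much smaller than 1 the TFBM curve is close to
#' the line `8/n - (8 x / n^2) l`, which does not depend on m; hence m is
#' only identifiable from the curvature of R(l).
#'
#' @param l Vector of distances.
#' @param n Number of fragile sites.
#' @param x Turnover rate.
#' @return The linear approximation of `R(l)`.
#' @export
linear_approx_R <- function(l, n, x) {
  8 / n - 8 * x / n^2 * l
}

#' Estimate TFBM parameters from a breakpoint-reuse curve
#'
#' Fits `theoretical_R(l; n, x, m)` to an empirical curve by weighted
#' nonlinear least squares (weights = the pair count of each distance bin),
#' with parameters transformed to `(log n, log x, log(m - n))` to enforce
#' positivity and n < m.  Starting values come from the model's own
#' moments: `n0 = 8 / R(l_min)`, `x0` from the initial slope via the linear
#' approximation, and `m0 = 2 n0`.
#'
#' A curve that is flat within noise (initial slope not significantly
#' negative) is reported as `x = 0` with `n = 8 / mean(R)` and the warning
#' `"no turnover signal"`; `m` is then unidentifiable and returned as `NA`.
#' When the fitted decay is nearly linear over the observed range an
#' identifiability warning marks `m` as weakly constrained.
#'
#' @param curve A `reuse_curve` data frame with columns `l`, `R` and
#'   optionally `pair_count` (defaults to equal weights); at least 4
#'   distinct `l` bins.
#' @param exclude_below Drop bins with `l` below this value before fitting.
#'   Small-l bins of an empirical curve are dominated by same-branch pairs
#'   whose reuse does not decay, so excluding bins below the shortest
#'   branch length can sharpen the fit; 0 (keep all) by default.
#' @return An object of class `"tfbm_fit"`: `n`, `x`, `m`, `residual`
#'   (weighted RSS), `warnings` (character vector), `fitted` (the fitted
#'   curve over the input bins) and `n_bins`.
#' @examples
#' curve <- data.frame(l = 0:200, R = theoretical_R(0:200, 900, 1, 2000),
#'                     pair_count = 1)
#' fit_tfbm(curve)
#' @export
fit_tfbm <- function(curve, exclude_below = 0) {
  df <- as.data.frame(curve)
  if (is.null(df$pair_count)) df$pair_count <- 1
  df <- df[df$l >= exclude_below & is.finite(df$R), , drop = FALSE]
  if (length(unique(df$l)) < 4L)
    stop("need at least 4 distinct distance bins to fit TFBM", call. = FALSE)
  df <- df[order(df$l), ]
  w <- df$pair_count
  warnings <- character(0)

  # moment-based starting values
  Rbar <- sum(w * df$R) / sum(w)
  R0 <- df$R[1L]
  sl <- stats::lm(R ~ l, data = df, weights = w)
  slope <- stats::coef(sl)[["l"]]
  slope_se <- suppressWarnings(summary(sl)$coefficients["l", "Std. Error"])
  flat <- !is.finite(slope) || slope >= 0 ||
    diff(range(df$R)) <= 1e-9 * max(abs(df$R)) ||
    (is.finite(slope_se) && slope_se > 0 && abs(slope) < 2 * slope_se)
  if (flat) {
    n_hat <- 8 / Rbar
    fit <- list(n = n_hat, x = 0, m = NA_real_,
                residual = sum(w * (df$R - 8 / n_hat)^2),
                warnings = "no turnover signal",
                fitted = transform(df, R_fit = 8 / n_hat),
                n_bins = nrow(df))
    class(fit) <- "tfbm_fit"
    return(fit)
  }
  n0 <- max(8 / R0, 4)
  x0 <- max(-slope * n0^2 / 8, 1e-3)
  start <- c(ln_n = log(n0), ln_x = log(x0), ln_mn = log(n0))
  pred <- function(p, l) {
    n <- exp(p[1L]); x <- exp(p[2L]); m <- n + exp(p[3L])
    8 * (m - n) / (n * m) * (1 - x * m / (n * (m - n)))^l + 8 / m
  }
  resid_fn <- function(p) sqrt(w) * (df$R - pred(p, df$l))
  ans <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- ans$par
  n_hat <- exp(p[[1L]]); x_hat <- exp(p[[2L]]); m_hat <- n_hat + exp(p[[3L]])
  # m is weakly constrained when the decay is nearly linear over the data
  curv <- x_hat * m_hat * max(df$l) / (n_hat * (m_hat - n_hat))
  if (curv < 0.2)
    warnings <- c(warnings, "near-linear decay: m weakly constrained")
  fit <- list(n = n_hat, x = x_hat, m = m_hat,
              residual = sum(ans$fvec^2),
              warnings = warnings,
              fitted = transform(df, R_fit = pred(p, df$l)),
              n_bins = nrow(df))
  class(fit) <- "tfbm_fit"
  fit
}

#' @export
print.tfbm_fit <- function(x, ...) {
  cat(sprintf("TFBM fit: n = %.4g, x = %.4g, m = %s (weighted RSS %.3g, %d bins)\n",
              x$n, x$x, ifelse(is.na(x$m), "NA", sprintf("%.4g", x$m)),
              x$residual, x$n_bins))
  if (length(x$warnings)) cat("  warning:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Export a TFBM fit report as JSON
#' @param fit A `tfbm_fit`.
#' @param path Output path.
#' @export
write_tfbm_fit <- function(fit, path) {
  jsonlite::write_json(list(n = fit$n, x = fit$x, m = fit$m,
                            residual = fit$residual,
                            warnings = fit$warnings),
                       path, auto_unbox = TRUE, na = "null", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
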