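#' Hill dose-response parameters
#'
#' Four-parameter sigmoidal viability model
#' \deqn{V(d) = V_0 \left(1 - E_{max}\frac{d^{n}}{d^{n} + EC_{50}^{n}}\right)}
#' where `v0` is the baseline (untreated) viability fraction, `emax` the
#' maximal effect fraction, `ec50` the half-effect dose and `hill_n` the
#' slope.
#'
#' @param v0 baseline viability fraction, in (0, 1].
#' @param emax maximal effect fraction, in \[0, 1\].
#' @param ec50_uM half-effect dose in micromolar (> 0).
#' @param hill_n Hill slope (> 0).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(v0 = 1, emax = 0.5, ec50_uM = 100, hill_n = 1) {
  if (!(v0 > 0 && v0 <= 1)) stop("hill_params: v0 must be in (0, 1]", call. = FALSE)
  if (!(emax >= 0 && emax <= 1)) stop("hill_params: emax must be in [0, 1]", call. = FALSE)
  if (!(ec50_uM > 0)) stop("hill_params: ec50_uM must be > 0", call. = FALSE)
  if (!(hill_n > 0)) stop("hill_params: hill_n must be > 0", call. = FALSE)
  structure(list(v0 = v0, emax = emax, ec50_uM = ec50_uM, hill_n = hill_n),
            class = "hill_params")
}

#' Hill fractional effect at a dose
#'
#' \eqn{e(d) = E_{max} d^n / (d^n + EC_{50}^n)}; 0 at dose 0, saturating
#' at `emax`.
#'
#' @param dose_uM dose(s) in micromolar (>= 0).
#' @param params a [hill_params()].
#' @return Effect fraction(s) in \[0, emax\].
#' @export
hill_effect <- function(dose_uM, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(dose_uM < 0)) stop("hill_effect: dose must be >= 0", call. = FALSE)
  dn <- ifelse(dose_uM > 0, dose_uM^params$hill_n, 0)
  params$emax * dn / (dn + params$ec50_uM^params$hill_n)
}

#' Hill viability at a dose
#'
#' @param dose_uM dose(s) in micromolar (>= 0).
#' @param params a [hill_params()].
#' @return Viability fraction(s); monotone non-increasing in dose.
#' @examples
#' hill_viability(600, hill_params(0.85, 0.6, 300, 1))  # 0.51
#' @export
hill_viability <- function(dose_uM, params) {
  params$v0 * (1 - hill_effect(dose_uM, params))
}

#' Fit a Hill dose-response curve to replicate viability data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}, falling back to `L-BFGS-B` on the residual sum of
#' squares if the LM step fails). Bounds: `emax` in \[0, 1\], `ec50` from a
#' tenth of the smallest positive dose to ten times the largest dose,
#' slope in 0.3-6, `v0` in
#' (0, 1]. Initial values: `v0` from the mean viability at dose 0, `ec50`
#' from the dose whose mean response is nearest half-maximal, slope 1.
#'
#' Data with essentially no response variation across doses cannot
#' identify the curve; such fits are flagged `non_identifiable` and return
#' the baseline-only model (`emax = 0`).
#'
#' @param dose_uM dose per observation (micromolar); at least 4 distinct
#'   levels including 0.
#' @param viability viability fraction per observation, in \[0, 1\].
#' @return An object of class `hill_fit`: the fitted [hill_params()] in
#'   `$params` plus `sse`, `converged`, `non_identifiable`, `method` and
#'   `n_obs`.
#' @export
fit_hill <- function(dose_uM, viability) {
  if (length(dose_uM) != length(viability))
    stop("fit_hill: dose and viability lengths differ", call. = FALSE)
  if (any(!is.finite(dose_uM)) || any(dose_uM < 0))
    stop("fit_hill: doses must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(viability)) || any(viability < 0) || any(viability > 1))
    stop("fit_hill: viabilities must lie in [0, 1]", call. = FALSE)
  lev <- sort(unique(dose_uM))
  if (length(lev) < 4)
    stop("fit_hill: need at least 4 distinct dose levels, got ", length(lev),
         call. = FALSE)
  if (!any(dose_uM == 0))
    stop("fit_hill: a dose-0 (control) level is required", call. = FALSE)
  df <- data.frame(d = dose_uM, v = viability)
  md <- tapply(df$v, df$d, mean)
  v0i <- min(max(mean(df$v[df$d == 0]), 1e-3), 1)
  if (diff(range(md)) < 1e-3) {
    out <- list(params = hill_params(v0 = v0i, emax = 0,
                                     ec50_uM = stats::median(lev[lev > 0]), hill_n = 1),
                sse = sum((df$v - v0i)^2), converged = FALSE,
                non_identifiable = TRUE, method = "none", n_obs = nrow(df))
    class(out) <- "hill_fit"
    return(out)
  }
  emaxi <- min(max(1 - min(md) / v0i, 0.05), 0.95)
  ds <- as.numeric(names(md))
  half <- v0i * (1 - emaxi / 2)
  ec50i <- ds[which.min(abs(md - half))]
  if (ec50i <= 0) ec50i <- stats::median(lev[lev > 0])
  lo <- c(v0 = 1e-3, emax = 0, ec50 = min(lev[lev > 0]) / 10, n = 0.3)
  hi <- c(v0 = 1, emax = 1, ec50 = max(lev) * 10, n = 6)
  start <- c(v0 = v0i, emax = emaxi, ec50 = min(max(ec50i, lo[["ec50"]]), hi[["ec50"]]),
             n = 1)
  model <- function(p, d) {
    dn <- ifelse(d > 0, d^p[["n"]], 0)
    p[["v0"]] * (1 - p[["emax"]] * dn / (dn + p[["ec50"]]^p[["n"]]))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ v0 * (1 - emax * ifelse(d > 0, d^n, 0) /
                                  (ifelse(d > 0, d^n, 0) + ec50^n)),
                      data = df, start = as.list(start),
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    p <- hill_params(v0 = cf[["v0"]], emax = cf[["emax"]], ec50_uM = cf[["ec50"]],
                     hill_n = cf[["n"]])
    out <- list(params = p, sse = sum(stats::resid(fit)^2),
                converged = fit$convInfo$isConv, non_identifiable = FALSE,
                method = "nlsLM", n_obs = nrow(df))
  } else {
    sse_fun <- function(p) {
      names(p) <- names(start)
      sum((df$v - model(as.list(p), df$d))^2)
    }
    op <- stats::optim(start, sse_fun, method = "L-BFGS-B", lower = lo, upper = hi,
                       control = list(maxit = 500))
    p <- hill_params(v0 = op$par[["v0"]], emax = op$par[["emax"]],
                     ec50_uM = op$par[["ec50"]], hill_n = op$par[["n"]])
    out <- list(params = p, sse = op$value, converged = op$convergence == 0,
                non_identifiable = FALSE, method = "L-BFGS-B", n_obs = nrow(df))
  }
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat("hill_fit (", x$method, if (!x$converged) ", NOT converged",
      if (x$non_identifiable) ", non-identifiable", "): ", sep = "")
  cat(sprintf("v0 = %.3f, emax = %.3f, ec50 = %.4g uM, n = %.3f; sse = %.3g (n = %d)\n",
              p$v0, p$emax, p$ec50_uM, p$hill_n, x$sse, x$n_obs))
  invisible(x)
}
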