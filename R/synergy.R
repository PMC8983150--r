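#' Bliss-independence combined effect
#'
#' Under Bliss independence two drugs act as independent "hit"
#' probabilities, so the expected combined effect is
#' \eqn{e_{AB} = e_A + e_B - e_A e_B}. An observed combined effect above
#' this null indicates synergy ("more than the sum of the individual
#' effects" once overlap is accounted for).
#'
#' @param ea,eb individual effect fractions, each in \[0, 1\].
#' @return Combined effect fraction(s) in `[max(ea, eb), 1]`.
#' @examples
#' bliss_effect(0.705, 0.644)  # 0.895
#' @export
bliss_effect <- function(ea, eb) {
  if (any(!is.finite(ea)) || any(!is.finite(eb)) ||
      any(ea < 0) || any(ea > 1) || any(eb < 0) || any(eb > 1))
    stop("bliss_effect: effects must lie in [0, 1]", call. = FALSE)
  ea + eb - ea * eb
}

#' Summary statistic of a replicate group
#'
#' @param mean group mean (viability percent or fraction - any consistent
#'   scale).
#' @param sem standard error of the mean (>= 0), same scale.
#' @param n number of replicates (>= 2).
#' @return An object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sem, n = 5) {
  if (!is.finite(sem) || sem < 0) stop("summary_stat: sem must be >= 0", call. = FALSE)
  if (!is.finite(n) || n < 2) stop("summary_stat: n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = as.integer(n)), class = "summary_stat")
}

#' Welch's t test from summary statistics
#'
#' Unpaired two-sided Welch test computed directly from group means, SEMs
#' and replicate counts:
#' \eqn{t = (\bar x_a - \bar x_b)/\sqrt{s_a^2 + s_b^2}} with the
#' Welch-Satterthwaite degrees of freedom on the squared SEMs. Identical to
#' a replicate-level `t.test(..., var.equal = FALSE)` whenever the
#' replicates have the supplied moments.
#'
#' @param a,b [summary_stat()] objects (or lists with `mean`, `sem`, `n`).
#' @return An object of class `welch_test` with `t`, `df`, `p` (two-sided)
#'   and `stars` (`"*"` for p < 0.05, `"**"` for p < 0.01).
#' @examples
#' welch_from_summary(summary_stat(58.9, 3.7, 5), summary_stat(70.6, 4.4, 5))
#' @export
welch_from_summary <- function(a, b) {
  for (s in list(a, b))
    if (!all(c("mean", "sem", "n") %in% names(s)))
      stop("welch_from_summary: arguments need mean, sem and n", call. = FALSE)
  if (a$n < 2 || b$n < 2)
    stop("welch_from_summary: both groups need n >= 2", call. = FALSE)
  if (a$sem == 0 && b$sem == 0)
    stop("welch_from_summary: both SEMs are zero; t is undefined", call. = FALSE)
  va <- a$sem^2; vb <- b$sem^2
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, stars = p_stars(p)), class = "welch_test")
}

p_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.3f, two-sided p = %.4g %s\n",
              x$t, x$df, x$p, x$stars))
  invisible(x)
}

stat_by_column <- function(table) {
  sp <- split(table$viability, table$column)
  data.frame(column = names(sp),
             mean = vapply(sp, mean, 0),
             sem = vapply(sp, function(v) stats::sd(v) / sqrt(length(v)), 0),
             n = vapply(sp, length, 0L),
             stringsAsFactors = FALSE)
}

#' Column-wise Bliss synergy report
#'
#' The chip's column layout turns one experiment into seven dose pairs:
#' near-pure drug A at the left edge column, near-pure drug B at the right
#' edge, graded mixtures between. For each column this report compares the
#' observed drug effect (viability loss relative to the untreated control
#' mean) with the Bliss-independence expectation computed from the two
#' single-drug Hill curves at that column's simulated doses, and tests each
#' column against the two edge (near-monotherapy) columns and against its
#' control by unpaired two-sided Welch tests. Holm-adjusted significance
#' flags are reported per comparison family alongside raw p-values.
#'
#' @param dose_map a `column_dose_map` from [extract_column_doses()] /
#'   [solve_gradient()].
#' @param table replicate-level viability data.frame (`cell_line`,
#'   `column`, `day`, `replicate`, `viability` as fraction) for one cell
#'   line and one day, covering every column of `dose_map`.
#' @param control matching untreated-control table (same format). The
#'   observed effect is normalised by the pooled control mean; the per-
#'   column Welch test against control uses that column's control
#'   replicates.
#' @param hill_tmz,hill_bay single-drug [hill_params()] used for the Bliss
#'   expectation.
#' @return A data.frame of class `synergy_report` with per-column doses,
#'   observed effect, Bliss-expected effect, excess (observed - expected),
#'   Welch statistics versus column A, versus the last column and versus
#'   control, and Holm flags. Attributes: `best_column` (largest observed
#'   effect), `control_mean`.
#' @export
build_synergy_report <- function(dose_map, table, control, hill_tmz, hill_bay) {
  stopifnot(inherits(hill_tmz, "hill_params"), inherits(hill_bay, "hill_params"))
  for (nm in c("column", "viability")) {
    if (!nm %in% names(table) || !nm %in% names(control))
      stop("build_synergy_report: tables need a '", nm, "' column", call. = FALSE)
  }
  if ("day" %in% names(table) && length(unique(table$day)) > 1)
    stop("build_synergy_report: supply a single day at a time", call. = FALSE)
  if ("cell_line" %in% names(table) && length(unique(table$cell_line)) > 1)
    stop("build_synergy_report: supply a single cell line at a time", call. = FALSE)
  labs <- dose_map$column
  missing <- setdiff(labs, unique(table$column))
  missing_c <- setdiff(labs, unique(control$column))
  if (length(missing) || length(missing_c))
    stop("build_synergy_report: missing column(s) ",
         paste(unique(c(missing, missing_c)), collapse = ", "),
         if (length(missing_c)) " (control)" else "", call. = FALSE)

  st <- stat_by_column(table)
  stc <- stat_by_column(control)
  st <- st[match(labs, st$column), ]
  stc <- stc[match(labs, stc$column), ]
  ctrl_mean <- mean(control$viability)

  e_obs <- 1 - st$mean / ctrl_mean
  e_tmz <- hill_effect(dose_map$dose_tmz_uM, hill_tmz)
  e_bay <- hill_effect(dose_map$dose_bay_uM, hill_bay)
  e_bliss <- bliss_effect(e_tmz, e_bay)

  wt <- function(i, j_stat) {
    welch_from_summary(summary_stat(st$mean[i], max(st$sem[i], 1e-12), st$n[i]),
                       j_stat)
  }
  nA <- 1L; nG <- length(labs)
  refA <- summary_stat(st$mean[nA], max(st$sem[nA], 1e-12), st$n[nA])
  refG <- summary_stat(st$mean[nG], max(st$sem[nG], 1e-12), st$n[nG])
  res <- lapply(seq_along(labs), function(i) {
    refC <- summary_stat(stc$mean[i], max(stc$sem[i], 1e-12), stc$n[i])
    list(A = wt(i, refA), G = wt(i, refG), C = wt(i, refC))
  })
  get <- function(cmp, fld) vapply(res, function(r) r[[cmp]][[fld]], 0)

  out <- data.frame(column = labs,
                    dose_tmz_uM = dose_map$dose_tmz_uM,
                    dose_bay_uM = dose_map$dose_bay_uM,
                    n = st$n, viability = st$mean, sem = st$sem,
                    effect_obs = e_obs, effect_bliss = e_bliss,
                    excess = e_obs - e_bliss,
                    t_vs_A = get("A", "t"), p_vs_A = get("A", "p"),
                    t_vs_G = get("G", "t"), p_vs_G = get("G", "p"),
                    t_vs_ctrl = get("C", "t"), p_vs_ctrl = get("C", "p"),
                    stringsAsFactors = FALSE)
  # Holm correction per comparison family; the self-comparisons (A vs A,
  # G vs G) are excluded from their family
  holm <- function(p, drop) {
    adj <- rep(NA_real_, length(p))
    adj[-drop] <- stats::p.adjust(p[-drop], method = "holm")
    adj
  }
  out$p_holm_vs_A <- holm(out$p_vs_A, nA)
  out$p_holm_vs_G <- holm(out$p_vs_G, nG)
  out$p_holm_vs_ctrl <- stats::p.adjust(out$p_vs_ctrl, method = "holm")
  out$holm_flags <- paste0(ifelse(!is.na(out$p_holm_vs_A) & out$p_holm_vs_A < 0.05, "A", ""),
                           ifelse(!is.na(out$p_holm_vs_G) & out$p_holm_vs_G < 0.05, "G", ""),
                           ifelse(out$p_holm_vs_ctrl < 0.05, "C", ""))
  attr(out, "best_column") <- labs[which.max(e_obs)]
  attr(out, "control_mean") <- ctrl_mean
  class(out) <- c("synergy_report", "data.frame")
  out
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("synergy_report (control mean ",
      sprintf("%.1f%%", 100 * attr(x, "control_mean")),
      "; strongest effect at column ", attr(x, "best_column"), ")\n", sep = "")
  show <- data.frame(column = x$column,
                     tmz_uM = signif(x$dose_tmz_uM, 4),
                     bay_uM = signif(x$dose_bay_uM, 4),
                     viab = sprintf("%.3f", x$viability),
                     e_obs = sprintf("%.3f", x$effect_obs),
                     e_bliss = sprintf("%.3f", x$effect_bliss),
                     excess = sprintf("%+.3f", x$excess),
                     p_vs_ctrl = signif(x$p_vs_ctrl, 3),
                     holm = x$holm_flags)
  print(show, row.names = FALSE)
  invisible(x)
}
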