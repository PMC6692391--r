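# Two-sample summary-level Mendelian randomization: allele harmonization,
# inverse-variance-weighted (IVW) and radial MR-Egger estimation, and
# heterogeneity / instrument-strength diagnostics.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) {
  toupper(ea) == unname(.complement[toupper(oa)])
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by ID and expresses both tables on the exposure's
#' effect allele: outcome effects are flipped (beta negated, EAF
#' complemented) where the allele pair is swapped, strand-complement
#' matches are resolved the same way, palindromic (A/T, C/G) variants with
#' exposure EAF inside `palindromic_window` are dropped (strand cannot be
#' resolved), and unresolvable allele pairs are dropped. Drops are logged.
#'
#' @param exposure,outcome summary-statistics data frames with columns
#'   `SNP`, `EA`, `OA`, `BETA`, `SE` and optionally `EAF`.
#' @param palindromic_window EAF interval within which palindromic
#'   variants are considered unresolvable (default `c(0.42, 0.58)`).
#' @return data frame with one row per retained instrument: `SNP`, `EA`,
#'   `OA`, `EAF`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`; dropped variant IDs in the `dropped` attribute.
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  palindromic_window = c(0.42, 0.58)) {
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (length(shared) == 0L) stop("no shared variants to harmonize")
  e <- exposure[match(shared, exposure$SNP), , drop = FALSE]
  o <- outcome[match(shared, outcome$SNP), , drop = FALSE]
  eea <- toupper(e$EA); eoa <- toupper(e$OA)
  oea <- toupper(o$EA); ooa <- toupper(o$OA)
  cea <- unname(.complement[oea]); coa <- unname(.complement[ooa])

  same <- oea == eea & ooa == eoa
  swap <- oea == eoa & ooa == eea
  comp_same <- cea == eea & coa == eoa
  comp_swap <- cea == eoa & coa == eea
  palindromic <- .is_palindromic(eea, eoa)
  ambiguous <- palindromic & !is.na(e$EAF) &
    e$EAF >= palindromic_window[1L] & e$EAF <= palindromic_window[2L]
  resolvable <- (same | swap | comp_same | comp_swap) & !ambiguous
  flip <- (swap | (comp_swap & !palindromic)) & resolvable

  dropped <- shared[!resolvable]
  if (length(dropped) > 0) {
    message(length(dropped), " variant(s) dropped during harmonization: ",
            paste(dropped, collapse = ", "))
  }
  beta_out <- ifelse(flip, -o$BETA, o$BETA)
  out <- data.frame(SNP = shared, EA = e$EA, OA = e$OA,
                    EAF = if ("EAF" %in% names(e)) e$EAF else NA_real_,
                    beta_exposure = e$BETA, se_exposure = e$SE,
                    beta_outcome = beta_out, se_outcome = o$SE)
  out <- out[resolvable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Per-instrument Wald ratios and first-order IVW weights
#'
#' Ratio estimate `beta_outcome / beta_exposure` per instrument, weighted
#' by `w = beta_exposure^2 / se_outcome^2` (first-order weights; the
#' exposure SE does not enter). Instruments with a zero exposure effect
#' are excluded with a message.
#'
#' @param instruments harmonized instrument data frame (from
#'   [harmonize_instruments] or [gen_mr_instruments]).
#' @return `instruments` with added columns `ratio` and `w`, zero-exposure
#'   rows removed.
#' @export
wald_weights <- function(instruments) {
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    message(sum(zero), " instrument(s) with zero exposure effect excluded")
    instruments <- instruments[!zero, , drop = FALSE]
  }
  instruments$ratio <- instruments$beta_outcome / instruments$beta_exposure
  instruments$w <- instruments$beta_exposure^2 / instruments$se_outcome^2
  instruments
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW: `beta = sum(w * ratio) / sum(w)` with
#' `SE = sum(w)^(-1/2)`, 95% CI `beta +/- 1.96 SE`, two-sided normal p.
#' Cochran's Q about the IVW slope, `Q = sum(w * (ratio - beta)^2)`, is
#' referred to chi-square with J - 1 df.
#'
#' @param instruments harmonized instruments; `ratio`/`w` columns are
#'   computed via [wald_weights] if absent. At least 2 instruments.
#' @return list with `estimate` (one-row data frame: `method`, `beta`,
#'   `se`, `ci_lo`, `ci_hi`, `p`, `n_snp`) and `heterogeneity` (`Q`, `df`,
#'   `p`).
#' @export
mr_ivw <- function(instruments) {
  if (!all(c("ratio", "w") %in% names(instruments))) {
    instruments <- wald_weights(instruments)
  }
  J <- nrow(instruments)
  if (J < 2L) stop("IVW needs at least 2 instruments")
  w <- instruments$w
  if (all(w == 0)) stop("all IVW weights are zero")
  beta <- sum(w * instruments$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (instruments$ratio - beta)^2)
  list(
    estimate = data.frame(method = "IVW", beta = beta, se = se,
                          ci_lo = beta - 1.96 * se,
                          ci_hi = beta + 1.96 * se,
                          p = 2 * stats::pnorm(-abs(beta / se)),
                          n_snp = J),
    heterogeneity = data.frame(statistic = "cochran_Q", Q = q,
                               df = J - 1L,
                               p = stats::pchisq(q, J - 1L,
                                                 lower.tail = FALSE))
  )
}

#' Radial MR-Egger regression
#'
#' Least-squares regression of the weight-scaled ratio estimates
#' `ratio * sqrt(w)` on `sqrt(w)` with a free intercept: the slope is the
#' pleiotropy-adjusted causal estimate and the intercept captures
#' directional pleiotropy. Rucker's Q is the residual sum of squares on
#' J - 2 df; standard errors are scaled by the multiplicative
#' overdispersion factor `max(1, sqrt(rucker_Q / (J - 2)))`.
#'
#' @param instruments harmonized instruments (>= 3); `ratio`/`w` computed
#'   via [wald_weights] if absent.
#' @return list with `estimate` (slope row and intercept row) and
#'   `heterogeneity` (Rucker's Q, df, p).
#' @export
mr_radial_egger <- function(instruments) {
  if (!all(c("ratio", "w") %in% names(instruments))) {
    instruments <- wald_weights(instruments)
  }
  J <- nrow(instruments)
  if (J < 3L) stop("radial MR-Egger needs at least 3 instruments")
  sw <- sqrt(instruments$w)
  if (stats::var(sw) == 0) {
    stop("collinear design: all instrument weights are equal")
  }
  X <- cbind(intercept = 1, sqrt_w = sw)
  y <- instruments$ratio * sw
  fit <- stats::lm.fit(X, y)
  rucker_q <- sum(fit$residuals^2)
  scale <- max(1, sqrt(rucker_q / (J - 2)))
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv)) * scale
  b <- fit$coefficients
  est <- data.frame(
    method = c("radial_egger", "radial_egger_intercept"),
    beta = c(b["sqrt_w"], b["intercept"]),
    se = se[c(2L, 1L)],
    n_snp = J
  )
  est$ci_lo <- est$beta - 1.96 * est$se
  est$ci_hi <- est$beta + 1.96 * est$se
  est$p <- 2 * stats::pnorm(-abs(est$beta / est$se))
  rownames(est) <- NULL
  list(
    estimate = est[, c("method", "beta", "se", "ci_lo", "ci_hi", "p",
                       "n_snp")],
    heterogeneity = data.frame(statistic = "rucker_Q", Q = rucker_q,
                               df = J - 2L,
                               p = stats::pchisq(rucker_q, J - 2L,
                                                 lower.tail = FALSE))
  )
}

#' Instrument-strength diagnostics
#'
#' Mean F statistic `mean(beta_exposure^2 / se_exposure^2)` (values above
#' ~10 conventionally indicate strong instruments) and the I2_GX statistic
#' for MR-Egger regression dilution:
#' `I2_GX = max(0, (Q_GX - (J - 1)) / Q_GX)` with
#' `Q_GX = sum((beta_exposure - gbar)^2 / se_exposure^2)` about the
#' inverse-variance-weighted mean `gbar`. Values near 1 indicate Egger
#' estimates are not attenuated by exposure measurement error.
#'
#' @param instruments harmonized instruments (>= 2).
#' @return one-row data frame: `mean_F`, `i2_gx`, `n_snp`.
#' @export
instrument_strength <- function(instruments) {
  J <- nrow(instruments)
  if (J < 2L) stop("need at least 2 instruments")
  g <- instruments$beta_exposure
  s2 <- instruments$se_exposure^2
  gbar <- sum(g / s2) / sum(1 / s2)
  q_gx <- sum((g - gbar)^2 / s2)
  data.frame(mean_F = mean(g^2 / s2),
             i2_gx = if (q_gx > 0) max(0, (q_gx - (J - 1)) / q_gx) else 0,
             n_snp = J)
}

#' Full two-sample MR analysis
#'
#' Harmonizes the two summary-statistics tables, computes Wald ratios and
#' first-order weights, estimates the IVW causal effect with Cochran's Q,
#' and -- when the Q test indicates heterogeneity (p < `egger_q_p`),
#' a marker of potential horizontal pleiotropy -- adds the radial MR-Egger
#' sensitivity estimate with Rucker's Q. Instrument-strength diagnostics
#' (mean F, I2_GX) are always reported. With `reverse = TRUE` the same
#' pipeline is rerun with the tables swapped.
#'
#' @param exposure,outcome summary-statistics data frames (see
#'   [harmonize_instruments]).
#' @param alpha_threshold significance level applied to the causal
#'   estimates after multiple-testing correction (default 0.003).
#' @param egger_q_p heterogeneity p-value below which the Egger
#'   sensitivity analysis is run (default 0.05).
#' @param reverse also run the reverse direction (default `FALSE`).
#' @return Object of class `mr_report`: list with `estimates` (all method
#'   rows, with `significant` flags), `heterogeneity`, `strength`,
#'   `n_dropped`, and optionally `reverse` (an `mr_report` for the swapped
#'   direction).
#' @export
mr_analyze <- function(exposure, outcome, alpha_threshold = 0.003,
                       egger_q_p = 0.05, reverse = FALSE) {
  harm <- harmonize_instruments(exposure, outcome)
  inst <- wald_weights(harm)
  ivw <- mr_ivw(inst)
  estimates <- ivw$estimate
  het <- ivw$heterogeneity
  if (nrow(inst) >= 3L && ivw$heterogeneity$p < egger_q_p) {
    egger <- mr_radial_egger(inst)
    estimates <- rbind(estimates, egger$estimate)
    het <- rbind(het, egger$heterogeneity)
  }
  estimates$significant <- estimates$p < alpha_threshold
  report <- structure(
    list(estimates = estimates, heterogeneity = het,
         strength = instrument_strength(inst),
         n_snp = nrow(inst),
         n_dropped = length(attr(harm, "dropped")),
         alpha_threshold = alpha_threshold),
    class = "mr_report")
  if (reverse) {
    report$reverse <- mr_analyze(outcome, exposure,
                                 alpha_threshold = alpha_threshold,
                                 egger_q_p = egger_q_p, reverse = FALSE)
  }
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d instrument(s), %d dropped\n", x$n_snp,
              x$n_dropped))
  print(x$estimates, row.names = FALSE, digits = 4)
  print(x$heterogeneity, row.names = FALSE, digits = 4)
  print(x$strength, row.names = FALSE, digits = 4)
  if (!is.null(x$reverse)) {
    cat("reverse direction:\n")
    print(x$reverse)
  }
  invisible(x)
}

#' Flatten an MR report to a tab-friendly data frame
#'
#' @param report an `mr_report` from [mr_analyze].
#' @return data frame with one row per method, carrying the heterogeneity
#'   and strength diagnostics.
#' @export
mr_report_table <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  est <- report$estimates
  est$Q <- report$heterogeneity$Q[match(
    ifelse(est$method == "IVW", "cochran_Q", "rucker_Q"),
    report$heterogeneity$statistic)]
  est$Q_df <- report$heterogeneity$df[match(
    ifelse(est$method == "IVW", "cochran_Q", "rucker_Q"),
    report$heterogeneity$statistic)]
  est$Q_p <- report$heterogeneity$p[match(
    ifelse(est$method == "IVW", "cochran_Q", "rucker_Q"),
    report$heterogeneity$statistic)]
  est$mean_F <- report$strength$mean_F
  est$i2_gx <- report$strength$i2_gx
  est$n_dropped <- report$n_dropped
  est
}
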