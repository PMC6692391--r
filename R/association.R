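# Phenotype coding, risk-allele orientation, z-matrix assembly, weighted
# genetic risk scores, association testing and Fisher's-method meta-analysis.

#' Encode raw sleep survey responses into analysis phenotypes
#'
#' Daytime sleepiness is coded continuously 1--4 with increasing severity
#' ("never/rarely" .. "all of the time"); "do not know" and "prefer not to
#' answer" become missing. Short sleep is duration < 7 h and long sleep
#' duration > 8 h, with the inclusive 7--8 h band serving as the shared
#' control group (both indicators 0). Frequent-insomnia cases are those
#' answering "usually"; chronotype is coded 1--4 towards morningness and
#' daytime napping 1--3 by frequency.
#'
#' @param raw data frame with a `person_id` column and any of:
#'   `sleepiness`, `sleep_duration_h`, `insomnia`, `chronotype`, `naps`
#'   (character responses or already-numeric codes). Other columns
#'   (covariates) pass through unchanged.
#' @return data frame with numeric `sleepiness_score`, `short_sleep`,
#'   `long_sleep`, `insomnia_case`, `chronotype`, `naps` (where inputs are
#'   present) plus the pass-through columns. Unknown category codes are
#'   flagged with a warning and set missing.
#' @export
encode_phenotypes <- function(raw) {
  stopifnot(is.data.frame(raw), "person_id" %in% names(raw))
  out <- raw
  missing_codes <- c("do not know", "prefer not to answer")
  recode <- function(x, map, what) {
    if (is.numeric(x)) return(x)
    key <- tolower(trimws(x))
    val <- map[key]
    bad <- !is.na(key) & !(key %in% c(names(map), missing_codes))
    if (any(bad)) {
      warning(sprintf("%d unknown %s code(s) set to missing: %s",
                      sum(bad), what,
                      paste(unique(key[bad]), collapse = ", ")))
    }
    unname(val)
  }
  if ("sleepiness" %in% names(raw)) {
    out$sleepiness_score <- recode(raw$sleepiness,
      c("never" = 1, "never/rarely" = 1, "sometimes" = 2, "often" = 3,
        "all of the time" = 4), "sleepiness")
    out$sleepiness <- NULL
  }
  if ("sleep_duration_h" %in% names(raw)) {
    out$short_sleep <- as.integer(raw$sleep_duration_h < 7)
    out$long_sleep <- as.integer(raw$sleep_duration_h > 8)
  }
  if ("insomnia" %in% names(raw)) {
    out$insomnia_case <- recode(raw$insomnia,
      c("never/rare" = 0, "never/rarely" = 0, "sometimes" = 0,
        "usually" = 1), "insomnia")
    out$insomnia <- NULL
  }
  if ("chronotype" %in% names(raw)) {
    out$chronotype <- recode(raw$chronotype,
      c("definitely evening" = 1, "more evening than morning" = 2,
        "more morning than evening" = 3, "definitely morning" = 4),
      "chronotype")
  }
  if ("naps" %in% names(raw)) {
    out$naps <- recode(raw$naps,
      c("never/rarely" = 1, "sometimes" = 2, "usually" = 3), "naps")
  }
  out
}

#' Read / write GWAS summary statistics
#'
#' Tab-delimited tables with header `SNP CHR POS EA OA EAF BETA SE P`
#' (1-based positions, effects on the `EA` allele).
#'
#' @param path file path.
#' @return data frame of summary statistics.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "EA", "OA", "BETA", "SE")
  if (!all(need %in% names(df))) {
    stop("summary statistics must contain columns: ",
         paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_summary_stats
#' @param stats data frame of summary statistics.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Align a companion table to the primary's effect alleles (swap -> flip)
.align_alleles <- function(primary, other) {
  m <- match(primary$SNP, other$SNP)
  other <- other[m, , drop = FALSE]
  same <- other$EA == primary$EA & other$OA == primary$OA
  swap <- other$EA == primary$OA & other$OA == primary$EA
  other$BETA[swap] <- -other$BETA[swap]
  if ("EAF" %in% names(other)) other$EAF[swap] <- 1 - other$EAF[swap]
  other$EA[swap] <- primary$EA[swap]
  other$OA[swap] <- primary$OA[swap]
  list(table = other, ok = !is.na(m) & (same | swap))
}

#' Orient summary statistics to the risk (trait-increasing) allele
#'
#' Flips alleles so that the primary-trait effect is positive at every
#' locus: at flipped loci the effect and other alleles swap, the beta
#' changes sign and the effect-allele frequency is complemented. Companion
#' trait tables are first aligned to the primary table's alleles and then
#' flipped in tandem, so their betas/z-scores stay expressed per
#' risk-increasing allele. Variants with unresolvable allele pairs in any
#' table are dropped with a message.
#'
#' @param primary primary-trait summary statistics (columns `SNP`, `EA`,
#'   `OA`, `BETA`, `SE`, optionally `EAF`, `P`).
#' @param traits named list of companion summary-statistics tables.
#' @return list with `primary`, `traits` (all oriented), and `dropped`
#'   (variant IDs removed for allele mismatch).
#' @export
orient_to_risk_allele <- function(primary, traits = list()) {
  stopifnot(is.data.frame(primary))
  keep <- rep(TRUE, nrow(primary))
  aligned <- lapply(traits, function(tb) {
    al <- .align_alleles(primary, tb)
    keep <<- keep & al$ok
    al$table
  })
  dropped <- primary$SNP[!keep]
  if (length(dropped) > 0) {
    message(length(dropped), " variant(s) dropped for allele mismatch: ",
            paste(dropped, collapse = ", "))
  }
  primary <- primary[keep, , drop = FALSE]
  aligned <- lapply(aligned, function(tb) tb[keep, , drop = FALSE])
  flip <- primary$BETA < 0
  ea <- primary$EA
  primary$EA[flip] <- primary$OA[flip]
  primary$OA[flip] <- ea[flip]
  primary$BETA[flip] <- -primary$BETA[flip]
  if ("EAF" %in% names(primary)) {
    primary$EAF[flip] <- 1 - primary$EAF[flip]
  }
  aligned <- lapply(aligned, function(tb) {
    tb$BETA[flip] <- -tb$BETA[flip]
    if ("EAF" %in% names(tb)) tb$EAF[flip] <- 1 - tb$EAF[flip]
    tb$EA <- primary$EA
    tb$OA <- primary$OA
    tb
  })
  list(primary = primary, traits = aligned, dropped = dropped)
}

#' Assemble the locus-by-trait z-score matrix
#'
#' z = beta / SE per locus and trait, columns in a fixed trait order. Loci
#' missing from any trait table are excluded with a warning.
#'
#' @param traits named list of oriented summary-statistics tables (e.g.
#'   `orient_to_risk_allele(...)$traits`).
#' @param trait_order column order; defaults to `names(traits)`.
#' @return numeric matrix, loci as rows (named by `SNP`), traits as
#'   columns.
#' @export
build_z_matrix <- function(traits, trait_order = names(traits)) {
  stopifnot(length(traits) >= 1, !is.null(names(traits)),
            all(trait_order %in% names(traits)))
  loci <- Reduce(intersect, lapply(traits, function(tb) tb$SNP))
  all_loci <- unique(unlist(lapply(traits, function(tb) tb$SNP)))
  if (length(miss <- setdiff(all_loci, loci)) > 0) {
    warning("excluding ", length(miss),
            " locus/loci missing from some trait table(s): ",
            paste(miss, collapse = ", "))
  }
  z <- vapply(trait_order, function(tr) {
    tb <- traits[[tr]]
    i <- match(loci, tb$SNP)
    tb$BETA[i] / tb$SE[i]
  }, numeric(length(loci)))
  z <- matrix(z, nrow = length(loci),
              dimnames = list(loci, trait_order))
  z
}

#' Weighted genetic risk score
#'
#' Per-individual score: the sum over variants of risk-allele dosage times
#' the discovery-GWAS effect estimate. Missing dosages are imputed with the
#' per-variant mean dosage (logged).
#'
#' @param dosages individuals x variants numeric matrix with entries in
#'   \[0, 2\], columns named by variant ID.
#' @param weights named numeric vector of per-allele weights aligned to
#'   the risk allele.
#' @return numeric vector of scores, named by individual.
#' @export
compute_grs <- function(dosages, weights) {
  stopifnot(is.matrix(dosages))
  if (is.null(names(weights)) || is.null(colnames(dosages))) {
    if (length(weights) != ncol(dosages)) {
      stop("unnamed weights must match the number of variants")
    }
    shared <- seq_len(ncol(dosages))
  } else {
    shared <- intersect(colnames(dosages), names(weights))
    if (length(shared) == 0L) {
      stop("no variants shared between dosages and weights")
    }
    weights <- weights[shared]
  }
  d <- dosages[, shared, drop = FALSE]
  if (anyNA(d)) {
    n_miss <- sum(is.na(d))
    message("mean-imputing ", n_miss, " missing dosage value(s)")
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  if (any(d < 0 | d > 2)) stop("dosages must lie within [0, 2]")
  drop(d %*% as.numeric(weights))
}

#' Linear association test
#'
#' Ordinary least squares of `y` on `x` adjusting for covariates;
#' two-sided p from the t statistic.
#'
#' @param y numeric outcome.
#' @param x predictor of interest (e.g. a GRS).
#' @param covariates optional data frame of adjustment covariates.
#' @return one-row data frame: `beta`, `se`, `statistic`, `p`, `n`.
#' @export
assoc_linear <- function(y, x, covariates = NULL) {
  df <- .assoc_frame(y, x, covariates)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (!"x" %in% rownames(cf)) {
    stop("predictor is constant or collinear with covariates")
  }
  data.frame(beta = cf["x", 1L], se = cf["x", 2L],
             statistic = cf["x", 3L], p = cf["x", 4L],
             n = stats::nobs(fit))
}

#' Logistic association test
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, up to 50
#' iterations) of a binary outcome on `x` adjusting for covariates. The
#' odds ratio is `exp(beta)` with Wald 95% CI `exp(beta +/- 1.96 se)`;
#' two-sided p from the normal approximation.
#'
#' @param y binary outcome (0/1), both classes present.
#' @param x predictor of interest.
#' @param covariates optional data frame of adjustment covariates.
#' @return one-row data frame: `beta`, `se`, `statistic`, `p`, `or`,
#'   `or_lo`, `or_hi`, `n`.
#' @export
assoc_logistic <- function(y, x, covariates = NULL) {
  df <- .assoc_frame(y, x, covariates)
  if (length(unique(df$y)) < 2L) {
    stop("both outcome classes must be present")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  )
  if (!fit$converged) warning("logistic fit did not converge")
  cf <- summary(fit)$coefficients
  if (!"x" %in% rownames(cf)) {
    stop("predictor is constant or collinear with covariates")
  }
  b <- cf["x", 1L]; se <- cf["x", 2L]
  if (abs(b) > 15) {
    warning("extreme estimate; possible complete separation")
  }
  data.frame(beta = b, se = se, statistic = b / se,
             p = 2 * stats::pnorm(-abs(b / se)),
             or = exp(b), or_lo = exp(b - 1.96 * se),
             or_hi = exp(b + 1.96 * se), n = stats::nobs(fit))
}

.assoc_frame <- function(y, x, covariates) {
  stopifnot(length(y) == length(x))
  if (stats::var(x, na.rm = TRUE) == 0) stop("predictor is constant")
  df <- data.frame(y = y, x = x)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 2L) stop("too few complete observations")
  df
}

#' Fisher's combined probability meta-analysis
#'
#' Combines independent cohort p-values: `X = -2 * sum(log(p))` is
#' chi-square with `2K` degrees of freedom under the global null, and the
#' combined p is its upper tail. A zero p-value is rejected; callers who
#' need one should floor it explicitly (e.g. at machine epsilon).
#'
#' @param p numeric vector of per-cohort p-values in (0, 1\].
#' @return one-row data frame: `statistic`, `df`, `p`.
#' @export
fisher_meta <- function(p) {
  if (length(p) < 1L || anyNA(p)) stop("need at least one p-value")
  if (any(p <= 0)) {
    stop("p-values must be strictly positive; floor zeros explicitly ",
         "(e.g. at .Machine$double.xmin) before combining")
  }
  if (any(p > 1)) stop("p-values cannot exceed 1")
  x <- -2 * sum(log(p))
  data.frame(statistic = x, df = 2L * length(p),
             p = stats::pchisq(x, 2 * length(p), lower.tail = FALSE))
}

#' Bonferroni significance flag
#'
#' @param p p-value(s).
#' @param m_tests number of tests corrected for.
#' @return logical, `TRUE` where `p < 0.05 / m_tests`.
#' @export
bonferroni_flag <- function(p, m_tests) {
  stopifnot(m_tests >= 1)
  p < 0.05 / m_tests
}

#' Read a dosage matrix
#'
#' `read_dosage_csv` reads a CSV with individuals in rows (first column
#' `person_id`) and variants in columns. `read_dosage_vcf` reads the `DS`
#' FORMAT field of a VCF (requires the `vcfR` package) and returns the
#' same individuals x variants orientation, dosages coded on the ALT
#' allele.
#'
#' @param path file path.
#' @return numeric matrix, individuals x variants.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_dosage_csv
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  t(ds)
}
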