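# Seeded generators for every input the pipeline consumes, each returning
# the simulated data together with the ground truth needed to score the
# downstream stage. All generators are pure functions of (config, seed).

#' Configuration for a synthetic accelerometer trace
#'
#' Describes a multi-day wrist recording with one planted nocturnal sleep
#' window per noon-to-noon analysis day. During the sleep window the z-angle
#' is held at a constant posture angle (apart from a configurable number of
#' discrete posture changes); outside it the wrist moves continuously, so
#' consecutive epochs differ by large angles. Gaussian measurement noise is
#' added everywhere.
#'
#' @param n_days number of noon-to-noon days (default 7, a typical wear
#'   protocol).
#' @param epoch_seconds epoch length in seconds (default 5).
#' @param sleep_onset_min,sleep_wake_min planted sleep onset/wake, minutes
#'   from the day start at noon (defaults 660 and 1140, i.e. 23:00--07:00).
#' @param angle_noise_sd measurement noise SD in degrees (default 1).
#' @param n_posture_changes_in_sleep discrete posture shifts planted inside
#'   each sleep window (default 2).
#' @param daytime_nap optional `c(start_min, end_min)` window (minutes from
#'   noon) of planted daytime stillness, exercising the diurnal-inactivity
#'   logic. `NULL` for none.
#' @param day_movement_sd SD (degrees) of the independent per-epoch daytime
#'   wrist angles (default 30).
#' @param activity_day_mean,activity_night_mean mean activity magnitude in
#'   and outside planted stillness (defaults 100 and 2, arbitrary units).
#' @param seed integer RNG seed.
#' @return A validated `accel_sim_config` list.
#' @export
accel_sim_config <- function(n_days = 7, epoch_seconds = 5,
                             sleep_onset_min = 660, sleep_wake_min = 1140,
                             angle_noise_sd = 1,
                             n_posture_changes_in_sleep = 2,
                             daytime_nap = NULL,
                             day_movement_sd = 30,
                             activity_day_mean = 100,
                             activity_night_mean = 2,
                             seed = 1L) {
  stopifnot(n_days >= 1, epoch_seconds > 0, angle_noise_sd >= 0,
            n_posture_changes_in_sleep >= 0, day_movement_sd > 0)
  if (sleep_onset_min >= sleep_wake_min) {
    stop("invalid planted window: sleep onset must precede wake")
  }
  if (sleep_wake_min - sleep_onset_min <= 30) {
    stop("planted sleep window must exceed 30 minutes")
  }
  epm <- epoch_seconds / 60
  for (m in c(sleep_onset_min, sleep_wake_min, daytime_nap)) {
    if (abs(m / epm - round(m / epm)) > 1e-9) {
      stop("window boundaries must be whole numbers of epochs")
    }
  }
  if (!is.null(daytime_nap)) {
    stopifnot(length(daytime_nap) == 2L, daytime_nap[1L] < daytime_nap[2L],
              daytime_nap[1L] >= 0, daytime_nap[2L] <= 1440)
  }
  structure(as.list(environment()), class = "accel_sim_config")
}

#' Generate a synthetic accelerometer trace with known sleep windows
#'
#' @param cfg an [accel_sim_config].
#' @return A list with `trace` (an [accel_epochs]) and `truth`, a data frame
#'   with one row per day giving the planted onset/wake in minutes from the
#'   day start (noon) and as 1-based global epoch indices (half-open
#'   `[onset_epoch, wake_epoch)`).
#' @export
gen_accel_trace <- function(cfg) {
  stopifnot(inherits(cfg, "accel_sim_config"))
  set.seed(cfg$seed)
  epd <- round(86400 / cfg$epoch_seconds)          # epochs per day
  to_ep <- function(min) round(min * 60 / cfg$epoch_seconds)
  n <- cfg$n_days * epd
  z <- pmin(88, pmax(-88, stats::rnorm(n, 0, cfg$day_movement_sd)))
  activity <- stats::rexp(n, 1 / cfg$activity_day_mean)

  plant_still <- function(z, activity, from, to, n_changes) {
    idx <- (from + 1L):to                          # 1-based epochs in window
    angle <- stats::runif(1, -45, 45)
    z[idx] <- angle
    if (n_changes > 0) {
      at <- sort(sample(idx[-1L], n_changes))
      bounds <- c(at, to + 1L)
      for (j in seq_len(n_changes)) {
        repeat {                                   # new posture >= 20 deg away
          cand <- stats::runif(1, -60, 60)
          if (abs(cand - angle) >= 20) break
        }
        angle <- cand
        z[bounds[j]:(bounds[j + 1L] - 1L)] <- angle
      }
    }
    activity[idx] <- stats::rexp(length(idx), 1 / cfg$activity_night_mean)
    list(z = z, activity = activity)
  }

  truth <- data.frame(day = seq_len(cfg$n_days),
                      onset_min = cfg$sleep_onset_min,
                      wake_min = cfg$sleep_wake_min,
                      onset_epoch = NA_integer_, wake_epoch = NA_integer_)
  for (d in seq_len(cfg$n_days)) {
    off <- (d - 1L) * epd
    from <- off + to_ep(cfg$sleep_onset_min)
    to <- off + to_ep(cfg$sleep_wake_min)
    out <- plant_still(z, activity, from, to, cfg$n_posture_changes_in_sleep)
    z <- out$z; activity <- out$activity
    truth$onset_epoch[d] <- from + 1L
    truth$wake_epoch[d] <- to + 1L
    if (!is.null(cfg$daytime_nap)) {
      nap <- plant_still(z, activity, off + to_ep(cfg$daytime_nap[1L]),
                         off + to_ep(cfg$daytime_nap[2L]), 0L)
      z <- nap$z; activity <- nap$activity
    }
  }
  if (cfg$angle_noise_sd > 0) {
    z <- z + stats::rnorm(n, 0, cfg$angle_noise_sd)
  }
  z <- pmin(90, pmax(-90, z))
  list(trace = accel_epochs(z, activity, epoch_seconds = cfg$epoch_seconds,
                            person_id = sprintf("sim_seed%d", cfg$seed)),
       truth = truth)
}

#' Configuration for a synthetic genotyped cohort
#'
#' Hardy--Weinberg genotypes at independent variants plus a trait driven
#' linearly (or through a logistic link) by the weighted genetic risk score.
#'
#' @param n_individuals,n_variants cohort dimensions (defaults 5000 and 42,
#'   the size of the sleepiness locus set).
#' @param maf_vector per-variant minor-allele frequencies in (0, 0.5];
#'   default spans 0.08--0.49, the frequency range of common lead variants.
#' @param weight_vector per-allele effect weights; default spans 0.01--0.04,
#'   the scale of per-allele effects on a 4-point symptom score.
#' @param grs_effect slope of the trait on the GRS (default 1, sized so
#'   the planted effect is estimable at desk-scale cohort sizes: with the
#'   default weights the GRS SD is about 0.1 trait units).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param baseline_prevalence marginal case probability for binary traits;
#'   the logistic intercept is solved numerically so the simulated
#'   prevalence matches it in expectation.
#' @param noise_sd residual SD for quantitative traits.
#' @param seed integer RNG seed.
#' @return A validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_individuals = 5000, n_variants = 42,
                              maf_vector = NULL, weight_vector = NULL,
                              grs_effect = 1,
                              trait_type = c("quantitative", "binary"),
                              baseline_prevalence = 0.1, noise_sd = 1,
                              seed = 1L) {
  trait_type <- match.arg(trait_type)
  if (is.null(maf_vector)) {
    maf_vector <- seq(0.08, 0.49, length.out = n_variants)
  }
  if (is.null(weight_vector)) {
    weight_vector <- seq(0.01, 0.04, length.out = n_variants)
  }
  stopifnot(n_individuals >= 2, n_variants >= 1, noise_sd >= 0,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (length(maf_vector) != n_variants ||
      length(weight_vector) != n_variants) {
    stop("maf_vector and weight_vector must have length n_variants")
  }
  if (any(maf_vector <= 0 | maf_vector > 0.5)) {
    stop("minor-allele frequencies must lie in (0, 0.5]")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Generate a synthetic cohort with a planted GRS effect
#'
#' @param cfg a [cohort_sim_config].
#' @return A list with `genotypes` (individuals x variants dosage matrix
#'   with entries in \{0, 1, 2\}), `phenotypes` (data frame with
#'   `person_id`, `trait`, and nuisance covariates `age`, `sex`), and
#'   `truth` (weights, MAFs, the realised GRS vector, the planted slope,
#'   and for binary traits the solved intercept).
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; m <- cfg$n_variants
  G <- vapply(seq_len(m),
              function(j) stats::rbinom(n, 2L, cfg$maf_vector[j]),
              integer(n))
  dimnames(G) <- list(sprintf("id_%04d", seq_len(n)),
                      sprintf("rs%05d", seq_len(m)))
  grs <- as.vector(G %*% cfg$weight_vector)
  intercept <- NA_real_
  if (cfg$trait_type == "quantitative") {
    trait <- cfg$grs_effect * grs + stats::rnorm(n, 0, cfg$noise_sd)
  } else {
    intercept <- stats::uniroot(
      function(b0) mean(stats::plogis(b0 + cfg$grs_effect * grs)) -
        cfg$baseline_prevalence,
      interval = c(-30, 30), tol = 1e-10)$root
    trait <- stats::rbinom(n, 1L, stats::plogis(intercept +
                                                  cfg$grs_effect * grs))
  }
  phen <- data.frame(person_id = rownames(G), trait = trait,
                     age = round(stats::runif(n, 40, 69)),
                     sex = stats::rbinom(n, 1L, 0.5))
  list(genotypes = G, phenotypes = phen,
       truth = list(weights = stats::setNames(cfg$weight_vector,
                                              colnames(G)),
                    maf = cfg$maf_vector, grs = grs,
                    grs_effect = cfg$grs_effect, intercept = intercept))
}

#' Configuration for a synthetic locus-by-trait z-score matrix
#'
#' Emulates the risk-allele-oriented z-score matrix over the four
#' subtype-defining traits (sleep efficiency, sleep duration, number of
#' sleep bouts, insomnia). Sleep-propensity loci follow the sign template
#' (+, +, -, -), fragmentation loci (-, -, +, +), and outliers get
#' randomized off-template sign patterns.
#'
#' @param n_propensity,n_fragmentation,n_outliers locus counts (defaults
#'   10, 27 and 5, the composition of the 42-locus sleepiness set).
#' @param mean_abs_z per-trait signal magnitude (default 3).
#' @param z_noise_sd additive z-score noise SD (default 1).
#' @param seed integer RNG seed.
#' @return A validated `zmatrix_sim_config` list.
#' @export
zmatrix_sim_config <- function(n_propensity = 10, n_fragmentation = 27,
                               n_outliers = 5, mean_abs_z = 3,
                               z_noise_sd = 1, seed = 1L) {
  stopifnot(n_propensity >= 0, n_fragmentation >= 0, n_outliers >= 0,
            mean_abs_z > 0, z_noise_sd >= 0)
  if (n_propensity + n_fragmentation < 2) {
    stop("need at least two template loci to cluster")
  }
  structure(as.list(environment()), class = "zmatrix_sim_config")
}

#' Trait columns of the subtype z-score matrix, in their fixed order
#' @export
subtype_trait_order <- c("z_efficiency", "z_duration", "z_bouts",
                         "z_insomnia")

# Sleep-propensity sign template over (efficiency, duration, bouts, insomnia)
propensity_template <- c(1, 1, -1, -1)

#' Generate a locus-by-trait z-score matrix with planted subtypes
#'
#' @param cfg a [zmatrix_sim_config].
#' @return A list with `z` (loci x 4 matrix, columns
#'   [subtype_trait_order]) and `labels` (factor with levels `propensity`,
#'   `fragmentation`, `outlier`).
#' @export
gen_locus_z_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "zmatrix_sim_config"))
  set.seed(cfg$seed)
  templates <- rbind(propensity = propensity_template,
                     fragmentation = -propensity_template)
  labels <- rep(c("propensity", "fragmentation", "outlier"),
                c(cfg$n_propensity, cfg$n_fragmentation, cfg$n_outliers))
  n <- length(labels)
  z <- matrix(NA_real_, n, 4,
              dimnames = list(sprintf("locus_%02d", seq_len(n)),
                              subtype_trait_order))
  for (i in seq_len(n)) {
    signs <- if (labels[i] == "outlier") {
      repeat {                                     # off-template pattern
        s <- sample(c(-1, 1), 4, replace = TRUE)
        if (!all(s == templates[1L, ]) && !all(s == templates[2L, ])) break
      }
      s
    } else {
      templates[labels[i], ]
    }
    z[i, ] <- cfg$mean_abs_z * signs + stats::rnorm(4, 0, cfg$z_noise_sd)
  }
  list(z = z, labels = factor(labels, levels = c("propensity",
                                                 "fragmentation",
                                                 "outlier")))
}

#' Configuration for synthetic two-sample MR instruments
#'
#' Summary-level instrument sets with a planted causal slope and optional
#' horizontal pleiotropy. Per instrument j: true exposure effect
#' `gamma_j ~ N(gamma_mean, gamma_sd)`, observed exposure effect
#' `gamma_j + N(0, se_exposure)`, observed outcome effect
#' `true_beta * gamma_j + alpha_j + N(0, se_outcome)` where the pleiotropic
#' intercept `alpha_j` is 0 (`none`), mean-zero (`balanced`) or has nonzero
#' mean (`directional`). By default `alpha_j` is drawn independently of
#' `gamma_j`, satisfying the InSIDE assumption MR-Egger relies on;
#' `inside_violation = TRUE` correlates them instead.
#'
#' @param n_instruments number of instruments J (default 100); at least 3.
#' @param true_beta planted causal slope (default 0.018, the scale of a
#'   small exposure effect on a 4-point symptom score).
#' @param gamma_mean,gamma_sd exposure-effect distribution (defaults
#'   0.068 and 0.04).
#' @param se_exposure,se_outcome per-instrument standard errors (defaults
#'   0.014 and 0.01). The defaults give a mean instrument F statistic of
#'   about 33 and an I2_GX of about 0.89 -- the strong-instrument regime
#'   reported for well-powered anthropometric exposures.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic-effect distribution
#'   (used per `pleiotropy_mode`).
#' @param inside_violation if `TRUE`, `alpha_j` is made to covary with
#'   `gamma_j`; Egger recovery guarantees then no longer apply.
#' @param seed integer RNG seed.
#' @return A validated `mr_sim_config` list.
#' @export
mr_sim_config <- function(n_instruments = 100, true_beta = 0.018,
                          gamma_mean = 0.068, gamma_sd = 0.04,
                          se_exposure = 0.014, se_outcome = 0.01,
                          pleiotropy_mode = c("none", "balanced",
                                              "directional"),
                          pleiotropy_mean = 0, pleiotropy_sd = 0,
                          inside_violation = FALSE, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_instruments < 3) stop("need at least 3 instruments")
  stopifnot(se_exposure > 0, se_outcome > 0, gamma_sd >= 0,
            pleiotropy_sd >= 0)
  structure(as.list(environment()), class = "mr_sim_config")
}

#' Generate a harmonized synthetic instrument set
#'
#' @param cfg an [mr_sim_config].
#' @return A list with `instruments` (data frame with columns `SNP`, `EA`,
#'   `OA`, `EAF`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`) and `truth` (planted slope, true `gamma`, pleiotropic
#'   `alpha`).
#' @export
gen_mr_instruments <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  set.seed(cfg$seed)
  J <- cfg$n_instruments
  gamma <- stats::rnorm(J, cfg$gamma_mean, cfg$gamma_sd)
  alpha <- switch(cfg$pleiotropy_mode,
                  none = numeric(J),
                  balanced = stats::rnorm(J, 0, cfg$pleiotropy_sd),
                  directional = stats::rnorm(J, cfg$pleiotropy_mean,
                                             cfg$pleiotropy_sd))
  if (cfg$inside_violation && cfg$gamma_sd > 0) {
    alpha <- alpha + cfg$pleiotropy_sd * (gamma - cfg$gamma_mean) /
      cfg$gamma_sd
  }
  beta_exp <- gamma + stats::rnorm(J, 0, cfg$se_exposure)
  beta_out <- cfg$true_beta * gamma + alpha +
    stats::rnorm(J, 0, cfg$se_outcome)
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  al <- pairs[sample.int(4L, J, replace = TRUE), , drop = FALSE]
  instruments <- data.frame(
    SNP = sprintf("rs%06d", sample.int(999999L, J)),
    EA = al[, 1L], OA = al[, 2L],
    EAF = round(stats::runif(J, 0.05, 0.95), 4),
    beta_exposure = beta_exp, se_exposure = cfg$se_exposure,
    beta_outcome = beta_out, se_outcome = cfg$se_outcome
  )
  list(instruments = instruments,
       truth = list(true_beta = cfg$true_beta, gamma = gamma,
                    alpha = alpha))
}

#' Split a synthetic instrument set into exposure/outcome summary tables
#'
#' Rewrites the output of [gen_mr_instruments] as the pair of
#' summary-statistics tables [harmonize_instruments] expects, so the full
#' harmonization path can be exercised.
#'
#' @param instruments data frame from [gen_mr_instruments].
#' @return List with `exposure` and `outcome` summary-statistics tables.
#' @export
instruments_as_tables <- function(instruments) {
  base <- data.frame(SNP = instruments$SNP, CHR = 1L,
                     POS = seq_len(nrow(instruments)),
                     EA = instruments$EA, OA = instruments$OA,
                     EAF = instruments$EAF)
  list(exposure = cbind(base, BETA = instruments$beta_exposure,
                        SE = instruments$se_exposure,
                        P = 2 * stats::pnorm(-abs(instruments$beta_exposure /
                                                    instruments$se_exposure))),
       outcome = cbind(base, BETA = instruments$beta_outcome,
                       SE = instruments$se_outcome,
                       P = 2 * stats::pnorm(-abs(instruments$beta_outcome /
                                                   instruments$se_outcome))))
}
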