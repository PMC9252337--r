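#' Simulate a longitudinal Parkinson's disease cohort
#'
#' Generates a cohort with the longitudinal, genetic and treatment structure
#' the next-visit ICD prediction task assumes, together with the ground truth
#' that produced it (per-visit true event probabilities and the coefficients
#' used), so that signal recovery is testable downstream.
#'
#' Each subject gets a baseline visit at time 0 and at least one follow-up at
#' strictly increasing, irregular times. Clinical scales evolve as Gaussian
#' AR(1) processes around subject-level means. Medication follows a simple
#' per-visit start/stop policy with piecewise-constant dopamine-agonist
#' dosing in levodopa equivalents; the drug-naive dialect has no exposure at
#' baseline. ICD status is generated sequentially by a first-order Markov
#' logistic hazard: the status at each visit after baseline is Bernoulli with
#' logit equal to a linear predictor over the previous visit's standardized
#' covariates, the previous ICD status, and cumulative dopamine-agonist
#' exposure at the previous visit. Covariates are standardized with the
#' configured population moments (clinical scales and age), Hardy-Weinberg
#' moments (SNP dosages), and fixed exposure scales (2 years of cumulative
#' duration, 500 LEDD-years of total dose) so that coefficients are log-odds
#' per standard-deviation-like unit.
#'
#' @param config An [cohort_config()] object.
#' @return An object of class `icd_cohort`: a list with tibbles `visits`
#'   (long format: subject, time, scales, ICD status, treatment flags, daily
#'   dopamine-agonist dose), `static` (age, sex, SNP dosages), `medication`
#'   (treatment intervals), a `ground_truth` list (per-visit true
#'   probabilities and the realized coefficients), and `meta`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 20, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "icd_cohort_config")) {
    abort_config("`config` must be created by cohort_config().")
  }
  set.seed(config$seed)
  n <- config$n_subjects
  fx <- config$effect_sizes
  policy <- config$treatment_policy
  scales <- config$scale_specs
  age_mu <- if (config$dialect == "drugnaive_baseline") 60.67 else 58.99
  age_sd <- if (config$dialect == "drugnaive_baseline") 9.71 else 9.75

  # --- static layer -------------------------------------------------------
  age <- rnorm(n, age_mu, age_sd)
  sex <- rbinom(n, 1, 0.65)             # 1 = male
  geno <- simulate_genotypes(n, config$n_snps, config$maf_range,
                             seed = NULL)
  maf <- attr(geno, "maf")
  gamma <- rep_len(fx$snp, config$n_snps)
  # standardized genotype contribution, fixed per subject
  geno_z <- sweep(geno, 2, 2 * maf, "-")
  geno_z <- sweep(geno_z, 2, sqrt(pmax(2 * maf * (1 - maf), 1e-12)), "/")
  snp_term <- as.numeric(geno_z %*% gamma)

  # --- visit counts and times --------------------------------------------
  n_visits <- pmax(2L, as.integer(round(
    rnorm(n, config$visits_per_subject$mean, config$visits_per_subject$sd))))
  total <- sum(n_visits)
  gaps <- pmax(config$interval_years$floor,
               rnorm(total - n, config$interval_years$mean, config$interval_years$sd))

  subj_id <- rep(seq_len(n), n_visits)
  visit_no <- sequence(n_visits)
  time_years <- numeric(total)
  gap_idx <- 0L
  row0 <- cumsum(c(0L, n_visits))       # row offset per subject

  scale_names <- names(scales)
  scale_vals <- matrix(NA_real_, total, length(scale_names),
                       dimnames = list(NULL, scale_names))
  on_flags <- matrix(0L, total, 3, dimnames = list(NULL, c("levodopa", "dopamine_agonist", "other")))
  da_dose_visit <- numeric(total)
  icd <- integer(total)
  p_true <- rep(NA_real_, total)        # P(icd at this visit), visits >= 2

  med_rows <- vector("list", n)

  for (i in seq_len(n)) {
    Ti <- n_visits[i]
    rows <- (row0[i] + 1L):(row0[i] + Ti)
    t_i <- c(0, cumsum(gaps[(gap_idx + 1L):(gap_idx + Ti - 1L)]))
    gap_idx <- gap_idx + Ti - 1L
    time_years[rows] <- t_i

    # clinical scales: AR(1) around a subject-level mean
    for (s in scale_names) {
      sp <- scales[[s]]
      mu_i <- rnorm(1, sp$mean, 0.6 * sp$sd)
      wsd <- 0.8 * sp$sd
      x <- numeric(Ti)
      x[1] <- mu_i + rnorm(1, 0, wsd)
      if (Ti > 1) {
        innov <- rnorm(Ti - 1, 0, wsd * sqrt(1 - sp$ar1^2))
        for (v in 2:Ti) x[v] <- mu_i + sp$ar1 * (x[v - 1] - mu_i) + innov[v - 1]
      }
      scale_vals[rows, s] <- x
    }

    # medication states per class, piecewise-constant dosing for agonists
    med <- simulate_medication(t_i, policy)
    on_flags[rows, ] <- med$flags
    da_dose_visit[rows] <- med$da_dose
    if (nrow(med$intervals)) {
      med$intervals$subject_id <- i
      med_rows[[i]] <- med$intervals
    }

    # cumulative dopamine-agonist exposure at each visit time
    da_int <- med$intervals[med$intervals$drug_class == "dopamine_agonist", , drop = FALSE]
    expo <- vapply(t_i, function(tt) da_exposure_at(da_int, tt), numeric(4))

    # sequential ICD outcomes (first-order Markov logistic hazard)
    z_scales <- vapply(scale_names, function(s) {
      (scale_vals[rows, s] - scales[[s]]$mean) / scales[[s]]$sd
    }, numeric(Ti))
    if (Ti == 1L) z_scales <- matrix(z_scales, nrow = 1)
    static_term <- fx$age * (age[i] - age_mu) / age_sd + fx$sex * sex[i] + snp_term[i]
    icd_i <- integer(Ti)
    for (v in seq_len(Ti)) {
      ref <- if (v == 1L) 1L else v - 1L   # covariates at the previous visit
      eta <- fx$intercept + static_term +
        (if (v == 1L) 0 else fx$prev * icd_i[v - 1]) +
        fx$da_duration * expo[4, ref] / 2 +
        fx$da_dose * expo[3, ref] / 500 +
        fx$anxiety * z_scales[ref, "anxiety"] +
        fx$depression * z_scales[ref, "depression"] +
        fx$rem * z_scales[ref, "rem"] +
        fx$motor * z_scales[ref, "updrs3"]
      p <- sigmoid(eta)
      icd_i[v] <- rbinom(1, 1, p)
      if (v > 1L) p_true[rows[v]] <- p
    }
    icd[rows] <- icd_i
  }

  visits <- tibble::tibble(
    subject_id = subj_id, visit = visit_no, time_years = time_years,
    anxiety = scale_vals[, "anxiety"], depression = scale_vals[, "depression"],
    rem = scale_vals[, "rem"], updrs3 = scale_vals[, "updrs3"],
    icd = icd,
    on_levodopa = on_flags[, "levodopa"],
    on_dopamine_agonist = on_flags[, "dopamine_agonist"],
    on_other = on_flags[, "other"],
    da_daily_dose = da_dose_visit
  )
  attr(geno, "maf") <- NULL
  colnames(geno) <- paste0("snp_", seq_len(config$n_snps))
  static <- tibble::tibble(subject_id = seq_len(n), age = age, sex = sex) |>
    dplyr::bind_cols(tibble::as_tibble(geno))
  medication <- dplyr::bind_rows(med_rows)
  if (nrow(medication)) {
    medication <- tibble::as_tibble(medication)[, c("subject_id", "drug_class",
                                                    "start_years", "end_years",
                                                    "daily_dose_ledd")]
  } else {
    medication <- tibble::tibble(subject_id = integer(), drug_class = character(),
                                 start_years = numeric(), end_years = numeric(),
                                 daily_dose_ledd = numeric())
  }

  ground_truth <- list(
    coefficients = fx,
    maf = maf,
    probabilities = tibble::tibble(
      subject_id = subj_id, visit = visit_no, p_true = p_true
    ) |> dplyr::filter(!is.na(.data$p_true))
  )

  new_icd_cohort(visits, static, medication,
                 meta = list(config = config), ground_truth = ground_truth)
}

# per-subject medication simulation over visit times t (length >= 2)
simulate_medication <- function(t, policy) {
  Ti <- length(t)
  classes <- c("levodopa", "dopamine_agonist", "other")
  flags <- matrix(0L, Ti, 3, dimnames = list(NULL, classes))
  da_dose <- numeric(Ti)
  ivs <- list()
  horizon <- t[Ti] + 1      # open-ended treatment extends past follow-up
  for (cl in classes) {
    on <- rbinom(1, 1, policy$p_baseline[[cl]]) == 1L
    dose <- if (cl == "dopamine_agonist" && on) runif(1, policy$da_dose_range[1], policy$da_dose_range[2]) else 0
    start_t <- if (on) t[1] else NA_real_
    for (v in seq_len(Ti)) {
      if (v > 1) {
        if (on && rbinom(1, 1, policy$p_stop[[cl]]) == 1L) {
          ivs[[length(ivs) + 1L]] <- list(drug_class = cl, start_years = start_t,
                                          end_years = t[v], daily_dose_ledd = dose)
          on <- FALSE; dose <- 0
        } else if (!on && rbinom(1, 1, policy$p_start[[cl]]) == 1L) {
          on <- TRUE; start_t <- t[v]
          dose <- if (cl == "dopamine_agonist") runif(1, policy$da_dose_range[1], policy$da_dose_range[2]) else 0
        } else if (on && cl == "dopamine_agonist" &&
                   rbinom(1, 1, policy$p_dose_change) == 1L) {
          ivs[[length(ivs) + 1L]] <- list(drug_class = cl, start_years = start_t,
                                          end_years = t[v], daily_dose_ledd = dose)
          start_t <- t[v]
          dose <- runif(1, policy$da_dose_range[1], policy$da_dose_range[2])
        }
      }
      flags[v, cl] <- as.integer(on)
      if (cl == "dopamine_agonist") da_dose[v] <- if (on) dose else 0
    }
    if (on) {
      ivs[[length(ivs) + 1L]] <- list(drug_class = cl, start_years = start_t,
                                      end_years = horizon, daily_dose_ledd = dose)
    }
  }
  intervals <- if (length(ivs)) {
    do.call(rbind.data.frame, c(ivs, list(stringsAsFactors = FALSE)))
  } else {
    data.frame(drug_class = character(), start_years = numeric(),
               end_years = numeric(), daily_dose_ledd = numeric())
  }
  list(flags = flags, da_dose = da_dose, intervals = intervals)
}

# (mean_daily, max_daily, total_dose, cum_duration) at time tt from DA intervals
da_exposure_at <- function(intervals, tt) {
  if (!nrow(intervals) || tt <= 0) {
    if (tt < 0) abort_arg("exposure time must be non-negative.")
    return(c(0, 0, 0, 0))
  }
  overlap <- pmax(0, pmin(intervals$end_years, tt) - intervals$start_years)
  dur <- sum(overlap)
  tot <- sum(intervals$daily_dose_ledd * overlap)
  mx <- if (any(overlap > 0)) max(intervals$daily_dose_ledd[overlap > 0]) else 0
  mn <- if (dur > 0) tot / dur else 0
  c(mn, mx, tot, dur)
}

#' Simulate a Hardy-Weinberg SNP dosage matrix
#'
#' Each SNP's minor allele frequency is drawn uniformly in `maf_range`, and
#' dosages are Binomial(2, MAF) counts in \{0, 1, 2\} (Hardy-Weinberg by
#' construction; no LD between SNPs).
#'
#' @param n_subjects,n_snps Positive counts.
#' @param maf_range Pair in (0, 0.5].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Integer matrix `n_subjects x n_snps` with attribute `maf`.
#' @examples
#' g <- simulate_genotypes(100, 31, c(0.05, 0.5), seed = 1)
#' dim(g)
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_range, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_snps <- check_count(n_snps, "n_snps")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5)) {
    abort_config("`maf_range` must be a pair within (0, 0.5].")
  }
  if (!is.null(seed)) set.seed(seed)
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  g <- vapply(maf, function(p) rbinom(n_subjects, 2L, p), integer(n_subjects))
  if (n_subjects == 1L) g <- matrix(g, nrow = 1)
  attr(g, "maf") <- maf
  g
}

#' Mask clinical scale values completely at random
#'
#' Sets each maskable clinical value (anxiety, depression, REM sleep, motor
#' exam) independently to missing with its per-scale rate. ICD status, sex,
#' age and medication columns are never masked. To keep baseline-mean
#' imputation computable, at least one baseline value per scale is always
#' retained across the cohort.
#'
#' @param cohort An `icd_cohort`.
#' @param missing_rate Named per-scale probabilities in [0, 1); defaults to
#'   the cohort's configured rates.
#' @param seed Integer seed.
#' @return The cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, missing_rate = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "icd_cohort"))
  if (is.null(missing_rate)) missing_rate <- cohort$meta$config$missing_rate
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    abort_config("`missing_rate` entries must lie in [0, 1).")
  }
  set.seed(seed)
  visits <- cohort$visits
  for (s in names(missing_rate)) {
    rate <- missing_rate[[s]]
    if (rate == 0) next
    mask <- runif(nrow(visits)) < rate
    base_rows <- which(visits$visit == 1L)
    if (all(mask[base_rows])) mask[base_rows[1]] <- FALSE
    visits[[s]][mask] <- NA_real_
  }
  cohort$visits <- visits
  cohort
}

new_icd_cohort <- function(visits, static, medication, meta = list(),
                           ground_truth = NULL) {
  structure(list(visits = visits, static = static, medication = medication,
                 ground_truth = ground_truth, meta = meta),
            class = "icd_cohort")
}

#' @export
print.icd_cohort <- function(x, ...) {
  n <- nrow(x$static)
  nv <- nrow(x$visits)
  prev <- mean(x$visits$icd)
  cat("<icd_cohort>\n")
  cat(sprintf("  %d subjects, %d visits (%d observations), visit-level ICD prevalence %.3f\n",
              n, nv, nv - n, prev))
  invisible(x)
}

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort An `icd_cohort`.
#' @param subject_ids Subject identifiers to keep.
#' @return An `icd_cohort` containing only those subjects.
#' @export
filter_subjects <- function(cohort, subject_ids) {
  stopifnot(inherits(cohort, "icd_cohort"))
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    gt$probabilities <- dplyr::filter(gt$probabilities, .data$subject_id %in% subject_ids)
  }
  new_icd_cohort(
    dplyr::filter(cohort$visits, .data$subject_id %in% subject_ids),
    dplyr::filter(cohort$static, .data$subject_id %in% subject_ids),
    dplyr::filter(cohort$medication, .data$subject_id %in% subject_ids),
    meta = cohort$meta, ground_truth = gt
  )
}
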