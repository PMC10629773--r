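#' Configure a synthetic glioma cohort
#'
#' The generator plants latent patient subtypes with characteristic panel
#' profiles, a domain-level panel-missingness process, and subtype-dependent
#' Weibull survival with administrative plus exponential-dropout censoring.
#' It supplies every downstream stage (graphs, block models, survival
#' comparison) with data of known structure.
#'
#' @param n_patients Cohort size.
#' @param subtypes List of subtype specs, each a list with `name`,
#'   `prevalence`, `profile` (named list: domain -> named probability vector
#'   over that domain's fine states, summing to 1), `hazard_scale` (Weibull
#'   scale, days) and `hazard_shape` (Weibull shape; equal shapes across
#'   subtypes give proportional hazards).
#' @param missing_probs Named numeric: probability each domain is left
#'   unassayed (whole-domain missingness). Unlisted domains default to 0.
#' @param censor_rate Probability of exponential dropout within the
#'   follow-up window (0 disables dropout).
#' @param follow_up_days Administrative censoring horizon.
#' @param survival_available Probability a patient has survival follow-up at
#'   all (others get NA time/event, mirroring referral-driven availability).
#' @param taxonomy Taxonomy the profiles refer to.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients, subtypes,
                             missing_probs = numeric(),
                             censor_rate = 0.1,
                             follow_up_days = 5110,
                             survival_available = 1,
                             taxonomy = default_taxonomy()) {
  prev <- vapply(subtypes, function(s) s$prevalence, numeric(1))
  if (abs(sum(prev) - 1) > 1e-9) stop("subtype prevalences must sum to 1")
  if (any(prev < 0)) stop("negative prevalence")
  for (s in subtypes) {
    for (dom in names(s$profile)) {
      p <- s$profile[[dom]]
      if (!dom %in% names(taxonomy)) stop("unknown domain '", dom, "'")
      if (any(p < 0) || any(p > 1)) stop("profile probabilities outside [0,1]")
      if (abs(sum(p) - 1) > 1e-9) {
        stop("profile for domain '", dom, "' in subtype '", s$name,
             "' must sum to 1")
      }
      if (!all(names(p) %in% taxonomy[[dom]])) {
        stop("profile for '", dom, "' names states outside the taxonomy")
      }
    }
    if (s$hazard_scale <= 0 || s$hazard_shape <= 0) {
      stop("hazard scale and shape must be positive")
    }
  }
  if (any(missing_probs < 0 | missing_probs > 1)) {
    stop("missing_probs outside [0,1]")
  }
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate outside [0,1]")
  structure(list(n_patients = n_patients, subtypes = subtypes,
                 missing_probs = missing_probs, censor_rate = censor_rate,
                 follow_up_days = follow_up_days,
                 survival_available = survival_available,
                 taxonomy = taxonomy),
            class = "synthetic_config")
}

#' Default synthetic cohort configuration
#'
#' Six planted subtypes, each with a deterministic signature panel
#' profile, mapped onto four diagnosis labels mirroring the structure of a
#' large routine glioma referral cohort.  Two subtypes share the
#' glioblastoma-like diagnosis but differ in their EGFR/MGMT/TERT
#' signature and in survival (median 250 vs 700 days), and two share the
#' astrocytoma-like diagnosis but differ in MGMT methylation and survival
#' (median 1100 vs 2600 days) — so the survival-relevant structure is
#' finer than the diagnosis, the regime the community-vs-diagnosis
#' comparison probes; the within-diagnosis hazard contrasts are sized so
#' the planted effect is detectable at desk-scale cohorts.  Cohort
#' marginals land near the familiar headline figures (IDH mutant ~50%,
#' EGFR amplified ~26%, 1p/19q codeleted ~21%).  Weibull shapes are 1
#' (exponential), so proportional hazards holds across subtypes; scales
#' put median survival near 250/700/1100/2600/2198/2195 days.  ATRX is
#' unassayed in 20% of patients; survival follow-up is available for one
#' third.
#'
#' Profiles are deterministic within subtype by design: the planted truth
#' must be identifiable for recovery testing, so within-subtype panel
#' heterogeneity is deliberately excluded from the default (a block model
#' resolves any systematically shared extra state into its own
#' sub-community, which is correct behaviour but makes "the" truth
#' ill-defined).  Heterogeneous profiles remain fully configurable.
#'
#' @param n_patients Cohort size (default 800).
#' @param survival_available Fraction with survival follow-up (default 1/3).
#' @return A `synthetic_config`.
#' @export
default_synthetic_config <- function(n_patients = 800,
                                     survival_available = 1 / 3) {
  ms <- function(median_days) median_days / log(2)  # exponential: scale from median
  gbm_a <- list(
    name = "GBM-EGFRamp", diagnosis = "glioblastoma-like",
    prevalence = 0.26,
    profile = list(IDH = c(wildtype = 1),
                   MGMT = c(`10-25% methylation` = 1),
                   EGFR = c(`high amplification` = 1),
                   `1p/19q` = c(`no codeletion` = 1),
                   Histone = c(wildtype = 1),
                   TERT = c(`TERT C228T` = 1),
                   ATRX = c(retained = 1),
                   BRAF = c(wildtype = 1)),
    hazard_scale = ms(250), hazard_shape = 1)
  gbm_b <- list(
    name = "GBM-C250T", diagnosis = "glioblastoma-like",
    prevalence = 0.17,
    profile = list(IDH = c(wildtype = 1),
                   MGMT = c(unmethylated = 1),
                   EGFR = c(`no amplification` = 1),
                   `1p/19q` = c(`no codeletion` = 1),
                   Histone = c(wildtype = 1),
                   TERT = c(`TERT C250T` = 1),
                   ATRX = c(retained = 1),
                   BRAF = c(wildtype = 1)),
    hazard_scale = ms(700), hazard_shape = 1)
  astro_u <- list(
    name = "astro-MGMTu", diagnosis = "astrocytoma-like",
    prevalence = 0.15,
    profile = list(IDH = c(`IDH1 G395A` = 1),
                   MGMT = c(unmethylated = 1),
                   EGFR = c(`no amplification` = 1),
                   `1p/19q` = c(`no codeletion` = 1),
                   Histone = c(wildtype = 1),
                   TERT = c(wildtype = 1),
                   ATRX = c(`loss of expression` = 1),
                   BRAF = c(wildtype = 1)),
    hazard_scale = ms(1100), hazard_shape = 1)
  astro_m <- list(
    name = "astro-MGMTm", diagnosis = "astrocytoma-like",
    prevalence = 0.14,
    profile = list(IDH = c(`IDH1 G395A` = 1),
                   MGMT = c(`>25% methylation` = 1),
                   EGFR = c(`no amplification` = 1),
                   `1p/19q` = c(`no codeletion` = 1),
                   Histone = c(wildtype = 1),
                   TERT = c(wildtype = 1),
                   ATRX = c(`loss of expression` = 1),
                   BRAF = c(wildtype = 1)),
    hazard_scale = ms(2600), hazard_shape = 1)
  oligo <- list(
    name = "oligo-like", diagnosis = "oligodendroglioma-like",
    prevalence = 0.21,
    profile = list(IDH = c(`IDH2 G515A` = 1),
                   MGMT = c(`5-10% methylation` = 1),
                   EGFR = c(`no amplification` = 1),
                   `1p/19q` = c(`1p/19q codeletion` = 1),
                   Histone = c(wildtype = 1),
                   TERT = c(`TERT C228T` = 1),
                   ATRX = c(retained = 1),
                   BRAF = c(wildtype = 1)),
    hazard_scale = ms(2198), hazard_shape = 1)
  other <- list(
    name = "other", diagnosis = "other glioma",
    prevalence = 0.07,
    profile = list(IDH = c(wildtype = 1),
                   MGMT = c(unmethylated = 1),
                   EGFR = c(`no amplification` = 1),
                   `1p/19q` = c(`no codeletion` = 1),
                   Histone = c(`Hist K27M` = 1),
                   TERT = c(wildtype = 1),
                   ATRX = c(retained = 1),
                   BRAF = c(`BRAF 1799 T>A` = 1)),
    hazard_scale = ms(2195), hazard_shape = 1)
  synthetic_config(
    n_patients = n_patients,
    subtypes = list(gbm_a, gbm_b, astro_u, astro_m, oligo, other),
    missing_probs = c(ATRX = 0.2),
    censor_rate = 0.1,
    follow_up_days = 5110,
    survival_available = survival_available)
}

#' Sample a synthetic cohort
#'
#' Draws each patient's subtype from the prevalences, a mutually exclusive
#' fine state per domain from the subtype profile, masks whole domains
#' missing with the configured probabilities, and draws survival from the
#' subtype's Weibull, right-censored at the minimum of an exponential
#' dropout time and the administrative follow-up horizon.  Fully
#' reproducible from `seed`.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer RNG seed.
#' @return List with `records` (cohort data.frame in the [read_cohort()]
#'   schema, `diagnosis` set to the subtype's diagnosis label, or its name
#'   when none is declared) and `truth` (data.frame of `patient_id`,
#'   `subtype`).
#' @export
sample_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- config$n_patients
  prev <- vapply(config$subtypes, function(s) s$prevalence, numeric(1))
  snames <- vapply(config$subtypes, function(s) s$name, character(1))
  dnames <- vapply(config$subtypes, function(s) {
    if (is.null(s$diagnosis)) s$name else s$diagnosis
  }, character(1))
  z <- sample.int(length(prev), n, replace = TRUE, prob = prev)
  records <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        diagnosis = dnames[z],
                        age = round(stats::rnorm(n, 52, 15), 1),
                        sex = sample(c("male", "female"), n, replace = TRUE,
                                     prob = c(0.55, 0.45)),
                        stringsAsFactors = FALSE)
  records$age[records$age < 0] <- 0
  for (dom in names(config$taxonomy)) {
    res <- character(n)
    for (k in seq_along(config$subtypes)) {
      idx <- which(z == k)
      if (!length(idx)) next
      p <- config$subtypes[[k]]$profile[[dom]]
      if (is.null(p)) p <- stats::setNames(1, config$taxonomy[[dom]][1])
      res[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    pm <- config$missing_probs[dom]
    if (!is.na(pm) && pm > 0) {
      res[stats::runif(n) < pm] <- NA_character_
    }
    records[[dom]] <- res
  }
  shape <- vapply(config$subtypes, function(s) s$hazard_shape, numeric(1))
  scale <- vapply(config$subtypes, function(s) s$hazard_scale, numeric(1))
  t_event <- stats::rweibull(n, shape = shape[z], scale = scale[z])
  t_cens <- rep(Inf, n)
  if (config$censor_rate > 0) {
    lam <- -log(1 - config$censor_rate) / config$follow_up_days
    t_cens <- stats::rexp(n, rate = lam)
  }
  t_cens <- pmin(t_cens, config$follow_up_days)
  records$survival_days <- floor(pmin(t_event, t_cens))
  records$event <- as.integer(t_event <= t_cens)
  keep <- stats::runif(n) < config$survival_available
  records$survival_days[!keep] <- NA
  records$event[!keep] <- NA
  list(records = records[, c("patient_id", "diagnosis", "age", "sex",
                             "survival_days", "event",
                             names(config$taxonomy))],
       truth = data.frame(patient_id = records$patient_id,
                          subtype = snames[z], stringsAsFactors = FALSE))
}

#' Summarize the planted truth of a synthetic cohort
#'
#' Deterministic aggregation used by recovery tests: subtype sizes and
#' per-subtype empirical frequencies of every (domain, state) result among
#' assayed patients.
#'
#' @param records Cohort records from [sample_cohort()].
#' @param truth Truth table from [sample_cohort()].
#' @param taxonomy Taxonomy of the panel columns.
#' @return List with `sizes` (named integer) and `frequencies`, a data.frame
#'   of subtype, domain, state, count, n_assayed, frequency.
#' @export
planted_truth_report <- function(records, truth,
                                 taxonomy = default_taxonomy()) {
  stopifnot(nrow(records) == nrow(truth))
  sizes <- table(truth$subtype)
  out <- list()
  for (sub in names(sizes)) {
    rows <- records[truth$subtype == sub, , drop = FALSE]
    for (dom in names(taxonomy)) {
      res <- rows[[dom]]
      n_ass <- sum(!is.na(res))
      for (st in taxonomy[[dom]]) {
        cnt <- sum(res == st, na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          subtype = sub, domain = dom, state = st, count = cnt,
          n_assayed = n_ass,
          frequency = if (n_ass > 0) cnt / n_ass else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(sizes = stats::setNames(as.integer(sizes), names(sizes)),
       frequencies = do.call(rbind, out))
}

# Seed-scoped RNG: sets the seed, returns a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
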