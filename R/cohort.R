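#' Specification of a simulated survival cohort
#'
#' Patients carry the clinical covariates of a pleural-mesothelioma cohort
#' (age, sex, side, histology, TNM stage group) plus a raw marker mean
#' intensity in \[0, 1\]. Survival is exponential with hazard
#' `baseline_hazard * exp(beta * marker * 1000)`: the log-linear
#' proportional-hazards structure on the x1000 intensity scale used in the
#' Cox screens. Censoring is administrative at a Uniform(0, H) horizon whose
#' H is calibrated so the expected censored fraction equals `censor_rate`.
#'
#' @param n_patients number of patients (>= 2)
#' @param beta log hazard ratio per unit of the scaled (x1000) marker
#' @param baseline_hazard events per month at marker 0 (> 0)
#' @param censor_rate target fraction censored, in \[0, 1)
#' @param marker_distribution function(n) drawing raw intensities in \[0, 1\]
#' @param covariate_distributions optional named list of function(n)
#'   generators overriding the defaults for `age`, `sex`, `side`,
#'   `histology`, `stage`
#' @param seed integer seed
#' @export
cohort_spec <- function(n_patients, beta = 0, baseline_hazard = 0.02,
                        censor_rate = 0.04,
                        marker_distribution = function(n) stats::rbeta(n, 2, 18),
                        covariate_distributions = list(), seed = 1L) {
  stopifnot(n_patients >= 2, is.finite(beta), baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1,
            is.function(marker_distribution))
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 marker_distribution = marker_distribution,
                 covariate_distributions = covariate_distributions,
                 seed = as.integer(seed)), class = "cohort_spec")
}

default_covariate_generators <- function() {
  list(
    age = function(n) round(pmin(90, pmax(40, stats::rnorm(n, 67, 9)))),
    sex = function(n) sample(c("male", "female"), n, TRUE, c(0.8, 0.2)),
    side = function(n) sample(c("left", "right"), n, TRUE),
    histology = function(n) sample(c("epithelioid", "biphasic", "sarcomatoid"),
                                   n, TRUE, c(0.7, 0.15, 0.15)),
    stage = function(n) sample(c("low", "high"), n, TRUE))
}

# Expected censored fraction under C ~ U(0, H) for subject hazards lambda:
# P(T > C) = (1 - exp(-lambda H)) / (lambda H), averaged over subjects.
censor_horizon <- function(lambda, target) {
  f <- function(H) mean((1 - exp(-lambda * H)) / (lambda * H)) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a survival cohort with known hazard structure
#'
#' @param spec a [cohort_spec()]
#' @param marker_values optional vector of raw marker intensities (length
#'   `n_patients`) overriding `marker_distribution`, so the hazard can be
#'   tied to externally simulated marker truth
#' @return data.frame with columns `patient_id`, `age`, `sex`, `side`,
#'   `histology`, `stage`, `marker` (raw intensity), `months`, `event`
#' @export
generate_cohort <- function(spec, marker_values = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.finite(spec$beta)) stop("beta must be finite", call. = FALSE)
  set.seed(spec$seed)
  n <- spec$n_patients
  gen <- utils::modifyList(default_covariate_generators(),
                           spec$covariate_distributions)
  marker <- if (is.null(marker_values)) {
    clamp01(spec$marker_distribution(n))
  } else {
    stopifnot(length(marker_values) == n)
    clamp01(marker_values)
  }
  lambda <- spec$baseline_hazard * exp(spec$beta * marker * 1000)
  t_event <- stats::rexp(n, rate = lambda)
  if (spec$censor_rate > 0) {
    H <- censor_horizon(lambda, spec$censor_rate)
    c_time <- stats::runif(n, 0, H)
    months <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    months <- t_event
    event <- rep(1L, n)
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             age = gen$age(n), sex = gen$sex(n), side = gen$side(n),
             histology = gen$histology(n), stage = gen$stage(n),
             marker = marker, months = pmax(months, 1e-6), event = event,
             stringsAsFactors = FALSE)
}
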