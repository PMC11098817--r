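#' Construct a patient cohort
#'
#' @param expression Gene-by-patient numeric matrix (dimnames required).
#' @param time Positive survival times (months), one per patient.
#' @param event Event indicators (0/1).
#' @param response Optional factor/character with levels `"responder"` and
#'   `"early_resistance"`.
#' @param covariates Optional data frame of clinical covariates, one row per
#'   patient.
#' @return An object of class `patient_cohort`.
#' @export
patient_cohort <- function(expression, time, event,
                           response = NULL, covariates = NULL) {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression))) {
    stop("`expression` must be a gene x patient matrix with dimnames",
         call. = FALSE)
  }
  n <- ncol(expression)
  if (length(time) != n || length(event) != n) {
    stop("time and event must have one entry per patient", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (anyNA(expression)) stop("expression must have no missing values", call. = FALSE)
  if (!is.null(response)) {
    response <- as.character(response)
    if (length(response) != n ||
        !all(response %in% c("responder", "early_resistance"))) {
      stop("response must label every patient responder/early_resistance",
           call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per patient", call. = FALSE)
    }
  }
  structure(
    list(patient_ids = colnames(expression),
         expression = expression,
         time = as.numeric(time),
         event = as.integer(event),
         response = response,
         covariates = covariates),
    class = "patient_cohort"
  )
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat("patient_cohort:", length(x$patient_ids), "patients,",
      nrow(x$expression), "genes,",
      sum(x$event), "events",
      if (!is.null(x$response)) sprintf("(%d early-resistance)",
                                        sum(x$response == "early_resistance"))
      else "", "\n")
  invisible(x)
}

#' Simulate a patient cohort under a proportional-hazards model
#'
#' Generates per-patient gene expression (standard normal per gene, i.e.
#' already on the z-score scale), survival times from an exponential or
#' Weibull proportional-hazards model whose log hazard is linear in the
#' expression of selected genes, independent exponential censoring
#' calibrated to a target censoring proportion, a binary early-resistance
#' outcome from a logistic model on the same expression scale, and binary
#' clinical covariates (ISS-like stage, adverse cytogenetics flags) sampled
#' independently of expression.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size (>= 20).
#' @param genes Character vector of gene ids to simulate.
#' @param log_hazard_effects Named numeric vector (names in `genes`): true
#'   log hazard ratio per standard deviation of expression.
#' @param log_odds_effects Named numeric vector: true log odds ratio of
#'   early resistance per standard deviation of expression.
#' @param censoring_rate Target fraction of censored patients (>= 0; 0 means
#'   every patient has an observed event).
#' @param baseline_hazard Baseline event hazard per month.
#' @param resistance_rate Baseline early-resistance probability at mean
#'   expression.
#' @param survival_dist `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Shape parameter when `survival_dist = "weibull"`.
#' @param covariate_spec Data frame (name, type, p, mean, sd) describing the
#'   clinical covariates; `NULL` uses a myeloma-like default (age, sex,
#'   ISS-3 stage, elevated LDH, high-risk translocation, del17p, gain1q).
#' @return A `patient_cohort`.
#' @export
generate_patient_cohort <- function(seed,
                                    n_patients,
                                    genes,
                                    log_hazard_effects = numeric(0),
                                    log_odds_effects = numeric(0),
                                    censoring_rate = 0.3,
                                    baseline_hazard = 0.02,
                                    resistance_rate = 0.2,
                                    survival_dist = c("exponential", "weibull"),
                                    weibull_shape = 1.2,
                                    covariate_spec = NULL) {
  n_patients <- assert_count(n_patients, "n_patients", min = 20)
  survival_dist <- match.arg(survival_dist)
  if (!is.numeric(censoring_rate) || censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  }
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes))
  for (eff in list(log_hazard_effects, log_odds_effects)) {
    if (length(eff) && !all(names(eff) %in% genes)) {
      stop("effect maps may only reference listed genes", call. = FALSE)
    }
  }
  if (is.null(covariate_spec)) covariate_spec <- default_covariate_spec()

  with_seed(seed, {
    expr <- matrix(rnorm(length(genes) * n_patients),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("pt_%04d", seq_len(n_patients))))

    eta_surv <- drop(crossprod(expr[names(log_hazard_effects), , drop = FALSE],
                               log_hazard_effects))
    if (!length(eta_surv)) eta_surv <- rep(0, n_patients)
    rate <- baseline_hazard * exp(eta_surv)
    t_event <- if (survival_dist == "exponential") {
      rexp(n_patients, rate = rate)
    } else {
      # Weibull PH: S(t) = exp(-(baseline_hazard * t)^shape * exp(eta))
      (rexp(n_patients, rate = exp(eta_surv)))^(1 / weibull_shape) / baseline_hazard
    }
    if (censoring_rate > 0) {
      c_rate <- baseline_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- rexp(n_patients, rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n_patients)
    }
    time <- pmax(time, 1 / 30)  # floor at one day on the month scale

    eta_resp <- drop(crossprod(expr[names(log_odds_effects), , drop = FALSE],
                               log_odds_effects))
    if (!length(eta_resp)) eta_resp <- rep(0, n_patients)
    p_resist <- plogis(qlogis(resistance_rate) + eta_resp)
    response <- ifelse(rbinom(n_patients, 1, p_resist) == 1,
                       "early_resistance", "responder")

    covariates <- draw_covariates(covariate_spec, n_patients)

    patient_cohort(expr, time, event, response, covariates)
  })
}

default_covariate_spec <- function() {
  data.frame(
    name = c("age", "sex_male", "iss3", "ldh_high", "hr_translocation",
             "del17p", "gain1q"),
    type = c("normal", rep("binary", 6)),
    p = c(NA, 0.55, 0.30, 0.25, 0.15, 0.10, 0.35),
    mean = c(65, rep(NA, 6)),
    sd = c(10, rep(NA, 6)),
    stringsAsFactors = FALSE
  )
}

draw_covariates <- function(spec, n) {
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    if (spec$type[i] == "binary") {
      rbinom(n, 1, spec$p[i])
    } else {
      rnorm(n, spec$mean[i], spec$sd[i])
    }
  })
  names(cols) <- spec$name
  as.data.frame(cols)
}
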