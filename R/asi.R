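#' Decile transform of a gene's expression across a cohort
#'
#' Empirical decile assignment by the quantile cut points
#' q_{0.1}, ..., q_{0.9} of the input values: a value at or below q_{0.1}
#' gets decile 1, above q_{0.9} decile 10 (1 = lowest expression,
#' 10 = highest).  Tied values always share a decile (each value's decile
#' is one plus the number of cut points strictly below it), which makes the
#' transform invariant under strictly monotone transformations of the
#' expression scale.
#'
#' @param values Numeric vector of one gene's expression across patients
#'   (names preserved).  Ten or more patients are recommended for a
#'   meaningful decile split; any n >= 1 is accepted.
#' @return Integer vector of deciles in 1..10.
#' @export
decile_transform <- function(values) {
  if (!length(values) || !is.numeric(values)) {
    stop("values must be a nonempty numeric vector", call. = FALSE)
  }
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- quantile(values, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
  dec <- vapply(values, function(v) 1L + sum(v > q), integer(1))
  names(dec) <- names(values)
  dec
}

#' Compute the Sigma-ASI decile-sum score
#'
#' Summary score of adverse stromal interactions over a 10-gene signature
#' (5 adverse, 5 favorable).  With deciles d in 1..10, the default
#' contribution rule is (d - 1) for each adverse gene and (10 - d) for
#' each favorable gene, summed over the 10 genes, giving the score range
#' 0..90: 0 means maximum expression of all favorable genes with minimum
#' expression of all adverse genes, 90 the reverse.
#'
#' `literal = TRUE` instead adds the raw decile d for adverse genes
#' (keeping 10 - d for favorable ones), a variant whose range is 5..95;
#' see the methods vignette for why the 0..90 rule is the default.
#'
#' @param deciles Either a named integer vector (one patient: gene ->
#'   decile) or a patients x genes matrix/data frame of deciles in 1..10.
#' @param signature A [signature_model()] whose adverse and favorable gene
#'   lists are all present in `deciles`.
#' @param literal Use the raw-decile adverse contribution (range 5..95).
#' @return Integer score per patient.
#' @export
compute_sigma_asi <- function(deciles, signature, literal = FALSE) {
  stopifnot(inherits(signature, "signature_model"))
  genes <- c(signature$adverse, signature$favorable)
  if (is.null(dim(deciles))) {
    deciles <- matrix(deciles, nrow = 1,
                      dimnames = list(NULL, names(deciles)))
  }
  deciles <- as.matrix(deciles)
  missing <- setdiff(genes, colnames(deciles))
  if (length(missing)) {
    stop(sprintf("missing decile(s) for gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d <- deciles[, genes, drop = FALSE]
  if (any(d < 1 | d > 10 | d != round(d))) {
    stop("deciles must be integers in 1..10", call. = FALSE)
  }
  adv <- d[, signature$adverse, drop = FALSE]
  fav <- d[, signature$favorable, drop = FALSE]
  adv_term <- if (literal) adv else adv - 1L
  score <- rowSums(adv_term) + rowSums(10L - fav)
  as.integer(score)
}

#' Dichotomize the Sigma-ASI score
#'
#' @param sigma Integer score(s).
#' @param cutoff Score at or above which a patient is called ASI+
#'   (default 50).
#' @return Factor with levels `"ASI-"`, `"ASI+"`.
#' @export
classify_asi <- function(sigma, cutoff = 50) {
  factor(ifelse(sigma >= cutoff, "ASI+", "ASI-"), levels = c("ASI-", "ASI+"))
}

#' Score a cohort with the Sigma-ASI classifier
#'
#' Computes per-gene expression deciles within the scoring cohort
#' (cross-sectional, not against an external reference), the Sigma-ASI
#' score per patient, and the ASI+/ASI- call at the given cutoff.
#'
#' @param cohort A [patient_cohort()] containing all signature genes.
#' @param signature A [signature_model()].
#' @param cutoff Dichotomization cutoff (default 50).
#' @param literal Passed to [compute_sigma_asi()].
#' @return Data frame with columns patient_id, sigma_asi, asi_status.
#' @export
compute_asi <- function(cohort, signature, cutoff = 50, literal = FALSE) {
  stopifnot(inherits(cohort, "patient_cohort"))
  genes <- c(signature$adverse, signature$favorable)
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing)) {
    stop(sprintf("cohort lacks signature gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dec <- vapply(genes, function(g) decile_transform(cohort$expression[g, ]),
                integer(length(cohort$patient_ids)))
  sigma <- compute_sigma_asi(dec, signature, literal = literal)
  data.frame(
    patient_id = cohort$patient_ids,
    sigma_asi = sigma,
    asi_status = classify_asi(sigma, cutoff),
    stringsAsFactors = FALSE
  )
}

#' Compare survival between ASI groups
#'
#' Kaplan-Meier estimates per group, the log-rank test, and Cox
#' proportional-hazards estimates of the ASI+ hazard ratio with Wald 95%
#' confidence intervals, unadjusted and (optionally) adjusted for clinical
#' covariates.
#'
#' @param cohort A [patient_cohort()].
#' @param labels Factor/character of group labels per patient (two groups;
#'   the second level — `"ASI+"` for [classify_asi()] output — is the
#'   exposure).
#' @param adjust_for Optional clinical covariate names for the adjusted
#'   model.
#' @return List with `km` (the `survfit` object), `logrank_chisq`,
#'   `logrank_p`, `hr_unadjusted` and (if requested) `hr_adjusted`, each a
#'   named vector (hr, lower, upper, p).
#' @export
survival_compare <- function(cohort, labels, adjust_for = NULL) {
  stopifnot(inherits(cohort, "patient_cohort"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    stop("labels must define exactly two non-empty groups", call. = FALSE)
  }
  if (sum(cohort$event) < 1) stop("no events in cohort", call. = FALSE)
  df <- data.frame(time = cohort$time, event = cohort$event, group = labels)
  if (!is.null(adjust_for)) {
    df <- cbind(df, cohort_design(cohort, adjust_for))
  }

  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_chisq <- sd$chisq
  logrank_p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)

  hr_of <- function(extra = NULL) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ group",
      if (length(extra)) paste("+", paste(sprintf("`%s`", extra), collapse = " + "))
      else ""
    ))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    b <- coef(fit)[1]
    se <- sqrt(diag(fit$var))[1]
    c(hr = exp(unname(b)),
      lower = exp(unname(b - 1.96 * se)),
      upper = exp(unname(b + 1.96 * se)),
      log_hr = unname(b), se = unname(se),
      p = 2 * pnorm(-abs(unname(b) / se)))
  }

  out <- list(km = km,
              logrank_chisq = logrank_chisq,
              logrank_p = logrank_p,
              hr_unadjusted = hr_of())
  if (!is.null(adjust_for)) out$hr_adjusted <- hr_of(adjust_for)
  out
}

#' Association between ASI status and early therapeutic resistance
#'
#' Cross-tabulates early resistance (stable or progressive disease three
#' months after starting first-line treatment) against ASI status, tests
#' it with Fisher's exact test, and estimates the odds ratio by logistic
#' regression (Wald 95% CI), optionally covariate-adjusted.  If the
#' outcome is constant the Fisher p is reported as 1 with a warning and
#' the logistic fit is skipped.
#'
#' @param cohort A [patient_cohort()] with a `response` outcome.
#' @param labels Two-level group labels (second level is the exposure).
#' @param adjust_for Optional clinical covariate names.
#' @return List with `table` (2x2), `fisher_p`, `or_unadjusted` and (if
#'   requested) `or_adjusted`, each a named vector (or, lower, upper, p).
#' @export
resistance_association <- function(cohort, labels, adjust_for = NULL) {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (is.null(cohort$response)) stop("cohort has no response outcome", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    stop("labels must define exactly two non-empty groups", call. = FALSE)
  }
  resist <- cohort$response == "early_resistance"
  tab <- table(group = labels, resistant = factor(resist, c(FALSE, TRUE)))

  if (length(unique(resist)) == 1) {
    warning("constant outcome: Fisher p = 1, logistic fit skipped", call. = FALSE)
    return(list(table = tab, fisher_p = 1, or_unadjusted = NULL))
  }

  fisher_p <- fisher.test(tab)$p.value
  df <- data.frame(resist = as.integer(resist), group = labels)
  if (!is.null(adjust_for)) df <- cbind(df, cohort_design(cohort, adjust_for))

  or_of <- function(extra = NULL) {
    fml <- stats::as.formula(paste(
      "resist ~ group",
      if (length(extra)) paste("+", paste(sprintf("`%s`", extra), collapse = " + "))
      else ""
    ))
    fit <- glm(fml, family = binomial(), data = df)
    b <- coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    c(or = exp(unname(b)),
      lower = exp(unname(b - 1.96 * se)),
      upper = exp(unname(b + 1.96 * se)),
      log_or = unname(b), se = unname(se),
      p = 2 * pnorm(-abs(unname(b) / se)))
  }

  out <- list(table = tab, fisher_p = fisher_p, or_unadjusted = or_of())
  if (!is.null(adjust_for)) out$or_adjusted <- or_of(adjust_for)
  out
}
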