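#' Fit a Cox proportional-hazards model on cohort covariates
#'
#' Maximum partial-likelihood fit (Efron handling of ties) of survival on
#' the named covariates, which may be genes (rows of the expression
#' matrix, used as-is) and/or columns of the clinical covariate table.
#'
#' @param cohort A [patient_cohort()].
#' @param covariates Character vector of gene ids and/or clinical covariate
#'   names.
#' @return List with `coefficients` (data frame: term, log_hr, se, p),
#'   `loglik` (log partial likelihood of the fitted model), `loglik_null`,
#'   and the underlying `survival::coxph` fit as `model`.
#' @export
fit_cox <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "patient_cohort"), length(covariates) >= 1)
  if (sum(cohort$event) < 1) stop("no events in cohort", call. = FALSE)
  df <- cohort_design(cohort, covariates)
  const <- vapply(df, function(x) var(as.numeric(x)) == 0, logical(1))
  if (any(const)) {
    stop(sprintf("constant covariate(s): %s",
                 paste(names(df)[const], collapse = ", ")), call. = FALSE)
  }
  df$.time <- cohort$time
  df$.event <- cohort$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " "))) {
    stop("Cox model did not converge", call. = FALSE)
  }
  s <- summary(fit)
  structure(list(
    coefficients = data.frame(
      term = covariates,
      log_hr = unname(coef(fit)),
      se = unname(s$coefficients[, "se(coef)"]),
      p = unname(s$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE
    ),
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    model = fit
  ), class = "cox_fit")
}

cohort_design <- function(cohort, covariates) {
  cols <- lapply(covariates, function(v) {
    if (v %in% rownames(cohort$expression)) {
      cohort$expression[v, ]
    } else if (!is.null(cohort$covariates) && v %in% names(cohort$covariates)) {
      cohort$covariates[[v]]
    } else {
      stop(sprintf("unknown covariate `%s`", v), call. = FALSE)
    }
  })
  names(cols) <- covariates
  as.data.frame(cols, check.names = FALSE)
}

#' Consensus forward/backward stepwise Cox gene selection
#'
#' Identifies genes independently associated with survival as the
#' consensus (intersection) of forward selection (a gene enters when its
#' likelihood-ratio p-value against the current model is the smallest and
#' below `p_enter`) and backward elimination (starting from the model with
#' all candidates, the gene with the largest likelihood-ratio p-value is
#' removed while that p-value is at or above `p_remove`).  Gene expression
#' is standardized (z-score per gene) before fitting so coefficients are
#' per standard deviation.  The consensus genes are refit jointly; genes
#' with hazard ratio above 1 in that joint model are labeled adverse,
#' below 1 favorable.
#'
#' Ties in the stepping p-values are broken by lexicographic gene id.  If
#' the full model for the backward pass cannot be fitted (more genes than
#' events, or non-convergence), the forward-only selection is returned,
#' flagged as non-consensus.
#'
#' @param cohort A [patient_cohort()].
#' @param candidates Candidate gene ids (subset of the expression rows).
#' @param p_enter Likelihood-ratio p-value to add a gene (default 0.200).
#' @param p_remove Likelihood-ratio p-value at or above which a gene is
#'   removed (default 0.200).
#' @param endpoint Label for the endpoint the cohort's time/event columns
#'   represent (`"pfs"` or `"os"`); recorded in the result.
#' @return Object of class `signature_model`: list with `adverse` and
#'   `favorable` ordered gene vectors, `coefficients` (joint-model data
#'   frame), `forward`, `backward`, `consensus` (logical flag), `endpoint`.
#' @export
stepwise_consensus <- function(cohort, candidates,
                               p_enter = 0.200, p_remove = 0.200,
                               endpoint = c("pfs", "os")) {
  stopifnot(inherits(cohort, "patient_cohort"))
  endpoint <- match.arg(endpoint)
  candidates <- sort(unique(as.character(candidates)))
  if (!all(candidates %in% rownames(cohort$expression))) {
    stop("candidates must be rows of the cohort expression matrix", call. = FALSE)
  }

  zc <- standardize_cohort(cohort, candidates)

  # coxph emits convergence chatter for weak candidates during the search;
  # only the final joint model's diagnostics matter to the caller
  loglik_of <- function(genes) {
    suppressWarnings({
      if (!length(genes)) {
        # null model log partial likelihood via any single-covariate fit
        fit_cox(zc, candidates[1])$loglik_null
      } else {
        fit_cox(zc, genes)$loglik
      }
    })
  }
  lr_p <- function(ll1, ll0, df = 1) pchisq(2 * (ll1 - ll0), df, lower.tail = FALSE)

  # forward pass
  forward <- character(0)
  ll_cur <- loglik_of(character(0))
  remaining <- candidates
  while (length(remaining)) {
    ps <- vapply(remaining, function(g) lr_p(loglik_of(c(forward, g)), ll_cur),
                 numeric(1))
    ord <- order(ps, remaining)
    best <- ord[1]
    if (ps[best] < p_enter) {
      g <- remaining[best]
      forward <- c(forward, g)
      ll_cur <- loglik_of(forward)
      remaining <- setdiff(remaining, g)
    } else break
  }

  # backward pass
  backward <- candidates
  consensus_ok <- TRUE
  ll_full <- tryCatch(loglik_of(backward), error = function(e) NA_real_)
  if (length(backward) >= sum(zc$event) || is.na(ll_full)) {
    warning("full model unfittable; returning forward-only selection flagged as non-consensus",
            call. = FALSE)
    consensus_ok <- FALSE
    selected <- forward
    backward <- NA_character_
  } else {
    ll_cur <- ll_full
    while (length(backward) > 0) {
      ps <- vapply(backward, function(g) {
        lr_p(ll_cur, loglik_of(setdiff(backward, g)))
      }, numeric(1))
      ord <- order(-ps, backward)
      worst <- ord[1]
      if (ps[worst] >= p_remove) {
        backward <- setdiff(backward, backward[worst])
        ll_cur <- loglik_of(backward)
      } else break
    }
    selected <- intersect(forward, backward)
  }

  if (length(selected)) {
    joint <- fit_cox(zc, selected)
    co <- joint$coefficients
    adverse <- co$term[co$log_hr > 0]
    favorable <- co$term[co$log_hr < 0]
    # order by effect size, strongest first
    adverse <- adverse[order(-co$log_hr[match(adverse, co$term)])]
    favorable <- favorable[order(co$log_hr[match(favorable, co$term)])]
  } else {
    co <- data.frame(term = character(0), log_hr = numeric(0),
                     se = numeric(0), p = numeric(0))
    adverse <- favorable <- character(0)
  }

  signature_model(adverse, favorable, coefficients = co,
                  forward = forward, backward = backward,
                  consensus = consensus_ok, endpoint = endpoint)
}

#' Construct a signature model
#'
#' @param adverse,favorable Disjoint ordered gene id vectors: adverse genes
#'   carry hazard ratios above 1 in the joint model, favorable below 1.
#' @param coefficients Optional data frame (term, log_hr, se, p).
#' @param forward,backward,consensus,endpoint Selection metadata.
#' @return Object of class `signature_model`.
#' @export
signature_model <- function(adverse, favorable, coefficients = NULL,
                            forward = NULL, backward = NULL,
                            consensus = TRUE, endpoint = "pfs") {
  adverse <- as.character(adverse)
  favorable <- as.character(favorable)
  if (length(intersect(adverse, favorable))) {
    stop("adverse and favorable gene lists must be disjoint", call. = FALSE)
  }
  structure(
    list(adverse = adverse, favorable = favorable,
         coefficients = coefficients,
         forward = forward, backward = backward,
         consensus = consensus, endpoint = endpoint),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature_model (", x$endpoint, "):\n",
      " adverse:   ", paste(x$adverse, collapse = ", "), "\n",
      " favorable: ", paste(x$favorable, collapse = ", "), "\n", sep = "")
  if (!isTRUE(x$consensus)) cat("  [forward-only, non-consensus]\n")
  invisible(x)
}

# z-score expression per gene; returns a shallow-copied cohort
standardize_cohort <- function(cohort, genes) {
  z <- cohort$expression
  zs <- z[genes, , drop = FALSE]
  mu <- rowMeans(zs)
  sdv <- apply(zs, 1, sd)
  if (any(sdv == 0)) {
    stop("candidate gene(s) with zero variance cannot be standardized",
         call. = FALSE)
  }
  z[genes, ] <- (zs - mu) / sdv
  out <- cohort
  out$expression <- z
  out
}
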