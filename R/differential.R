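#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the DESeq style: a per-feature
#' geometric mean is computed across samples (features containing any zero
#' are excluded), each sample's factor is the median over features of
#' count / geometric mean, and the factors are rescaled so that their
#' geometric mean is 1.
#'
#' @param counts A [count_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  k <- counts$counts
  if (any(colSums(k) == 0)) {
    stop("every sample must have at least one nonzero count", call. = FALSE)
  }
  keep <- rowSums(k == 0) == 0
  if (!any(keep)) {
    stop(paste("no feature has nonzero counts in every sample;",
               "add a pseudo-count to the matrix before normalization"),
         call. = FALSE)
  }
  logk <- log(k[keep, , drop = FALSE])
  loggeo <- rowMeans(logk)
  factors <- apply(logk, 2, function(col) exp(median(col - loggeo)))
  factors <- factors / exp(mean(log(factors)))
  factors
}

#' Differential testing of count features between conditions
#'
#' Negative-binomial Wald test per feature, co-culture versus control,
#' on size-factor-normalized counts.  The per-feature dispersion is a
#' pooled method-of-moments estimate moderated toward the across-feature
#' trimmed-mean dispersion with prior weight `prior_df` (an empirical-Bayes
#' stabilization in the spirit of limma/DESeq2, needed because a raw
#' 3-versus-3 moment estimate is too noisy to be both calibrated and
#' powerful), floored at a small constant.  The Wald statistic is the log2
#' fold change over its delta-method standard error, referred to a t
#' distribution with `n1 + n2 - 2 + prior_df` degrees of freedom.
#' Features whose mean normalized count falls below `min_count` are not
#' tested (p and FDR reported as `NA`).
#'
#' @param counts A [count_matrix()] with >= 2 replicates per condition.
#' @param size_factors Named positive factors per sample; defaults to
#'   [compute_size_factors()].
#' @param min_count Minimum mean normalized count for a feature to be
#'   tested.
#' @param fdr_threshold FDR cutoff used only to call the `direction` label.
#' @param pseudo_count Pseudo-count added to condition means for the fold
#'   change.
#' @param dispersion_floor Lower bound for the moderated dispersion.
#' @param prior_df Prior weight (pseudo-degrees of freedom) given to the
#'   across-feature dispersion in the moderation; 0 recovers the raw
#'   per-feature moment estimate.
#' @return Data frame with columns feature_id, base_mean, log2fc, p_value,
#'   fdr, direction (`"up"`, `"down"`, `"none"`).
#' @export
test_differential <- function(counts,
                              size_factors = compute_size_factors(counts),
                              min_count = 10,
                              fdr_threshold = 0.05,
                              pseudo_count = 0.5,
                              dispersion_floor = 1e-8,
                              prior_df = 20) {
  stopifnot(inherits(counts, "count_matrix"))
  ctrl <- counts$sample_ids[counts$condition == "control"]
  cocx <- counts$sample_ids[counts$condition == "coculture"]
  if (length(ctrl) < 2 || length(cocx) < 2) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  sf <- size_factors[counts$sample_ids]
  if (anyNA(sf) || any(sf <= 0)) {
    stop("size factors must be positive and cover every sample", call. = FALSE)
  }

  norm <- sweep(counts$counts, 2, sf, "/")
  n1 <- norm[, ctrl, drop = FALSE]
  n2 <- norm[, cocx, drop = FALSE]
  r1 <- length(ctrl); r2 <- length(cocx)
  m1 <- rowMeans(n1); m2 <- rowMeans(n2)
  v1 <- apply(n1, 1, var); v2 <- apply(n2, 1, var)

  base_mean <- rowMeans(norm)
  log2fc <- log2((m2 + pseudo_count) / (m1 + pseudo_count))

  # pooled method-of-moments NB dispersion: var = mu + alpha * mu^2,
  # moderated toward the across-feature trimmed mean
  m_pool <- (m1 + m2) / 2
  v_pool <- (v1 * (r1 - 1) + v2 * (r2 - 1)) / (r1 + r2 - 2)
  alpha_mm <- (v_pool - m_pool) / m_pool^2
  df_resid <- r1 + r2 - 2
  alpha_prior <- mean(alpha_mm[is.finite(alpha_mm)], trim = 0.05)
  alpha <- pmax((df_resid * alpha_mm + prior_df * alpha_prior) /
                  (df_resid + prior_df), dispersion_floor)

  se1 <- sqrt((m1 + alpha * m1^2) / r1) / ((m1 + pseudo_count) * log(2))
  se2 <- sqrt((m2 + alpha * m2^2) / r2) / ((m2 + pseudo_count) * log(2))
  wald <- log2fc / sqrt(se1^2 + se2^2)
  p <- 2 * pt(-abs(wald), df = df_resid + prior_df)

  tested <- base_mean >= min_count
  p[!tested] <- NA_real_
  fdr <- adjust_bh(p)

  direction <- rep("none", length(p))
  direction[!is.na(fdr) & fdr < fdr_threshold & log2fc > 0] <- "up"
  direction[!is.na(fdr) & fdr < fdr_threshold & log2fc < 0] <- "down"

  data.frame(
    feature_id = counts$feature_ids,
    base_mean = base_mean,
    log2fc = log2fc,
    p_value = p,
    fdr = fdr,
    direction = direction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing values are passed through untouched and do not count toward the
#' number of tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values in the input order.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}
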