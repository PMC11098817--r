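#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list accumulating `|stat|^weight / sum(|stat|^weight)`
#' at gene-set hits and subtracting `1 / (N - |set|)` at misses; the
#' enrichment score (ES) is the signed extremum of the running sum.  With
#' `weight = 0` this is the classic KS statistic and ES lies in [-1, 1].
#' The list is ordered by decreasing statistic with ties broken by gene id.
#'
#' @param statistics Named numeric vector of per-gene ranking statistics
#'   (finite, unique names).
#' @param gene_set Character vector; must share at least one gene with the
#'   list.
#' @param weight Non-negative exponent on the hit increments (default 1).
#' @return List with `es`, `running_sum` (named numeric in list order) and
#'   `peak_position` (index of the extremum).
#' @export
enrichment_score <- function(statistics, gene_set, weight = 1) {
  if (is.null(names(statistics)) || anyDuplicated(names(statistics))) {
    stop("statistics must carry unique gene names", call. = FALSE)
  }
  if (any(!is.finite(statistics))) stop("statistics must be finite", call. = FALSE)
  if (weight < 0) stop("weight must be non-negative", call. = FALSE)
  hit_ids <- intersect(names(statistics), gene_set)
  if (!length(hit_ids)) {
    stop("gene_set shares no genes with the ranked list", call. = FALSE)
  }
  ord <- order(-statistics, names(statistics))
  stats_o <- statistics[ord]
  hit <- names(stats_o) %in% hit_ids
  n <- length(stats_o)
  n_hit <- sum(hit)
  if (n_hit == n) stop("gene_set covers the entire list", call. = FALSE)

  w <- abs(stats_o)^weight
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak],
       running_sum = setNames(running, names(stats_o)),
       peak_position = peak)
}

# signal-to-noise ratio per gene between two column groups, with the
# standard GSEA standard-deviation floors (0.2 * |mean|, minimum 0.2)
signal_to_noise <- function(x, idx1, idx2) {
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  sd_adj <- function(xs, m) {
    n <- ncol(xs)
    s <- sqrt(pmax(rowSums((xs - m)^2) / (n - 1), 0))
    pmax(s, 0.2 * abs(m), 0.2)
  }
  s1 <- sd_adj(x[, idx1, drop = FALSE], m1)
  s2 <- sd_adj(x[, idx2, drop = FALSE], m2)
  (m1 - m2) / (s1 + s2)
}

#' Gene set enrichment with phenotype-permutation significance
#'
#' Ranks genes by the signal-to-noise ratio between the two groups (first
#' group level minus second), computes the weighted KS enrichment score of
#' the gene set, and assesses significance by permuting the group labels:
#' the normalized enrichment score (NES) divides the observed ES by the
#' mean |null ES| of matching sign, the nominal p-value is the fraction of
#' same-sign null ES at least as extreme, and the family-wise error rate
#' (FWER) p-value is the fraction of permutations whose most extreme
#' normalized null ES exceeds |NES| in magnitude, floored at the nominal
#' p-value (a family-wise rate cannot undercut the per-set rate).
#'
#' @param expression Gene x cell numeric matrix (dimnames required).
#' @param groups Factor/character of length `ncol(expression)` with two
#'   levels and at least 3 cells each.
#' @param gene_set Character vector of gene ids.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param weight Weight for [enrichment_score()] (default 1).
#' @return List with `es`, `nes`, `p_nominal`, `p_fwer`, `peak_position`,
#'   `running_sum`, and the per-gene `ranking` statistic.
#' @export
gsea_significance <- function(expression, groups, gene_set,
                              n_permutations = 1000, seed, weight = 1) {
  if (!is.matrix(expression) || is.null(rownames(expression))) {
    stop("expression must be a gene x cell matrix with rownames", call. = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || length(groups) != ncol(expression)) {
    stop("groups must label every cell with one of two levels", call. = FALSE)
  }
  if (min(table(groups)) < 3) stop("each group needs >= 3 cells", call. = FALSE)
  n_permutations <- assert_count(n_permutations, "n_permutations", min = 1)

  idx1 <- which(groups == levels(groups)[1])
  idx2 <- which(groups == levels(groups)[2])
  stat_obs <- signal_to_noise(expression, idx1, idx2)
  names(stat_obs) <- rownames(expression)
  obs <- enrichment_score(stat_obs, gene_set, weight)

  n1 <- length(idx1)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- sample(ncol(expression))
      s <- signal_to_noise(expression, perm[seq_len(n1)], perm[-seq_len(n1)])
      names(s) <- rownames(expression)
      enrichment_score(s, gene_set, weight)$es
    }, numeric(1))
  })

  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  mean_pos <- mean(abs(null_es[null_es >= 0]))
  mean_neg <- mean(abs(null_es[null_es < 0]))
  norm_by_sign <- function(es) {
    denom <- ifelse(es >= 0, mean_pos, mean_neg)
    es / denom
  }
  nes <- norm_by_sign(obs$es)
  p_nominal <- if (length(same_sign)) {
    mean(abs(same_sign) >= abs(obs$es))
  } else {
    0
  }
  null_nes <- norm_by_sign(null_es)
  p_fwer <- mean(abs(null_nes) >= abs(nes), na.rm = TRUE)
  # a family-wise error rate can never undercut the per-set nominal rate;
  # floor the Monte-Carlo FWER estimate accordingly
  p_fwer <- max(p_fwer, p_nominal)

  list(es = obs$es, nes = nes,
       p_nominal = p_nominal, p_fwer = p_fwer,
       peak_position = obs$peak_position,
       running_sum = obs$running_sum,
       ranking = stat_obs,
       null_es = null_es)
}

#' Subsample the larger of two groups to balance sizes
#'
#' Randomly samples (without replacement) cells of the larger group so both
#' groups have the size of the smaller one; deterministic for a fixed seed.
#'
#' @param groups Factor/character of group labels.
#' @param seed Integer seed.
#' @return Integer vector of retained column indices (sorted).
#' @export
balance_groups <- function(groups, seed) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  tab <- table(groups)
  small <- names(tab)[which.min(tab)]
  big <- setdiff(names(tab), small)
  keep_small <- which(groups == small)
  keep_big <- with_seed(seed, sample(which(groups == big), min(tab)))
  sort(c(keep_small, keep_big))
}
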