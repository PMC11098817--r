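#' Derive the concordant gene set from expression, accessibility and links
#'
#' A gene is concordant when it is up-regulated (expression FDR below
#' `expr_fdr` with positive log2 fold change) and is linked to at least one
#' CRE with increased accessibility (accessibility FDR below `access_fdr`
#' with positive log2 fold change).  "De novo accessibility" is interpreted
#' as a significant accessibility increase, not peak presence/absence; no
#' dosage requirement is imposed on genes with several CREs.
#'
#' Alongside the set, the 2x2 table needed for over-representation testing
#' is returned over the universe of tested genes (non-missing expression
#' FDR): up-regulation cross-classified against linkage to at least one CRE
#' with *altered* (either direction) accessibility.
#'
#' @param expr,access Data frames as returned by [test_differential()] for
#'   genes and CREs respectively.
#' @param interactions Data frame with columns cre_id, gene_id (as from
#'   [assign_target_genes()]).
#' @param expr_fdr,access_fdr FDR thresholds.
#' @return Object of class `concordant_set`: list with `gene_ids` (sorted
#'   character vector), `table` (named counts a, b, c, d), `universe`
#'   (number of tested genes) and `rule` (thresholds and interpretation
#'   flags).
#' @export
derive_concordant_set <- function(expr, access, interactions,
                                  expr_fdr = 0.05, access_fdr = 0.05) {
  stopifnot(all(c("feature_id", "log2fc", "fdr") %in% names(expr)),
            all(c("feature_id", "log2fc", "fdr") %in% names(access)))
  if (nrow(interactions) == 0) {
    warning("empty interaction map: concordant set is empty", call. = FALSE)
  } else {
    stopifnot(all(c("cre_id", "gene_id") %in% names(interactions)))
    if (!all(interactions$gene_id %in% expr$feature_id) ||
        !all(interactions$cre_id %in% access$feature_id)) {
      stop("interactions reference features absent from the results tables",
           call. = FALSE)
    }
  }

  tested <- expr[!is.na(expr$fdr), , drop = FALSE]
  up_genes <- tested$feature_id[tested$fdr < expr_fdr & tested$log2fc > 0]

  acc_sig <- access$feature_id[!is.na(access$fdr) & access$fdr < access_fdr]
  acc_up <- access$feature_id[!is.na(access$fdr) & access$fdr < access_fdr &
                                access$log2fc > 0]

  if (nrow(interactions)) {
    linked_altered <- unique(interactions$gene_id[interactions$cre_id %in% acc_sig])
    linked_up <- unique(interactions$gene_id[interactions$cre_id %in% acc_up])
  } else {
    linked_altered <- linked_up <- character(0)
  }

  concordant <- sort(intersect(up_genes, linked_up))

  u <- tested$feature_id
  is_up <- u %in% up_genes
  is_linked <- u %in% linked_altered
  tab <- c(
    a = sum(is_up & is_linked),
    b = sum(is_up & !is_linked),
    c = sum(!is_up & is_linked),
    d = sum(!is_up & !is_linked)
  )

  structure(
    list(
      gene_ids = concordant,
      table = tab,
      universe = length(u),
      up_genes = sort(up_genes),
      linked_genes = sort(linked_altered),
      rule = list(expr_fdr = expr_fdr, access_fdr = access_fdr,
                  expression_direction = "up",
                  accessibility_direction = "up",
                  de_novo_as = "significant increase")
    ),
    class = "concordant_set"
  )
}

#' @export
print.concordant_set <- function(x, ...) {
  cat("concordant_set:", length(x$gene_ids), "genes",
      sprintf("(universe %d; 2x2 a=%d b=%d c=%d d=%d)\n",
              x$universe, x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  invisible(x)
}

#' Fisher exact over-representation test on a 2x2 table
#'
#' Two-sided exact p-value (summing hypergeometric probabilities no larger
#' than that of the observed table) and the sample odds ratio
#' `(a*d)/(b*c)`, reported without continuity correction (`Inf` or 0 when a
#' margin cell is zero).
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are the condition
#'   of interest (e.g. up-regulated yes/no), columns the annotation (linked
#'   yes/no).
#' @return List with `odds_ratio` and `p_value`.
#' @export
overrepresentation_test <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("all-zero 2x2 table", call. = FALSE)
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Hypergeometric upper-tail overlap test
#'
#' Probability of observing an overlap at least as large as `overlap`
#' between two sets of sizes `set1` and `set2` drawn from a universe of
#' size `universe`: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param universe Universe size N.
#' @param set1 Size K of the first set.
#' @param set2 Size n of the second set.
#' @param overlap Observed overlap k.
#' @return Upper-tail p-value.
#' @export
overlap_hypergeometric <- function(universe, set1, set2, overlap) {
  for (v in c(universe, set1, set2, overlap)) {
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
  }
  if (set1 > universe || set2 > universe || overlap > min(set1, set2)) {
    stop("inconsistent counts: need overlap <= min(set1, set2) <= universe",
         call. = FALSE)
  }
  phyper(overlap - 1, set1, universe - set1, set2, lower.tail = FALSE)
}

#' Median fold change of target genes by CRE-TSS distance bin
#'
#' Buckets CRE-gene interactions by distance and reports, per bin, the
#' number of interactions and the median target-gene log2 fold change —
#' the summary used to show regulatory effects decaying with distance.
#' Bins are half-open `[edge_i, edge_{i+1})`; interactions outside the
#' edges are dropped; empty bins keep `n = 0` and a missing median.
#'
#' @param interactions Data frame with columns gene_id, distance.
#' @param expr Expression differential results (feature_id, log2fc).
#' @param bin_edges Strictly increasing numeric vector of bp edges.
#' @return Data frame with columns bin_start, bin_end, n, median_log2fc.
#' @export
distance_decay <- function(interactions, expr, bin_edges) {
  if (any(diff(bin_edges) <= 0) || length(bin_edges) < 2) {
    stop("bin_edges must be strictly increasing with >= 2 edges", call. = FALSE)
  }
  nb <- length(bin_edges) - 1
  out <- data.frame(
    bin_start = bin_edges[-length(bin_edges)],
    bin_end = bin_edges[-1],
    n = integer(nb),
    median_log2fc = rep(NA_real_, nb)
  )
  if (!nrow(interactions)) return(out)
  lfc <- expr$log2fc[match(interactions$gene_id, expr$feature_id)]
  bin <- findInterval(interactions$distance, bin_edges,
                      rightmost.closed = FALSE)
  keep <- bin >= 1 & bin <= nb & interactions$distance < bin_edges[nb + 1]
  for (b in seq_len(nb)) {
    sel <- keep & bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) out$median_log2fc[b] <- median(lfc[sel], na.rm = TRUE)
  }
  out
}
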