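#' Construct a feature-by-sample count matrix with condition labels
#'
#' @param counts Non-negative integer matrix, features in rows, samples in
#'   columns; dimnames required and unique.
#' @param condition Named character vector mapping every sample to
#'   `"control"` or `"coculture"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must be a matrix with row (feature) and column (sample) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("feature_ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  condition <- condition[colnames(counts)]
  if (anyNA(condition) || !all(condition %in% c("control", "coculture"))) {
    stop("`condition` must label every sample as control or coculture",
         call. = FALSE)
  }
  structure(
    list(counts = counts,
         feature_ids = rownames(counts),
         sample_ids = colnames(counts),
         condition = condition),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples (",
      sum(x$condition == "control"), "control,",
      sum(x$condition == "coculture"), "coculture )\n")
  invisible(x)
}

#' Simulate a two-condition co-culture experiment with planted cis-effects
#'
#' Emulates the bulk readout of a myeloma / bone-marrow-stroma co-culture
#' design: ATAC-seq counts over the annotation's CREs and RNA-seq counts
#' over its genes, in matched control and co-culture conditions.  A chosen
#' fraction of CREs gains accessibility in the co-culture condition
#' (`effect_log2fc`), and a `coupling` fraction of those CREs transmits the
#' same fold change to the nearest gene in the same TAD within
#' `max_link_distance` of the CRE midpoint — the planted cis-regulatory
#' interactions the integration stage should recover.
#'
#' Counts are negative binomial with mean `baseline_mean` and dispersion
#' `dispersion` (variance mu + dispersion * mu^2).  Unplanted features keep
#' the baseline mean in both conditions.
#'
#' @param annotation A `genome_annotation`.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param baseline_mean Baseline NB mean count per feature.
#' @param dispersion NB dispersion alpha (> 0).
#' @param planted_fraction Fraction of CREs receiving the accessibility
#'   effect.
#' @param effect_log2fc Planted log2 fold change (co-culture vs control).
#' @param coupling Fraction of planted CREs whose effect is transmitted to a
#'   same-TAD target gene.
#' @param max_link_distance Maximum CRE-midpoint-to-TSS distance for a
#'   planted interaction, in bp.
#'
#' @return A list with elements `atac` and `rna` (`count_matrix` objects)
#'   and `truth` (class `planted_truth`): data frames `differential_cres`
#'   (cre_id, log2fc), `differential_genes` (gene_id, log2fc) and
#'   `interactions` (cre_id, gene_id, tad_id, distance).
#' @export
generate_coculture_experiment <- function(annotation,
                                          seed,
                                          n_replicates = 3,
                                          baseline_mean = 100,
                                          dispersion = 0.05,
                                          planted_fraction = 0.1,
                                          effect_log2fc = 2,
                                          coupling = 1,
                                          max_link_distance = 1e6) {
  stopifnot(inherits(annotation, "genome_annotation"))
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2)
  assert_scalar_number(baseline_mean, "baseline_mean", min = 1)
  assert_scalar_number(dispersion, "dispersion", min = .Machine$double.eps)
  assert_scalar_number(planted_fraction, "planted_fraction", min = 0, max = 1)
  assert_scalar_number(effect_log2fc, "effect_log2fc")
  assert_scalar_number(coupling, "coupling", min = 0, max = 1)
  if (coupling > 0 && all(is.na(annotation$cres$tad_id))) {
    stop("coupling > 0 requires an annotation with TADs", call. = FALSE)
  }

  cres <- annotation$cres
  genes <- annotation$genes
  n_cres <- nrow(cres)
  n_genes <- nrow(genes)

  with_seed(seed, {
    n_planted <- round(planted_fraction * n_cres)
    planted_cres <- if (n_planted > 0) {
      sort(sample(cres$cre_id, n_planted))
    } else character(0)

    # couple a fraction of planted CREs to their nearest same-TAD gene
    n_coupled <- round(coupling * n_planted)
    coupled_cres <- if (n_coupled > 0) {
      sort(sample(planted_cres, n_coupled))
    } else character(0)

    interactions <- nearest_same_tad_gene(
      cres[match(coupled_cres, cres$cre_id), , drop = FALSE],
      genes, max_link_distance
    )
    diff_genes <- sort(unique(interactions$gene_id))

    mu_mat <- function(ids, planted_ids) {
      mu0 <- rep(baseline_mean, length(ids))
      mu1 <- mu0
      mu1[ids %in% planted_ids] <- baseline_mean * 2^effect_log2fc
      cbind(matrix(rep(mu0, n_replicates), ncol = n_replicates),
            matrix(rep(mu1, n_replicates), ncol = n_replicates))
    }
    draw <- function(mu, ids, prefix) {
      k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                  nrow = nrow(mu))
      rownames(k) <- ids
      colnames(k) <- c(paste0(prefix, "_ctrl_", seq_len(n_replicates)),
                       paste0(prefix, "_cocx_", seq_len(n_replicates)))
      k
    }
    cond <- function(prefix) {
      setNames(rep(c("control", "coculture"), each = n_replicates),
               c(paste0(prefix, "_ctrl_", seq_len(n_replicates)),
                 paste0(prefix, "_cocx_", seq_len(n_replicates))))
    }

    atac <- count_matrix(draw(mu_mat(cres$cre_id, planted_cres),
                              cres$cre_id, "atac"), cond("atac"))
    rna <- count_matrix(draw(mu_mat(genes$gene_id, diff_genes),
                             genes$gene_id, "rna"), cond("rna"))

    truth <- structure(
      list(
        differential_cres = data.frame(
          cre_id = planted_cres,
          log2fc = rep(effect_log2fc, length(planted_cres)),
          stringsAsFactors = FALSE
        ),
        differential_genes = data.frame(
          gene_id = diff_genes,
          log2fc = rep(effect_log2fc, length(diff_genes)),
          stringsAsFactors = FALSE
        ),
        interactions = interactions
      ),
      class = "planted_truth"
    )

    list(atac = atac, rna = rna, truth = truth)
  })
}

# For each region, the nearest gene sharing its tad_id within max_distance
# of the region midpoint; regions with no eligible gene yield no row.
nearest_same_tad_gene <- function(regions, genes, max_distance) {
  if (nrow(regions) == 0) {
    return(data.frame(cre_id = character(0), gene_id = character(0),
                      tad_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  mids <- region_midpoint(regions)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    if (is.na(regions$tad_id[i])) return(NULL)
    cand <- genes[!is.na(genes$tad_id) & genes$tad_id == regions$tad_id[i], ,
                  drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    d <- abs(cand$tss - mids[i])
    ok <- d <= max_distance
    if (!any(ok)) return(NULL)
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    j <- order(d, cand$gene_id)[1]
    data.frame(cre_id = regions$cre_id[i], gene_id = cand$gene_id[j],
               tad_id = regions$tad_id[i], distance = d[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cre_id = character(0), gene_id = character(0),
                      tad_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
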