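#' Intersect two sets of genomic regions
#'
#' All overlapping pairs between query and database regions under 0-based
#' half-open (BED) semantics; bookended intervals ([0,10) vs [10,20)) do
#' not overlap.  Overlap width is `min(ends) - max(starts)`.
#'
#' @param query,database Data frames with columns chrom, start, end and an
#'   id column (`id`, or the first column ending in `_id`).
#' @return Data frame with columns query_id, database_id, overlap_bp.
#' @export
intersect_regions <- function(query, database) {
  if (!nrow(query) || !nrow(database)) {
    stop("query and database must be nonempty", call. = FALSE)
  }
  qid <- region_ids(query, "query")
  did <- region_ids(database, "database")
  validate_regions(query, "query")
  validate_regions(database, "database")

  lv <- union(unique(query$chrom), unique(database$chrom))
  qr <- regions_to_granges(query, lv)
  dr <- regions_to_granges(database, lv)
  hits <- GenomicRanges::findOverlaps(qr, dr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  dh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(qr[qh], dr[dh]))
  data.frame(
    query_id = qid[qh],
    database_id = did[dh],
    overlap_bp = as.numeric(ov),
    stringsAsFactors = FALSE
  )
}

#' Count, per query region, how many databases it overlaps
#'
#' Venn-style summary across several CRE databases: each query region is
#' labeled with the number of databases containing at least one overlapping
#' element.
#'
#' @param query Region data frame.
#' @param databases Named list of region data frames.
#' @return Data frame with columns query_id, n_databases, and one logical
#'   column per database.
#' @export
count_database_hits <- function(query, databases) {
  stopifnot(is.list(databases), length(databases) >= 1)
  if (is.null(names(databases))) {
    names(databases) <- paste0("db", seq_along(databases))
  }
  qid <- region_ids(query, "query")
  flags <- vapply(databases, function(db) {
    hit <- intersect_regions(query, db)
    qid %in% hit$query_id
  }, logical(length(qid)))
  flags <- matrix(flags, nrow = length(qid),
                  dimnames = list(NULL, names(databases)))
  out <- data.frame(query_id = qid, n_databases = rowSums(flags),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(flags))
}

#' Assign differential regions to proximal target genes within TADs
#'
#' Implements the two selection criteria for enhancer-to-gene assignment:
#' linear proximity (gene TSS within `max_distance` of the region midpoint)
#' and shared TAD membership (the TSS must lie in the same TAD as the
#' region midpoint, so no assignment crosses a TAD boundary).  For each
#' region the `max_genes` nearest eligible genes are retained, ranked by
#' distance, with distance ties broken by lexicographic gene id.  Regions
#' whose midpoint falls in no TAD are skipped with a warning; regions with
#' no eligible gene simply produce no interaction.
#'
#' @param regions Region data frame (chrom, start, end, id column).
#' @param genes Data frame with columns gene_id, chrom, tss (and optionally
#'   strand).
#' @param tads Data frame of non-overlapping TADs (chrom, start, end,
#'   tad_id).
#' @param max_distance Maximum midpoint-to-TSS distance in bp.
#' @param max_genes Number of target genes retained per region (1 or 2).
#' @return Data frame with columns cre_id, gene_id, distance, tad_id,
#'   same_tad (always `TRUE` for retained rows), rank.
#' @export
assign_target_genes <- function(regions, genes, tads,
                                max_distance = 1e6, max_genes = 2) {
  validate_regions(regions, "regions")
  validate_regions(tads, "tads", id_col = "tad_id")
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  if (!max_genes %in% c(1, 2)) stop("max_genes must be 1 or 2", call. = FALSE)
  rid <- region_ids(regions, "regions")

  mids <- region_midpoint(regions)
  region_tad <- locate_tad(regions$chrom, mids, tads)
  gene_tad <- locate_tad(genes$chrom, genes$tss, tads)

  n_orphan <- sum(is.na(region_tad))
  if (n_orphan > 0) {
    warning(sprintf("%d region(s) with midpoint outside any TAD were skipped",
                    n_orphan), call. = FALSE)
  }

  rows <- lapply(which(!is.na(region_tad)), function(i) {
    sel <- !is.na(gene_tad) & gene_tad == region_tad[i]
    if (!any(sel)) return(NULL)
    cand <- genes[sel, , drop = FALSE]
    d <- abs(cand$tss - mids[i])
    ok <- d <= max_distance
    if (!any(ok)) return(NULL)
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    ord <- order(d, cand$gene_id)
    take <- head(ord, max_genes)
    data.frame(
      cre_id = rid[i],
      gene_id = cand$gene_id[take],
      distance = d[take],
      tad_id = region_tad[i],
      same_tad = TRUE,
      rank = seq_along(take),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cre_id = character(0), gene_id = character(0),
                      distance = numeric(0), tad_id = character(0),
                      same_tad = logical(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

region_ids <- function(regions, what) {
  if ("id" %in% names(regions)) return(as.character(regions$id))
  idc <- grep("_id$", names(regions), value = TRUE)
  if (length(idc)) return(as.character(regions[[idc[1]]]))
  as.character(seq_len(nrow(regions)))
}

# 0-based half-open data frame -> 1-based closed GRanges
regions_to_granges <- function(regions, seqlevels = unique(regions$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}
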