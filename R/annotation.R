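#' Generate a synthetic genome annotation with TADs, genes and CREs
#'
#' Builds a small genome of one or more chromosomes, tiles each chromosome
#' with non-overlapping topologically associating domains (TADs), and places
#' genes (as strand-aware transcription start sites) and cis-regulatory
#' elements (CREs, short ATAC-peak-like intervals) uniformly along the
#' genome.  Every gene TSS and every CRE is tagged with the TAD containing
#' it (by TSS for genes, by interval midpoint for CREs), the geometry the
#' downstream TAD-constrained enhancer-gene linking relies on.
#'
#' All coordinates are 0-based half-open (BED convention).  A position
#' sitting exactly on a TAD boundary belongs to the TAD on its right.
#'
#' @param seed Integer seed; the annotation is deterministic given the seed
#'   and parameters.
#' @param n_chromosomes Number of chromosomes (named `"chr1"`, `"chr2"`, ...).
#' @param chromosome_length Length of each chromosome in bp.
#' @param n_tads Number of TADs per chromosome; TADs tile the chromosome
#'   without overlap, with breakpoints drawn at random subject to a minimum
#'   width.
#' @param n_genes,n_cres Total numbers of genes and CREs across the genome;
#'   elements are assigned to chromosomes with probability proportional to
#'   chromosome length.
#' @param min_tad_width Minimum TAD width in bp.
#' @param cre_width_range Range (min, max) of CRE interval widths in bp.
#'
#' @return An object of class `genome_annotation`: a list with data frames
#'   `chromosomes` (name, length), `tads` (chrom, start, end, tad_id),
#'   `genes` (gene_id, chrom, tss, strand, tad_id) and `cres`
#'   (cre_id, chrom, start, end, tad_id).
#' @export
generate_genome_annotation <- function(seed,
                                       n_chromosomes = 1,
                                       chromosome_length = 1e7,
                                       n_tads = 10,
                                       n_genes = 100,
                                       n_cres = 500,
                                       min_tad_width = 5e4,
                                       cre_width_range = c(200, 800)) {
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", min = 1)
  chromosome_length <- assert_count(chromosome_length, "chromosome_length", min = 1)
  n_tads <- assert_count(n_tads, "n_tads", min = 1)
  n_genes <- assert_count(n_genes, "n_genes", min = 1)
  n_cres <- assert_count(n_cres, "n_cres", min = 1)
  if (n_tads * min_tad_width > chromosome_length) {
    stop("infeasible geometry: n_tads * min_tad_width exceeds chromosome_length",
         call. = FALSE)
  }
  if (max(cre_width_range) >= chromosome_length) {
    stop("CRE width exceeds chromosome length", call. = FALSE)
  }

  with_seed(seed, {
    chroms <- data.frame(
      name = paste0("chr", seq_len(n_chromosomes)),
      length = rep(chromosome_length, n_chromosomes),
      stringsAsFactors = FALSE
    )

    tads <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
      # random interior breakpoints with the minimum width enforced by
      # spreading the slack uniformly between TADs
      slack <- chromosome_length - n_tads * min_tad_width
      cuts <- if (n_tads > 1) sort(runif(n_tads - 1, 0, slack)) else numeric(0)
      widths <- diff(c(0, cuts, slack)) + min_tad_width
      ends <- round(cumsum(widths))
      ends[n_tads] <- chromosome_length
      data.frame(
        chrom = chroms$name[ci],
        start = c(0, head(ends, -1)),
        end = ends,
        tad_id = sprintf("tad_%s_%03d", chroms$name[ci], seq_len(n_tads)),
        stringsAsFactors = FALSE
      )
    }))
    tads$start <- as.numeric(tads$start)
    tads$end <- as.numeric(tads$end)

    place <- function(n) {
      chrom <- chroms$name[sample.int(n_chromosomes, n, replace = TRUE,
                                      prob = chroms$length)]
      pos <- floor(runif(n, 0, chromosome_length))
      list(chrom = chrom, pos = pos)
    }

    gp <- place(n_genes)
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = gp$chrom,
      tss = gp$pos,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    genes$tad_id <- locate_tad(genes$chrom, genes$tss, tads)

    cp <- place(n_cres)
    widths <- floor(runif(n_cres, cre_width_range[1], cre_width_range[2] + 1))
    start <- pmin(cp$pos, chromosome_length - widths)
    cres <- data.frame(
      cre_id = sprintf("cre_%05d", seq_len(n_cres)),
      chrom = cp$chrom,
      start = start,
      end = start + widths,
      stringsAsFactors = FALSE
    )
    cres$tad_id <- locate_tad(cres$chrom, region_midpoint(cres), tads)

    structure(
      list(chromosomes = chroms, tads = tads, genes = genes, cres = cres),
      class = "genome_annotation"
    )
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      nrow(x$chromosomes), "chromosome(s),",
      nrow(x$tads), "TADs,",
      nrow(x$genes), "genes,",
      nrow(x$cres), "CREs\n")
  invisible(x)
}

# Midpoint of half-open intervals, floored to an integer position.
region_midpoint <- function(regions) {
  floor((regions$start + regions$end) / 2)
}

#' Locate the TAD containing each position
#'
#' Membership follows half-open semantics: a position on a TAD's start
#' coordinate belongs to that TAD, a position on its end coordinate does
#' not.  Positions in inter-TAD gaps (or on chromosomes without TADs) get
#' `NA`.
#'
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param tads Data frame with columns chrom, start, end, tad_id;
#'   non-overlapping within a chromosome.
#' @return Character vector of tad_ids (NA where uncovered).
#' @export
locate_tad <- function(chrom, pos, tads) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    tt <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[idx] + 1L, width = 1L),
      IRanges::IRanges(start = tt$start + 1L, end = tt$end)
    )
    out[idx[S4Vectors::queryHits(hits)]] <- tt$tad_id[S4Vectors::subjectHits(hits)]
  }
  out
}

# Validate a data frame of 0-based half-open genomic regions.
validate_regions <- function(regions, what = "regions", id_col = "id") {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(regions) || !all(req %in% names(regions))) {
    stop(sprintf("%s must be a data frame with columns chrom, start, end", what),
         call. = FALSE)
  }
  bad <- which(!is.finite(regions$start) | !is.finite(regions$end) |
                 regions$start >= regions$end | !nzchar(regions$chrom) |
                 is.na(regions$chrom))
  if (length(bad)) {
    lbl <- if (id_col %in% names(regions)) regions[[id_col]][bad[1]] else bad[1]
    stop(sprintf("malformed interval in %s (record %s): start must be < end and chrom non-empty",
                 what, lbl), call. = FALSE)
  }
  invisible(regions)
}
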