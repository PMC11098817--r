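#' Write a genome annotation to BED/TSV files
#'
#' Writes `tads.bed` and `cres.bed` (0-based half-open BED with the element
#' id in the name column) plus `genes.tsv` (gene_id, chrom, tss, strand,
#' tad_id) into `outdir`.
#'
#' @param annotation A `genome_annotation`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_annotation <- function(annotation, outdir) {
  stopifnot(inherits(annotation, "genome_annotation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tads = file.path(outdir, "tads.bed"),
    cres = file.path(outdir, "cres.bed"),
    genes = file.path(outdir, "genes.tsv")
  )
  write_bed(annotation$tads, paths["tads"], id_col = "tad_id")
  write_bed(annotation$cres, paths["cres"], id_col = "cre_id")
  write.table(annotation$genes, paths["genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_bed <- function(regions, path, id_col) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = regions[[id_col]])
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' Reads the first four columns of a BED file (chrom, start, end, name)
#' into the 0-based half-open region data frame used across the package.
#'
#' @param path BED file path.
#' @param id_col Name for the id column in the result (e.g. `"tad_id"`).
#' @return Data frame with columns chrom, start, end and `id_col`.
#' @export
read_bed_regions <- function(path, id_col = "id") {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]),
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  out[[id_col]] <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    as.character(seq_len(nrow(bed)))
  validate_regions(out, basename(path), id_col = id_col)
  out
}

#' Write / read a count matrix as TSV
#'
#' The counts go to `<prefix>_counts.tsv` (feature ids as the first
#' column, samples as the remaining columns) and the sample sheet to
#' `<prefix>_samples.tsv` (sample_id, condition).
#'
#' @param counts A [count_matrix()].
#' @param prefix Path prefix for the two files.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, prefix) {
  stopifnot(inherits(counts, "count_matrix"))
  cpath <- paste0(prefix, "_counts.tsv")
  spath <- paste0(prefix, "_samples.tsv")
  df <- data.frame(feature_id = counts$feature_ids, counts$counts,
                   check.names = FALSE)
  write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = counts$sample_ids,
                         condition = unname(counts$condition)),
              spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cpath, samples = spath))
}

#' @rdname write_counts
#' @export
read_counts <- function(prefix) {
  df <- read.delim(paste0(prefix, "_counts.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  ss <- read.delim(paste0(prefix, "_samples.tsv"), stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  count_matrix(m, setNames(ss$condition, ss$sample_id))
}

#' Write / read a signature model as JSON
#'
#' @param signature A [signature_model()].
#' @param path JSON file path.
#' @return Invisibly (`write`) or the reconstructed model (`read`).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "signature_model"))
  obj <- list(adverse = signature$adverse,
              favorable = signature$favorable,
              endpoint = signature$endpoint,
              consensus = signature$consensus,
              coefficients = signature$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_model(obj$adverse, obj$favorable,
                  coefficients = obj$coefficients,
                  consensus = obj$consensus %||% TRUE,
                  endpoint = obj$endpoint %||% "pfs")
}

#' Write a planted-truth ledger as JSON
#'
#' @param truth A `planted_truth` object.
#' @param path JSON file path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
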