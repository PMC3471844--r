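# TSV readers/writers for the tabular dialects the package consumes.
# All in-memory coordinates are 1-based closed; BED input is shifted at the
# boundary (start + 1), matching the Bioconductor convention.

#' Read a per-marker copy-number table
#'
#' @param path TSV with header columns `sample_id`, `chrom`, `pos`, `cn`.
#' @return data.frame with those columns.
#' @export
read_markers <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "cn")
  if (!all(need %in% names(mk))) {
    stop("marker file needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(mk$cn)) || any(mk$cn < 0)) {
    stop("marker cn values must be finite and non-negative")
  }
  mk[need]
}

#' Read and write SEG-style segment tables
#'
#' Columns: `sample_id`, `chrom`, `start`, `end`, `n_markers`, `mean_cn`
#' (1-based closed coordinates).
#'
#' @param path File path.
#' @return `read_seg()` returns a data.frame; `write_seg()` returns `path`
#'   invisibly.
#' @export
read_seg <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "mean_cn")
  if (!all(need %in% names(seg))) {
    stop("SEG file needs columns: ", paste(need, collapse = ", "))
  }
  seg
}

#' @param segments Segment data.frame as returned by [segment_profile()].
#' @rdname read_seg
#' @export
write_seg <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA locus annotation
#'
#' Accepts either a headered TSV with columns `mirna_id`, `chrom`, `start`,
#' `end` (1-based closed, optional `cytoband`), or a headerless BED file
#' (`chrom`, `start`, `end`, `name`; 0-based half-open) when `bed = TRUE`.
#'
#' @param path File path.
#' @param bed Logical; interpret the file as BED (default FALSE).
#' @return data.frame with columns `mirna_id`, `chrom`, `start`, `end` and
#'   `cytoband` (NA when absent), in 1-based closed coordinates.
#' @export
read_mirna_loci <- function(path, bed = FALSE) {
  if (bed) {
    b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(b) < 4L) stop("BED annotation needs >= 4 columns")
    loci <- data.frame(mirna_id = b[[4L]], chrom = b[[1L]],
                       start = b[[2L]] + 1L, end = b[[3L]],
                       cytoband = NA_character_)
  } else {
    loci <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("mirna_id", "chrom", "start", "end")
    if (!all(need %in% names(loci))) {
      stop("locus file needs columns: ", paste(need, collapse = ", "))
    }
    if (is.null(loci$cytoband)) loci$cytoband <- NA_character_
    loci <- loci[c(need, "cytoband")]
  }
  if (anyDuplicated(loci$mirna_id)) stop("duplicate mirna_id in annotation")
  if (any(loci$start < 1L) || any(loci$end < loci$start)) {
    stop("invalid locus coordinates")
  }
  loci
}

#' Published miRNA copy-number calls in 16 myeloid cell lines
#'
#' Loads the bundled table of 19 miRNA loci whose expression was associated
#' with copy-number state in a panel of 16 myeloid leukemia cell lines:
#' per-miRNA cytoband, coordinates, mean copy-number value of the altered
#' region, the reported expression direction, and the affected lines.
#'
#' @return data.frame with columns `mirna_id`, `cytoband`, `start`, `end`,
#'   `mean_cn`, `expression`, `cell_lines`.
#' @examples
#' tab <- mir_cnv_table()
#' table(classify_cn(tab$mean_cn))
#' @export
mir_cnv_table <- function() {
  path <- system.file("extdata", "mir_cnv_cell_lines.tsv",
                      package = "mirdose", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
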