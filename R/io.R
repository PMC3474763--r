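#' File formats
#'
#' Plain-text interchange used by the pipeline: FASTA for sequences
#' (via \pkg{Biostrings}), TSV for coordinate tables, expression matrices
#' and sample designs (1-based inclusive coordinates on disk), and JSON
#' for ground-truth ledgers and reports.
#'
#' @name survey_io
NULL

#' @rdname survey_io
#' @param sequences Named character vector.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(sequences, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::AAStringSet(sequences)
  } else {
    Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname survey_io
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname survey_io
#' @param loci Coordinate data.frame.
#' @export
write_coord_table <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @export
read_coord_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "family", "chromosome", "start", "end", "strand")
  if (!all(required %in% names(tab))) {
    stop(sprintf("coordinate table must have columns: %s",
                 paste(required, collapse = ", ")))
  }
  if (any(tab$start >= tab$end)) stop("coordinate table: start must be < end")
  tab
}

#' @rdname survey_io
#' @param mat Expression matrix (genes x samples).
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  if (anyNA(mat)) stop("expression matrix contains missing values")
  attr(mat, "scale") <- "log2"
  mat
}

#' @rdname survey_io
#' @param design Sample design data.frame.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @export
read_design_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  required <- c("sample_id", "condition", "replicate", "mock_partner")
  if (!all(required %in% names(tab))) {
    stop(sprintf("design table must have columns: %s",
                 paste(required, collapse = ", ")))
  }
  tab
}
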