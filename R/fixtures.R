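#' Load the packaged MAPK/MAPKK nomenclature table
#'
#' Returns the packaged nomenclature fixture for the *Brachypodium
#' distachyon* MAPK and MAPKK families: the Bd gene name and gene-model
#' identifier for each family member, side by side with the *Arabidopsis*
#' and rice nomenclature columns as printed (cross-species cells are `NA`
#' where the source table leaves them blank).
#'
#' Load-time invariants are asserted: 16 rows labelled `MAPK`, 12 labelled
#' `MAPKK`, and every Bd gene-model identifier following the
#' `Bradi<chr>g<locus>` convention.
#'
#' @return A data.frame with columns `family`, `bd_name`, `bd_gene_model`,
#'   `at_name`, `at_code`, `os_name`, `os_code`.
#' @export
#' @examples
#' tab1 <- load_table1_fixture()
#' table(tab1$family)
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_nomenclature.tsv",
                      package = "mapksurvey", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = c("", "NA"))
  required <- c("family", "bd_name", "bd_gene_model", "at_name", "at_code",
                "os_name", "os_code")
  if (!identical(names(tab), required)) {
    stop("malformed nomenclature fixture: unexpected columns")
  }
  bad <- which(!grepl("^Bradi[0-9]+g[0-9]+$", tab$bd_gene_model))
  if (length(bad) > 0) {
    stop(sprintf("malformed nomenclature fixture: bad gene model in row %d (%s)",
                 bad[1], tab$bd_gene_model[bad[1]]))
  }
  counts <- table(factor(tab$family, levels = c("MAPK", "MAPKK")))
  if (counts[["MAPK"]] != 16L || counts[["MAPKK"]] != 12L) {
    stop("malformed nomenclature fixture: expected 16 MAPK and 12 MAPKK rows")
  }
  tab
}

#' Load the packaged ortholog/paralog pair-correlation table
#'
#' Returns the packaged fixture of 17 ortholog or paralog pairs from the
#' *B. distachyon* / rice MAPK and MAPKK families, each with its printed
#' amino-acid similarity (%) and the Pearson correlation of the pair's
#' expression profiles under matched light and temperature conditions.
#'
#' Load-time invariants are asserted: 10 `MAPK` and 7 `MAPKK` rows,
#' correlations within \[-1, 1\], similarities within \[0, 100\].
#'
#' @return A data.frame with columns `family`, `gene_a`, `gene_b`,
#'   `similarity`, `correlation`.
#' @export
#' @examples
#' tab2 <- load_table2_fixture()
#' sum(tab2$correlation > 0.5)
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_pair_correlations.tsv",
                      package = "mapksurvey", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("family", "gene_a", "gene_b", "similarity", "correlation")
  if (!identical(names(tab), required)) {
    stop("malformed pair-correlation fixture: unexpected columns")
  }
  if (nrow(tab) != 17L) {
    stop("malformed pair-correlation fixture: expected 17 rows")
  }
  counts <- table(factor(tab$family, levels = c("MAPK", "MAPKK")))
  if (counts[["MAPK"]] != 10L || counts[["MAPKK"]] != 7L) {
    stop("malformed pair-correlation fixture: expected 10 MAPK and 7 MAPKK rows")
  }
  bad <- which(abs(tab$correlation) > 1 | tab$similarity < 0 | tab$similarity > 100)
  if (length(bad) > 0) {
    stop(sprintf("malformed pair-correlation fixture: out-of-range value in row %d",
                 bad[1]))
  }
  tab
}
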