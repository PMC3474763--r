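#' Promoter cis-element scanning
#'
#' Extraction of 1-kb upstream promoter regions and counting of the four
#' stress-responsive cis-elements tracked by the survey: the W-box
#' (`TGACY`, WRKY binding), the CBF box (`GTCGAC`), the DRE box
#' (`RCCGAC`) and the GCC box (`GCCGCC`, ERF binding). Patterns are IUPAC
#' degenerate strings and are configurable.
#'
#' @name promoter_scan
NULL

#' Default cis-element patterns
#'
#' @param scan_both_strands Whether occurrences on the reverse strand are
#'   counted as well (default `TRUE`; cis-elements are conventionally
#'   treated as orientation-independent).
#' @return Data.frame with columns `name`, `iupac`, `scan_both_strands`.
#' @export
default_element_patterns <- function(scan_both_strands = TRUE) {
  data.frame(name = c("WBOX", "CBF", "DRE", "GCC"),
             iupac = c("TGACY", "GTCGAC", "RCCGAC", "GCCGCC"),
             scan_both_strands = scan_both_strands,
             stringsAsFactors = FALSE)
}

#' Extract the upstream promoter region of a locus
#'
#' Strand-aware: for a `+` strand gene the `length` bases immediately
#' upstream of the gene start; for a `-` strand gene the `length` bases
#' immediately downstream of the gene end, reverse-complemented. The region
#' is truncated (with a warning) at chromosome edges. Coordinates are
#' 1-based inclusive.
#'
#' @param genome Named character vector or `DNAStringSet`, one sequence per
#'   chromosome.
#' @param locus One-row data.frame with `chromosome`, `start`, `end`,
#'   `strand`.
#' @param length Promoter length in bp (default 1000).
#' @return The promoter sequence (single string, gene-upstream orientation).
#' @export
extract_upstream <- function(genome, locus, length = 1000) {
  chr <- as.character(locus$chromosome)
  if (!chr %in% names(genome)) stop(sprintf("chromosome '%s' not in genome", chr))
  chrom <- as.character(genome[[chr]])
  chrom_len <- nchar(chrom)
  if (locus$start < 1 || locus$end > chrom_len) {
    stop("locus lies outside its chromosome")
  }
  if (identical(as.character(locus$strand), "-")) {
    from <- locus$end + 1
    to <- locus$end + length
    if (to > chrom_len) {
      warning("promoter truncated at chromosome end")
      to <- chrom_len
    }
    if (from > to) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom, from, to))))
  } else {
    from <- locus$start - length
    to <- locus$start - 1
    if (from < 1) {
      warning("promoter truncated at chromosome start")
      from <- 1
    }
    if (from > to) return("")
    substr(chrom, from, to)
  }
}

#' Count cis-element occurrences in a promoter
#'
#' Counts every occurrence of each IUPAC pattern (overlapping occurrences
#' included). Where a pattern is scanned on both strands, reverse-strand
#' hits are added and flagged; for palindromic patterns a reverse-strand
#' hit coinciding with a forward hit is not double-counted. Ambiguity codes
#' are interpreted in the pattern only -- subject bases are matched
#' literally, so `N` runs in the promoter match nothing.
#'
#' @param promoter DNA sequence (single string over IUPAC letters).
#' @param patterns Pattern table as from [default_element_patterns()].
#' @return A list: `counts` (named integer vector) and `hits` (data.frame
#'   `element`, `start`, `end`, `strand`).
#' @export
#' @examples
#' scan_elements("TGACCTGACT")$counts
scan_elements <- function(promoter, patterns = default_element_patterns()) {
  if (grepl("[^ACGTRYSWKMBDHVN]", promoter)) {
    stop("promoter contains non-DNA characters")
  }
  hits <- list()
  subject <- Biostrings::DNAString(promoter)
  for (k in seq_len(nrow(patterns))) {
    pat <- Biostrings::DNAString(patterns$iupac[k])
    fwd <- Biostrings::matchPattern(pat, subject,
                                    fixed = c(pattern = FALSE, subject = TRUE))
    fr <- data.frame(element = rep(patterns$name[k], length(fwd)),
                     start = Biostrings::start(fwd),
                     end = Biostrings::end(fwd),
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
    rr <- NULL
    if (isTRUE(patterns$scan_both_strands[k])) {
      rc <- Biostrings::reverseComplement(pat)
      rev <- Biostrings::matchPattern(rc, subject,
                                      fixed = c(pattern = FALSE, subject = TRUE))
      rr <- data.frame(element = rep(patterns$name[k], length(rev)),
                       start = Biostrings::start(rev),
                       end = Biostrings::end(rev),
                       strand = rep("-", length(rev)),
                       stringsAsFactors = FALSE)
      # palindrome: identical interval found on both strands counts once
      dup <- paste(rr$start, rr$end) %in% paste(fr$start, fr$end)
      rr <- rr[!dup, , drop = FALSE]
    }
    hits[[k]] <- rbind(fr, rr)
  }
  hits <- do.call(rbind, hits)
  counts <- vapply(patterns$name, function(nm) sum(hits$element == nm),
                   integer(1))
  list(counts = counts, hits = hits)
}

#' Scan a set of promoters
#'
#' @param promoters Named character vector of promoter sequences.
#' @param patterns Pattern table as from [default_element_patterns()].
#' @return Data.frame with one row per promoter: `gene_id` plus one count
#'   column per element.
#' @export
scan_promoter_set <- function(promoters, patterns = default_element_patterns()) {
  if (is.null(names(promoters))) stop("`promoters` must be named")
  rows <- lapply(names(promoters), function(g) {
    counts <- scan_elements(promoters[[g]], patterns)$counts
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  do.call(rbind, rows)
}

#' Per-family summary of cis-element counts
#'
#' @param counts Data.frame as from [scan_promoter_set()].
#' @param families Named character vector mapping `gene_id` to family.
#' @param wbox_at_least Threshold for the "many W-boxes" fraction
#'   (default 6).
#' @return Data.frame with one row per family: mean count per element, the
#'   fraction of genes with at least `wbox_at_least` W-boxes, and the
#'   fraction containing at least one of each of the four elements.
#' @export
summarize_family <- function(counts, families, wbox_at_least = 6) {
  if (!all(counts$gene_id %in% names(families))) {
    stop("every gene must be assigned a family")
  }
  elements <- setdiff(names(counts), "gene_id")
  fam <- families[counts$gene_id]
  out <- lapply(unique(fam), function(f) {
    sub <- counts[fam == f, , drop = FALSE]
    means <- vapply(elements, function(e) mean(sub[[e]]), numeric(1))
    names(means) <- paste0("mean_", tolower(elements))
    all_four <- mean(apply(sub[, elements, drop = FALSE] >= 1, 1, all))
    frac_wbox <- if ("WBOX" %in% elements) {
      mean(sub$WBOX >= wbox_at_least)
    } else {
      NA_real_
    }
    cbind(data.frame(family = f, n_genes = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(frac_wbox_at_least = frac_wbox,
                     frac_all_four = all_four, stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}
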