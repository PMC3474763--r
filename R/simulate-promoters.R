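#' Synthetic promoters with planted cis-elements
#'
#' Generates fixed-length promoter sequences carrying an exact number of
#' planted instances of each cis-element, on either strand, with a ledger
#' of every planted position. Background bases are uniform over A/C/G/T
#' and cleaned by targeted mutation until no unplanned occurrence of any
#' element pattern (on either strand) remains, so a scan of the output
#' recovers exactly the ledger.
#'
#' @name simulate_promoters
NULL

iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(iupac) {
  paste0(vapply(split1(iupac), function(ch) {
    opts <- iupac_expand[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

iupac_instantiate <- function(iupac) {
  paste0(vapply(split1(iupac), function(ch) {
    opts <- split1(iupac_expand[[ch]])
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_palindromic_pattern <- function(iupac) identical(revcomp_chr(iupac), iupac)

# Break unplanned pattern matches (both strands) outside protected spans.
clean_dna_background <- function(chars, protected, iupac_patterns) {
  regexes <- unique(unlist(lapply(iupac_patterns, function(p) {
    c(iupac_regex(p), iupac_regex(revcomp_chr(p)))
  })))
  for (pass in seq_len(500L)) {
    seqstr <- paste0c(chars)
    dirty <- FALSE
    for (pat in regexes) {
      for (s in regex_starts(pat, seqstr)) {
        mt <- regex_match_at(pat, seqstr, s)
        if (is.na(mt)) next
        span <- s:(s + nchar(mt) - 1L)
        if (all(protected[span])) next
        dirty <- TRUE
        fixed <- FALSE
        for (pos in span[!protected[span]]) {
          for (repl in sample(DNA_ALPHABET)) {
            if (repl == chars[pos]) next
            trial <- chars
            trial[pos] <- repl
            if (is.na(regex_match_at(pat, paste0c(trial), s))) {
              chars <- trial
              fixed <- TRUE
              break
            }
          }
          if (fixed) break
        }
        if (!fixed) stop("internal error: could not break a spurious element match")
        seqstr <- paste0c(chars)
      }
    }
    if (!dirty) return(chars)
  }
  stop("internal error: promoter background cleanup did not converge")
}

#' Generate synthetic promoters with planted element counts
#'
#' @param n Number of promoters.
#' @param planted_counts Named integer vector of forward-strand instances
#'   per element (names must appear in `patterns$name`); applied to every
#'   promoter.
#' @param planted_counts_rev Like `planted_counts` but planted on the
#'   reverse strand (the reverse complement of an instance is inserted).
#'   Reverse planting of palindromic patterns is rejected.
#' @param length Promoter length in bp (default 1000).
#' @param patterns Element patterns, as [default_element_patterns()].
#' @param seed Integer seed.
#' @return A list: `promoters` (named character vector) and `ledger`
#'   (data.frame: `gene_id`, `element`, `start`, `end`, `strand`).
#' @export
generate_promoters <- function(n, planted_counts = c(WBOX = 0, CBF = 0,
                                                     DRE = 0, GCC = 0),
                               planted_counts_rev = NULL, length = 1000L,
                               patterns = default_element_patterns(),
                               seed = 1L) {
  planted_counts <- planted_counts[planted_counts > 0]
  if (is.null(planted_counts_rev)) planted_counts_rev <- integer(0)
  planted_counts_rev <- planted_counts_rev[planted_counts_rev > 0]
  all_names <- c(names(planted_counts), names(planted_counts_rev))
  if (!all(all_names %in% patterns$name)) {
    stop("planted element names must match the pattern table")
  }
  for (nm in names(planted_counts_rev)) {
    if (is_palindromic_pattern(patterns$iupac[patterns$name == nm])) {
      stop(sprintf("element '%s' is palindromic; reverse-strand planting is ambiguous", nm))
    }
  }
  gap <- 6L
  inst_spec <- c(rep(names(planted_counts), planted_counts),
                 rep(names(planted_counts_rev), planted_counts_rev))
  inst_strand <- c(rep("+", sum(planted_counts)),
                   rep("-", sum(planted_counts_rev)))
  widths <- vapply(inst_spec, function(nm) {
    nchar(patterns$iupac[patterns$name == nm])
  }, integer(1))
  if (sum(widths) + gap * (length(inst_spec) + 1L) > length) {
    stop("promoter cannot hold the planted elements without overlap")
  }
  with_local_seed(seed, {
    proms <- character(n)
    ledger <- list()
    for (g in seq_len(n)) {
      chars <- sample(DNA_ALPHABET, length, replace = TRUE)
      protected <- rep(FALSE, length)
      k <- length(inst_spec)
      if (k > 0) {
        ord <- sample.int(k)
        free <- length - sum(widths) - gap * (k + 1L)
        extra <- if (free > 0) {
          stats::rmultinom(1, free, rep(1, k + 1L))[, 1]
        } else {
          rep(0L, k + 1L)
        }
        pos <- 1L + gap + extra[1]
        for (idx in seq_len(k)) {
          i <- ord[idx]
          nm <- inst_spec[i]
          iupac <- patterns$iupac[patterns$name == nm]
          inst <- iupac_instantiate(iupac)
          ins <- if (inst_strand[i] == "-") revcomp_chr(inst) else inst
          span <- pos:(pos + nchar(ins) - 1L)
          chars[span] <- split1(ins)
          protected[span] <- TRUE
          ledger[[length(ledger) + 1L]] <- data.frame(
            gene_id = sprintf("PROM%03d", g), element = nm,
            start = pos, end = pos + nchar(ins) - 1L,
            strand = inst_strand[i], stringsAsFactors = FALSE)
          pos <- pos + nchar(ins) + gap + extra[idx + 1L]
        }
      }
      chars <- clean_dna_background(chars, protected, patterns$iupac)
      proms[g] <- paste0c(chars)
    }
    names(proms) <- sprintf("PROM%03d", seq_len(n))
    ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else
      data.frame(gene_id = character(0), element = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    list(promoters = proms, ledger = ledger)
  })
}
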