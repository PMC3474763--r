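# Internal helpers shared across modules.

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

# Residues that occur in no constrained position of any scanned protein
# pattern; mutating a spurious match to one of these can never create a new
# match (wildcard slots accept anything, so they matched before the edit too).
AA_NEUTRAL <- c("N", "Q", "W")

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

paste0c <- function(chars) paste(chars, collapse = "")

# All match start positions (1-based) of a regex, overlapping matches allowed.
regex_starts <- function(pattern, x) {
  starts <- integer(0)
  offset <- 0L
  s <- x
  repeat {
    m <- regexpr(pattern, s, perl = TRUE)
    if (m == -1L) break
    starts <- c(starts, offset + as.integer(m))
    skip <- as.integer(m) # advance one past the match start -> overlaps kept
    s <- substr(s, skip + 1L, nchar(s))
    offset <- offset + skip
  }
  starts
}

# Match length at each start for a fixed-width-ish regex: re-run anchored.
regex_match_at <- function(pattern, x, start) {
  s <- substr(x, start, nchar(x))
  m <- regexpr(paste0("^(?:", pattern, ")"), s, perl = TRUE)
  if (m == -1L) return(NA_character_)
  substr(s, 1L, attr(m, "match.length"))
}
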