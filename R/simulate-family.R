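#' Synthetic kinase-family sequences with exact ground truth
#'
#' Generates protein records with planted kinase motifs (anchors,
#' activation loops, active sites) and a ledger giving the exact position
#' and type of every planted motif. Background residues are drawn uniformly
#' over the 20 standard residues and then cleaned so that no unplanned
#' match to any scanned motif pattern remains: spurious matches are broken
#' by mutating an unprotected constrained position to one of the residues
#' (N, Q, W) that occur in no constrained position of any scanned pattern,
#' which provably cannot create new matches. The ledger is therefore exact
#' ground truth for the motif-rule validators.
#'
#' @name simulate_family
NULL

# every pattern the motif validators consult; background must be free of them
protein_scan_patterns <- function() {
  c("T.Y", "MEY", "HRD", "DFG", "APE", "D[ILV]K", "[ST].{5}[ST]", "D..DEP?.C")
}

#' Specification for a synthetic kinase family
#'
#' @param n_genes Number of records (>= 0).
#' @param loop_types Planted activation-loop label per MAPK-type record
#'   (recycled): `"TEY"`, `"TDY"`, `"MEY"` or `"none"`.
#' @param mapkk_fraction Proportion of records generated as MAPKK-type
#'   models (active site + S/T-X5-S/T loop) rather than MAPK-type.
#' @param loop_shift Offset per MAPKK-type record (recycled): 0 plants the
#'   loop at its canonical position, 3-5 plants it that many residues
#'   downstream of the canonical window, `NA` plants no loop (absent).
#' @param seq_length Record length in residues.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `family_sim_spec` list.
#' @export
family_sim_spec <- function(n_genes, loop_types = "TEY", mapkk_fraction = 0,
                            loop_shift = 0L, seq_length = 350L, seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 0)
  stopifnot_scalar_number(mapkk_fraction, "mapkk_fraction", 0, 1)
  if (!all(loop_types %in% c("TEY", "TDY", "MEY", "none"))) {
    stop("`loop_types` must be TEY, TDY, MEY or none")
  }
  if (!all(is.na(loop_shift) | loop_shift %in% c(0L, 3L, 4L, 5L))) {
    stop("`loop_shift` entries must be 0, 3-5 or NA (absent)")
  }
  structure(list(n_genes = as.integer(n_genes), loop_types = loop_types,
                 mapkk_fraction = mapkk_fraction,
                 loop_shift = loop_shift, seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "family_sim_spec")
}

# Break every match of `patterns` not lying fully inside a protected span.
# Mutations use the neutral residues only, so no new match can appear.
clean_protein_background <- function(chars, protected, patterns) {
  for (pass in seq_len(100L)) {
    seqstr <- paste0c(chars)
    dirty <- FALSE
    for (pat in patterns) {
      for (s in regex_starts(pat, seqstr)) {
        mt <- regex_match_at(pat, seqstr, s)
        if (is.na(mt)) next # stale: an earlier fix already removed this match
        span <- s:(s + nchar(mt) - 1L)
        if (all(protected[span])) next # a planted motif
        dirty <- TRUE
        fixed <- FALSE
        for (pos in span[!protected[span]]) {
          for (repl in sample(AA_NEUTRAL)) {
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
        if (!fixed) stop("internal error: could not break a spurious motif match")
        seqstr <- paste0c(chars)
      }
    }
    if (!dirty) return(chars)
  }
  stop("internal error: background cleanup did not converge")
}

plant <- function(chars, protected, motif, at) {
  span <- at:(at + nchar(motif) - 1L)
  if (at < 1 || max(span) > length(chars)) {
    stop("sequence too short for the planted motifs")
  }
  if (any(protected[span])) stop("planted motifs overlap")
  chars[span] <- split1(motif)
  protected[span] <- TRUE
  list(chars = chars, protected = protected)
}

#' Generate synthetic kinase-family protein records
#'
#' @param spec A [family_sim_spec()].
#' @return A list with `sequences` (named character vector) and `ledger`
#'   (data.frame: `gene_id`, `type`, `loop_type`, `loop_position`,
#'   `loop_status`, `loop_offset`, `active_site_position`).
#' @export
generate_family_sequences <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  if (spec$n_genes == 0) {
    return(list(sequences = stats::setNames(character(0), character(0)),
                ledger = data.frame(gene_id = character(0), type = character(0),
                                    loop_type = character(0),
                                    loop_position = integer(0),
                                    loop_status = character(0),
                                    loop_offset = integer(0),
                                    active_site_position = integer(0),
                                    stringsAsFactors = FALSE)))
  }
  n_kk <- round(spec$n_genes * spec$mapkk_fraction)
  n_k <- spec$n_genes - n_kk
  loop_types <- rep_len(spec$loop_types, max(n_k, 1L))
  loop_shift <- rep_len(spec$loop_shift, max(n_kk, 1L))
  patterns <- protein_scan_patterns()
  with_local_seed(spec$seed, {
    seqs <- character(spec$n_genes)
    rows <- vector("list", spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      is_kk <- g > n_k
      chars <- sample(AA_ALPHABET20, spec$seq_length, replace = TRUE)
      protected <- rep(FALSE, spec$seq_length)
      if (!is_kk) {
        lt <- loop_types[g]
        h <- 30L + sample.int(10L, 1L)
        dfg <- h + 35L
        loop <- dfg + 12L
        ape <- loop + 18L
        for (m in list(c("HRD", h), c("DFG", dfg), c("APE", ape))) {
          p <- plant(chars, protected, m[1], as.integer(m[2]))
          chars <- p$chars; protected <- p$protected
        }
        if (lt != "none") {
          p <- plant(chars, protected, lt, loop)
          chars <- p$chars; protected <- p$protected
        }
        rows[[g]] <- data.frame(
          gene_id = sprintf("SIMK%03d", g), type = "MAPK",
          loop_type = lt,
          loop_position = if (lt == "none") NA_integer_ else loop,
          loop_status = NA_character_, loop_offset = NA_integer_,
          active_site_position = NA_integer_, stringsAsFactors = FALSE)
      } else {
        shift <- loop_shift[g - n_k]
        a <- 50L + sample.int(10L, 1L)
        p <- plant(chars, protected, paste0("D", sample(c("I", "L", "V"), 1), "K"), a)
        chars <- p$chars; protected <- p$protected
        status <- "absent"
        loop_pos <- NA_integer_
        if (!is.na(shift)) {
          # canonical window is active_site + 120..170 (validator default)
          loop_pos <- if (shift == 0L) a + 140L else a + 170L + shift
          inst <- paste0(sample(c("S", "T"), 1),
                         paste0c(sample(AA_NEUTRAL, 5, replace = TRUE)),
                         sample(c("S", "T"), 1))
          p <- plant(chars, protected, inst, loop_pos)
          chars <- p$chars; protected <- p$protected
          status <- if (shift == 0L) "canonical" else "shifted"
        }
        rows[[g]] <- data.frame(
          gene_id = sprintf("SIMK%03d", g), type = "MAPKK",
          loop_type = NA_character_, loop_position = loop_pos,
          loop_status = status,
          loop_offset = if (is.na(shift)) NA_integer_ else as.integer(shift),
          active_site_position = a, stringsAsFactors = FALSE)
      }
      chars <- clean_protein_background(chars, protected, patterns)
      seqs[g] <- paste0c(chars)
    }
    ledger <- do.call(rbind, rows)
    names(seqs) <- ledger$gene_id
    list(sequences = seqs, ledger = ledger)
  })
}

#' Generate a gap-free alignment of related sequences with known cherries
#'
#' Builds a star-of-cherries family: from one master sequence, `n_pairs`
#' ancestral sequences are derived at `identity_between` percent identity,
#' and each ancestor spawns two sister taxa at `identity_within` percent
#' identity. Sisters are much closer to each other than to anything else,
#' so the planted pairs are the expected terminal cherries of a
#' neighbor-joining tree, and distances stay far from saturation.
#'
#' @param n_pairs Number of sister pairs (>= 2).
#' @param length Sequence length in residues.
#' @param identity_within Percent identity between sisters (default 95).
#' @param identity_between Percent identity of each ancestor to the master
#'   (default 70).
#' @param seed Integer seed.
#' @return A list: `alignment` (named character vector, equal lengths) and
#'   `pairs` (data.frame `leaf_a`, `leaf_b` of planted cherries).
#' @export
generate_related_alignment <- function(n_pairs = 4L, length = 300L,
                                       identity_within = 95,
                                       identity_between = 70, seed = 1L) {
  if (n_pairs < 2) stop("need at least 2 sister pairs")
  mutate_to <- function(chars, identity) {
    n_mut <- round(base::length(chars) * (1 - identity / 100))
    if (n_mut > 0) {
      at <- sample.int(base::length(chars), n_mut)
      chars[at] <- vapply(at, function(i) {
        sample(setdiff(AA_ALPHABET20, chars[i]), 1)
      }, character(1))
    }
    chars
  }
  with_local_seed(seed, {
    master <- sample(AA_ALPHABET20, length, replace = TRUE)
    aln <- list()
    pairs <- list()
    for (k in seq_len(n_pairs)) {
      anc <- mutate_to(master, identity_between)
      a <- sprintf("T%02da", k)
      b <- sprintf("T%02db", k)
      aln[[a]] <- paste0c(mutate_to(anc, identity_within))
      aln[[b]] <- paste0c(mutate_to(anc, identity_within))
      pairs[[k]] <- data.frame(leaf_a = a, leaf_b = b,
                               stringsAsFactors = FALSE)
    }
    list(alignment = unlist(aln), pairs = do.call(rbind, pairs))
  })
}

#' Generate a pair of sequences with controlled percent identity
#'
#' The first sequence is uniform random; the second carries substitutions
#' (always to a different residue) at an exact number of positions chosen
#' to realize the target identity, so the realized identity -- the
#' position-wise agreement before any alignment -- is within half a
#' percentage point of the nearest achievable value.
#'
#' @param length Sequence length in residues (>= 10).
#' @param target_identity Target percent identity in \[0, 100\].
#' @param seed Integer seed.
#' @return A list: `a`, `b` (sequences), `realized_identity` (percent).
#' @export
generate_duplicate_pair <- function(length, target_identity, seed = 1L) {
  stopifnot_scalar_number(target_identity, "target_identity", 0, 100)
  if (length < 10) stop("`length` must be at least 10")
  with_local_seed(seed, {
    a <- sample(AA_ALPHABET20, length, replace = TRUE)
    b <- a
    n_mut <- round(length * (1 - target_identity / 100))
    if (n_mut > 0) {
      at <- sample.int(length, n_mut)
      b[at] <- vapply(at, function(i) {
        sample(setdiff(AA_ALPHABET20, a[i]), 1)
      }, character(1))
    }
    list(a = paste0c(a), b = paste0c(b),
         realized_identity = 100 * mean(a == b))
  })
}
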