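#' Kinase motif rules
#'
#' Motif-rule validation of candidate MAPK and MAPKK gene models. The rules
#' operationalize the classical acceptance criteria for the two families:
#' MAPKs must carry the serine/threonine-kinase anchor motifs (HRD catalytic
#' loop, DFG, APE) with a TxY (or MEY) activation loop appropriately
#' positioned between DFG and APE; MAPKKs must carry the dual-specificity
#' active-site motif D(I/L/V)K and the plant S/T-X5-S/T phosphorylation
#' target site, which in divergent members is absent or shifted 3-5 residues
#' downstream of its canonical position.
#'
#' All positions returned by this module are 1-based residue indices.
#'
#' @name kinase_motifs
NULL

LOOP_PATTERNS <- c(TEY = "TEY", TDY = "TDY", MEY = "MEY")

default_kinase_anchors <- function() {
  list(catalytic = "HRD", upstream = "DFG", downstream = "APE")
}

validate_protein_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  if (grepl(paste0("[^", paste(c(AA_ALPHABET20, "X"), collapse = ""), "]"),
            sequence)) {
    stop("protein sequence contains characters outside the 20 residues + X",
         call. = FALSE)
  }
  invisible(sequence)
}

#' Locate the MAPK activation loop (TEY/TDY/MEY)
#'
#' Scans a protein sequence for the activation-loop signature. TEY has
#' priority over TDY, which has priority over MEY; within a signature type,
#' a match lying between the DFG and APE anchors is preferred over one
#' outside, then the leftmost match wins. `in_kinase_context` is `TRUE` iff
#' the reported match lies strictly between the upstream anchor (default
#' `DFG`) and the downstream anchor (default `APE`) when both occur.
#'
#' @param sequence Protein sequence (single string over the 20 residues + X).
#' @param anchors Named list with `upstream` and `downstream` anchor motifs,
#'   as from [default_kinase_anchors()].
#' @return A one-row data.frame (`loop_type`, `position`, `in_kinase_context`);
#'   `loop_type` is `"none"` with `NA` position when no signature occurs.
#'   `position` is the 1-based index of the first loop residue (T or M).
#' @export
#' @examples
#' find_activation_loop("AAADFGAAATEYAAAAPEAAA")
find_activation_loop <- function(sequence, anchors = default_kinase_anchors()) {
  validate_protein_sequence(sequence)
  up <- regex_starts(anchors$upstream, sequence)
  down <- regex_starts(anchors$downstream, sequence)
  up_len <- nchar(anchors$upstream)
  in_context <- function(pos) {
    # some upstream anchor ends before the loop starts, and some downstream
    # anchor starts after the loop ends
    length(up) > 0 && length(down) > 0 &&
      any(up + up_len - 1 < pos) && any(down > pos + 2)
  }
  for (lt in names(LOOP_PATTERNS)) {
    starts <- regex_starts(LOOP_PATTERNS[[lt]], sequence)
    if (length(starts) == 0) next
    ctx <- vapply(starts, in_context, logical(1))
    pick <- if (any(ctx)) starts[ctx][1] else starts[1]
    return(data.frame(loop_type = lt, position = pick,
                      in_kinase_context = in_context(pick),
                      stringsAsFactors = FALSE))
  }
  data.frame(loop_type = "none", position = NA_integer_,
             in_kinase_context = FALSE, stringsAsFactors = FALSE)
}

#' Validate a candidate MAPK gene model
#'
#' A model is accepted iff the serine/threonine-kinase anchors (catalytic
#' `HRD`, then `DFG`, then `APE`) occur in order and a `TxY` (or the rare
#' `MEY` variant) activation loop lies between the DFG and APE anchors.
#'
#' @inheritParams find_activation_loop
#' @return A list with `accepted` (flag) and `loop` (the [find_activation_loop()]
#'   row).
#' @export
validate_mapk_model <- function(sequence, anchors = default_kinase_anchors()) {
  validate_protein_sequence(sequence)
  loop <- find_activation_loop(sequence, anchors)
  cat_pos <- regex_starts(anchors$catalytic, sequence)
  up_pos <- regex_starts(anchors$upstream, sequence)
  down_pos <- regex_starts(anchors$downstream, sequence)
  accepted <- FALSE
  if (length(cat_pos) > 0 && length(up_pos) > 0 && length(down_pos) > 0) {
    # anchors in order, with a TxY-or-MEY loop inside some DFG..APE span
    txy <- sort(unique(c(regex_starts("T.Y", sequence),
                         regex_starts("MEY", sequence))))
    for (u in up_pos[up_pos > min(cat_pos)]) {
      d_after <- down_pos[down_pos > u + nchar(anchors$upstream) - 1]
      if (length(d_after) == 0) next
      d <- d_after[1]
      if (any(txy > u + nchar(anchors$upstream) - 1 & txy + 2 < d)) {
        accepted <- TRUE
        break
      }
    }
  }
  list(accepted = accepted, loop = loop)
}

#' Validate a candidate MAPKK gene model
#'
#' Checks the dual-specificity active-site motif `D(I/L/V)K` and the plant
#' phosphorylation target site `S/T-X5-S/T`. The canonical loop position is
#' defined relative to the active site: the first `[ST]x{5}[ST]` match whose
#' start falls within `active_site + canonical_window` is canonical; a first
#' match starting 3-5 residues downstream of the window end is reported as
#' `shifted` with its offset; anything else is `absent`. In `strict` mode a
#' model is accepted iff it has the active site and a non-absent loop;
#' `lenient` mode also accepts absent-loop models (flagged for review).
#'
#' @param sequence Protein sequence.
#' @param canonical_window Integer length-2 vector: offsets (in residues,
#'   relative to the active-site D) within which the loop start is canonical.
#' @param mode `"strict"` or `"lenient"`.
#' @return A one-row data.frame: `has_active_site`, `active_site_position`,
#'   `loop_status` (`canonical`/`shifted`/`absent`), `loop_offset` (0 for
#'   canonical, 3-5 for shifted, `NA` for absent), `loop_position`, `accepted`.
#' @export
validate_mapkk_model <- function(sequence, canonical_window = c(120L, 170L),
                                 mode = c("strict", "lenient")) {
  validate_protein_sequence(sequence)
  mode <- match.arg(mode)
  as_pos <- regex_starts("D[ILV]K", sequence)
  has_as <- length(as_pos) > 0
  loop_status <- "absent"
  loop_offset <- NA_integer_
  loop_position <- NA_integer_
  if (has_as) {
    a <- as_pos[1]
    lo <- a + canonical_window[1]
    hi <- a + canonical_window[2]
    loop_starts <- regex_starts("[ST].{5}[ST]", sequence)
    loop_starts <- loop_starts[loop_starts > a + 2]
    if (length(loop_starts) > 0) {
      first <- loop_starts[1]
      if (first >= lo && first <= hi) {
        loop_status <- "canonical"
        loop_offset <- 0L
        loop_position <- first
      } else if (first > hi && first - hi >= 3 && first - hi <= 5) {
        loop_status <- "shifted"
        loop_offset <- first - hi
        loop_position <- first
      }
    }
  }
  accepted <- has_as && (loop_status != "absent" || mode == "lenient")
  data.frame(has_active_site = has_as,
             active_site_position = if (has_as) as_pos[1] else NA_integer_,
             loop_status = loop_status, loop_offset = loop_offset,
             loop_position = loop_position, accepted = accepted,
             stringsAsFactors = FALSE)
}

#' Detect the C-terminal CD docking domain of MAPKs
#'
#' Searches the trailing `c_window` residues for the docking motif
#' `DxxDE(P)xC`, the MAPKK-binding CD domain carried by some MAPKs. The
#' parenthesised proline is treated as optional.
#'
#' @param sequence Protein sequence.
#' @param c_window Number of trailing residues to search (default 150).
#' @return A one-row data.frame: `present`, `position` (1-based, in the full
#'   sequence), `matched_text`.
#' @export
#' @examples
#' detect_cd_domain(paste0(strrep("A", 200), "DAKDEPQC", strrep("A", 10)))
detect_cd_domain <- function(sequence, c_window = 150L) {
  validate_protein_sequence(sequence)
  n <- nchar(sequence)
  from <- max(1L, n - c_window + 1L)
  tail_seq <- substr(sequence, from, n)
  pat <- "D..DEP?.C"
  starts <- regex_starts(pat, tail_seq)
  if (length(starts) == 0) {
    return(data.frame(present = FALSE, position = NA_integer_,
                      matched_text = NA_character_, stringsAsFactors = FALSE))
  }
  pos <- from + starts[1] - 1L
  data.frame(present = TRUE, position = pos,
             matched_text = regex_match_at(pat, tail_seq, starts[1]),
             stringsAsFactors = FALSE)
}

#' EST support for a predicted coding sequence
#'
#' Aligns each EST locally against the CDS (match +1, mismatch -1, gap open
#' 2, gap extend 1) and reports whether the best-scoring EST reaches the
#' identity threshold over its aligned region. Only the single top-scoring
#' EST is reported, mirroring the practice of considering only top matches
#' when family members are highly similar.
#'
#' @param cds Nucleotide sequence (A/C/G/T/N) of the predicted gene model.
#' @param ests Character vector of EST nucleotide sequences (may be named).
#' @param min_identity Percent identity over the aligned region required for
#'   support (default 95).
#' @return A list: `supported` (flag), `best_est` (name or index, `NA` if no
#'   ESTs), `identity` (percent over aligned columns), `score`.
#' @export
est_support <- function(cds, ests, min_identity = 95) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) == 0) {
    stop("`cds` must be a single non-empty nucleotide string")
  }
  if (grepl("[^ACGTN]", cds) || (length(ests) > 0 && any(grepl("[^ACGTN]", ests)))) {
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  }
  if (length(ests) == 0) {
    return(list(supported = FALSE, best_est = NA_character_,
                identity = NA_real_, score = NA_real_))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  best <- NULL
  for (i in seq_along(ests)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ests[[i]]), Biostrings::DNAString(cds),
      type = "local", substitutionMatrix = submat,
      gapOpening = 2, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      stats <- alignment_identity(as.character(Biostrings::alignedPattern(aln)),
                                  as.character(Biostrings::alignedSubject(aln)))
      best <- list(index = i, score = sc, identity = stats$identity)
    }
  }
  nm <- names(ests)[best$index]
  list(supported = best$identity >= min_identity,
       best_est = if (!is.null(nm) && nzchar(nm)) nm else as.character(best$index),
       identity = best$identity, score = best$score)
}

#' Motif report for a set of protein records
#'
#' Applies the family-appropriate motif rules to every record and returns a
#' tabular report suitable for TSV export.
#'
#' @param sequences Named character vector of protein sequences.
#' @param families Character vector (recycled) of family hints, `"MAPK"` or
#'   `"MAPKK"`.
#' @param ... Passed on to the per-family validators.
#' @return A data.frame with one row per record: `gene_id`, `family`,
#'   `accepted`, `loop_type`, `loop_position`, `loop_status`, `cd_domain`.
#' @export
motif_report <- function(sequences, families, ...) {
  if (is.null(names(sequences))) stop("`sequences` must be named")
  families <- rep_len(families, length(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    if (families[i] == "MAPK") {
      v <- validate_mapk_model(s, ...)
      cd <- detect_cd_domain(s)
      data.frame(gene_id = names(sequences)[i], family = "MAPK",
                 accepted = v$accepted, loop_type = v$loop$loop_type,
                 loop_position = v$loop$position,
                 loop_status = NA_character_, cd_domain = cd$present,
                 stringsAsFactors = FALSE)
    } else {
      v <- validate_mapkk_model(s, ...)
      data.frame(gene_id = names(sequences)[i], family = "MAPKK",
                 accepted = v$accepted, loop_type = NA_character_,
                 loop_position = v$loop_position,
                 loop_status = v$loop_status, cd_domain = NA,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
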