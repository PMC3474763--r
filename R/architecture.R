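#' Genome architecture of a gene family
#'
#' Duplication calling by the coverage/identity criterion (alignment length
#' covering at least 70% of the longer gene, identity of at least 70% over
#' the aligned region, one event per group of tightly linked duplicates),
#' Holub-style cluster detection (four or more genes within 200 kb, with a
#' relaxed two-gene variant), chromosome distribution summaries, and mapping
#' of family genes onto precomputed synteny blocks.
#'
#' Gene coordinates are handled as 1-based inclusive intervals, the
#' convention used by the TSV coordinate tables this package reads and
#' writes.
#'
#' @name genome_architecture
NULL

#' Parse the chromosome number out of a plant gene-model identifier
#'
#' Understands the `Bradi<N>g<locus>` (*B. distachyon*), `Os<NN>g<locus>`
#' (rice) and `At<N>g<locus>` (*Arabidopsis*) conventions.
#'
#' @param gene_id Character vector of gene-model identifiers.
#' @return Integer vector of chromosome numbers.
#' @export
#' @examples
#' parse_gene_id_chromosome(c("Bradi1g65810", "Os10g38950", "At3g45640"))
parse_gene_id_chromosome <- function(gene_id) {
  m <- regmatches(gene_id,
                  regexec("^(?:Bradi|Os|At)0*([0-9]+)g[0-9]+", gene_id))
  out <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) < 2L) {
      stop(sprintf("unrecognized gene-model identifier: '%s'", gene_id[i]),
           call. = FALSE)
    }
    as.integer(m[[i]][2])
  }, integer(1))
  out
}

# Coverage/identity bookkeeping from two gap-padded aligned strings.
# aligned columns = columns where both sequences carry a residue;
# identity     = identical aligned columns / aligned columns * 100;
# coverage     = aligned columns / length of the longer input * 100.
alignment_identity <- function(aligned_a, aligned_b) {
  a <- split1(aligned_a)
  b <- split1(aligned_b)
  both <- a != "-" & b != "-"
  n_aligned <- sum(both)
  if (n_aligned == 0) {
    return(list(n_aligned = 0L, identity = NA_real_, n_identical = 0L))
  }
  n_id <- sum(a[both] == b[both])
  list(n_aligned = n_aligned, identity = 100 * n_id / n_aligned,
       n_identical = n_id)
}

#' Global pairwise alignment with coverage and identity
#'
#' Needleman-Wunsch global alignment (affine gaps) of two protein
#' sequences, reporting the two statistics the duplication criterion needs:
#' coverage, the fraction of the longer sequence covered by aligned
#' (residue-against-residue) columns, and identity over those aligned
#' columns. Defaults are BLOSUM62 with gap open 10 and gap extension 0.5.
#'
#' @param a,b Protein sequences (single strings).
#' @param substitution_matrix Name of a packaged scoring matrix (e.g.
#'   `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_opening,gap_extension Affine gap penalties (positive numbers;
#'   a gap of length L costs `gap_opening + L * gap_extension`).
#' @return A list: `coverage` and `identity` (percent), `score`,
#'   `aligned_a`, `aligned_b` (gap-padded strings).
#' @export
#' @examples
#' global_align("AAAA", "AAAATTTT")$coverage  # 50
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_identity(pa, pb)
  list(coverage = 100 * stats$n_aligned / max(nchar(a), nchar(b)),
       identity = stats$identity,
       score = Biostrings::score(aln),
       aligned_a = pa, aligned_b = pb)
}

#' Call gene duplications within a family
#'
#' Scores every within-family pair of loci by global alignment and applies
#' the duplication criterion: the aligned region must cover at least
#' `min_coverage` percent of the longer gene and have at least
#' `min_identity` percent identity. Duplicated pairs on the same chromosome
#' separated by at most `tandem_distance` bp are classified `tandem`,
#' other duplicated pairs `segmental`. Tightly linked duplicates (connected
#' through tandem links) are collapsed to a single duplication event; each
#' segmental link between the resulting groups counts as one further event.
#'
#' @param loci Data.frame with columns `gene_id`, `family`, `chromosome`,
#'   `start`, `end` (1-based inclusive), `strand`.
#' @param sequences Named character vector of protein sequences covering
#'   every `gene_id`.
#' @param min_coverage,min_identity Thresholds in percent (default 70/70).
#' @param tandem_distance Maximum gap (bp) between tightly linked genes
#'   (default 200000).
#' @param ... Passed to [global_align()].
#' @return A list with `calls` (data.frame: `gene_a`, `gene_b`, `coverage`,
#'   `identity`, `is_duplicate`, `mode`) and `n_events` (integer).
#' @export
call_duplication <- function(loci, sequences, min_coverage = 70,
                             min_identity = 70, tandem_distance = 200000,
                             ...) {
  missing <- setdiff(loci$gene_id, names(sequences))
  if (length(missing) > 0) {
    stop(sprintf("missing sequence for gene '%s'", missing[1]))
  }
  calls <- list()
  fams <- unique(loci$family)
  for (fam in fams) {
    sub <- loci[loci$family == fam, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        ga <- sub$gene_id[i]
        gb <- sub$gene_id[j]
        al <- global_align(sequences[[ga]], sequences[[gb]], ...)
        dup <- al$coverage >= min_coverage && al$identity >= min_identity
        mode <- "none"
        if (dup) {
          same_chr <- sub$chromosome[i] == sub$chromosome[j]
          gap <- max(sub$start[i], sub$start[j]) - min(sub$end[i], sub$end[j]) - 1
          mode <- if (same_chr && gap <= tandem_distance) "tandem" else "segmental"
        }
        calls[[length(calls) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb, family = fam,
          coverage = al$coverage, identity = al$identity,
          is_duplicate = dup, mode = mode, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(gene_a = character(0), gene_b = character(0),
               family = character(0), coverage = numeric(0),
               identity = numeric(0), is_duplicate = logical(0),
               mode = character(0), stringsAsFactors = FALSE)
  list(calls = calls, n_events = count_duplication_events(calls))
}

# One event per connected component of tandem-linked duplicates; each
# segmental duplicate link between the collapsed groups adds one event.
count_duplication_events <- function(calls) {
  dup <- calls[calls$is_duplicate, , drop = FALSE]
  if (nrow(dup) == 0) return(0L)
  genes <- unique(c(dup$gene_a, dup$gene_b))
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  tan <- dup[dup$mode == "tandem", , drop = FALSE]
  for (k in seq_len(nrow(tan))) {
    ra <- find(tan$gene_a[k])
    rb <- find(tan$gene_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(genes, find, character(1))
  tandem_groups <- unique(roots[c(tan$gene_a, tan$gene_b)])
  seg <- dup[dup$mode == "segmental", , drop = FALSE]
  seg_links <- unique(vapply(seq_len(nrow(seg)), function(k) {
    paste(sort(c(find(seg$gene_a[k]), find(seg$gene_b[k]))), collapse = "|")
  }, character(1)))
  length(tandem_groups) + length(seg_links)
}

#' Detect chromosomal gene clusters
#'
#' Finds, per chromosome and family, every maximal run of consecutive
#' family genes whose span (max end - min start) is at most `max_span` and
#' which contains at least `min_genes` genes. The defaults implement the
#' Holub cluster rule (four or more genes within 200 kb); `min_genes = 2`
#' gives the relaxed variant.
#'
#' @param loci Coordinate data.frame (see [call_duplication()]).
#' @param max_span Maximum cluster span in bp (default 200000).
#' @param min_genes Minimum genes per cluster (default 4; use 2 for the
#'   relaxed criterion).
#' @return Data.frame with one row per cluster: `chromosome`, `family`,
#'   `members` (comma-separated, in chromosomal order), `n_genes`, `span`,
#'   `criterion`.
#' @export
detect_clusters <- function(loci, max_span = 200000, min_genes = 4) {
  out <- list()
  for (fam in unique(loci$family)) {
    for (chr in unique(loci$chromosome[loci$family == fam])) {
      sub <- loci[loci$family == fam & loci$chromosome == chr, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      n <- nrow(sub)
      if (n < min_genes) next
      j_prev <- 0L
      for (i in seq_len(n)) {
        j <- i
        while (j < n && sub$end[j + 1] - sub$start[i] <= max_span) j <- j + 1
        # maximal: cannot extend left (i == 1 or window starting at i-1 fails)
        left_ext <- i > 1 && sub$end[j] - sub$start[i - 1] <= max_span
        if (j - i + 1 >= min_genes && !left_ext && j > j_prev) {
          out[[length(out) + 1L]] <- data.frame(
            chromosome = chr, family = fam,
            members = paste(sub$gene_id[i:j], collapse = ","),
            n_genes = j - i + 1L, span = sub$end[j] - sub$start[i],
            criterion = if (min_genes >= 4) "strict" else "relaxed",
            stringsAsFactors = FALSE)
          j_prev <- j
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(0), family = character(0),
                      members = character(0), n_genes = integer(0),
                      span = numeric(0), criterion = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Chromosome distribution of family members
#'
#' Per-family counts and percentages of genes per chromosome. Chromosomes
#' can be taken from a coordinate table or parsed from gene-model
#' identifiers via [parse_gene_id_chromosome()].
#'
#' @param loci Either a coordinate data.frame with `gene_id`, `family` and
#'   `chromosome` columns, or a data.frame with `gene_id` and `family` only,
#'   in which case chromosomes are parsed from the identifiers.
#' @return Data.frame: `family`, `chromosome`, `n`, `percent` (percent of
#'   the family's genes on that chromosome).
#' @export
chromosome_distribution <- function(loci) {
  if (nrow(loci) == 0) {
    return(data.frame(family = character(0), chromosome = character(0),
                      n = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE))
  }
  chr <- if ("chromosome" %in% names(loci)) as.character(loci$chromosome) else
    as.character(parse_gene_id_chromosome(loci$gene_id))
  out <- list()
  for (fam in unique(loci$family)) {
    cc <- chr[loci$family == fam]
    tab <- table(cc)
    out[[fam]] <- data.frame(family = fam, chromosome = names(tab),
                             n = as.integer(tab),
                             percent = 100 * as.integer(tab) / length(cc),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map family genes onto synteny blocks
#'
#' Assigns each gene of species A to every block whose species-A interval
#' it overlaps, and reports cross-species partner pairs: family genes of
#' species B overlapping the mate interval of the same block. Intervals are
#' 1-based inclusive; overlap requires at least one shared base.
#'
#' @param loci_a,loci_b Coordinate data.frames for the two species.
#' @param blocks Data.frame: `block_id`, `chr_a`, `start_a`, `end_a`,
#'   `chr_b`, `start_b`, `end_b`.
#' @return A list with `assignments` (gene of A -> block) and `pairs`
#'   (`gene_a`, `gene_b`, `block_id`), plus `fraction_syntenic`: the
#'   fraction of species-A family genes assigned to at least one block with
#'   a partner.
#' @export
map_genes_to_synteny <- function(loci_a, loci_b, blocks) {
  overlaps <- function(start, end, bstart, bend, chr, bchr) {
    chr == bchr & start <= bend & end >= bstart
  }
  assignments <- list()
  pairs <- list()
  for (k in seq_len(nrow(blocks))) {
    blk <- blocks[k, ]
    hit_a <- loci_a[overlaps(loci_a$start, loci_a$end, blk$start_a, blk$end_a,
                             as.character(loci_a$chromosome),
                             as.character(blk$chr_a)), , drop = FALSE]
    if (nrow(hit_a) == 0) next
    assignments[[length(assignments) + 1L]] <- data.frame(
      gene_id = hit_a$gene_id, block_id = blk$block_id,
      stringsAsFactors = FALSE)
    hit_b <- loci_b[overlaps(loci_b$start, loci_b$end, blk$start_b, blk$end_b,
                             as.character(loci_b$chromosome),
                             as.character(blk$chr_b)), , drop = FALSE]
    if (nrow(hit_b) == 0) next
    grid <- expand.grid(gene_a = hit_a$gene_id, gene_b = hit_b$gene_id,
                        stringsAsFactors = FALSE)
    grid$block_id <- blk$block_id
    pairs[[length(pairs) + 1L]] <- grid
  }
  assignments <- if (length(assignments) > 0) do.call(rbind, assignments) else
    data.frame(gene_id = character(0), block_id = character(0),
               stringsAsFactors = FALSE)
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               block_id = character(0), stringsAsFactors = FALSE)
  frac <- if (nrow(loci_a) == 0) NA_real_ else
    length(unique(pairs$gene_a)) / nrow(loci_a)
  list(assignments = assignments, pairs = pairs, fraction_syntenic = frac)
}
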