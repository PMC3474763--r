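#' Synthetic gene coordinates with planted architecture
#'
#' Generates a coordinate table with planted gene clusters, dispersed
#' singletons and duplicate pairs of controlled identity, plus the protein
#' sequences needed by the duplication caller and a ledger of the planted
#' ground truth. Placement leaves at least 250 kb between independent
#' blocks, so planted clusters are exactly the maximal cluster runs and
#' dispersed genes never fall within the 200-kb linkage distance of any
#' other family gene.
#'
#' @name simulate_genome
NULL

#' Specification for a synthetic family genome layout
#'
#' @param chromosome_lengths Numeric vector of chromosome lengths (bp).
#' @param planted_clusters List of `list(chromosome=, n_genes=, span=)`
#'   entries; each plants `n_genes` family genes within `span` bp.
#' @param n_dispersed Number of isolated family genes (> 200 kb from any
#'   other member).
#' @param duplicate_pairs List of `list(identity=, mode=)` entries with
#'   target percent identity and mode `"tandem"` or `"dispersed"`.
#' @param gene_length Gene length in bp (default 3000).
#' @param protein_length Protein length for generated sequences (default
#'   300 residues).
#' @param family Family label for all generated loci (default `"MAPK"`).
#' @param seed Integer seed.
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(chromosome_lengths, planted_clusters = list(),
                            n_dispersed = 0L, duplicate_pairs = list(),
                            gene_length = 3000L, protein_length = 300L,
                            family = "MAPK", seed = 1L) {
  for (cl in planted_clusters) {
    if (cl$span > chromosome_lengths[cl$chromosome]) {
      stop("planted cluster span exceeds its chromosome length")
    }
    if (cl$span < cl$n_genes * gene_length) {
      stop("planted cluster span too small for its genes")
    }
  }
  for (dp in duplicate_pairs) {
    stopifnot_scalar_number(dp$identity, "duplicate pair identity", 0, 100)
    if (!dp$mode %in% c("tandem", "dispersed")) {
      stop("duplicate pair mode must be 'tandem' or 'dispersed'")
    }
    if (dp$mode == "dispersed" && length(chromosome_lengths) < 2) {
      stop("dispersed duplicate pairs need at least 2 chromosomes")
    }
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 planted_clusters = planted_clusters,
                 n_dispersed = as.integer(n_dispersed),
                 duplicate_pairs = duplicate_pairs,
                 gene_length = as.integer(gene_length),
                 protein_length = as.integer(protein_length),
                 family = family, seed = as.integer(seed)),
            class = "genome_sim_spec")
}

#' Generate synthetic gene coordinates, sequences and ground truth
#'
#' @param spec A [genome_sim_spec()].
#' @return A list: `loci` (coordinate data.frame: `gene_id`, `family`,
#'   `chromosome`, `start`, `end`, `strand`; 1-based inclusive),
#'   `sequences` (named protein vector), and `ledger` with `clusters`
#'   (planted cluster memberships), `dispersed` (gene ids) and
#'   `duplications` (`gene_a`, `gene_b`, `target_identity`,
#'   `realized_identity`, `mode`).
#' @export
generate_gene_coordinates <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  margin <- 250001 # inter-block gap: beyond any 200-kb linkage rule
  with_local_seed(spec$seed, {
    n_chr <- length(spec$chromosome_lengths)
    cursor <- 10000 + sample.int(20000, n_chr, replace = TRUE)
    counter <- rep(0L, n_chr)
    loci <- list()
    seqs <- list()
    next_id <- function(chr) {
      counter[chr] <<- counter[chr] + 1L
      sprintf("Bradi%dg%05d", chr, counter[chr] * 10L)
    }
    place_block <- function(chr, width) {
      start <- cursor[chr]
      if (start + width - 1 > spec$chromosome_lengths[chr]) {
        stop(sprintf("chromosome %d overflow: layout does not fit", chr))
      }
      cursor[chr] <<- start + width + margin
      start
    }
    add_gene <- function(chr, start, seq = NULL) {
      id <- next_id(chr)
      loci[[length(loci) + 1L]] <<- data.frame(
        gene_id = id, family = spec$family, chromosome = chr,
        start = start, end = start + spec$gene_length - 1L,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      seqs[[id]] <<- if (is.null(seq)) {
        paste0c(sample(AA_ALPHABET20, spec$protein_length, replace = TRUE))
      } else {
        seq
      }
      id
    }
    clusters <- list()
    for (cl in spec$planted_clusters) {
      start <- place_block(cl$chromosome, cl$span)
      step <- if (cl$n_genes > 1) {
        (cl$span - spec$gene_length) %/% (cl$n_genes - 1L)
      } else {
        0L
      }
      ids <- vapply(seq_len(cl$n_genes), function(i) {
        add_gene(cl$chromosome, start + (i - 1L) * step)
      }, character(1))
      clusters[[length(clusters) + 1L]] <- data.frame(
        chromosome = cl$chromosome, members = paste(ids, collapse = ","),
        n_genes = cl$n_genes, stringsAsFactors = FALSE)
    }
    dispersed <- character(0)
    for (k in seq_len(spec$n_dispersed)) {
      chr <- ((k - 1L) %% n_chr) + 1L
      start <- place_block(chr, spec$gene_length)
      dispersed <- c(dispersed, add_gene(chr, start))
    }
    duplications <- list()
    for (k in seq_along(spec$duplicate_pairs)) {
      dp <- spec$duplicate_pairs[[k]]
      pair <- generate_duplicate_pair(spec$protein_length, dp$identity,
                                      seed = sample.int(.Machine$integer.max, 1))
      if (dp$mode == "tandem") {
        chr <- ((k - 1L) %% n_chr) + 1L
        start <- place_block(chr, 2L * spec$gene_length + 10000L)
        id_a <- add_gene(chr, start, pair$a)
        id_b <- add_gene(chr, start + spec$gene_length + 10000L, pair$b)
      } else {
        chrs <- 1L + (((k - 1L) + 0:1) %% n_chr)
        if (chrs[1] == chrs[2]) chrs[2] <- chrs[1] %% n_chr + 1L
        id_a <- add_gene(chrs[1], place_block(chrs[1], spec$gene_length), pair$a)
        id_b <- add_gene(chrs[2], place_block(chrs[2], spec$gene_length), pair$b)
      }
      duplications[[length(duplications) + 1L]] <- data.frame(
        gene_a = id_a, gene_b = id_b, target_identity = dp$identity,
        realized_identity = pair$realized_identity, mode = dp$mode,
        stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, c(loci, list(NULL)))
    if (is.null(loci)) {
      loci <- data.frame(gene_id = character(0), family = character(0),
                         chromosome = integer(0), start = numeric(0),
                         end = numeric(0), strand = character(0),
                         stringsAsFactors = FALSE)
    }
    list(loci = loci,
         sequences = if (length(seqs) > 0) unlist(seqs) else
           stats::setNames(character(0), character(0)),
         ledger = list(
           clusters = if (length(clusters) > 0) do.call(rbind, clusters) else
             data.frame(chromosome = integer(0), members = character(0),
                        n_genes = integer(0), stringsAsFactors = FALSE),
           dispersed = dispersed,
           duplications = if (length(duplications) > 0) {
             do.call(rbind, duplications)
           } else {
             data.frame(gene_a = character(0), gene_b = character(0),
                        target_identity = numeric(0),
                        realized_identity = numeric(0), mode = character(0),
                        stringsAsFactors = FALSE)
           }))
  })
}
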