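test_that("chromosome numbers parse from the three ID conventions", {
  expect_equal(parse_gene_id_chromosome("Bradi1g65810"), 1L)
  expect_equal(parse_gene_id_chromosome("Os10g38950"), 10L)
  expect_equal(parse_gene_id_chromosome("At3g45640"), 3L)
  expect_equal(parse_gene_id_chromosome("Os03g17700"), 3L)
  expect_error(parse_gene_id_chromosome("XyZ123"), "unrecognized")
})

test_that("global alignment reports the expected coverage and identity", {
  self <- global_align("MKTEYAAGG", "MKTEYAAGG")
  expect_equal(self$coverage, 100)
  expect_equal(self$identity, 100)

  half <- global_align("AAAA", "AAAATTTT")
  expect_equal(half$coverage, 50) # 4 aligned columns / 8 residues of longer
  expect_equal(half$identity, 100)

  pair <- generate_duplicate_pair(300, 70, seed = 7)
  al <- global_align(pair$a, pair$b)
  expect_equal(al$identity, pair$realized_identity, tolerance = 0.03)
  expect_gte(al$coverage, 98)
})

test_that("alignment scores agree with an independent affine-gap DP oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(101)
  for (rep in 1:25) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    al <- global_align(a, b)
    expect_equal(al$score, gotoh_score(a, b, BLOSUM62, 10, 0.5))
  }
})

test_that("alignment identity and coverage fall within the optimal-alignment set", {
  # linear-gap scoring so every co-optimal traceback can be enumerated
  submat <- identity_submat()
  set.seed(202)
  for (rep in 1:20) {
    a <- random_protein(sample(4:20, 1), alphabet = AA20[1:4])
    b <- random_protein(sample(4:20, 1), alphabet = AA20[1:4])
    al <- global_align(a, b, substitution_matrix = submat,
                       gap_opening = 0, gap_extension = 1)
    oracle <- nw_all_optimal_stats(a, b, match = 2, mismatch = -1, gap = 1)
    expect_equal(al$score, oracle$score)
    hit <- any(abs(oracle$coverage - al$coverage) < 1e-9 &
                 abs(oracle$identity - al$identity) < 1e-9)
    expect_true(hit)
  }
})

test_that("duplication calling is symmetric and monotone in its thresholds", {
  g <- generate_gene_coordinates(genome_sim_spec(
    chromosome_lengths = c(5e6, 5e6),
    duplicate_pairs = list(list(identity = 75, mode = "tandem"),
                           list(identity = 72, mode = "dispersed")),
    n_dispersed = 2, seed = 12))
  base <- call_duplication(g$loci, g$sequences)$calls
  # symmetry: swapping loci rows changes nothing about the pair verdicts
  rev_loci <- g$loci[rev(seq_len(nrow(g$loci))), ]
  swapped <- call_duplication(rev_loci, g$sequences)$calls
  key <- function(df) sort(paste(pmin(df$gene_a, df$gene_b),
                                 pmax(df$gene_a, df$gene_b),
                                 df$is_duplicate))
  expect_equal(key(base), key(swapped))
  # monotonicity: raising thresholds never adds duplicates
  stricter <- call_duplication(g$loci, g$sequences, min_identity = 80)$calls
  expect_true(all(stricter$is_duplicate <= base$is_duplicate))
  stricter2 <- call_duplication(g$loci, g$sequences, min_coverage = 99.9)$calls
  expect_true(all(stricter2$is_duplicate <= base$is_duplicate))
})

test_that("a tandem array of mutual duplicates counts as a single event", {
  master <- generate_duplicate_pair(200, 95, seed = 31)
  # third copy: mutate 5% of the first sequence directly
  third_chars <- strsplit(master$a, "")[[1]]
  set.seed(33)
  at <- sample(200, 10)
  third_chars[at] <- vapply(third_chars[at], function(x) {
    sample(setdiff(AA20, x), 1)
  }, character(1))
  third <- paste(third_chars, collapse = "")
  loci <- data.frame(gene_id = c("Bradi1g00010", "Bradi1g00020", "Bradi1g00030"),
                     family = "MAPK", chromosome = 1,
                     start = c(1e5, 2e5, 3e5), end = c(1e5, 2e5, 3e5) + 2999,
                     strand = "+", stringsAsFactors = FALSE)
  seqs <- c(Bradi1g00010 = master$a, Bradi1g00020 = master$b,
            Bradi1g00030 = third)
  # third is derived from master$a as well, so all three are mutually similar
  res <- call_duplication(loci, seqs)
  expect_equal(sum(res$calls$is_duplicate), 3L)
  expect_true(all(res$calls$mode[res$calls$is_duplicate] == "tandem"))
  expect_equal(res$n_events, 1L)
})

test_that("tightly linked but dissimilar genes are not called duplicates", {
  # the classic counterexample: adjacent loci sharing only ~44% identity
  pair <- generate_duplicate_pair(250, 44, seed = 44)
  loci <- data.frame(gene_id = c("Bradi1g00100", "Bradi1g00110"),
                     family = "MAPK", chromosome = 1,
                     start = c(1e5, 1.5e5), end = c(1e5, 1.5e5) + 2999,
                     strand = "+", stringsAsFactors = FALSE)
  res <- call_duplication(loci, c(Bradi1g00100 = pair$a, Bradi1g00110 = pair$b))
  expect_false(res$calls$is_duplicate)
  expect_equal(res$calls$mode, "none")
  expect_equal(res$n_events, 0L)
})

test_that("cluster detection applies the span and size rules", {
  mk_loci <- function(starts, chr = 1) {
    data.frame(gene_id = sprintf("Bradi1g%05d", seq_along(starts) * 10),
               family = "MAPK", chromosome = chr, start = starts,
               end = starts + 2999, strand = "+", stringsAsFactors = FALSE)
  }
  two_close <- mk_loci(c(1e5, 1.5e5))
  expect_equal(nrow(detect_clusters(two_close, min_genes = 4)), 0L)
  relaxed <- detect_clusters(two_close, min_genes = 2)
  expect_equal(nrow(relaxed), 1L)
  expect_equal(relaxed$criterion, "relaxed")

  two_far <- mk_loci(c(1e5, 3.6e5))
  expect_equal(nrow(detect_clusters(two_far, min_genes = 4)), 0L)
  expect_equal(nrow(detect_clusters(two_far, min_genes = 2)), 0L)
})

test_that("every strict cluster is contained in some relaxed cluster", {
  g <- generate_gene_coordinates(genome_sim_spec(
    chromosome_lengths = c(8e6, 8e6),
    planted_clusters = list(list(chromosome = 1, n_genes = 4, span = 120000),
                            list(chromosome = 2, n_genes = 5, span = 180000)),
    n_dispersed = 3, seed = 8))
  strict <- detect_clusters(g$loci, min_genes = 4)
  relaxed <- detect_clusters(g$loci, min_genes = 2)
  for (k in seq_len(nrow(strict))) {
    members <- strsplit(strict$members[k], ",")[[1]]
    contained <- any(vapply(strsplit(relaxed$members, ","), function(r) {
      all(members %in% r)
    }, logical(1)))
    expect_true(contained)
  }
})

test_that("chromosome distribution sums to family size", {
  tab <- load_table1_fixture()
  loci <- data.frame(gene_id = tab$bd_gene_model, family = tab$family,
                     stringsAsFactors = FALSE)
  dist <- chromosome_distribution(loci)
  for (fam in c("MAPK", "MAPKK")) {
    sub <- dist[dist$family == fam, ]
    expect_equal(sum(sub$n), sum(tab$family == fam))
    expect_equal(sum(sub$percent), 100)
  }
  expect_equal(nrow(chromosome_distribution(loci[0, ])), 0L)
})

test_that("synteny mapping uses interval overlap and finds planted partners", {
  blocks <- data.frame(block_id = c("B1", "B2", "B3"),
                       chr_a = c(1, 1, 2), start_a = c(1e5, 5e5, 1e5),
                       end_a = c(2e5, 6e5, 2e5),
                       chr_b = c(3, 4, 5), start_b = c(1e6, 2e6, 3e6),
                       end_b = c(1.1e6, 2.1e6, 3.1e6),
                       stringsAsFactors = FALSE)
  loci_a <- data.frame(
    gene_id = c("Bradi1g00010", "Bradi1g00020", "Bradi2g00010", "Bradi1g00030"),
    family = "MAPK", chromosome = c(1, 1, 2, 1),
    start = c(1.5e5, 5.5e5, 1.5e5, 2e5 + 1), # last one abuts B1 without overlap
    end = c(1.53e5, 5.53e5, 1.53e5, 2.1e5), strand = "+",
    stringsAsFactors = FALSE)
  loci_b <- data.frame(
    gene_id = c("Os03g00010", "Os04g00010", "Os05g00010"),
    family = "MAPK", chromosome = c(3, 4, 5),
    start = c(1.05e6, 2.05e6, 3.05e6), end = c(1.053e6, 2.053e6, 3.053e6),
    strand = "+", stringsAsFactors = FALSE)
  res <- map_genes_to_synteny(loci_a, loci_b, blocks)
  expect_equal(nrow(res$pairs), 3L)
  expect_setequal(res$pairs$gene_b, loci_b$gene_id)
  # the abutting gene (start == block end + 1) is not assigned
  expect_false("Bradi1g00030" %in% res$assignments$gene_id)
  expect_equal(res$fraction_syntenic, 3 / 4)
})
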