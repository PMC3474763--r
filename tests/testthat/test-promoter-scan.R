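test_that("upstream extraction is strand-aware and truncates at edges", {
  set.seed(1)
  chrom <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  plus <- data.frame(chromosome = "chr1", start = 5001, end = 6000,
                     strand = "+")
  expect_equal(extract_upstream(genome, plus), substr(chrom, 4001, 5000))

  minus <- data.frame(chromosome = "chr1", start = 4001, end = 5000,
                      strand = "-")
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 5001, 6000))))
  expect_equal(extract_upstream(genome, minus), expected)

  near_edge <- data.frame(chromosome = "chr1", start = 301, end = 1300,
                          strand = "+")
  expect_warning(p <- extract_upstream(genome, near_edge), "truncated")
  expect_equal(nchar(p), 300)

  off <- data.frame(chromosome = "chr1", start = 7000, end = 9000, strand = "+")
  expect_error(extract_upstream(genome, off), "outside")
})

test_that("element counting enumerates overlapping degenerate matches", {
  counts <- scan_elements("TGACCTGACT",
                          default_element_patterns(scan_both_strands = FALSE))$counts
  expect_equal(counts[["WBOX"]], 2L) # TGACC and TGACT
  expect_equal(counts[["CBF"]], 0L)

  polyN <- scan_elements(strrep("N", 50))$counts
  expect_true(all(polyN == 0))

  expect_error(scan_elements("ACGTQQ"), "non-DNA")
})

test_that("scanning recovers planted promoter ledgers exactly", {
  out <- generate_promoters(5, planted_counts = c(WBOX = 3, DRE = 1, GCC = 2),
                            seed = 6)
  for (g in names(out$promoters)) {
    counts <- scan_elements(out$promoters[[g]])$counts
    led <- out$ledger[out$ledger$gene_id == g, ]
    expect_equal(counts[["WBOX"]], sum(led$element == "WBOX"))
    expect_equal(counts[["CBF"]], 0L)
    expect_equal(counts[["DRE"]], sum(led$element == "DRE"))
    expect_equal(counts[["GCC"]], sum(led$element == "GCC"))
    # positions, not just totals
    hits <- scan_elements(out$promoters[[g]])$hits
    expect_setequal(paste(hits$element, hits$start),
                    paste(led$element, led$start))
  }
  zero <- generate_promoters(2, planted_counts = c(WBOX = 0), seed = 7)
  for (g in names(zero$promoters)) {
    expect_true(all(scan_elements(zero$promoters[[g]])$counts == 0))
  }
})

test_that("reverse-strand plantings are invisible to a forward-only scan", {
  out <- generate_promoters(3, planted_counts = c(WBOX = 0),
                            planted_counts_rev = c(WBOX = 2), seed = 8)
  fwd_only <- default_element_patterns(scan_both_strands = FALSE)
  for (g in names(out$promoters)) {
    expect_equal(scan_elements(out$promoters[[g]], fwd_only)$counts[["WBOX"]], 0L)
    expect_equal(scan_elements(out$promoters[[g]])$counts[["WBOX"]], 2L)
  }
  # palindromic CBF cannot be planted in reverse
  expect_error(generate_promoters(1, planted_counts_rev = c(CBF = 1), seed = 1),
               "palindromic")
})

test_that("both-strand totals are symmetric under reverse complement", {
  out <- generate_promoters(4, planted_counts = c(WBOX = 2, DRE = 1, CBF = 1),
                            seed = 9)
  for (g in names(out$promoters)) {
    p <- out$promoters[[g]]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    expect_equal(scan_elements(p)$counts, scan_elements(rc)$counts)
  }
})

test_that("counts are additive under concatenation minus boundary hits", {
  out <- generate_promoters(2, planted_counts = c(WBOX = 3, GCC = 1), seed = 10)
  p1 <- out$promoters[[1]]
  p2 <- out$promoters[[2]]
  cat_scan <- scan_elements(paste0(p1, p2))
  boundary <- cat_scan$hits$start <= nchar(p1) & cat_scan$hits$end > nchar(p1)
  interior <- cat_scan$hits[!boundary, ]
  sums <- scan_elements(p1)$counts + scan_elements(p2)$counts
  for (nm in names(sums)) {
    expect_equal(sum(interior$element == nm), sums[[nm]])
  }
})

test_that("family summaries compute means and threshold fractions", {
  counts <- data.frame(gene_id = c("g1", "g2", "g3"),
                       WBOX = c(6, 8, 0), CBF = c(1, 0, 0),
                       DRE = c(1, 1, 0), GCC = c(2, 1, 0),
                       stringsAsFactors = FALSE)
  fams <- c(g1 = "MAPK", g2 = "MAPK", g3 = "MAPKK")
  s <- summarize_family(counts, fams)
  mapk <- s[s$family == "MAPK", ]
  expect_equal(mapk$mean_wbox, 7)
  expect_equal(mapk$frac_wbox_at_least, 1)
  expect_equal(mapk$frac_all_four, 0.5) # only g1 has all four elements
  mapkk <- s[s$family == "MAPKK", ]
  expect_equal(mapkk$mean_wbox, 0)
  expect_equal(mapkk$frac_all_four, 0)
  expect_error(summarize_family(counts, fams[1:2]), "family")
})
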