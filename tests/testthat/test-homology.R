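test_that("needleman_wunsch scores and tracebacks match hand examples", {
  r <- needleman_wunsch("ACGT", "ACGT")
  expect_equal(r$score, 4)
  expect_equal(r$aligned_a, "ACGT")
  expect_equal(r$aligned_b, "ACGT")
  r2 <- needleman_wunsch("ACGT", "ACGA")
  expect_equal(r2$score, 2)  # 3 matches - 1 mismatch under defaults
  expect_equal(nchar(r2$aligned_a), nchar(r2$aligned_b))
  r3 <- needleman_wunsch("ACGT", "AC")
  expect_equal(r3$score, 2 * 1 + 2 * (-2))
  # de-gapping reproduces the inputs
  expect_equal(gsub("-", "", r3$aligned_a), "ACGT")
  expect_equal(gsub("-", "", r3$aligned_b), "AC")
  expect_error(needleman_wunsch("A", ""), "non-empty")
  expect_error(needleman_wunsch("", "A"), "non-empty")
  expect_error(needleman_wunsch("AXG", "A"), "A,C,G,T,N")
})

test_that("alignment_scoring validates its parameters", {
  expect_error(alignment_scoring(match = -1, mismatch = 0), "match > mismatch")
  expect_error(alignment_scoring(gap = 0), "gap < 0")
  s <- alignment_scoring(2, -3, -4)
  expect_equal(needleman_wunsch("ACGT", "ACGT", s)$score, 8)
})

test_that("NW score equals brute-force enumeration over all global alignments", {
  withr::with_seed(7, {
    sc_sets <- list(alignment_scoring(),
                    alignment_scoring(2, -3, -4),
                    alignment_scoring(1, -2, -1))
    for (k in 1:120) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
                 collapse = "")
      sc <- sc_sets[[1 + k %% 3]]
      expect_equal(needleman_wunsch(a, b, sc)$score, nw_enum_score(a, b, sc),
                   info = paste(a, b))
    }
  })
})

test_that("motif_similarity computes identity over alignment columns", {
  expect_equal(motif_similarity("ACGT", "ACGT"), 100)
  expect_equal(motif_similarity("ACGT", "ACGA"), 75)
  expect_equal(motif_similarity("ACGT", "CGTA", mode = "best_rotation_revcomp"),
               100)
  expect_lt(motif_similarity("ACGT", "CGTA"), 100)
  # reverse complement is also recognized in rotation mode
  expect_equal(motif_similarity("ACCG", "CGGT", mode = "best_rotation_revcomp"),
               100)
  # disjoint alphabets of equal length stay low but bounded
  s <- motif_similarity("AAAA", "CCCC")
  expect_gte(s, 0)
  expect_lte(s, 50)
})

test_that("similarity is bounded in [0, 100] on random motif pairs", {
  withr::with_seed(13, {
    for (k in 1:60) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), TRUE),
                 collapse = "")
      s <- motif_similarity(a, b)
      expect_gte(s, 0)
      expect_lte(s, 100)
      expect_equal(motif_similarity(a, a), 100)
    }
  })
})

test_that("intersect_with_overlap applies the lifted-relative threshold", {
  lifted <- data.frame(source_id = "a1", q_chrom = "chrB",
                       q_start = 100L, q_end = 200L, stringsAsFactors = FALSE)
  cat_b <- mini_catalog("chrB", 150L, 400L)
  hit <- intersect_with_overlap(lifted, cat_b, min_overlap = 0.1)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$overlap_fraction, 0.5)  # 50 bp / 100 bp lifted
  expect_equal(nrow(intersect_with_overlap(lifted, cat_b, 0.6)), 0L)
  # identical intervals give fraction 1 at any threshold
  same <- intersect_with_overlap(lifted, mini_catalog("chrB", 100L, 200L), 1)
  expect_equal(same$overlap_fraction, 1)
  # disjoint intervals never pair
  expect_equal(nrow(intersect_with_overlap(
    lifted, mini_catalog("chrB", 300L, 350L), 0.01)), 0L)
  expect_error(intersect_with_overlap(lifted, cat_b, 0), "min_overlap")
  expect_error(intersect_with_overlap(lifted, cat_b, 1.2), "min_overlap")
})

test_that("reciprocal overlap mode also gates on the catalog record", {
  lifted <- data.frame(source_id = "a1", q_chrom = "chrB",
                       q_start = 100L, q_end = 200L, stringsAsFactors = FALSE)
  cat_b <- mini_catalog("chrB", 150L, 650L)  # overlap 50/100 vs 50/500
  expect_equal(nrow(intersect_with_overlap(lifted, cat_b, 0.5)), 1L)
  expect_equal(nrow(intersect_with_overlap(lifted, cat_b, 0.5,
                                           reciprocal = TRUE)), 0L)
})

test_that("one lifted interval can pair with several catalog records", {
  lifted <- data.frame(source_id = "a1", q_chrom = "chrB",
                       q_start = 0L, q_end = 100L, stringsAsFactors = FALSE)
  cat_b <- mini_catalog("chrB", c(0L, 60L), c(40L, 100L))
  hits <- intersect_with_overlap(lifted, cat_b, 0.2)
  expect_equal(nrow(hits), 2L)
})

test_that("reciprocal_homologs recovers an exact planted correspondence", {
  spec <- fixture_spec(31, n_chroms = 1L, chrom_length = 20000L,
                       n_shared_trs = 6L, n_private_trs = 3L,
                       motif_divergence = 0, indel_blocks = 0L)
  b <- make_genome_pair(spec)
  pairs <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab,
                               b$chain_ba, min_overlap = 0.5,
                               min_similarity = 99)
  expect_equal(nrow(pairs), 6L)
  expect_true(all(pairs$similarity == 100))
  expect_true(all(pairs$overlap_ab == 1 & pairs$overlap_ba == 1))
  truth_ids <- locus_id(b$truth$chrom_a, b$truth$start_a, b$truth$end_a)
  expect_setequal(pairs$locus_a, truth_ids)
  # private loci never appear
  priv_a <- setdiff(locus_id(b$catalog_a$chrom, b$catalog_a$start,
                             b$catalog_a$end), truth_ids)
  expect_length(intersect(pairs$locus_a, priv_a), 0L)
  # sorted output
  expect_equal(pairs$start_a, sort(pairs$start_a))
  # GC fractions are 4-decimal values in [0,1]
  expect_true(all(pairs$gc_a >= 0 & pairs$gc_a <= 1))
  expect_equal(pairs$gc_a, round(pairs$gc_a, 4))
})

test_that("homolog search is symmetric and monotone in its thresholds", {
  spec <- fixture_spec(32, n_chroms = 1L, chrom_length = 25000L,
                       n_shared_trs = 10L, n_private_trs = 5L,
                       motif_divergence = 0.1, indel_blocks = 2L)
  b <- make_genome_pair(spec)
  fwd <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab, b$chain_ba,
                             min_overlap = 0.1, min_similarity = 85)
  rev <- reciprocal_homologs(b$catalog_b, b$catalog_a, b$chain_ba, b$chain_ab,
                             min_overlap = 0.1, min_similarity = 85)
  expect_setequal(paste(fwd$locus_a, fwd$locus_b),
                  paste(rev$locus_b, rev$locus_a))
  for (sim in c(90, 95, 100)) {
    tighter <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab,
                                   b$chain_ba, min_overlap = 0.1,
                                   min_similarity = sim)
    expect_lte(nrow(tighter), nrow(fwd))
    expect_true(all(paste(tighter$locus_a, tighter$locus_b) %in%
                      paste(fwd$locus_a, fwd$locus_b)))
  }
  tighter_ov <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab,
                                    b$chain_ba, min_overlap = 0.9,
                                    min_similarity = 85)
  expect_lte(nrow(tighter_ov), nrow(fwd))
})

test_that("a TR present in only one catalog yields no pair", {
  spec <- fixture_spec(33, n_chroms = 1L, chrom_length = 15000L,
                       n_shared_trs = 0L, n_private_trs = 4L,
                       indel_blocks = 0L)
  b <- make_genome_pair(spec)
  pairs <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab,
                               b$chain_ba, min_overlap = 0.1,
                               min_similarity = 50)
  expect_equal(nrow(pairs), 0L)
})

test_that("inconsistent assemblies are a configuration error", {
  spec <- fixture_spec(34, n_chroms = 1L, chrom_length = 15000L,
                       n_shared_trs = 4L, n_private_trs = 0L)
  b <- make_genome_pair(spec)
  wrong <- b$catalog_a
  wrong$chrom <- "chrZ"
  expect_error(reciprocal_homologs(wrong, b$catalog_b, b$chain_ab, b$chain_ba),
               "inconsistent")
})

test_that("shared_length_table and the homolog writer emit the pair schema", {
  spec <- fixture_spec(35, n_chroms = 1L, chrom_length = 20000L,
                       n_shared_trs = 5L, n_private_trs = 0L,
                       motif_divergence = 0)
  b <- make_genome_pair(spec)
  pairs <- reciprocal_homologs(b$catalog_a, b$catalog_b, b$chain_ab,
                               b$chain_ba)
  tab <- shared_length_table(pairs)
  expect_equal(nrow(tab), nrow(pairs))
  expect_equal(tab$length_a, pairs$end_a - pairs$start_a)
  expect_equal(tab$length_b, pairs$end_b - pairs$start_b)
  expect_equal(nrow(shared_length_table(pairs[0, ])), 0L)
  p <- tempfile(fileext = ".tsv")
  write_homolog_table(pairs, p)
  lines <- readLines(p)
  expect_equal(length(lines), nrow(pairs) + 1L)
  expect_match(lines[1], "^#chrom_a\tstart_a\tend_a\tmotif_a")
  expect_equal(length(strsplit(lines[2], "\t")[[1]]), 17L)
})
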