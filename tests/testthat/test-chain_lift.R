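identity_chain_txt <- "chain 100 chrA 100 + 0 100 chrB 100 + 0 100 1\n100\n"
two_block_txt <- "chain 100 chrA 100 + 0 60 chrB 100 + 0 55 1\n20\t10\t5\n30\n"

test_that("parse_chain reads headers and blocks and validates sums", {
  id <- parse_chain(identity_chain_txt)
  expect_length(id, 1L)
  expect_equal(nrow(id[[1]]$blocks), 1L)
  expect_equal(id[[1]]$blocks$size, 100)

  ch <- parse_chain(two_block_txt)[[1]]
  expect_equal(ch$blocks$size, c(20, 30))
  expect_equal(ch$blocks$dt, c(10, 0))
  expect_equal(ch$blocks$dq, c(5, 0))
  # hand sums: 20+10+30 = 60 target, 20+5+30 = 55 query
  expect_equal(sum(ch$blocks$size) + sum(ch$blocks$dt), ch$t_end - ch$t_start)
  expect_equal(sum(ch$blocks$size) + sum(ch$blocks$dq), ch$q_end - ch$q_start)
  expect_equal(ch$blocks$t_off, c(0, 30))
  expect_equal(ch$blocks$q_off, c(0, 25))
})

test_that("parse_chain rejects inconsistent or malformed chains", {
  bad_sum <- "chain 100 chrA 100 + 0 61 chrB 100 + 0 55 7\n20\t10\t5\n30\n"
  expect_error(parse_chain(bad_sum), "chain 7.*target block sums")
  bad_q <- "chain 100 chrA 100 + 0 60 chrB 100 + 0 56 8\n20\t10\t5\n30\n"
  expect_error(parse_chain(bad_q), "chain 8.*query block sums")
  expect_error(parse_chain("chain 100 chrA 100 + 0 60 chrB 100 + 0 55\n60\n"),
               "13 fields")
  neg <- "chain 100 chrA 100 + 0 60 chrB 100 + 0 55 1\n20\t-10\t5\n30\n"
  expect_error(parse_chain(neg), "negative")
  expect_error(parse_chain("chain 100 chrA 100 - 0 60 chrB 100 + 0 55 1\n60\n"),
               "target strand")
})

test_that("chain writer round-trips through the parser", {
  withr::with_seed(11, {
    chains <- get("new_chain_set", asNamespace("trcompare"))(
      lapply(1:5, random_chain))
    p <- tempfile(fileext = ".chain")
    write_chain(chains, p)
    re <- parse_chain(p)
    expect_length(re, 5L)
    for (k in 1:5) {
      expect_equal(re[[k]]$blocks, chains[[k]]$blocks)
      for (f in c("score", "t_name", "t_size", "t_start", "t_end", "q_name",
                  "q_size", "q_strand", "q_start", "q_end", "chain_id")) {
        expect_equal(re[[k]][[f]], chains[[k]][[f]], info = f)
      }
    }
  })
})

test_that("lift_interval maps through an identity chain unchanged", {
  id <- parse_chain(identity_chain_txt)
  r <- lift_interval(id, "chrA", 10, 20)
  expect_equal(r$status, "mapped")
  expect_equal(r$q_chrom, "chrB")
  expect_equal(r$q_start, 10L)
  expect_equal(r$q_end, 20L)
  expect_equal(r$strand, "+")
  expect_equal(r$mapped_fraction, 1)
})

test_that("lift_interval handles gaps, thresholds and failure reasons", {
  ch <- parse_chain(two_block_txt)
  # wholly inside block 1
  r1 <- lift_interval(ch, "chrA", 0, 20)
  expect_equal(c(r1$q_start, r1$q_end), c(0L, 20L))
  expect_equal(r1$mapped_fraction, 1)
  # straddles the target gap (bases 20..29 unaligned): 5 of 10 bases map
  r2 <- lift_interval(ch, "chrA", 25, 35)
  expect_equal(r2$status, "partially_deleted")
  expect_equal(r2$mapped_fraction, 0.5)
  r3 <- lift_interval(ch, "chrA", 25, 35, min_match = 0.1)
  expect_equal(r3$status, "mapped")
  expect_equal(c(r3$q_start, r3$q_end), c(25L, 30L))
  # fully inside the gap
  r4 <- lift_interval(ch, "chrA", 21, 29, min_match = 0.01)
  expect_equal(r4$status, "partially_deleted")
  # outside all chains
  expect_equal(lift_interval(ch, "chrA", 70, 80)$status, "no_chain")
  expect_equal(lift_interval(ch, "chrX", 0, 10)$status, "no_chain")
  # span semantics bridge internal gaps
  r5 <- lift_interval(ch, "chrA", 10, 40, min_match = 0.1)
  expect_equal(c(r5$q_start, r5$q_end), c(10L, 35L))
  expect_equal(r5$mapped_fraction, 20 / 30)
})

test_that("split_across_chains is reported when several chains touch", {
  two <- paste0("chain 200 chrA 100 + 0 20 chrB 200 + 0 20 1\n20\n\n",
                "chain 100 chrA 100 + 30 50 chrB 200 + 50 70 2\n20\n")
  chains <- parse_chain(two)
  r <- lift_interval(chains, "chrA", 10, 45)
  expect_equal(r$status, "split_across_chains")
  # best chain alone is used when it satisfies min_match
  r2 <- lift_interval(chains, "chrA", 10, 45, min_match = 0.2)
  expect_equal(r2$chain_id, 1)
  expect_equal(c(r2$q_start, r2$q_end), c(10L, 20L))
})

test_that("minus-strand lifts are flipped to plus-strand coordinates", {
  chm <- parse_chain("chain 5 chrA 100 + 0 30 chrB 100 - 0 30 2\n30\n")
  # strand-local base 10 -> plus-strand 100 - 10 - 1 = 89
  r <- lift_interval(chm, "chrA", 10, 11)
  expect_equal(c(r$q_start, r$q_end), c(89L, 90L))
  expect_equal(r$strand, "-")
  r2 <- lift_interval(chm, "chrA", 10, 20)
  expect_equal(c(r2$q_start, r2$q_end), c(80L, 90L))
})

test_that("raising min_match never increases the number of mapped intervals", {
  withr::with_seed(5, {
    chains <- get("new_chain_set", asNamespace("trcompare"))(
      lapply(1:10, random_chain))
    ivs <- lapply(1:60, function(i) {
      s <- sample(0:150, 1)
      c(s, s + sample(1:40, 1))
    })
    counts <- vapply(c(0.05, 0.25, 0.5, 0.75, 0.95, 1), function(mm) {
      sum(vapply(ivs, function(iv) {
        lift_interval(chains, "tA", iv[1], iv[2], min_match = mm)$status ==
          "mapped"
      }, logical(1)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("lift_catalog preserves order and reports failure reasons", {
  ch <- parse_chain(two_block_txt)
  cat <- mini_catalog("chrA", c(0L, 22L, 30L), c(15L, 28L, 50L))
  res <- lift_catalog(cat, ch)
  expect_equal(nrow(res$lifted), 2L)
  expect_equal(res$lifted$source_id, c("chrA_0_15", "chrA_30_50"))
  expect_equal(res$report[["partially_deleted"]], 1L)
  expect_equal(res$unmapped$reason, "partially_deleted")
  # empty catalog -> empty result
  res0 <- lift_catalog(cat[0, ], ch)
  expect_equal(nrow(res0$lifted), 0L)
  expect_equal(sum(res0$report), 0L)
  # identity chain maps a catalog onto itself
  id <- parse_chain(identity_chain_txt)
  cat5 <- mini_catalog("chrA", seq(0L, 80L, 20L), seq(10L, 90L, 20L))
  lifted5 <- lift_catalog(cat5, id)$lifted
  expect_equal(nrow(lifted5), 5L)
  expect_equal(lifted5$q_start, cat5$start)
  expect_equal(lifted5$q_end, cat5$end)
})

test_that("lifted span agrees with the per-base brute-force mapper", {
  withr::with_seed(99, {
    n_checked <- 0L
    for (rep in 1:60) {
      chains <- get("new_chain_set", asNamespace("trcompare"))(
        lapply(seq_len(sample(1:3, 1)), random_chain))
      for (k in 1:6) {
        s <- sample(0:150, 1)
        e <- s + sample(1:50, 1)
        got <- lift_interval(chains, "tA", s, e, min_match = 1e-9)
        want <- brute_lift(chains, "tA", s, e)
        if (is.null(want)) {
          expect_equal(got$status, "no_chain")
        } else if (is.null(want$span)) {
          expect_true(got$status %in% c("partially_deleted",
                                        "split_across_chains"))
          expect_equal(got$mapped_fraction, 0)
        } else {
          expect_equal(got$status, "mapped")
          expect_equal(c(got$q_start, got$q_end), as.integer(want$span))
          expect_equal(got$mapped_fraction, want$frac)
          expect_equal(got$strand, want$strand)
        }
        n_checked <- n_checked + 1L
      }
    }
    expect_gte(n_checked, 200L)
  })
})

test_that("round trip through a chain and its exact inverse is the identity", {
  spec <- fixture_spec(21, n_chroms = 1L, chrom_length = 20000L,
                       n_shared_trs = 8L, n_private_trs = 3L,
                       indel_blocks = 3L)
  b <- make_genome_pair(spec)
  for (i in seq_len(nrow(b$catalog_a))) {
    fwd <- lift_interval(b$chain_ab, b$catalog_a$chrom[i],
                         b$catalog_a$start[i], b$catalog_a$end[i])
    expect_equal(fwd$status, "mapped")
    back <- lift_interval(b$chain_ba, fwd$q_chrom, fwd$q_start, fwd$q_end)
    expect_equal(back$q_start, b$catalog_a$start[i])
    expect_equal(back$q_end, b$catalog_a$end[i])
  }
})

test_that("strand involution: flipping q_strand twice returns identical output", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      ch <- random_chain(1L)
      flip <- ch
      flip$q_strand <- if (ch$q_strand == "+") "-" else "+"
      flip2 <- flip
      flip2$q_strand <- ch$q_strand
      s <- ch$t_start
      e <- ch$t_end
      r0 <- lift_interval(chain_set1(ch), "tA", s, e, min_match = 1e-9)
      r2 <- lift_interval(chain_set1(flip2), "tA", s, e, min_match = 1e-9)
      expect_equal(r0, r2)
    }
  })
})
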