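# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own algorithms: the alignment oracle enumerates every
# global alignment recursively, and the liftover oracle walks chains base by
# base.

# Optimal global alignment score by brute-force recursion over all
# alignments (match/mismatch/gap applied per column). Exponential; only for
# short strings.
nw_enum_score <- function(a, b, scoring) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) scoring$match else scoring$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= length(av)) best <- max(best, scoring$gap + rec(i + 1L, j))
    if (j <= length(bv)) best <- max(best, scoring$gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Map every base of [start, end) through the best-scoring overlapping chain,
# one base at a time. Returns list(frac, span = c(start, end) plus-strand,
# strand) or NULL when nothing maps / no chain overlaps.
brute_lift <- function(chains, chrom, start, end) {
  cand <- Filter(function(ch) ch$t_name == chrom && ch$t_start < end &&
                   ch$t_end > start, chains)
  if (!length(cand)) return(NULL)
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ids <- vapply(cand, `[[`, numeric(1), "chain_id")
  ch <- cand[[order(-scores, ids)[1]]]
  b <- ch$blocks
  qpos <- integer(0)
  for (p in start:(end - 1L)) {
    for (k in seq_len(nrow(b))) {
      if (p >= b$t_off[k] && p < b$t_off[k] + b$size[k]) {
        qpos <- c(qpos, b$q_off[k] + (p - b$t_off[k]))
        break
      }
    }
  }
  if (!length(qpos)) return(list(frac = 0, span = NULL, strand = ch$q_strand,
                                 n_candidates = length(cand)))
  if (ch$q_strand == "-") qpos <- ch$q_size - qpos - 1L
  list(frac = length(qpos) / (end - start),
       span = c(min(qpos), max(qpos) + 1L), strand = ch$q_strand,
       n_candidates = length(cand))
}

# A random valid chain with <= max_blocks blocks, random gaps and strand.
# Spans are derived from the blocks so validation always passes.
random_chain <- function(chain_id, t_name = "tA", q_name = "qB",
                         max_blocks = 6L) {
  n <- sample.int(max_blocks, 1L)
  size <- sample(1:30, n, replace = TRUE)
  dt <- c(sample(0:15, n - 1L, replace = TRUE), 0L)
  dq <- c(sample(0:15, n - 1L, replace = TRUE), 0L)
  t_start <- sample(0:20, 1L)
  q_start <- sample(0:20, 1L)
  t_end <- t_start + sum(size) + sum(dt)
  q_end <- q_start + sum(size) + sum(dq)
  validate_ch <- get("validate_chain", asNamespace("trcompare"))
  validate_ch(list(
    score = sample(1:1000, 1L), t_name = t_name,
    t_size = t_end + sample(0:50, 1L), t_strand = "+",
    t_start = t_start, t_end = t_end, q_name = q_name,
    q_size = q_end + sample(0:50, 1L), q_strand = sample(c("+", "-"), 1L),
    q_start = q_start, q_end = q_end, chain_id = chain_id,
    blocks = data.frame(size = size, dt = dt, dq = dq)))
}

chain_set1 <- function(ch) {
  get("new_chain_set", asNamespace("trcompare"))(list(ch))
}

# Small hand-rolled catalog builder for interval tests.
mini_catalog <- function(chrom, start, end, motif = "ACGT",
                         copy_number = 3, score = 50) {
  tr_catalog(chrom = chrom, start = start, end = end,
             motif = rep_len(motif, length(start)),
             copy_number = rep_len(copy_number, length(start)),
             alignment_score = rep_len(score, length(start)))
}

# Write a small multi-sample VCF from genotype strings; returns the path.
write_mini_vcf <- function(gt, samples = paste0("S", seq_along(gt)),
                           ref = "ACACACACACAC",
                           alts = c("ACACACACACACACACAC"),
                           id = "tr1", chrom = "chr1", pos = 11L,
                           format = "GT", extra_records = character(0)) {
  path <- tempfile(fileext = ".vcf")
  alt_field <- if (length(alts)) paste(alts, collapse = ",") else "."
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=100000>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AL,Number=.,Type=Integer,Description=\"Allele lengths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c(chrom, pos, id, ref, alt_field, ".", ".", ".", format, gt),
          collapse = "\t"),
    extra_records
  ), path)
  path
}
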