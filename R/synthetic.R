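#' Specification for synthetic comparative-TR fixtures
#'
#' Describes a fully seeded toy world: a pair of genomes where genome B is
#' derived from genome A by block insertions/deletions and by substituting
#' bases in the motifs of shared (homologous) TRs, plus a diploid cohort
#' genotyped at the planted loci. All randomness flows from `seed`; the same
#' spec yields byte-identical outputs.
#'
#' Motif divergence applies exactly `floor(motif_divergence * motif length)`
#' substitutions per shared motif (no indels), so the realized per-base
#' divergence never exceeds the stated rate and the planted pair similarity
#' has the closed form `100 * (1 - k / L)`. Planted TRs are non-overlapping
#' with at least 50 bp spacing and all pass the default [filter_policy()].
#'
#' @param seed Integer seed (single source of randomness).
#' @param n_chroms Number of chromosomes per genome.
#' @param chrom_length Approximate chromosome length, bp.
#' @param n_shared_trs Total number of homologous TRs planted in both genomes.
#' @param n_private_trs TRs planted in only one genome, per species.
#' @param motif_length Length-2 integer range of motif lengths, bp.
#' @param copy_number Length-2 numeric range of copy numbers (min >= 2.5).
#' @param motif_divergence Per-base substitution rate between homologous
#'   motifs, in \[0, 0.2\].
#' @param indel_blocks Number of unaligned blocks inserted between the
#'   genomes (split between A-only and B-only).
#' @param indel_size Length-2 range of unaligned block sizes, bp.
#' @param n_samples Cohort size for the genotype VCF.
#' @param allele_count Length-2 integer range of alleles per locus.
#' @param n_populations Number of populations the cohort is split into.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed,
                         n_chroms = 2L,
                         chrom_length = 60000L,
                         n_shared_trs = 50L,
                         n_private_trs = 20L,
                         motif_length = c(10L, 30L),
                         copy_number = c(3, 8),
                         motif_divergence = 0.05,
                         indel_blocks = 4L,
                         indel_size = c(200L, 800L),
                         n_samples = 24L,
                         allele_count = c(1L, 4L),
                         n_populations = 3L) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_chroms >= 1L, chrom_length > 0,
            length(motif_length) == 2L, motif_length[1] >= 1L,
            motif_length[1] <= motif_length[2],
            length(copy_number) == 2L, copy_number[1] >= 2.5,
            copy_number[1] <= copy_number[2],
            motif_divergence >= 0, motif_divergence <= 0.2,
            indel_blocks >= 0L, length(indel_size) == 2L,
            n_samples >= 1L, length(allele_count) == 2L,
            allele_count[1] >= 1L, n_populations >= 1L)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_shared_trs = as.integer(n_shared_trs),
                 n_private_trs = as.integer(n_private_trs),
                 motif_length = as.integer(motif_length),
                 copy_number = as.numeric(copy_number),
                 motif_divergence = motif_divergence,
                 indel_blocks = as.integer(indel_blocks),
                 indel_size = as.integer(indel_size),
                 n_samples = as.integer(n_samples),
                 allele_count = as.integer(allele_count),
                 n_populations = as.integer(n_populations)),
            class = "fixture_spec")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Repeat array of `copies` (possibly fractional) copies of `motif`.
repeat_array <- function(motif, copies) {
  L <- nchar(motif)
  total <- round(L * copies)
  paste0(strrep(motif, total %/% L), substr(motif, 1L, total %% L))
}

# Substitute exactly k bases of motif at distinct positions (always changing
# the base), so realized divergence is exactly k / nchar(motif).
mutate_motif <- function(motif, k) {
  if (k == 0L) return(motif)
  v <- strsplit(motif, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), k)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# Distribute n items over k bins as evenly as possible.
split_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Generate a paired-genome fixture bundle
#'
#' Builds genome A from random background sequence with planted TR arrays,
#' derives genome B from it (shared TRs carry substituted motifs at the
#' spec's divergence; unaligned indel blocks are inserted into one genome or
#' the other; private TRs are backed by plain background in the other
#' genome), and emits exact chain files in both directions whose block
#' structure follows the edit plan, so every chain satisfies the block-sum
#' invariants by construction.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; when given, FASTA, catalog BED,
#'   chain and ground-truth files are written there.
#' @return List with `genome_a`, `genome_b` (named character vectors),
#'   `catalog_a`, `catalog_b` (`tr_catalog`s of planted loci), `chain_ab`,
#'   `chain_ba` (`chain_set`s), `truth` (data.frame of planted homolog pairs
#'   with realized motif divergence), and — when `dir` is given — `paths`.
#' @export
make_genome_pair <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, make_genome_pair_impl(spec, dir))
}

make_genome_pair_impl <- function(spec, dir) {
  n_ch <- spec$n_chroms
  sh_per <- split_counts(spec$n_shared_trs, n_ch)
  pa_per <- split_counts(spec$n_private_trs, n_ch)
  pb_per <- split_counts(spec$n_private_trs, n_ch)
  ind_per <- split_counts(spec$indel_blocks, n_ch)
  genome_a <- character(0)
  genome_b <- character(0)
  cat_a <- list()
  cat_b <- list()
  truth <- list()
  chains_ab <- list()
  chains_ba <- list()
  for (ci in seq_len(n_ch)) {
    chrom_a <- paste0("chrA", ci)
    chrom_b <- paste0("chrB", ci)
    types <- sample(c(rep("shared", sh_per[ci]), rep("private_a", pa_per[ci]),
                      rep("private_b", pb_per[ci])))
    n_tr <- length(types)
    # plan TRs
    trs <- lapply(seq_len(n_tr), function(i) {
      L <- sample(spec$motif_length[1]:spec$motif_length[2], 1L)
      copies <- stats::runif(1, spec$copy_number[1], spec$copy_number[2])
      motif_a <- random_dna(L)
      arr_a <- repeat_array(motif_a, copies)
      k <- floor(spec$motif_divergence * L)
      motif_b <- if (types[i] == "shared") mutate_motif(motif_a, k) else NA
      arr_b <- if (types[i] == "shared") {
        paste0(strrep(motif_b, nchar(arr_a) %/% L),
               substr(motif_b, 1L, nchar(arr_a) %% L))
      } else NA
      list(type = types[i], motif_a = motif_a, motif_b = motif_b,
           arr_a = arr_a, arr_b = arr_b, len = nchar(arr_a),
           copies = nchar(arr_a) / L, div = if (types[i] == "shared") k / L else NA)
    })
    tr_total <- sum(vapply(trs, `[[`, numeric(1), "len"))
    n_gaps <- n_tr + 1L
    bg_total <- spec$chrom_length - tr_total
    if (bg_total < n_gaps * 50L) {
      stop("chrom_length too small to place all TRs with 50 bp spacing",
           call. = FALSE)
    }
    gap_len <- rep(bg_total %/% n_gaps, n_gaps)
    gap_len[seq_len(bg_total %% n_gaps)] <- gap_len[seq_len(bg_total %% n_gaps)] + 1L
    # choose gaps to host indel blocks (never the first or last gap, so the
    # chain starts and ends on an aligned block)
    host <- if (ind_per[ci] > 0L && n_gaps > 2L) {
      sample(2:(n_gaps - 1L), min(ind_per[ci], n_gaps - 2L))
    } else integer(0)
    # build the ordered segment plan: type, len_a, len_b, sequences
    segs <- list()
    add <- function(type, seq_a, seq_b) {
      segs[[length(segs) + 1L]] <<- list(type = type, seq_a = seq_a,
                                         seq_b = seq_b)
    }
    for (g in seq_len(n_gaps)) {
      if (g %in% host) {
        isz <- sample(spec$indel_size[1]:spec$indel_size[2], 1L)
        side <- sample(c("a", "b"), 1L)
        half <- gap_len[g] %/% 2L
        bg1 <- random_dna(half)
        bg2 <- random_dna(gap_len[g] - half)
        add("aligned", bg1, bg1)
        ins <- random_dna(isz)
        if (side == "a") add("a_only", ins, "") else add("b_only", "", ins)
        add("aligned", bg2, bg2)
      } else {
        bg <- random_dna(gap_len[g])
        add("aligned", bg, bg)
      }
      if (g <= n_tr) {
        tr <- trs[[g]]
        if (tr$type == "shared") {
          add("tr_shared", tr$arr_a, tr$arr_b)
        } else if (tr$type == "private_a") {
          add("tr_a", tr$arr_a, random_dna(tr$len))
        } else {
          add("tr_b", random_dna(tr$len), tr$arr_a)
        }
      }
    }
    # materialize sequences, record catalogs/truth, derive chain blocks
    pos_a <- 0L
    pos_b <- 0L
    seq_a <- character(length(segs))
    seq_b <- character(length(segs))
    blocks <- list()  # (size, dt, dq) for chain A->B
    cur_size <- 0L
    cur_dt <- 0L
    cur_dq <- 0L
    tr_idx <- 0L
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      la <- nchar(s$seq_a)
      lb <- nchar(s$seq_b)
      seq_a[si] <- s$seq_a
      seq_b[si] <- s$seq_b
      if (s$type == "a_only") {
        cur_dt <- cur_dt + la
      } else if (s$type == "b_only") {
        cur_dq <- cur_dq + lb
      } else {
        # aligned segment (background or TR); la == lb
        if (cur_dt > 0L || cur_dq > 0L) {
          blocks[[length(blocks) + 1L]] <- c(cur_size, cur_dt, cur_dq)
          cur_size <- 0L
          cur_dt <- 0L
          cur_dq <- 0L
        }
        cur_size <- cur_size + la
      }
      if (s$type %in% c("tr_shared", "tr_a", "tr_b")) {
        tr_idx <- tr_idx + 1L
        tr <- trs[[tr_idx]]
      }
      if (s$type == "tr_shared") {
        cat_a[[length(cat_a) + 1L]] <- list(
          chrom = chrom_a, start = pos_a, end = pos_a + la,
          motif = tr$motif_a, copies = tr$copies, seq = s$seq_a)
        cat_b[[length(cat_b) + 1L]] <- list(
          chrom = chrom_b, start = pos_b, end = pos_b + lb,
          motif = tr$motif_b, copies = tr$copies, seq = s$seq_b)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom_a = chrom_a, start_a = pos_a, end_a = pos_a + la,
          chrom_b = chrom_b, start_b = pos_b, end_b = pos_b + lb,
          motif_a = tr$motif_a, motif_b = tr$motif_b,
          divergence = tr$div, stringsAsFactors = FALSE)
      } else if (s$type == "tr_a") {
        cat_a[[length(cat_a) + 1L]] <- list(
          chrom = chrom_a, start = pos_a, end = pos_a + la,
          motif = tr$motif_a, copies = tr$copies, seq = s$seq_a)
      } else if (s$type == "tr_b") {
        cat_b[[length(cat_b) + 1L]] <- list(
          chrom = chrom_b, start = pos_b, end = pos_b + lb,
          motif = tr$motif_a, copies = tr$copies, seq = s$seq_b)
      }
      pos_a <- pos_a + la
      pos_b <- pos_b + lb
    }
    blocks[[length(blocks) + 1L]] <- c(cur_size, 0L, 0L)
    b <- as.data.frame(do.call(rbind, blocks))
    names(b) <- c("size", "dt", "dq")
    aligned <- sum(b$size)
    ch_ab <- validate_chain(list(
      score = 2 * aligned, t_name = chrom_a, t_size = pos_a, t_strand = "+",
      t_start = 0, t_end = pos_a, q_name = chrom_b, q_size = pos_b,
      q_strand = "+", q_start = 0, q_end = pos_b, chain_id = ci,
      blocks = b[c("size", "dt", "dq")]))
    b_inv <- b[c("size", "dq", "dt")]
    names(b_inv) <- c("size", "dt", "dq")
    ch_ba <- validate_chain(list(
      score = 2 * aligned, t_name = chrom_b, t_size = pos_b, t_strand = "+",
      t_start = 0, t_end = pos_b, q_name = chrom_a, q_size = pos_a,
      q_strand = "+", q_start = 0, q_end = pos_a, chain_id = ci,
      blocks = b_inv))
    chains_ab[[ci]] <- ch_ab
    chains_ba[[ci]] <- ch_ba
    genome_a[chrom_a] <- paste(seq_a, collapse = "")
    genome_b[chrom_b] <- paste(seq_b, collapse = "")
  }
  build_cat <- function(items) {
    if (!length(items)) return(empty_catalog())
    tr_catalog(
      chrom = vapply(items, `[[`, character(1), "chrom"),
      start = vapply(items, `[[`, numeric(1), "start"),
      end = vapply(items, `[[`, numeric(1), "end"),
      motif = vapply(items, `[[`, character(1), "motif"),
      copy_number = vapply(items, `[[`, numeric(1), "copies"),
      percent_matches = 100, percent_indels = 0,
      alignment_score = 2 * (vapply(items, `[[`, numeric(1), "end") -
                               vapply(items, `[[`, numeric(1), "start")),
      sequence = vapply(items, `[[`, character(1), "seq"))
  }
  catalog_a <- build_cat(cat_a)
  catalog_b <- build_cat(cat_b)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
               chrom_b = character(), start_b = integer(), end_b = integer(),
               motif_a = character(), motif_b = character(),
               divergence = numeric(), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  out <- list(genome_a = genome_a, genome_b = genome_b,
              catalog_a = catalog_a, catalog_b = catalog_b,
              chain_ab = new_chain_set(chains_ab),
              chain_ba = new_chain_set(chains_ba),
              truth = truth_df)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta_a = file.path(dir, "genomeA.fa"),
      fasta_b = file.path(dir, "genomeB.fa"),
      catalog_a = file.path(dir, "catalogA.bed"),
      catalog_b = file.path(dir, "catalogB.bed"),
      chain_ab = file.path(dir, "AtoB.chain"),
      chain_ba = file.path(dir, "BtoA.chain"),
      truth = file.path(dir, "homolog_truth.tsv"))
    write_fasta(genome_a, paths$fasta_a)
    write_fasta(genome_b, paths$fasta_b)
    write_catalog_bed(catalog_a, paths$catalog_a)
    write_catalog_bed(catalog_b, paths$catalog_b)
    write_chain(out$chain_ab, paths$chain_ab)
    write_chain(out$chain_ba, paths$chain_ba)
    write_tsv_plain(truth_df, paths$truth, col.names = TRUE)
    out$paths <- paths
  }
  out
}

write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 60L)
  invisible(path)
}

#' Generate a synthetic cohort genotype VCF for a catalog
#'
#' For each catalog locus an allele pool is built from the reference repeat
#' array by varying the number of motif copies (so alleles differ in length
#' and sequence), per-population allele frequencies are drawn from a flat
#' Dirichlet, and each sample's diploid genotype is sampled independently
#' from its population's frequencies. The VCF carries full allele sequences
#' in REF/ALT, an `AL` per-allele length FORMAT field, and one record per
#' catalog locus. Also emits the sample-to-population map and ground-truth
#' tables (per-population allele frequencies and the sampled genotypes).
#'
#' Randomness derives from `spec$seed + 1`, so the cohort is reproducible
#' independently of whether [make_genome_pair()] was called.
#'
#' @param spec A [fixture_spec()].
#' @param catalog A `tr_catalog` (typically `catalog_a` from
#'   [make_genome_pair()]).
#' @param dir Output directory (default `tempdir()`); the VCF must live on
#'   disk to be parsed back.
#' @return List: `vcf` (path), `pop_map` (data.frame + written TSV),
#'   `truth_freq` (locus, population, allele index, length, frequency),
#'   `truth_genotypes` (sampled allele indices and lengths per call) and
#'   `paths`.
#' @export
make_cohort_vcf <- function(spec, catalog, dir = tempdir()) {
  stopifnot(inherits(spec, "fixture_spec"), nrow(catalog) >= 1L)
  withr::with_seed(spec$seed + 1L, make_cohort_vcf_impl(spec, catalog, dir))
}

make_cohort_vcf_impl <- function(spec, catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  pops <- paste0("POP", rep_len(seq_len(spec$n_populations), n))
  pop_map <- data.frame(sample = samples, population = pops,
                        stringsAsFactors = FALSE)
  ord <- order(catalog$chrom, catalog$start)
  catalog <- catalog[ord, , drop = FALSE]
  records <- character(nrow(catalog))
  truth_freq <- list()
  truth_gt <- list()
  for (i in seq_len(nrow(catalog))) {
    motif <- catalog$motif[i]
    L <- nchar(motif)
    ref_seq <- catalog$sequence[i]
    if (is.na(ref_seq)) ref_seq <- repeat_array(motif, catalog$copy_number[i])
    id <- locus_id(catalog$chrom[i], catalog$start[i], catalog$end[i])
    k <- sample(spec$allele_count[1]:spec$allele_count[2], 1L)
    base_copies <- max(1L, floor(catalog$copy_number[i]))
    cand_copies <- setdiff(seq(max(1L, base_copies - 3L), base_copies + 5L),
                           base_copies)
    alt_seqs <- if (k > 1L) {
      vapply(sample(cand_copies, k - 1L), function(cc) strrep(motif, cc),
             character(1))
    } else character(0)
    alleles <- c(ref_seq, alt_seqs)
    lens <- nchar(alleles)
    # per-population frequencies: flat Dirichlet via normalized gammas
    freqs <- lapply(unique(pops), function(p) {
      f <- stats::rgamma(k, shape = 1)
      f / sum(f)
    })
    names(freqs) <- unique(pops)
    for (p in unique(pops)) {
      truth_freq[[length(truth_freq) + 1L]] <- data.frame(
        locus_id = id, population = p, allele = seq_len(k) - 1L,
        length = lens, freq = freqs[[p]], stringsAsFactors = FALSE)
    }
    gt_field <- character(n)
    a1 <- integer(n)
    a2 <- integer(n)
    for (s in seq_len(n)) {
      f <- freqs[[pops[s]]]
      dr <- sample.int(k, 2L, replace = TRUE, prob = f) - 1L
      a1[s] <- dr[1]
      a2[s] <- dr[2]
      gt_field[s] <- sprintf("%d/%d:%d,%d", dr[1], dr[2],
                             lens[dr[1] + 1L], lens[dr[2] + 1L])
    }
    truth_gt[[length(truth_gt) + 1L]] <- data.frame(
      locus_id = id, sample = samples, a1 = a1, a2 = a2,
      len1 = lens[a1 + 1L], len2 = lens[a2 + 1L], stringsAsFactors = FALSE)
    alt_field <- if (k > 1L) paste(alt_seqs, collapse = ",") else "."
    records[i] <- paste(c(catalog$chrom[i], catalog$start[i] + 1L, id,
                          ref_seq, alt_field, ".", ".",
                          sprintf("MOTIF=%s;END=%d", motif, catalog$end[i]),
                          "GT:AL", gt_field), collapse = "\t")
  }
  contigs <- unique(catalog$chrom)
  contig_len <- vapply(contigs, function(cc) {
    max(catalog$end[catalog$chrom == cc]) + 1000L
  }, numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs, contig_len),
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Repeat motif\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Locus end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AL,Number=.,Type=Integer,Description=\"Allele lengths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                pop_map = file.path(dir, "pop_map.tsv"),
                truth_freq = file.path(dir, "allele_freq_truth.tsv"))
  writeLines(c(header, records), paths$vcf)
  write_tsv_plain(pop_map, paths$pop_map)
  truth_freq_df <- do.call(rbind, truth_freq)
  truth_gt_df <- do.call(rbind, truth_gt)
  rownames(truth_freq_df) <- rownames(truth_gt_df) <- NULL
  write_tsv_plain(truth_freq_df, paths$truth_freq, col.names = TRUE)
  list(vcf = paths$vcf, pop_map = pop_map, truth_freq = truth_freq_df,
       truth_genotypes = truth_gt_df, paths = paths)
}
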