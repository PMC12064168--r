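#' Parse a multi-sample TR genotype VCF into per-sample calls
#'
#' Reads a VCF (plain or bgzipped) whose REF/ALT fields carry full repeat
#' allele sequences and whose genotypes are diploid, as produced by
#' TRGT-style TR genotypers. Allele sequences are resolved from GT indices
#' against REF/ALT; a per-allele integer length FORMAT field (default `AL`)
#' overrides sequence lengths when present. The locus identifier is the VCF
#' ID field when present, else `chrom_pos`.
#'
#' Phasing is ignored (`0|1` is treated as `0/1`). Haploid or higher-ploidy
#' genotypes are rejected. Missing genotypes (`./.`) are kept as calls marked
#' missing and excluded from all statistic denominators downstream.
#'
#' @param path Path to the VCF file.
#' @param length_field Name of the optional per-allele length FORMAT field
#'   (default `"AL"`).
#' @return Data.frame of genotype calls with columns `locus_id, chrom, pos,
#'   sample, a1, a2` (0-based allele indices, `NA` when missing), `seq1,
#'   seq2, len1, len2, missing`; the VCF sample order is kept in
#'   `attr(, "samples")` and the locus order in `attr(, "loci")`.
#' @export
parse_tr_vcf <- function(path, length_field = "AL") {
  assert_gt_format(path)
  vcf <- VariantAnnotation::readVcf(path)
  geno <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(geno)) {
    stop("VCF has no GT FORMAT field", call. = FALSE)
  }
  gt <- geno$GT
  samples <- colnames(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- VariantAnnotation::alt(vcf)
  ids <- rownames(gt)
  # readVcf substitutes "chrom:pos_REF/ALT" when the ID column is "."
  auto <- vapply(seq_along(ids), function(i) {
    grepl(":", ids[i], fixed = TRUE) &&
      startsWith(ids[i], paste0(chrom[i], ":", pos[i], "_"))
  }, logical(1))
  ids[auto] <- paste(chrom[auto], pos[auto], sep = "_")
  al <- if (length_field %in% names(geno)) geno[[length_field]] else NULL
  n_loci <- nrow(gt)
  n_samp <- ncol(gt)
  res <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    alleles <- c(ref[i], as.character(alt[[i]]))
    gti <- gt[i, ]
    fully_missing <- gti %in% c(".", "./.", ".|.") | is.na(gti)
    parts <- strsplit(ifelse(fully_missing, "./.", gti), "[/|]")
    ploidy <- lengths(parts)
    if (any(ploidy != 2L)) {
      stop("locus ", ids[i], ": non-diploid genotype for sample ",
           samples[which(ploidy != 2L)[1]], call. = FALSE)
    }
    m <- matrix(suppressWarnings(as.integer(unlist(parts))), nrow = 2L)
    dot <- vapply(parts, function(p) any(p == "."), logical(1))
    miss <- dot | apply(is.na(m), 2, any)
    if (any(!miss & apply(m, 2, max) > length(alleles) - 1L)) {
      bad <- which(!miss & apply(m, 2, max) > length(alleles) - 1L)[1]
      stop("locus ", ids[i], ": GT index exceeds ALT count for sample ",
           samples[bad], call. = FALSE)
    }
    a1 <- ifelse(miss, NA_integer_, m[1, ])
    a2 <- ifelse(miss, NA_integer_, m[2, ])
    seq1 <- ifelse(miss, NA_character_, alleles[a1 + 1L])
    seq2 <- ifelse(miss, NA_character_, alleles[a2 + 1L])
    len1 <- nchar(seq1)
    len2 <- nchar(seq2)
    if (!is.null(al)) {
      for (k in seq_len(n_samp)) {
        v <- suppressWarnings(as.integer(al[[(k - 1L) * n_loci + i]]))
        if (!miss[k] && length(v) == 2L && !anyNA(v)) {
          len1[k] <- v[1]
          len2[k] <- v[2]
        }
      }
    }
    res[[i]] <- data.frame(locus_id = ids[i], chrom = chrom[i], pos = pos[i],
                           sample = samples, a1 = a1, a2 = a2,
                           seq1 = seq1, seq2 = seq2, len1 = len1, len2 = len2,
                           missing = miss, stringsAsFactors = FALSE)
  }
  out <- if (n_loci) do.call(rbind, res) else
    data.frame(locus_id = character(), chrom = character(), pos = integer(),
               sample = character(), a1 = integer(), a2 = integer(),
               seq1 = character(), seq2 = character(), len1 = integer(),
               len2 = integer(), missing = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "loci") <- ids
  out
}

# A VCF whose records never carry GT in FORMAT must be a format error, but
# readVcf fills header-declared fields with missing values, so check the
# FORMAT column of the records directly.
assert_gt_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    batch <- readLines(con, n = 200L)
    if (!length(batch)) return(invisible(TRUE))
    data_lines <- batch[!startsWith(batch, "#") & nzchar(batch)]
    if (length(data_lines)) {
      fmt <- vapply(strsplit(data_lines, "\t", fixed = TRUE), function(f) {
        if (length(f) >= 9L) f[9] else ""
      }, character(1))
      has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(f) "GT" %in% f, logical(1))
      if (!all(has_gt)) {
        stop("VCF has no GT FORMAT field", call. = FALSE)
      }
      return(invisible(TRUE))
    }
  }
}

# Statistics for the calls of a single locus (assumes one locus_id).
locus_stats_one <- function(calls, by = "sequence", unbiased = TRUE) {
  called <- calls[!calls$missing, , drop = FALSE]
  n <- nrow(called)
  id <- calls$locus_id[1]
  if (n == 0L) {
    return(data.frame(locus_id = id, n_called = 0L, obs_het = NA_real_,
                      gene_diversity = NA_real_, n_unique_alleles = NA_integer_,
                      min_allele_len = NA_integer_, max_allele_len = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  key1 <- if (by == "length") as.character(called$len1) else called$seq1
  key2 <- if (by == "length") as.character(called$len2) else called$seq2
  obs_het <- mean(key1 != key2)
  p <- as.numeric(table(c(key1, key2))) / (2 * n)
  gd <- 1 - sum(p^2)
  if (unbiased) gd <- gd * (2 * n) / (2 * n - 1)
  data.frame(locus_id = id, n_called = n, obs_het = obs_het,
             gene_diversity = gd,
             n_unique_alleles = length(unique(c(key1, key2))),
             min_allele_len = min(called$len1, called$len2),
             max_allele_len = max(called$len1, called$len2),
             stringsAsFactors = FALSE)
}

#' Per-locus population-genetic statistics
#'
#' For each locus: the number of called diploid samples, observed
#' heterozygosity (fraction of called samples carrying two distinct
#' alleles), gene diversity, the number of unique alleles, and the range of
#' allele lengths over all called alleles. Gene diversity is Nei's unbiased
#' estimator `(2n / (2n - 1)) * (1 - sum(p_i^2))` with allele frequencies
#' `p_i` over the `2n` called chromosomes; `unbiased = FALSE` drops the
#' small-sample correction. Alleles are distinguished by their full sequence
#' string by default (sequence-composition variants count as distinct
#' alleles); `by = "length"` collapses alleles of equal length.
#'
#' A locus with zero non-missing calls is reported with `NA` statistics.
#'
#' @param calls Calls from [parse_tr_vcf()] (one or several loci).
#' @param by `"sequence"` (default) or `"length"`.
#' @param unbiased Apply the `2n/(2n-1)` correction (default `TRUE`).
#' @return Data.frame with one row per locus, in the VCF locus order.
#' @export
locus_stats <- function(calls, by = c("sequence", "length"), unbiased = TRUE) {
  by <- match.arg(by)
  loci <- attr(calls, "loci")
  if (is.null(loci)) loci <- unique(calls$locus_id)
  rows <- lapply(loci, function(id) {
    locus_stats_one(calls[calls$locus_id == id, , drop = FALSE], by, unbiased)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    locus_stats_one(data.frame(locus_id = character(), missing = logical()))[0, ]
  rownames(out) <- NULL
  out
}

#' Read a sample-to-population map
#'
#' Two tab-separated columns, sample and population, no header.
#'
#' @param path Path to the TSV.
#' @return Data.frame `sample`, `population`.
#' @export
read_pop_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sample", "population"),
                         colClasses = "character")
  x
}

#' Per-population locus statistics in long format
#'
#' Recomputes [locus_stats()] within each population using only that
#' population's samples and returns a long, plot-ready table
#' (`population, locus_id, statistic, value`), e.g. for violin plots of
#' observed heterozygosity per population.
#'
#' Samples absent from the map are an error in strict mode (default) and are
#' dropped with a warning otherwise. A population left with no samples is
#' omitted with a warning.
#'
#' @param calls Calls from [parse_tr_vcf()].
#' @param pop_map Data.frame `sample`, `population` (see [read_pop_map()]).
#' @param strict Error on unmapped samples (default `TRUE`).
#' @param by,unbiased Passed to [locus_stats()].
#' @return Long data.frame `population, locus_id, statistic, value`.
#' @export
population_summary <- function(calls, pop_map, strict = TRUE,
                               by = "sequence", unbiased = TRUE) {
  samples <- attr(calls, "samples")
  if (is.null(samples)) samples <- unique(calls$sample)
  unmapped <- setdiff(samples, pop_map$sample)
  if (length(unmapped)) {
    if (strict) {
      stop("samples absent from the population map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(unmapped),
            " sample(s) absent from the population map", call. = FALSE)
  }
  stat_cols <- c("n_called", "obs_het", "gene_diversity", "n_unique_alleles",
                 "min_allele_len", "max_allele_len")
  out <- list()
  for (pop in unique(pop_map$population)) {
    members <- intersect(samples, pop_map$sample[pop_map$population == pop])
    if (!length(members)) {
      warning("population ", pop, " has no samples after mapping; omitted",
              call. = FALSE)
      next
    }
    sub <- calls[calls$sample %in% members, , drop = FALSE]
    attr(sub, "loci") <- attr(calls, "loci")
    st <- locus_stats(sub, by = by, unbiased = unbiased)
    long <- data.frame(
      population = pop,
      locus_id = rep(st$locus_id, times = length(stat_cols)),
      statistic = rep(stat_cols, each = nrow(st)),
      value = unlist(lapply(stat_cols, function(cn) as.numeric(st[[cn]]))),
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- long
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(population = character(), locus_id = character(),
               statistic = character(), value = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Genotype matrix (loci x samples) of allele lengths
#'
#' Wide table with one row per locus (ordered by locus coordinate) and one
#' column per sample (VCF sample order). Cells render the two allele lengths
#' as `"len1/len2"` preserving GT order (unphased rendering); missing calls
#' render `"./."`.
#'
#' @param calls Calls from [parse_tr_vcf()].
#' @return Data.frame with a `locus_id` column followed by one column per
#'   sample.
#' @export
genotype_matrix <- function(calls) {
  samples <- attr(calls, "samples")
  if (is.null(samples)) samples <- unique(calls$sample)
  key <- unique(calls[c("locus_id", "chrom", "pos")])
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  loci <- key$locus_id
  cell <- ifelse(calls$missing, "./.", paste0(calls$len1, "/", calls$len2))
  m <- matrix("./.", nrow = length(loci), ncol = length(samples),
              dimnames = list(loci, samples))
  m[cbind(match(calls$locus_id, loci), match(calls$sample, samples))] <- cell
  out <- data.frame(locus_id = loci, m, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  out
}
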