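#' Alignment scoring scheme for motif comparison
#'
#' Linear gap penalties. The defaults (+1 match, -1 mismatch, -2 gap) are the
#' simplest standard scheme; all three are configurable.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap Gap penalty per base (< 0).
#' @return An `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -1L, gap = -2L) {
  if (!(match > mismatch)) stop("require match > mismatch", call. = FALSE)
  if (!(gap < 0)) stop("require gap < 0", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

#' Needleman-Wunsch global alignment of two motifs
#'
#' Classic dynamic-programming global alignment with linear gap penalties.
#' Traceback ties are broken deterministically: diagonal, then up (gap in
#' `b`), then left (gap in `a`).
#'
#' @param a,b Non-empty motif strings over \{A,C,G,T,N\}.
#' @param scoring An [alignment_scoring()].
#' @return List with `score` (optimal global score), `aligned_a` and
#'   `aligned_b` (equal-length gapped strings; removing `-` recovers the
#'   inputs).
#' @export
needleman_wunsch <- function(a, b, scoring = alignment_scoring()) {
  a <- assert_motif(a, "a")
  b <- assert_motif(b, "b")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  # pointers: 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  P <- matrix(0L, n + 1L, m + 1L)
  S[1, ] <- scoring$gap * (0:m)
  S[, 1] <- scoring$gap * (0:n)
  P[1, -1] <- 3L
  P[-1, 1] <- 2L
  for (i in seq_len(n)) {
    sub <- ifelse(av[i] == bv, scoring$match, scoring$mismatch)
    for (j in seq_len(m)) {
      d <- S[i, j] + sub[j]
      u <- S[i, j + 1L] + scoring$gap
      l <- S[i + 1L, j] + scoring$gap
      if (d >= u && d >= l) {
        S[i + 1L, j + 1L] <- d
        P[i + 1L, j + 1L] <- 1L
      } else if (u >= l) {
        S[i + 1L, j + 1L] <- u
        P[i + 1L, j + 1L] <- 2L
      } else {
        S[i + 1L, j + 1L] <- l
        P[i + 1L, j + 1L] <- 3L
      }
    }
  }
  # traceback
  i <- n + 1L
  j <- m + 1L
  ra <- character(0)
  rb <- character(0)
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ra <- c(av[i - 1L], ra)
      rb <- c(bv[j - 1L], rb)
      i <- i - 1L
      j <- j - 1L
    } else if (p == 2L) {
      ra <- c(av[i - 1L], ra)
      rb <- c("-", rb)
      i <- i - 1L
    } else {
      ra <- c("-", ra)
      rb <- c(bv[j - 1L], rb)
      j <- j - 1L
    }
  }
  list(score = S[n + 1L, m + 1L],
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Percent similarity between two motifs
#'
#' Percent identity of the global alignment: `100 * matched columns /
#' alignment length`, where gap columns count toward the denominator. In
#' `best_rotation_revcomp` mode the maximum plain identity over all cyclic
#' rotations of `b` and of `b`'s reverse complement is returned, which makes
#' the comparison insensitive to the arbitrary phase and strand of a reported
#' motif. Plain mode (motifs compared as reported) is the default.
#'
#' @param a,b Motif strings.
#' @param scoring An [alignment_scoring()].
#' @param mode `"plain"` or `"best_rotation_revcomp"`.
#' @return Percent similarity in \[0, 100\].
#' @export
motif_similarity <- function(a, b, scoring = alignment_scoring(),
                             mode = c("plain", "best_rotation_revcomp")) {
  mode <- match.arg(mode)
  a <- assert_motif(a, "a")
  b <- assert_motif(b, "b")
  plain <- function(x, y) {
    al <- needleman_wunsch(x, y, scoring)
    ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    100 * sum(ca == cb & ca != "-") / length(ca)
  }
  if (mode == "plain") return(plain(a, b))
  max(vapply(c(rotations(b), rotations(revcomp(b))), function(bb) plain(a, bb),
             numeric(1)))
}

#' Intersect lifted intervals with a catalog at an overlap threshold
#'
#' For every lifted interval, emits each catalog record on the same
#' chromosome whose half-open span overlaps it by at least
#' `min_overlap * lifted length` (overlap fraction is measured relative to
#' the lifted interval, like `bedtools intersect -f` on the lifted file).
#' With `reciprocal = TRUE` the fraction relative to the catalog record must
#' also reach the threshold. One lifted interval may pair with several
#' catalog records.
#'
#' @param lifted `lifted` data.frame from [lift_catalog()].
#' @param query_catalog A `tr_catalog` on the lifted intervals' assembly.
#' @param min_overlap Overlap threshold in (0, 1].
#' @param reciprocal Additionally require the fraction relative to the
#'   catalog record (default `FALSE`).
#' @return Data.frame: `source_id`, lifted coordinates, matched record's
#'   `query_id` and coordinates/motif, `overlap_fraction`.
#' @export
intersect_with_overlap <- function(lifted, query_catalog, min_overlap,
                                   reciprocal = FALSE) {
  if (!(is.numeric(min_overlap) && length(min_overlap) == 1L &&
        min_overlap > 0 && min_overlap <= 1)) {
    stop("min_overlap must be in (0, 1]", call. = FALSE)
  }
  empty <- data.frame(source_id = character(), q_chrom = character(),
                      q_start = integer(), q_end = integer(),
                      query_id = character(), query_start = integer(),
                      query_end = integer(), query_motif = character(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE)
  if (!nrow(lifted) || !nrow(query_catalog)) return(empty)
  out <- list()
  for (chr in intersect(unique(lifted$q_chrom), unique(query_catalog$chrom))) {
    li <- which(lifted$q_chrom == chr)
    ci <- which(query_catalog$chrom == chr)
    # IRanges is 1-based inclusive; half-open [s, e) -> [s + 1, e]
    fo <- IRanges::findOverlaps(
      IRanges::IRanges(lifted$q_start[li] + 1L, lifted$q_end[li]),
      IRanges::IRanges(query_catalog$start[ci] + 1L, query_catalog$end[ci]))
    if (!length(fo)) next
    i <- li[S4Vectors::queryHits(fo)]
    j <- ci[S4Vectors::subjectHits(fo)]
    ov <- pmin(lifted$q_end[i], query_catalog$end[j]) -
      pmax(lifted$q_start[i], query_catalog$start[j])
    frac <- ov / (lifted$q_end[i] - lifted$q_start[i])
    keep <- frac >= min_overlap
    if (reciprocal) {
      frac_rec <- ov / (query_catalog$end[j] - query_catalog$start[j])
      keep <- keep & frac_rec >= min_overlap
    }
    if (!any(keep)) next
    i <- i[keep]
    j <- j[keep]
    out[[length(out) + 1L]] <- data.frame(
      source_id = lifted$source_id[i],
      q_chrom = lifted$q_chrom[i], q_start = lifted$q_start[i],
      q_end = lifted$q_end[i],
      query_id = locus_id(query_catalog$chrom[j], query_catalog$start[j],
                          query_catalog$end[j]),
      query_start = query_catalog$start[j], query_end = query_catalog$end[j],
      query_motif = query_catalog$motif[j],
      overlap_fraction = frac[keep], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# One direction of the homology search: lift catalog_x onto catalog_y's
# assembly, intersect with catalog_y, gate on motif similarity. Returns
# (x_id, y_id, overlap, similarity).
directional_candidates <- function(catalog_x, catalog_y, chain_xy,
                                   min_overlap, min_similarity, min_match,
                                   scoring, mode) {
  lifted <- lift_catalog(catalog_x, chain_xy, min_match = min_match)$lifted
  hits <- intersect_with_overlap(lifted, catalog_y, min_overlap)
  if (!nrow(hits)) {
    return(data.frame(x_id = character(), y_id = character(),
                      overlap = numeric(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  x_motif <- setNames(catalog_x$motif,
                      locus_id(catalog_x$chrom, catalog_x$start, catalog_x$end))
  sim <- mapply(function(xid, ym) {
    motif_similarity(x_motif[[xid]], ym, scoring, mode)
  }, hits$source_id, hits$query_motif)
  keep <- sim >= min_similarity
  data.frame(x_id = hits$source_id[keep], y_id = hits$query_id[keep],
             overlap = hits$overlap_fraction[keep], similarity = sim[keep],
             stringsAsFactors = FALSE)
}

#' Identify putatively homologous TR pairs between two assemblies
#'
#' Runs the liftover-based homology search bidirectionally: catalog A is
#' lifted onto assembly B and intersected with catalog B at the overlap
#' threshold, candidate pairs are gated on motif percent similarity, the same
#' is done from B to A, and the final set of putatively homologous TRs
#' (phTRs) is the intersection of the two directional sets, matched on the
#' (locus A, locus B) identity. Each retained pair carries both directional
#' overlap fractions and the motif similarity.
#'
#' @param catalog_a,catalog_b Filtered `tr_catalog`s for the two assemblies.
#' @param chain_ab Chains with assembly A as target, B as query.
#' @param chain_ba Chains with assembly B as target, A as query.
#' @param min_overlap Overlap threshold in (0, 1] (default 0.10).
#' @param min_similarity Motif percent-similarity threshold (default 95).
#' @param scoring An [alignment_scoring()].
#' @param mode Similarity mode, see [motif_similarity()].
#' @param min_match Liftover mapped-fraction threshold (default 0.95).
#' @param best_hit Collapse multiple matches of one A locus to the highest
#'   similarity (ties: larger overlap, then smaller B start). Default `FALSE`.
#' @return Data.frame sorted by (`chrom_a`, `start_a`) with columns
#'   `chrom_a, start_a, end_a, motif_a, motif_len_a, tr_len_a,
#'   chrom_b, start_b, end_b, motif_b, motif_len_b, tr_len_b,
#'   overlap_ab, overlap_ba, similarity, gc_a, gc_b, locus_a, locus_b`.
#' @export
reciprocal_homologs <- function(catalog_a, catalog_b, chain_ab, chain_ba,
                                min_overlap = 0.10, min_similarity = 95,
                                scoring = alignment_scoring(),
                                mode = c("plain", "best_rotation_revcomp"),
                                min_match = 0.95, best_hit = FALSE) {
  mode <- match.arg(mode)
  ab_t <- vapply(chain_ab, `[[`, character(1), "t_name")
  ab_q <- vapply(chain_ab, `[[`, character(1), "q_name")
  ba_t <- vapply(chain_ba, `[[`, character(1), "t_name")
  ba_q <- vapply(chain_ba, `[[`, character(1), "q_name")
  if (!length(intersect(catalog_a$chrom, ab_t)) ||
      !length(intersect(catalog_b$chrom, ab_q)) ||
      !length(intersect(catalog_b$chrom, ba_t)) ||
      !length(intersect(catalog_a$chrom, ba_q))) {
    stop("chain and catalog assemblies are inconsistent: no shared sequence names",
         call. = FALSE)
  }
  ab <- directional_candidates(catalog_a, catalog_b, chain_ab,
                               min_overlap, min_similarity, min_match,
                               scoring, mode)
  ba <- directional_candidates(catalog_b, catalog_a, chain_ba,
                               min_overlap, min_similarity, min_match,
                               scoring, mode)
  pairs <- merge(ab, ba,
                 by.x = c("x_id", "y_id"), by.y = c("y_id", "x_id"),
                 suffixes = c("_ab", "_ba"))
  cols <- c("chrom_a", "start_a", "end_a", "motif_a", "motif_len_a",
            "tr_len_a", "chrom_b", "start_b", "end_b", "motif_b",
            "motif_len_b", "tr_len_b", "overlap_ab", "overlap_ba",
            "similarity", "gc_a", "gc_b", "locus_a", "locus_b")
  if (!nrow(pairs)) {
    out <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), motif_a = character(),
                      motif_len_a = integer(), tr_len_a = integer(),
                      chrom_b = character(), start_b = integer(),
                      end_b = integer(), motif_b = character(),
                      motif_len_b = integer(), tr_len_b = integer(),
                      overlap_ab = numeric(), overlap_ba = numeric(),
                      similarity = numeric(), gc_a = numeric(),
                      gc_b = numeric(), locus_a = character(),
                      locus_b = character(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  a_ids <- locus_id(catalog_a$chrom, catalog_a$start, catalog_a$end)
  b_ids <- locus_id(catalog_b$chrom, catalog_b$start, catalog_b$end)
  ia <- match(pairs$x_id, a_ids)
  ib <- match(pairs$y_id, b_ids)
  seq_a <- ifelse(is.na(catalog_a$sequence[ia]), catalog_a$motif[ia],
                  catalog_a$sequence[ia])
  seq_b <- ifelse(is.na(catalog_b$sequence[ib]), catalog_b$motif[ib],
                  catalog_b$sequence[ib])
  out <- data.frame(
    chrom_a = catalog_a$chrom[ia], start_a = catalog_a$start[ia],
    end_a = catalog_a$end[ia], motif_a = catalog_a$motif[ia],
    motif_len_a = nchar(catalog_a$motif[ia]),
    tr_len_a = catalog_a$end[ia] - catalog_a$start[ia],
    chrom_b = catalog_b$chrom[ib], start_b = catalog_b$start[ib],
    end_b = catalog_b$end[ib], motif_b = catalog_b$motif[ib],
    motif_len_b = nchar(catalog_b$motif[ib]),
    tr_len_b = catalog_b$end[ib] - catalog_b$start[ib],
    overlap_ab = pairs$overlap_ab, overlap_ba = pairs$overlap_ba,
    similarity = pairs$similarity_ab,
    gc_a = round(gc_fraction(seq_a), 4), gc_b = round(gc_fraction(seq_b), 4),
    locus_a = pairs$x_id, locus_b = pairs$y_id,
    stringsAsFactors = FALSE)
  if (best_hit && nrow(out)) {
    ord <- order(out$locus_a, -out$similarity, -out$overlap_ab, out$start_b)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$locus_a), , drop = FALSE]
  }
  out <- out[order(out$chrom_a, out$start_a, out$start_b), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total-length table for shared TR pairs
#'
#' One row per homologous pair with the total array length of each member —
#' the data behind a scatterplot of shared-TR lengths between two assemblies.
#'
#' @param pairs Output of [reciprocal_homologs()].
#' @return Data.frame `locus_a, length_a, locus_b, length_b` (order
#'   preserved).
#' @export
shared_length_table <- function(pairs) {
  data.frame(locus_a = pairs$locus_a, length_a = pairs$tr_len_a,
             locus_b = pairs$locus_b, length_b = pairs$tr_len_b,
             stringsAsFactors = FALSE)
}

#' Write a phTR pair table as TSV
#'
#' Fixed column order: `chrom_a, start_a, end_a, motif_a, motif_len_a,
#' tr_len_a, chrom_b, start_b, end_b, motif_b, motif_len_b, tr_len_b,
#' overlap_ab, overlap_ba, similarity, gc_a, gc_b`.
#'
#' @param pairs Output of [reciprocal_homologs()].
#' @param path Output path.
#' @param header Write a `#`-prefixed header line (default `TRUE`).
#' @return The path, invisibly.
#' @export
write_homolog_table <- function(pairs, path, header = TRUE) {
  cols <- c("chrom_a", "start_a", "end_a", "motif_a", "motif_len_a",
            "tr_len_a", "chrom_b", "start_b", "end_b", "motif_b",
            "motif_len_b", "tr_len_b", "overlap_ab", "overlap_ba",
            "similarity", "gc_a", "gc_b")
  tab <- pairs[cols]
  lines <- do.call(sprintf, c(
    list(paste(rep("%s", length(cols)), collapse = "\t")),
    lapply(tab, function(col) {
      if (is.numeric(col)) vapply(col, format, character(1), digits = 6)
      else as.character(col)
    })))
  if (header) lines <- c(paste0("#", paste(cols, collapse = "\t")), lines)
  writeLines(lines, path)
  invisible(path)
}
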