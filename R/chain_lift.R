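#' Parse a UCSC chain file
#'
#' A chain describes one pairwise alignment between a *target* and a *query*
#' assembly as an ordered list of ungapped blocks. Each header line is
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id`;
#' block lines are `size dt dq` (gap on target, gap on query) with a final
#' bare `size`. Target strand must be `+`; query coordinates are in the
#' strand-local frame when `qStrand` is `-`.
#'
#' Chains are validated eagerly: block sizes and gaps must sum exactly to the
#' header spans on both sides, otherwise parsing aborts naming the chain id.
#' Gzipped files are handled transparently.
#'
#' @param path Path to a `.chain` file (optionally gzipped), or a character
#'   vector of lines.
#' @return A `chain_set`: a list of chains, each a list with the header
#'   fields and a `blocks` data.frame (`size`, `dt`, `dq`, plus precomputed
#'   block offsets `t_off`, `q_off`).
#' @export
parse_chain <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path)  # file() auto-detects gzip
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  chains <- list()
  header <- NULL
  blocks <- NULL
  n_blocks <- 0L
  finish <- function(header, blocks, n_blocks) {
    if (is.null(header)) return(NULL)
    if (n_blocks == 0L) {
      stop("chain ", header$chain_id, ": no alignment blocks", call. = FALSE)
    }
    b <- do.call(rbind, blocks[seq_len(n_blocks)])
    b <- as.data.frame(b)
    names(b) <- c("size", "dt", "dq")
    validate_chain(c(header, list(blocks = b)))
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "chain") {
      ch <- finish(header, blocks, n_blocks)
      if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
      if (length(tok) != 13L) {
        stop(sprintf("line %d: chain header must have 13 fields", i),
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(tok[c(2, 4, 6, 7, 9, 11, 12, 13)]))
      if (anyNA(num)) {
        stop(sprintf("line %d: non-numeric chain header field", i),
             call. = FALSE)
      }
      if (any(num < 0)) {
        stop(sprintf("line %d: negative chain header field", i), call. = FALSE)
      }
      if (tok[5] != "+") {
        stop(sprintf("line %d: target strand must be '+'", i), call. = FALSE)
      }
      if (!tok[10] %in% c("+", "-")) {
        stop(sprintf("line %d: query strand must be '+' or '-'", i),
             call. = FALSE)
      }
      header <- list(score = num[1], t_name = tok[3], t_size = num[2],
                     t_strand = "+", t_start = num[3], t_end = num[4],
                     q_name = tok[8], q_size = num[4 + 1], q_strand = tok[10],
                     q_start = num[6], q_end = num[7], chain_id = num[8])
      blocks <- vector("list", 64L)
      n_blocks <- 0L
    } else {
      if (is.null(header)) {
        stop(sprintf("line %d: block line before any chain header", i),
             call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals) || !length(vals) %in% c(1L, 3L)) {
        stop(sprintf("line %d: malformed block line", i), call. = FALSE)
      }
      if (any(vals < 0)) {
        stop(sprintf("line %d: negative block field", i), call. = FALSE)
      }
      if (length(vals) == 1L) vals <- c(vals, 0, 0)
      n_blocks <- n_blocks + 1L
      if (n_blocks > length(blocks)) blocks <- c(blocks, vector("list", length(blocks)))
      blocks[[n_blocks]] <- vals
    }
  }
  ch <- finish(header, blocks, n_blocks)
  if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
  new_chain_set(chains)
}

new_chain_set <- function(chains) {
  structure(chains, class = "chain_set")
}

validate_chain <- function(ch) {
  b <- ch$blocks
  if (any(b$size < 1)) {
    stop("chain ", ch$chain_id, ": block size < 1", call. = FALSE)
  }
  t_span <- sum(b$size) + sum(b$dt)
  q_span <- sum(b$size) + sum(b$dq)
  if (t_span != ch$t_end - ch$t_start) {
    stop("chain ", ch$chain_id, ": target block sums (", t_span,
         ") do not match header span (", ch$t_end - ch$t_start, ")",
         call. = FALSE)
  }
  if (q_span != ch$q_end - ch$q_start) {
    stop("chain ", ch$chain_id, ": query block sums (", q_span,
         ") do not match header span (", ch$q_end - ch$q_start, ")",
         call. = FALSE)
  }
  if (!(ch$t_start < ch$t_end && ch$q_start < ch$q_end)) {
    stop("chain ", ch$chain_id, ": empty span", call. = FALSE)
  }
  n <- nrow(b)
  b$t_off <- ch$t_start + cumsum(c(0, head(b$size + b$dt, -1L)))
  b$q_off <- ch$q_start + cumsum(c(0, head(b$size + b$dq, -1L)))
  ch$blocks <- b
  ch
}

#' Write a chain set to a UCSC chain file
#'
#' @param chains A `chain_set` from [parse_chain()] or the fixture generator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    hdr <- sprintf("chain %s %s %s + %s %s %s %s %s %s %s %s",
                   format(ch$score), ch$t_name, format(ch$t_size),
                   format(ch$t_start), format(ch$t_end),
                   ch$q_name, format(ch$q_size), ch$q_strand,
                   format(ch$q_start), format(ch$q_end), format(ch$chain_id))
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1L) {
      sprintf("%d\t%d\t%d", b$size[-n], b$dt[-n], b$dq[-n])
    } else character(0)
    out <- c(out, hdr, body, format(b$size[n]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Lift one interval between assemblies through chains
#'
#' Maps a 0-based half-open interval on the chains' target assembly into
#' query coordinates through the single best-scoring chain that overlaps it
#' (no multi-chain stitching, mirroring `liftOver` semantics). Bases inside
#' aligned blocks are mapped; the emitted query span bridges from the first
#' to the last mapped base. A result is emitted only when the fraction of
#' source bases inside aligned blocks is at least `min_match`; otherwise the
#' interval is reported unmapped with a reason: `no_chain` (no chain touches
#' it), `partially_deleted` (only one chain touches it but too few bases
#' align) or `split_across_chains` (several chains touch it and the best one
#' alone aligns too few bases).
#'
#' Emitted query coordinates are always plus-strand 0-based half-open; for a
#' minus-strand chain each strand-local base `p` maps to plus-strand
#' `q_size - p - 1` and the result carries `strand = "-"`.
#'
#' @param chains A `chain_set`.
#' @param chrom,start,end Source interval on the target assembly.
#' @param min_match Minimum mapped fraction of source bases (default 0.95,
#'   the conventional liftOver default).
#' @return One-row `data.frame`: `source_chrom, source_start, source_end,
#'   q_chrom, q_start, q_end, strand, mapped_fraction, chain_id, status`
#'   (`"mapped"` or the failure reason; query fields `NA` when unmapped).
#' @export
lift_interval <- function(chains, chrom, start, end, min_match = 0.95) {
  stopifnot(inherits(chains, "chain_set"), start < end,
            min_match > 0, min_match <= 1)
  row <- function(q_chrom = NA_character_, q_start = NA_integer_,
                  q_end = NA_integer_, strand = NA_character_,
                  frac = NA_real_, chain_id = NA_real_, status) {
    data.frame(source_chrom = chrom, source_start = as.integer(start),
               source_end = as.integer(end), q_chrom = q_chrom,
               q_start = q_start, q_end = q_end, strand = strand,
               mapped_fraction = frac, chain_id = chain_id, status = status,
               stringsAsFactors = FALSE)
  }
  cand <- Filter(function(ch) ch$t_name == chrom && ch$t_start < end &&
                   ch$t_end > start, chains)
  if (!length(cand)) return(row(status = "no_chain"))
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ids <- vapply(cand, `[[`, numeric(1), "chain_id")
  best <- cand[[order(-scores, ids)[1]]]
  b <- best$blocks
  ov_start <- pmax(start, b$t_off)
  ov_end <- pmin(end, b$t_off + b$size)
  hit <- ov_start < ov_end
  mapped <- sum(pmax(0, ov_end - ov_start))
  frac <- mapped / (end - start)
  if (mapped == 0 || frac < min_match) {
    reason <- if (length(cand) > 1L) "split_across_chains" else "partially_deleted"
    return(row(frac = frac, chain_id = best$chain_id, status = reason))
  }
  q_lo <- min(b$q_off[hit] + (ov_start[hit] - b$t_off[hit]))
  q_hi <- max(b$q_off[hit] + (ov_end[hit] - b$t_off[hit]))
  if (best$q_strand == "-") {
    # strand-local [q_lo, q_hi) -> plus-strand per-base flip p' = size - p - 1
    plus_lo <- best$q_size - q_hi
    plus_hi <- best$q_size - q_lo
    row(best$q_name, as.integer(plus_lo), as.integer(plus_hi), "-",
        frac, best$chain_id, "mapped")
  } else {
    row(best$q_name, as.integer(q_lo), as.integer(q_hi), "+",
        frac, best$chain_id, "mapped")
  }
}

#' Lift a whole catalog between assemblies
#'
#' Order-preserving application of [lift_interval()] to every record of a
#' catalog. Returns the mapped intervals together with a per-record unmapped
#' report and per-reason counts.
#'
#' @param catalog A `tr_catalog` on the chains' target assembly.
#' @param chains A `chain_set`.
#' @param min_match Minimum mapped fraction (see [lift_interval()]).
#' @return List with elements `lifted` (data.frame of mapped intervals with a
#'   `source_id` column), `unmapped` (data.frame `source_id`, `reason`) and
#'   `report` (named counts per failure reason).
#' @export
lift_catalog <- function(catalog, chains, min_match = 0.95) {
  n <- nrow(catalog)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- lift_interval(chains, catalog$chrom[i], catalog$start[i],
                               catalog$end[i], min_match = min_match)
  }
  all_rows <- if (n) do.call(rbind, rows) else
    lift_interval(parse_chain("chain 1 c 2 + 0 1 c 2 + 0 1 1\n1"),
                  "c", 0, 1)[0, ]
  all_rows$source_id <- locus_id(all_rows$source_chrom, all_rows$source_start,
                                 all_rows$source_end)
  ok <- all_rows$status == "mapped"
  lifted <- all_rows[ok, c("source_id", "source_chrom", "source_start",
                           "source_end", "q_chrom", "q_start", "q_end",
                           "strand", "mapped_fraction", "chain_id")]
  unmapped <- data.frame(source_id = all_rows$source_id[!ok],
                         reason = all_rows$status[!ok],
                         stringsAsFactors = FALSE)
  rownames(lifted) <- rownames(unmapped) <- NULL
  report <- c(no_chain = sum(unmapped$reason == "no_chain"),
              partially_deleted = sum(unmapped$reason == "partially_deleted"),
              split_across_chains = sum(unmapped$reason == "split_across_chains"))
  list(lifted = lifted, unmapped = unmapped, report = report)
}

#' Write lifted intervals as BED
#'
#' Columns: query chrom, start, end, source locus id, mapped fraction, strand.
#'
#' @param lifted The `lifted` data.frame from [lift_catalog()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_lifted_bed <- function(lifted, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   lifted$q_chrom, lifted$q_start, lifted$q_end,
                   lifted$source_id,
                   vapply(lifted$mapped_fraction, format, character(1), digits = 6),
                   lifted$strand)
  writeLines(lines, path)
  invisible(path)
}
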