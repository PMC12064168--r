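#' Construct a tandem-repeat catalog
#'
#' A catalog is a plain `data.frame` with one row per TR locus and a fixed
#' set of columns. Coordinates are 0-based half-open (BED convention); the
#' total array length of a record is `end - start`.
#'
#' @param chrom Sequence name.
#' @param start,end 0-based half-open span of the repeat array.
#' @param motif Consensus motif over \{A,C,G,T,N\}.
#' @param copy_number Number of motif repetitions (may be fractional, >= 0).
#' @param period_size Period size in bp; defaults to the motif length.
#' @param consensus_size Consensus length in bp; defaults to the motif length.
#' @param percent_matches,percent_indels TRF alignment percentages (0-100),
#'   `NA` when unknown.
#' @param alignment_score TRF alignment score (>= 0).
#' @param sequence Optional full repeat-array sequence (`NA` when unknown).
#' @return A `data.frame` with class `tr_catalog`.
#' @export
tr_catalog <- function(chrom, start, end, motif, copy_number,
                       period_size = nchar(motif),
                       consensus_size = nchar(motif),
                       percent_matches = NA_real_,
                       percent_indels = NA_real_,
                       alignment_score = 0L,
                       sequence = NA_character_) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    period_size = as.integer(period_size),
    copy_number = as.numeric(copy_number),
    consensus_size = as.integer(consensus_size),
    percent_matches = as.numeric(percent_matches),
    percent_indels = as.numeric(percent_indels),
    alignment_score = as.numeric(alignment_score),
    motif = toupper(as.character(motif)),
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  validate_catalog(x)
}

catalog_columns <- c("chrom", "start", "end", "period_size", "copy_number",
                     "consensus_size", "percent_matches", "percent_indels",
                     "alignment_score", "motif", "sequence")

#' Validate a tandem-repeat catalog
#'
#' Checks the structural invariants of a catalog: `start < end`, motifs over
#' \{A,C,G,T,N\}, non-negative copy numbers and scores, and motif length equal
#' to `consensus_size` where both are present.
#'
#' @param x A catalog `data.frame`.
#' @return `x`, invisibly classed as `tr_catalog`.
#' @export
validate_catalog <- function(x) {
  missing_cols <- setdiff(catalog_columns, names(x))
  if (length(missing_cols)) {
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x)) {
    if (any(x$start >= x$end)) {
      stop("catalog has records with start >= end", call. = FALSE)
    }
    if (any(grepl("[^ACGTN]", x$motif))) {
      stop("catalog motifs must be over {A,C,G,T,N}", call. = FALSE)
    }
    if (any(x$copy_number < 0, na.rm = TRUE)) {
      stop("copy_number must be >= 0", call. = FALSE)
    }
    if (any(x$alignment_score < 0, na.rm = TRUE)) {
      stop("alignment_score must be >= 0", call. = FALSE)
    }
    bad <- !is.na(x$consensus_size) & nchar(x$motif) != x$consensus_size
    if (any(bad)) {
      stop("motif length must equal consensus_size (record ",
           which(bad)[1], ")", call. = FALSE)
    }
  }
  class(x) <- unique(c("tr_catalog", class(x)))
  x
}

empty_catalog <- function() {
  tr_catalog(character(), integer(), integer(), character(), numeric(),
             integer(), integer(), numeric(), numeric(), numeric(),
             character())
}

#' Default TRF run parameters
#'
#' Metadata describing the Tandem Repeat Finder invocation whose output the
#' catalog module expects: match/mismatch/indel weights, matching and indel
#' probabilities, minimum alignment score and maximum period size. These are
#' provenance only — TR detection itself is out of scope.
#'
#' @return Named list of TRF parameters.
#' @export
trf_defaults <- function() {
  list(match = 2L, mismatch = 5L, indel = 7L,
       match_probability = 80L, indel_probability = 10L,
       min_alignment_score = 24L, max_period_size = 2000L)
}

#' Minimum admissible repeat length under TRF scoring defaults
#'
#' A perfect repeat array scores `match * length`, so the shortest array that
#' can reach the minimum alignment score has
#' `ceiling(min_alignment_score / match)` bases. With the default match weight
#' 2 and minimum score 24 this bound is 12 bp.
#'
#' @param match Match weight (default 2).
#' @param min_alignment_score Minimum reported alignment score (default 24).
#' @return Minimum total length in bp (integer).
#' @export
trf_min_length <- function(match = trf_defaults()$match,
                           min_alignment_score = trf_defaults()$min_alignment_score) {
  stopifnot(match > 0, min_alignment_score > 0)
  as.integer(ceiling(min_alignment_score / match))
}

#' Parse Tandem Repeat Finder tabular output
#'
#' Reads TRF "Data file" (`-d`) output, where loci are grouped under
#' `Sequence: <name>` headers, or the `-ngs` dialect with `@<name>` headers.
#' The dialect is auto-detected. TRF rows carry 1-based inclusive coordinates;
#' they are converted to 0-based half-open at ingest (this is the only place
#' conversion happens).
#'
#' Rows whose period size exceeds `max_period` are kept but marked in the
#' `flagged` column (with a warning), since they fall outside the default TRF
#' parameter space.
#'
#' @param path Path to a TRF output file, or a character vector of lines.
#' @param chrom_resolver Optional named character vector or function mapping
#'   header sequence names to chromosome names (default: identity, first
#'   whitespace-delimited token of the header).
#' @param max_period Period-size flag threshold (default 2000).
#' @return A `tr_catalog` data.frame with an extra logical `flagged` column.
#' @export
parse_trf_dat <- function(path, chrom_resolver = NULL, max_period = 2000L) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  resolve <- function(nm) {
    if (is.null(chrom_resolver)) return(nm)
    if (is.function(chrom_resolver)) return(chrom_resolver(nm))
    out <- unname(chrom_resolver[nm])
    if (is.na(out)) nm else out
  }
  chrom <- NA_character_
  rows <- vector("list", length(lines))
  n_rows <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    first <- substr(line, 1L, 1L)
    if (startsWith(line, "Sequence:")) {
      nm <- trimws(sub("^Sequence:", "", line))
      chrom <- resolve(strsplit(nm, "\\s+")[[1]][1])
      next
    }
    if (first == "@") {
      chrom <- resolve(strsplit(substring(line, 2L), "\\s+")[[1]][1])
      next
    }
    if (!grepl("^[0-9]", line)) next  # preamble / parameter lines
    if (is.na(chrom)) {
      stop(sprintf(
        "line %d: data row before any 'Sequence:' or '@' header (unknown dialect)",
        i), call. = FALSE)
    }
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 15L) {
      stop(sprintf("line %d: expected >= 15 columns, got %d", i, length(tok)),
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(tok[1:13]))
    if (anyNA(num)) {
      stop(sprintf("line %d: non-numeric value in numeric field %d",
                   i, which(is.na(num))[1]), call. = FALSE)
    }
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- list(chrom = chrom, start = num[1] - 1, end = num[2],
                           period_size = num[3], copy_number = num[4],
                           consensus_size = num[5], percent_matches = num[6],
                           percent_indels = num[7], alignment_score = num[8],
                           motif = toupper(tok[14]), sequence = toupper(tok[15]))
  }
  if (n_rows == 0L) {
    out <- empty_catalog()
    out$flagged <- logical(0)
    return(out)
  }
  rows <- rows[seq_len(n_rows)]
  get <- function(f) vapply(rows, `[[`, rows[[1]][[f]], f)
  out <- tr_catalog(
    chrom = get("chrom"), start = get("start"), end = get("end"),
    motif = get("motif"), copy_number = get("copy_number"),
    period_size = get("period_size"), consensus_size = get("consensus_size"),
    percent_matches = get("percent_matches"),
    percent_indels = get("percent_indels"),
    alignment_score = get("alignment_score"), sequence = get("sequence")
  )
  out$flagged <- out$period_size > max_period
  if (any(out$flagged)) {
    warning(sum(out$flagged), " record(s) exceed the maximum period size of ",
            max_period, " and were flagged", call. = FALSE)
  }
  out
}

#' Merge overlapping catalog records
#'
#' TRF can report several overlapping arrays at the same genomic index. Any
#' two same-chromosome records whose half-open spans overlap by at least 1 bp
#' (`start2 < end1`; abutting records are *not* merged) are replaced by one
#' record spanning their union. Representative attributes (motif, scores,
#' copy number) are taken from the member with the highest alignment score,
#' tie-broken by smaller start, then lexicographically smallest motif. The
#' `sequence` of a multi-member merge is set to `NA` (the union is no longer
#' the representative's array).
#'
#' @param records A `tr_catalog` data.frame.
#' @return A sorted, non-overlapping `tr_catalog`.
#' @export
merge_overlapping <- function(records) {
  records <- validate_catalog(as.data.frame(records)[catalog_columns])
  if (!nrow(records)) return(records)
  ord <- order(records$chrom, records$start, records$end)
  records <- records[ord, , drop = FALSE]
  out <- vector("list", nrow(records))
  n_out <- 0L
  cluster <- integer(0)
  cur_chrom <- ""
  cur_end <- -Inf
  flush <- function(cluster) {
    members <- records[cluster, , drop = FALSE]
    rep_ord <- order(-members$alignment_score, members$start, members$motif)
    rep_row <- members[rep_ord[1], , drop = FALSE]
    rep_row$start <- min(members$start)
    rep_row$end <- max(members$end)
    if (nrow(members) > 1L) rep_row$sequence <- NA_character_
    rep_row
  }
  for (i in seq_len(nrow(records))) {
    if (length(cluster) && records$chrom[i] == cur_chrom &&
        records$start[i] < cur_end) {
      cluster <- c(cluster, i)
      cur_end <- max(cur_end, records$end[i])
    } else {
      if (length(cluster)) {
        n_out <- n_out + 1L
        out[[n_out]] <- flush(cluster)
      }
      cluster <- i
      cur_chrom <- records$chrom[i]
      cur_end <- records$end[i]
    }
  }
  n_out <- n_out + 1L
  out[[n_out]] <- flush(cluster)
  res <- do.call(rbind, out[seq_len(n_out)])
  rownames(res) <- NULL
  validate_catalog(res)
}

#' Catalog filter policy
#'
#' Defaults mirror the catalog-cleaning step: records longer than 10 kbp or
#' with fewer than 2.5 motif copies are removed. Both bounds are read as
#' strict exclusions, so a record of exactly 10000 bp or exactly 2.5 copies
#' is retained. `min_total_length` is an informational floor (the analytic
#' minimum under default TRF scoring is 12 bp, see [trf_min_length()]); it
#' defaults to 0 so nothing is removed by it.
#'
#' @param max_total_length Maximum total array length kept, bp.
#' @param min_copy_number Minimum copy number kept.
#' @param min_total_length Minimum total array length kept, bp.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(max_total_length = 10000L, min_copy_number = 2.5,
                          min_total_length = 0L) {
  if (!(max_total_length > min_total_length && min_total_length >= 0)) {
    stop("require max_total_length > min_total_length >= 0", call. = FALSE)
  }
  structure(list(max_total_length = max_total_length,
                 min_copy_number = min_copy_number,
                 min_total_length = min_total_length),
            class = "filter_policy")
}

#' Filter a catalog by length and copy number
#'
#' Retains exactly the records with total length `<= max_total_length`,
#' total length `>= min_total_length`, and `copy_number >= min_copy_number`.
#' Order is preserved. The filter is idempotent.
#'
#' @param records A `tr_catalog`.
#' @param policy A [filter_policy()].
#' @return The filtered `tr_catalog`.
#' @export
filter_catalog <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (!nrow(records)) return(records)
  len <- records$end - records$start
  keep <- len <= policy$max_total_length &
    len >= policy$min_total_length &
    records$copy_number >= policy$min_copy_number
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a catalog as BED+TSV
#'
#' The on-disk format is tab-separated with columns, in fixed order:
#' `chrom, start, end, motif, copy_number, alignment_score, sequence`
#' (a `.` encodes a missing sequence). Coordinates are 0-based half-open.
#' An optional `#`-prefixed header line is ignored on read. On read,
#' `period_size` and `consensus_size` are reconstructed from the motif and
#' the TRF alignment percentages are `NA`, so `read(write(x))` is the
#' identity on the BED-representable fields.
#'
#' @param path File path.
#' @param records A `tr_catalog`.
#' @param header Write a `#`-prefixed header line (default `FALSE`).
#' @return `read_catalog_bed`: a `tr_catalog`; `write_catalog_bed`: the path,
#'   invisibly.
#' @export
read_catalog_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- empty_catalog()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 6L)) {
    stop(sprintf("line %d: expected >= 6 tab-separated columns",
                 lineno[which(ncol < 6L)[1]]), call. = FALSE)
  }
  field <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else ".",
                              character(1))
  start <- suppressWarnings(as.integer(field(2)))
  end <- suppressWarnings(as.integer(field(3)))
  bad <- is.na(start) | is.na(end) |
    field(2) != as.character(start) | field(3) != as.character(end)
  if (any(bad)) {
    stop(sprintf("line %d: non-integer coordinates", lineno[which(bad)[1]]),
         call. = FALSE)
  }
  if (any(start >= end)) {
    stop(sprintf("line %d: start >= end", lineno[which(start >= end)[1]]),
         call. = FALSE)
  }
  copy_number <- suppressWarnings(as.numeric(field(5)))
  score <- suppressWarnings(as.numeric(field(6)))
  if (anyNA(copy_number) || anyNA(score)) {
    stop(sprintf("line %d: non-numeric copy number or score",
                 lineno[which(is.na(copy_number) | is.na(score))[1]]),
         call. = FALSE)
  }
  seqs <- field(7)
  seqs[seqs == "."] <- NA_character_
  tr_catalog(chrom = field(1), start = start, end = end, motif = field(4),
             copy_number = copy_number, alignment_score = score,
             sequence = seqs)
}

#' @rdname read_catalog_bed
#' @export
write_catalog_bed <- function(records, path, header = FALSE) {
  records <- validate_catalog(as.data.frame(records)[catalog_columns])
  seqs <- records$sequence
  seqs[is.na(seqs)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   records$chrom, records$start, records$end, records$motif,
                   vapply(records$copy_number, format, character(1), digits = 15),
                   vapply(records$alignment_score, format, character(1), digits = 15),
                   seqs)
  if (header) {
    lines <- c("#chrom\tstart\tend\tmotif\tcopy_number\talignment_score\tsequence",
               lines)
  }
  writeLines(lines, path)
  invisible(path)
}
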