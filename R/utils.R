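#' Build a locus identifier from coordinates
#'
#' Identifiers are `chrom_start_end` in 0-based half-open coordinates, the
#' convention used across catalogs, lifted intervals and homolog tables.
#'
#' @param chrom Sequence name(s).
#' @param start,end 0-based half-open coordinates.
#' @return Character vector of locus ids.
#' @export
locus_id <- function(chrom, start, end) {
  paste(chrom, start, end, sep = "_")
}

#' GC fraction of a sequence
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Numeric vector in \[0, 1\]; `NaN` for empty strings.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / n
}

# Reverse complement preserving N.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All cyclic rotations of a string (including the identity rotation).
rotations <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(x, k + 1L, n), substr(x, 1L, k))
  }, character(1))
}

assert_motif <- function(x, arg = "motif") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("'%s' must be a non-empty string", arg), call. = FALSE)
  }
  if (grepl("[^ACGTNacgtn]", x)) {
    stop(sprintf("'%s' contains characters outside {A,C,G,T,N}: %s", arg, x),
         call. = FALSE)
  }
  invisible(toupper(x))
}

# write.table with the conventions used for all TSV artifacts
write_tsv_plain <- function(x, path, col.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}
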