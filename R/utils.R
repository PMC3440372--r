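# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' that simulation functions are deterministic without clobbering the
#' session RNG.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stream seed below 2^31 from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h * 97 + 11) %% 2147483587)
}

#' Reverse-complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Sequences are stored internally as DNA (T); mature small-RNA sequences
#' are printed in the RNA alphabet (U) in reports.
#' @param x character vector.
#' @return character vector with T<->U swapped.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

#' Format a genomic location for human-readable reports
#'
#' Internal coordinates are 0-based half-open (BED convention); reports
#' print 1-based inclusive coordinates as `chrN:start-end (strand)`.
#'
#' @param chrom,start,end,strand location (start/end 0-based half-open).
#' @return character vector.
#' @export
#' @examples
#' format_location("chr17", 27455399, 27455700, "-")
format_location <- function(chrom, start, end, strand) {
  sprintf("%s:%d\u2013%d (%s)", chrom, start + 1L, end, strand)
}

# Normalize nucleotide sequences: uppercase, strip whitespace, U->T.
# Errors name the offending record and 1-based position of the first
# illegal character.  N is allowed only when allow_n = TRUE.
normalize_seq <- function(seqs, ids = NULL, allow_n = TRUE) {
  s <- chartr("Uu", "Tt", toupper(gsub("[[:space:]]", "", seqs)))
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGTN]"
  bad <- regexpr(pat, s)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    who <- if (!is.null(ids)) ids[i] else as.character(i)
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(s[i], bad[i], bad[i]), who, bad[i]), call. = FALSE)
  }
  if (!allow_n && any(grepl("N", s, fixed = TRUE))) {
    i <- which(grepl("N", s, fixed = TRUE))[1]
    who <- if (!is.null(ids)) ids[i] else as.character(i)
    stop(sprintf("ambiguous base N not allowed in record '%s'", who),
         call. = FALSE)
  }
  s
}

# Usage errors (missing files, invalid config) get their own condition
# class so callers can distinguish them from stage failures.
usage_error <- function(...) {
  stop(structure(class = c("sprfinder_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
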