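# Expression quantification: RPM normalization, cross-library
# enrichment ratios, 3' non-templated variant calling against the
# genomic context, length histograms, and in-silico poly(A)-tailed
# RT-PCR amplicon sizing.

#' Reads-per-million normalization
#'
#' `rpm = raw_count / library_total * 1e6`; the denominator is the total
#' read count of the library (all supplied rows for that library id).
#' RPM sums to one million within each library.
#'
#' @param counts counts data.frame (`sequence`, `library_id`,
#'   `raw_count`).
#' @return the input with an `rpm` column added.
#' @export
rpm_normalize <- function(counts) {
  counts <- validate_counts(counts)
  tot <- tapply(counts$raw_count, counts$library_id, sum)
  if (any(tot == 0))
    stop("library with zero total reads: ",
         paste(names(tot)[tot == 0], collapse = ", "), call. = FALSE)
  counts$rpm <- counts$raw_count / as.numeric(tot[counts$library_id]) * 1e6
  counts
}

#' Cross-library enrichment ratio
#'
#' Ratio of two RPM values (e.g. sperm/testis), with a formatted label
#' at 2 significant figures; a zero denominator is flagged `"inf"`, and
#' zero over zero `"undefined"`.
#'
#' @param rpm_num,rpm_den non-negative RPM values.
#' @param sig significant figures for the label.
#' @return a list with `value` (numeric; `Inf`/`NaN` in the degenerate
#'   cases) and `label` (character).
#' @export
#' @examples
#' enrichment_ratio(59.9, 0.4)$label   # "150"
#' enrichment_ratio(35.9, 69.2)$label  # "0.52"
enrichment_ratio <- function(rpm_num, rpm_den, sig = 2) {
  stopifnot(rpm_num >= 0, rpm_den >= 0)
  value <- rpm_num / rpm_den
  list(value = value, label = format_ratio(value, sig = sig))
}

#' Format a ratio for reporting
#'
#' @param x numeric ratio.
#' @param sig significant figures (default 2).
#' @param decimals if given, round to this many decimal places instead.
#' @return character: the formatted ratio, `"inf"` for an infinite
#'   ratio, `"undefined"` for 0/0.
#' @export
format_ratio <- function(x, sig = 2, decimals = NULL) {
  if (is.nan(x)) return("undefined")
  if (is.infinite(x)) return("inf")
  v <- if (is.null(decimals)) signif(x, sig) else round(x, decimals)
  format(v, scientific = FALSE, trim = TRUE)
}

#' Call 3' variants of reads sharing a canonical 5' start
#'
#' Each read is split into its maximal genome-matching (templated)
#' prefix and the remaining non-templated 3' suffix, relative to the
#' genomic context beginning at the shared 5' position.
#'
#' @param reads_at_locus data.frame with a `sequence` column and
#'   optionally `library_id`/`raw_count` (counts are spread into one
#'   column per library in the output).
#' @param genome_context genomic sequence starting at the canonical 5'
#'   position and extending at least to the longest read.
#' @return a data.frame with `sequence`, `templated_len`,
#'   `nontemplated_suffix`, and one count column per library, sorted by
#'   (templated_len desc, suffix).
#' @export
call_3prime_variants <- function(reads_at_locus, genome_context) {
  genome_context <- normalize_seq(genome_context)
  seqs <- unique(normalize_seq(reads_at_locus$sequence))
  if (any(nchar(seqs) > nchar(genome_context)))
    stop("genome context shorter than the longest read", call. = FALSE)
  ctx <- strsplit(genome_context, "")[[1]]
  tlen <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    cmp <- b == ctx[seq_along(b)]
    if (!cmp[1])
      stop("read mismatches the genomic context at position 1 ",
           "(not a 5'-anchored variant): ", s, call. = FALSE)
    if (all(cmp)) length(b) else which(!cmp)[1] - 1L
  }, integer(1))
  suffix <- substring(seqs, tlen + 1L)
  stopifnot(paste0(substring(seqs, 1L, tlen), suffix) == seqs)
  out <- data.frame(sequence = seqs, templated_len = unname(tlen),
                    nontemplated_suffix = unname(suffix),
                    stringsAsFactors = FALSE)
  if (!is.null(reads_at_locus$library_id) &&
      !is.null(reads_at_locus$raw_count)) {
    for (lib in unique(reads_at_locus$library_id)) {
      sub <- reads_at_locus[reads_at_locus$library_id == lib, ]
      cnt <- setNames(sub$raw_count, normalize_seq(sub$sequence))
      out[[paste0("count_", lib)]] <-
        ifelse(is.na(cnt[out$sequence]), 0, cnt[out$sequence])
    }
  } else if (!is.null(reads_at_locus$raw_count)) {
    cnt <- setNames(reads_at_locus$raw_count,
                    normalize_seq(reads_at_locus$sequence))
    out$count <- as.numeric(cnt[out$sequence])
  }
  out <- out[order(-out$templated_len, out$nontemplated_suffix), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length histogram
#'
#' @param counts counts data.frame (`sequence`, `raw_count`).
#' @return data.frame with `length` and total `count`, sorted by length;
#'   counts sum to the library size.
#' @export
length_histogram <- function(counts) {
  if (!nrow(counts)) return(data.frame(length = integer(0),
                                       count = numeric(0)))
  agg <- rowsum(counts$raw_count, nchar(counts$sequence))
  data.frame(length = as.integer(rownames(agg)), count = as.numeric(agg[, 1]))
}

#' The poly(A)-tailed RT-PCR RT primer
#'
#' Anchored oligo-dT RT primer used for small-RNA poly(A)-tailed RT-PCR:
#' a 73 nt universal head, a run of 25 T, and a degenerate VN anchor.
#' @export
RTQ_PRIMER <- paste0(
  "CGAATTCTAGAGCTCGAGGCAGGCGACATGGCTGGCTAGTTAAGCTTGGTACCGAGCTCGGATCC",
  "ACTAGTCC", strrep("T", 25), "VN")

#' Predicted poly(A)-tailed RT-PCR amplicon size
#'
#' After polyadenylation, reverse transcription with an anchored
#' oligo-dT primer (head + (T)n + VN) and PCR with a small-RNA-specific
#' forward primer, the expected cDNA size is the small-RNA length plus
#' the primer head, the T run, and the 2 nt VN anchor.
#'
#' @param small_rna_len mature small-RNA length (nt).
#' @param rtq_primer_seq the RT primer; either fully written out or with
#'   a `(T)25`-style run.  Default: [RTQ_PRIMER].
#' @return amplicon length in bp.
#' @export
#' @examples
#' predict_polya_rtpcr_amplicon(21)  # 121, i.e. ~120 bp
predict_polya_rtpcr_amplicon <- function(small_rna_len,
                                         rtq_primer_seq = RTQ_PRIMER) {
  stopifnot(small_rna_len >= 0)
  s <- toupper(gsub("[[:space:]]", "", rtq_primer_seq))
  # expand a compact (T)25 / (T)_25_ run
  m <- regmatches(s, regexec("\\(T\\)_?([0-9]+)_?", s))[[1]]
  if (length(m)) s <- sub("\\(T\\)_?[0-9]+_?", strrep("T", as.integer(m[2])), s)
  parts <- regmatches(s, regexec("^([ACGT]*[ACG])(T+)([VN]+)$", s))[[1]]
  if (!length(parts))
    stop("cannot parse RT primer into head + T-run + VN anchor", call. = FALSE)
  small_rna_len + nchar(parts[2]) + nchar(parts[3]) + nchar(parts[4])
}
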