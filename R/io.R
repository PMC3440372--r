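# Readers and writers for the external formats the pipeline touches:
# FASTA, FASTQ, BED6, Vienna dot-bracket, and the sequence/count TSV.
#
# Conventions: the internal alphabet is DNA (U is normalized to T on
# input); all internal genomic coordinates are 0-based half-open as in
# BED; human-readable reports use 1-based inclusive coordinates.

#' Read a FASTA file into a table of sequence records
#'
#' Sequences are uppercased and U is normalized to T.  Allowed symbols
#' after normalization are A, C, G, T and N; anything else is an error
#' naming the record and position.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `seq`, `description`, one row
#'   per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) usage_error("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- names(set)
  id <- sub("[[:space:]].*$", "", nm)
  if (any(!nzchar(id))) stop("FASTA record with empty id", call. = FALSE)
  desc <- ifelse(grepl("[[:space:]]", nm), sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
  seq <- normalize_seq(as.character(set), ids = id)
  if (any(!nzchar(seq)))
    stop("empty sequence in record '", id[which(!nzchar(seq))[1]], "'",
         call. = FALSE)
  data.frame(id = id, seq = unname(seq), description = desc,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records a data.frame with columns `id`, `seq` and optionally
#'   `description`, or a named character vector.
#' @param path output path.
#' @param alphabet `"dna"` (default) writes sequences as stored;
#'   `"rna"` converts T to U (used for mature small-RNA reports).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (is.character(records))
    records <- data.frame(id = names(records), seq = unname(records),
                          description = "", stringsAsFactors = FALSE)
  seqs <- if (alphabet == "rna") to_rna(records$seq) else records$seq
  nm <- ifelse(nzchar(records$description %||% ""),
               paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file, discarding qualities
#'
#' Classification uses exact sequence identity only, so base qualities
#' are dropped on input.
#'
#' @inheritParams read_fasta
#' @return same layout as [read_fasta()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) usage_error("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  if (length(set) == 0) stop("empty FASTQ file: ", path, call. = FALSE)
  nm <- names(set)
  id <- sub("[[:space:]].*$", "", nm)
  desc <- ifelse(grepl("[[:space:]]", nm), sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
  seq <- normalize_seq(as.character(set), ids = id)
  data.frame(id = id, seq = unname(seq), description = desc,
             stringsAsFactors = FALSE)
}

#' Read a BED6 annotation file
#'
#' Coordinates are kept 0-based half-open as in BED.  The feature label
#' (e.g. `piRNA_cluster`, `repeat`) is parsed from the name field prefix
#' before the first `:`; a name without `:` is its own label.
#'
#' @param path path to a BED6 file.
#' @return a data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) usage_error("file not found: ", path)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(lines))) return(empty)
  nfield <- lengths(strsplit(lines[nzchar(lines)], "\t", fixed = TRUE))
  if (any(nfield < 6))
    stop("malformed BED line: expected 6 tab-separated fields, got ",
         min(nfield), call. = FALSE)
  raw <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  start <- as.integer(vapply(raw, `[[`, "", 2L))
  end <- as.integer(vapply(raw, `[[`, "", 3L))
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric BED coordinates", call. = FALSE)
  if (any(start >= end))
    stop("BED interval with start >= end at line ",
         which(start >= end)[1], call. = FALSE)
  strand <- vapply(raw, `[[`, "", 6L)
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol '",
         strand[!strand %in% c("+", "-")][1], "' in BED file", call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")  # validates syntax
  nm <- vapply(raw, `[[`, "", 4L)
  data.frame(chrom = vapply(raw, `[[`, "", 1L),
             start = start, end = end, name = nm,
             score = as.numeric(vapply(raw, `[[`, "", 5L)),
             strand = strand,
             label = sub(":.*$", "", nm),
             stringsAsFactors = FALSE)
}

#' Write annotation records as BED6
#'
#' @param ann a data.frame as returned by [read_bed()] (the `label`
#'   column is ignored on output: it is derived from `name` on input).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  if (!nrow(ann)) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(ann$start < ann$end), all(ann$strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$name <- ann$name
  gr$score <- ann$score %||% 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a Vienna dot-bracket file
#'
#' Expects an optional `>` header line, a sequence line, and a structure
#' line of the same length over `(`, `)` and `.` (an RNAfold-style
#' trailing energy annotation after the structure is tolerated).
#'
#' @param path path to the dot-bracket file.
#' @return a list with elements `seq` (U normalized to T) and
#'   `structure`.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) usage_error("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2)
    stop("dot-bracket file needs a sequence line and a structure line",
         call. = FALSE)
  seq <- normalize_seq(lines[1])
  db <- sub("[[:space:]]+\\(.*\\)[[:space:]]*$", "", trimws(lines[2]))
  if (grepl("[^().]", db))
    stop("structure line contains characters other than ( ) .",
         call. = FALSE)
  if (nchar(db) != nchar(seq))
    stop("sequence and structure lengths differ (", nchar(seq), " vs ",
         nchar(db), ")", call. = FALSE)
  dotbracket_to_pairs(db)  # errors if unbalanced
  list(seq = unname(seq), structure = db)
}

#' Write a sequence and structure in Vienna dot-bracket format
#'
#' @param structure an `rna_structure` object (see [fold_nussinov()]).
#' @param path output path.
#' @param id header line text (written as `>id`).
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structure, path, id = "structure") {
  writeLines(c(paste0(">", id), structure$seq, structure$dotbracket), path)
  invisible(path)
}

#' Read a sequence/count table
#'
#' The TSV must have a header row with columns `sequence`, `library_id`
#' and `raw_count`; (sequence, library_id) pairs must be unique and
#' counts non-negative integers.
#'
#' @param path path to the TSV file.
#' @return a validated counts data.frame.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) usage_error("file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_counts(x)
}

#' @rdname read_counts_tsv
#' @param counts a counts data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(x) {
  need <- c("sequence", "library_id", "raw_count")
  if (!all(need %in% names(x)))
    stop("counts table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x$sequence <- normalize_seq(x$sequence, allow_n = TRUE)
  if (anyDuplicated(paste(x$sequence, x$library_id)))
    stop("duplicate (sequence, library_id) rows in counts table",
         call. = FALSE)
  if (any(x$raw_count < 0) || any(x$raw_count != round(x$raw_count)))
    stop("raw_count must be non-negative integers", call. = FALSE)
  x$raw_count <- as.numeric(x$raw_count)
  x
}
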