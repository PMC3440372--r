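# Hierarchical complete-match classification of reads into known RNA
# classes, then genome/repeat categories.  Matching is exact substring
# matching in the sense orientation against each class's reference set
# (degraded long RNAs must classify to their parent class), and exact
# matching on both genome strands for the remainder.

#' Recognized RNA classes, in default priority order
#'
#' When a read matches several reference sets it receives the first
#' matching class in this order; the classes used as discovery
#' exclusions (miRNA, rRNA) come first.  The last three labels are
#' assigned from genome matching, not reference sets.
#' @export
RNA_CLASSES <- c("miRNA", "rRNA", "tRNA", "snoRNA", "snRNA", "piRNA",
                 "mRNA", "repeat_associated", "genomic_unannotated",
                 "unmapped")

REF_CLASSES <- c("miRNA", "rRNA", "tRNA", "snoRNA", "snRNA", "piRNA", "mRNA")

# Coerce genome representations (named character vector, DNAStringSet,
# or a simulated genome object) to a named character vector of
# chromosome sequences.
as_genome_seqs <- function(genome) {
  if (inherits(genome, "spr_genome")) return(genome$seqs)
  if (methods::is(genome, "DNAStringSet")) {
    s <- as.character(genome)
    return(setNames(unname(s), names(genome)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("genome sequences must be named by chromosome", call. = FALSE)
    return(genome)
  }
  stop("unsupported genome representation", call. = FALSE)
}

#' Build an exact-substring match index over reference sets
#'
#' `query_index()` reports every class whose reference set contains the
#' query as an exact substring: a read wholly inside a longer reference
#' counts, as does a mature-length reference matched end-to-end.
#'
#' @param reference_sets named list (class -> data.frame with `seq`, or
#'   character vector of sequences).  Names must be RNA classes.
#' @param priority class priority used at classification time; defaults
#'   to the reference classes in [RNA_CLASSES] order.
#' @return a `match_index` object.
#' @export
build_exact_index <- function(reference_sets,
                              priority = intersect(REF_CLASSES,
                                                   names(reference_sets))) {
  if (!length(reference_sets)) stop("empty reference sets", call. = FALSE)
  if (is.null(names(reference_sets)) || any(!nzchar(names(reference_sets))))
    stop("reference sets must be named by RNA class", call. = FALSE)
  subjects <- lapply(reference_sets, function(rs) {
    seqs <- if (is.data.frame(rs)) rs$seq else as.character(rs)
    seqs <- normalize_seq(seqs)
    # N separators prevent matches across reference boundaries; trailing
    # pad keeps every subject longer than any plausible read.
    Biostrings::DNAString(paste0(paste(seqs, collapse = "NN"),
                                 strrep("N", 260)))
  })
  structure(list(subjects = subjects, priority = priority),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat("match_index over", length(x$subjects), "classes:",
      paste(names(x$subjects), collapse = ", "), "\n")
  invisible(x)
}

#' Query the match index with a single sequence
#'
#' @param index a `match_index`.
#' @param seq a nucleotide string.
#' @return character vector of classes containing `seq` as an exact
#'   substring (possibly empty).
#' @export
query_index <- function(index, seq) {
  seq <- normalize_seq(seq, allow_n = FALSE)
  hit <- vapply(index$subjects, function(subj) {
    length(Biostrings::matchPattern(seq, subj, fixed = TRUE)) > 0
  }, logical(1))
  names(hit)[hit]
}

# Vectorized class membership: nseq x nclass logical matrix via PDict.
match_classes <- function(seqs, index) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs),
                          tb.start = 1,
                          tb.end = min(nchar(seqs)))
  m <- vapply(index$subjects, function(subj) {
    Biostrings::countPDict(pd, subj) > 0
  }, logical(length(seqs)))
  if (length(seqs) == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(index$subjects)))
  m
}

#' Locate every exact occurrence of a sequence in a genome
#'
#' Finds all exact occurrences on both strands; a hit is the triple
#' (chrom, start, strand) with 0-based half-open coordinates, and for a
#' minus-strand hit `genome[start:end]` equals the reverse complement of
#' the query.  Hits are sorted by (chrom, start, strand).
#'
#' @param seq a nucleotide string of length >= 13.
#' @param genome named character vector / DNAStringSet / simulated
#'   genome.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
locate_in_genome <- function(seq, genome) {
  seq <- normalize_seq(seq, allow_n = FALSE)
  if (nchar(seq) < 13)
    stop("sequence shorter than 13 nt", call. = FALSE)
  hits <- locate_reads(seq, genome)
  hits$sequence <- NULL
  hits
}

# Vectorized genome search over unique sequences; returns one row per
# hit with the query in column `sequence`.
locate_reads <- function(seqs, genome) {
  gs <- as_genome_seqs(genome)
  stopifnot(!anyDuplicated(seqs))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs),
                          tb.start = 1,
                          tb.end = min(nchar(seqs)))
  rows <- list()
  for (chrom in names(gs)) {
    subj <- Biostrings::DNAString(gs[[chrom]])
    L <- length(subj)
    m <- Biostrings::matchPDict(pd, subj)
    st <- Biostrings::startIndex(m)
    for (q in which(lengths(st) > 0)) {
      s0 <- st[[q]] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs[q], chrom = chrom, start = s0,
        end = s0 + nchar(seqs[q]), strand = "+",
        stringsAsFactors = FALSE)
    }
    mrc <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
    strc <- Biostrings::startIndex(mrc)
    for (q in which(lengths(strc) > 0)) {
      w <- nchar(seqs[q])
      s0 <- L - (strc[[q]] - 1L) - w
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs[q], chrom = chrom, start = s0,
        end = s0 + w, strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sequence, out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify reads into RNA classes
#'
#' Each distinct sequence gets exactly one label: the first matching
#' reference class in priority order; otherwise, if it matches the
#' genome exactly (either strand), `repeat_associated` when a hit
#' overlaps a repeat annotation and `genomic_unannotated` when none
#' does; otherwise `unmapped`.  Multi-mapping does not affect the class,
#' only discovery screening.  Reads containing N are dropped with a
#' message reporting the count.
#'
#' @param counts a counts data.frame (`sequence`, `library_id`,
#'   `raw_count`) or any data.frame with a `sequence` column.
#' @param index a `match_index` from [build_exact_index()].
#' @param genome genome sequences (see [locate_in_genome()]).
#' @param annotation optional annotation data.frame (as from
#'   [read_bed()]); rows with `label == "repeat"` define repeats.
#' @return the input with a `class` column added (and `n_hits` for
#'   genome-matched reads; NA where the genome search did not run).
#'   The per-hit table for genome-searched reads is attached as
#'   attribute `"hits"`.
#' @export
classify_reads <- function(counts, index, genome, annotation = NULL) {
  if (!nrow(counts)) stop("no reads to classify", call. = FALSE)
  counts$sequence <- normalize_seq(counts$sequence)
  if (any(nchar(counts$sequence) == 0))
    stop("empty read sequence", call. = FALSE)
  hasN <- grepl("N", counts$sequence, fixed = TRUE)
  if (any(hasN)) {
    message("dropping ", sum(hasN), " read(s) containing N")
    counts <- counts[!hasN, , drop = FALSE]
    if (!nrow(counts)) stop("no reads left after dropping N", call. = FALSE)
  }
  seqs <- unique(counts$sequence)
  memb <- match_classes(seqs, index)
  pri <- intersect(index$priority, colnames(memb))
  cls <- rep(NA_character_, length(seqs))
  for (p in pri) cls[is.na(cls) & memb[, p]] <- p
  n_hits <- rep(NA_integer_, length(seqs))
  rest <- which(is.na(cls))
  hits <- NULL
  if (length(rest)) {
    hits <- locate_reads(seqs[rest], genome)
    nh <- table(factor(hits$sequence, levels = seqs[rest]))
    n_hits[rest] <- as.integer(nh)
    rep_ann <- if (!is.null(annotation))
      annotation[annotation$label == "repeat", , drop = FALSE]
    in_repeat <- rep(FALSE, nrow(hits))
    if (!is.null(rep_ann) && nrow(rep_ann) && nrow(hits)) {
      for (r in seq_len(nrow(rep_ann))) {
        in_repeat <- in_repeat |
          (hits$chrom == rep_ann$chrom[r] &
             hits$start < rep_ann$end[r] & hits$end > rep_ann$start[r])
      }
    }
    rep_seqs <- unique(hits$sequence[in_repeat])
    cls[rest] <- ifelse(n_hits[rest] == 0, "unmapped",
                        ifelse(seqs[rest] %in% rep_seqs,
                               "repeat_associated", "genomic_unannotated"))
  }
  lut <- setNames(cls, seqs)
  nh_lut <- setNames(n_hits, seqs)
  counts$class <- factor(unname(lut[counts$sequence]), levels = RNA_CLASSES)
  counts$n_hits <- unname(nh_lut[counts$sequence])
  attr(counts, "hits") <- hits
  counts
}

#' Classify a single read
#'
#' @param read a nucleotide string.
#' @inheritParams classify_reads
#' @return the class label (character); genomic hits, when the genome
#'   search ran, are attached as attribute `"hits"`.
#' @export
classify_read <- function(read, index, genome, annotation = NULL) {
  if (!nzchar(read)) stop("empty read", call. = FALSE)
  res <- classify_reads(data.frame(sequence = read,
                                   stringsAsFactors = FALSE),
                        index, genome, annotation)
  out <- as.character(res$class[1])
  attr(out, "hits") <- attr(res, "hits")
  out
}

#' Per-class library composition
#'
#' Per-class read counts and fractions, weighted by raw counts;
#' fractions sum to 1.
#'
#' @param classified output of [classify_reads()] including a
#'   `raw_count` column.
#' @return data.frame with columns `class`, `n_reads`, `fraction`, one
#'   row per class in [RNA_CLASSES].
#' @export
classify_library <- function(classified) {
  if (!nrow(classified)) stop("empty library", call. = FALSE)
  if (is.null(classified$raw_count) || is.null(classified$class))
    stop("expected columns raw_count and class", call. = FALSE)
  tot <- tapply(classified$raw_count, classified$class, sum, default = 0)
  n <- as.numeric(tot[RNA_CLASSES])
  n[is.na(n)] <- 0
  if (sum(n) == 0) stop("library has zero total reads", call. = FALSE)
  data.frame(class = RNA_CLASSES, n_reads = n, fraction = n / sum(n),
             stringsAsFactors = FALSE)
}
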