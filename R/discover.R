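# The candidate pipeline: length window -> class exclusion ->
# unique-locus screen -> window folding -> stem-containment criterion ->
# candidate report.

#' Discovery parameters
#'
#' Bundles every tunable of the candidate pipeline with its documented
#' default: a 20-23 nt length window excluding miRNA- and
#' rRNA-classified reads, a 140 nt flank (about 300 nt folded window),
#' base-pair maximization with a 3 nt minimum loop and GU wobble, stem
#' extension tolerating internal loops of up to 6 nt per side, and a
#' minimum paired fraction of 0.6 for stem containment.
#'
#' @param min_len,max_len read length window (nt).
#' @param excluded_classes classes removed before screening.
#' @param flank genomic flank added on each side of the read before
#'   folding.
#' @param min_loop,allow_gu folding parameters (see [fold_nussinov()]).
#' @param max_internal_loop stem extension tolerance (see
#'   [find_hairpins()]).
#' @param min_paired_frac stem containment threshold (see
#'   [stem_containment()]).
#' @return a list of class `discovery_params`.
#' @export
discovery_params <- function(min_len = 20L, max_len = 23L,
                             excluded_classes = c("miRNA", "rRNA"),
                             flank = 140L, min_loop = 3L, allow_gu = TRUE,
                             max_internal_loop = 6L,
                             min_paired_frac = 0.6) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  structure(list(min_len = min_len, max_len = max_len,
                 excluded_classes = excluded_classes, flank = flank,
                 min_loop = min_loop, allow_gu = allow_gu,
                 max_internal_loop = max_internal_loop,
                 min_paired_frac = min_paired_frac),
            class = "discovery_params")
}

#' Filter classified reads to discovery candidates
#'
#' Retains reads whose length is within the window and whose class is
#' neither excluded nor `unmapped`.
#'
#' @param classified output of [classify_reads()] (needs `sequence` and
#'   `class`).
#' @param min_len,max_len length window.
#' @param excluded_classes classes to drop.
#' @return the filtered data.frame.
#' @export
candidate_filter <- function(classified, min_len = 20L, max_len = 23L,
                             excluded_classes = c("miRNA", "rRNA")) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  len <- nchar(classified$sequence)
  cls <- as.character(classified$class)
  keep <- len >= min_len & len <= max_len &
    !cls %in% excluded_classes & cls != "unmapped"
  out <- classified[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep candidates mapping to exactly one genomic locus
#'
#' @param candidates data.frame with a `sequence` column.
#' @param hits per-hit table (`sequence`, `chrom`, `start`, `end`,
#'   `strand`) covering the candidates, e.g. from the internal genome
#'   search; by default taken from `attr(candidates, "hits")`.
#' @return candidates with exactly one hit, joined with their hit
#'   columns.
#' @export
screen_unique <- function(candidates, hits = attr(candidates, "hits")) {
  if (is.null(hits)) stop("candidates carry no genomic hits", call. = FALSE)
  nh <- table(hits$sequence)
  uni <- names(nh)[nh == 1]
  keep <- candidates$sequence %in% uni
  out <- candidates[keep, , drop = FALSE]
  h1 <- hits[match(out$sequence, hits$sequence), c("chrom", "start", "end",
                                                   "strand")]
  out <- cbind(out, h1)
  rownames(out) <- NULL
  out
}

#' Extract the proximal genomic window around a hit
#'
#' The window is `[start - flank, end + flank)`, clipped to chromosome
#' bounds.  For minus-strand hits the window sequence is
#' reverse-complemented so the read appears in sense orientation; the
#' read's interval within the window is returned 1-based inclusive.
#'
#' @param hit a list/row with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @param genome genome sequences.
#' @param flank flank size in nt (default 140, i.e. a ~300 nt window for
#'   a ~21 nt read).
#' @return a list with `seq`, `chrom`, `start`, `end` (window, 0-based
#'   half-open), `strand`, `read_start`, `read_end` (1-based inclusive
#'   within `seq`).
#' @export
extract_window <- function(hit, genome, flank = 140L) {
  gs <- as_genome_seqs(genome)
  chr <- gs[[hit$chrom]]
  if (is.null(chr) || is.na(chr)) stop("unknown chromosome: ", hit$chrom,
                                       call. = FALSE)
  L <- nchar(chr)
  ws <- max(0L, hit$start - flank)
  we <- min(L, hit$end + flank)
  seq <- substr(chr, ws + 1L, we)
  if (hit$strand == "-") {
    seq <- revcomp(seq)
    rs <- we - hit$end + 1L
  } else {
    rs <- hit$start - ws + 1L
  }
  list(seq = seq, chrom = hit$chrom, start = ws, end = we,
       strand = hit$strand,
       read_start = as.integer(rs),
       read_end = as.integer(rs + (hit$end - hit$start) - 1L))
}

#' Does a hit fall inside an annotated piRNA cluster?
#'
#' Overlap is by at least one base and strand-agnostic, since a cluster
#' hosts divergently oriented small RNAs.
#'
#' @param hit a list/row with `chrom`, `start`, `end`.
#' @param annotation annotation data.frame; rows with
#'   `label == "piRNA_cluster"` define clusters.
#' @return logical.
#' @export
annotate_pirna_locus <- function(hit, annotation) {
  cl <- annotation[annotation$label == "piRNA_cluster", , drop = FALSE]
  if (!nrow(cl)) return(FALSE)
  any(cl$chrom == hit$chrom & hit$start < cl$end & hit$end > cl$start)
}

#' Run the candidate discovery pipeline
#'
#' Composes classification, the length/class filter, the unique-locus
#' screen, window extraction, folding, the stem-containment criterion,
#' and piRNA-cluster annotation into a candidate report.
#'
#' @param counts counts data.frame (`sequence`, `library_id`,
#'   `raw_count`); counts are summed per sequence across the supplied
#'   rows.
#' @param genome genome sequences.
#' @param refs named list of reference sets (see
#'   [build_exact_index()]), or an already-built `match_index`.
#' @param annotation annotation data.frame (piRNA clusters, repeats).
#' @param params a [discovery_params()].
#' @return a data.frame, one row per candidate (exactly one genomic hit
#'   each), with columns `seq` (RNA alphabet), `size`, `n_reads`,
#'   `location`, `chrom`, `start`, `end`, `strand`, `in_pirna_locus`,
#'   `stem_loop`, `paired_fraction`, `window_start`, `window_end`,
#'   sorted by (stem_loop desc, n_reads desc, location).
#' @export
run_discovery <- function(counts, genome, refs, annotation = NULL,
                          params = discovery_params()) {
  empty <- data.frame(seq = character(0), size = integer(0),
                      n_reads = numeric(0), location = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      in_pirna_locus = logical(0), stem_loop = logical(0),
                      paired_fraction = numeric(0),
                      window_start = integer(0), window_end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(counts) || !nrow(counts)) return(empty)
  message("discovery: length window [", params$min_len, ", ",
          params$max_len, "], excluding ",
          paste(params$excluded_classes, collapse = "/"),
          ", flank ", params$flank, ", min_loop ", params$min_loop,
          ", GU ", params$allow_gu, ", max_internal_loop ",
          params$max_internal_loop, ", min_paired_frac ",
          params$min_paired_frac)
  index <- if (inherits(refs, "match_index")) refs else build_exact_index(refs)
  # sum counts per distinct sequence
  agg <- rowsum(counts$raw_count, counts$sequence)
  reads <- data.frame(sequence = rownames(agg), raw_count = agg[, 1],
                      stringsAsFactors = FALSE)
  classified <- classify_reads(reads, index, genome, annotation)
  cand <- candidate_filter(classified, params$min_len, params$max_len,
                           params$excluded_classes)
  if (!nrow(cand)) return(empty)
  hits <- locate_reads(unique(cand$sequence), genome)
  cand <- screen_unique(cand, hits)
  if (!nrow(cand)) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    hit <- cand[r, ]
    win <- extract_window(hit, genome, params$flank)
    st <- fold_nussinov(win$seq, min_loop = params$min_loop,
                        allow_gu = params$allow_gu)
    hp <- find_hairpins(st, max_internal_loop = params$max_internal_loop)
    sc <- stem_containment(hp, win$read_start, win$read_end,
                           min_paired_frac = params$min_paired_frac)
    data.frame(seq = to_rna(hit$sequence),
               size = nchar(hit$sequence),
               n_reads = hit$raw_count,
               location = format_location(hit$chrom, hit$start, hit$end,
                                          hit$strand),
               chrom = hit$chrom, start = hit$start, end = hit$end,
               strand = hit$strand,
               in_pirna_locus = if (is.null(annotation)) NA else
                 annotate_pirna_locus(hit, annotation),
               stem_loop = sc$contained,
               paired_fraction = sc$paired_fraction,
               window_start = win$start, window_end = win$end,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$stem_loop, -rep$n_reads, rep$chrom, rep$start), ,
             drop = FALSE]
  rownames(rep) <- NULL
  rep
}
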