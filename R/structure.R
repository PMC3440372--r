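# Secondary structure: base-pair-maximization folding, hairpin
# decomposition, and the stem-containment criterion used for candidate
# selection.  Structure-local coordinates are 1-based inclusive (R
# convention); genomic coordinates elsewhere stay 0-based half-open.

#' Construct an rna_structure object from a pair table
#'
#' Validates the pair-table invariants: involution (`p[p[i]] == i`),
#' proper nesting (no pseudoknots), and the minimum hairpin loop.
#'
#' @param seq nucleotide string (internally DNA; U accepted).
#' @param pairs integer vector, `pairs[i] = j` if (i, j) paired, 0 if
#'   unpaired (1-based).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return an object of class `rna_structure`: a list with `seq`,
#'   `pairs`, and `dotbracket`.
#' @export
rna_structure <- function(seq, pairs, min_loop = 0) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  pairs <- as.integer(pairs)
  stopifnot(length(pairs) == n, all(pairs >= 0), all(pairs <= n))
  idx <- which(pairs > 0)
  if (any(pairs[idx] == idx))
    stop("a base cannot pair with itself", call. = FALSE)
  if (any(pairs[pairs[idx]] != idx))
    stop("pair table is not an involution", call. = FALSE)
  op <- idx[pairs[idx] > idx]
  if (any(pairs[op] - op - 1 < min_loop))
    stop("hairpin loop shorter than min_loop", call. = FALSE)
  # nesting check via dot-bracket conversion (errors on crossing pairs)
  db <- pairs_to_dotbracket(pairs)
  structure(list(seq = seq, pairs = pairs, dotbracket = db),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure:", nchar(x$seq), "nt,",
      sum(x$pairs > 0) / 2, "pairs\n")
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Convert a pair table to dot-bracket notation
#'
#' @param pairs 1-based pair table (0 = unpaired).
#' @return dot-bracket string; errors if pairs cross (pseudoknot).
#' @export
pairs_to_dotbracket <- function(pairs) {
  n <- length(pairs)
  db <- rep(".", n)
  open <- integer(0)
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j > i) {
      db[i] <- "("
      open <- c(open, j)
    } else if (j > 0 && j < i) {
      if (!length(open) || open[length(open)] != i)
        stop("crossing pairs: structure is pseudoknotted", call. = FALSE)
      open <- open[-length(open)]
      db[i] <- ")"
    }
  }
  if (length(open)) stop("inconsistent pair table", call. = FALSE)
  paste(db, collapse = "")
}

#' Convert dot-bracket notation to a pair table
#'
#' @param db dot-bracket string over `(`, `)` and `.`.
#' @return 1-based integer pair table (0 = unpaired); errors if
#'   parentheses are unbalanced.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket contains characters other than ( ) .", call. = FALSE)
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced structure: unmatched ')' at position ", i,
             call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ",
         stack[length(stack)], call. = FALSE)
  pairs
}

#' Fold a sequence by base-pair maximization
#'
#' A Nussinov-style dynamic program maximizing the number of nested base
#' pairs with a minimum hairpin loop.  It replaces thermodynamic folding
#' because the downstream criterion needs hairpin topology, not free
#' energies; an externally computed structure (e.g. from RNAfold) can be
#' injected via [read_dotbracket()] and [rna_structure()].
#'
#' @param seq nucleotide string (A/C/G/T/U; N allowed but never pairs).
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3,
#'   the steric minimum).
#' @param allow_gu allow G:U wobble pairs (default TRUE).
#' @return an `rna_structure` with the maximal pair count and a
#'   deterministic traceback (the 5' base of each interval pairs with
#'   its smallest admissible partner achieving the optimum).
#' @export
#' @examples
#' fold_nussinov("GGGAAAACCC")
fold_nussinov <- function(seq, min_loop = 3, allow_gu = TRUE) {
  seq <- normalize_seq(seq)
  if (nchar(seq) < 1) stop("empty sequence", call. = FALSE)
  p <- .nussinov_pairs(seq, as.integer(min_loop), isTRUE(allow_gu))
  rna_structure(seq, p, min_loop = min_loop)
}

#' Exact maximum pair count by exhaustive enumeration
#'
#' Recursively enumerates every valid nested pairing (no memoization)
#' and returns the maximum pair count.  This is the test oracle for
#' [fold_nussinov()]; it is limited to short sequences.
#'
#' @inheritParams fold_nussinov
#' @return integer: the maximum number of pairs over all valid nested
#'   structures.
#' @export
enumerate_structures_bruteforce <- function(seq, min_loop = 3,
                                            allow_gu = TRUE) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n > 16) stop("sequence too long for brute-force enumeration (max 16)",
                   call. = FALSE)
  if (n == 0) return(0L)
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  ok <- matrix(FALSE, 5, 5)
  ok[1, 4] <- ok[4, 1] <- ok[2, 3] <- ok[3, 2] <- TRUE
  if (allow_gu) ok[3, 4] <- ok[4, 3] <- TRUE
  b[is.na(b)] <- 5
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (ok[b[i], b[k]]) {
        v <- 1L + rec(i + 1L, k - 1L) + (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, n)
}

#' Decompose a structure into hairpins
#'
#' Starting at each hairpin loop (a closing pair with no pairs inside),
#' the stem is extended outward through nested pairs, tolerating
#' unpaired interruptions of at most `max_internal_loop` bases per side;
#' extension stops at a bifurcation.  Arms are the contiguous position
#' intervals of the 5' and 3' stem strands.
#'
#' @param structure an `rna_structure`.
#' @param max_internal_loop maximum unpaired interruption per side when
#'   extending a stem (default 6).
#' @return a data.frame sorted by `n_pairs` descending with columns
#'   `n_pairs`, `arm5_start`, `arm5_end`, `loop_start`, `loop_end`,
#'   `arm3_start`, `arm3_end` (1-based inclusive) and list-columns
#'   `stem5`, `stem3` holding the paired positions of each arm.
#' @export
find_hairpins <- function(structure, max_internal_loop = 6) {
  p <- structure$pairs
  n <- length(p)
  out <- list()
  opens <- which(p > seq_len(n))
  for (i in opens) {
    j <- p[i]
    if (j - i > 1 && any(p[(i + 1):(j - 1)] > 0)) next  # not innermost
    stem5 <- i
    stem3 <- j
    ii <- i
    jj <- j
    repeat {
      k <- ii - 1L
      while (k >= 1L && p[k] == 0L) k <- k - 1L
      if (k < 1L) break
      kk <- p[k]
      if (kk <= jj) break                       # bifurcation / sibling helix
      between3 <- if (kk - jj > 1L) (jj + 1L):(kk - 1L) else integer(0)
      if (any(p[between3] > 0L)) break          # multiloop on the 3' side
      if (ii - k - 1L > max_internal_loop ||
          kk - jj - 1L > max_internal_loop) break
      stem5 <- c(k, stem5)
      stem3 <- c(stem3, kk)
      ii <- k
      jj <- kk
    }
    out[[length(out) + 1L]] <- list(
      n_pairs = length(stem5),
      arm5_start = ii, arm5_end = i,
      loop_start = i + 1L, loop_end = j - 1L,
      arm3_start = j, arm3_end = jj,
      stem5 = stem5, stem3 = sort(stem3))
  }
  if (!length(out)) {
    hp <- data.frame(n_pairs = integer(0), arm5_start = integer(0),
                     arm5_end = integer(0), loop_start = integer(0),
                     loop_end = integer(0), arm3_start = integer(0),
                     arm3_end = integer(0))
    hp$stem5 <- list()
    hp$stem3 <- list()
  } else {
    hp <- data.frame(
      n_pairs = vapply(out, `[[`, 1L, "n_pairs"),
      arm5_start = vapply(out, `[[`, 1L, "arm5_start"),
      arm5_end = vapply(out, `[[`, 1L, "arm5_end"),
      loop_start = vapply(out, `[[`, 1L, "loop_start"),
      loop_end = vapply(out, `[[`, 1L, "loop_end"),
      arm3_start = vapply(out, `[[`, 1L, "arm3_start"),
      arm3_end = vapply(out, `[[`, 1L, "arm3_end"))
    hp$stem5 <- lapply(out, `[[`, "stem5")
    hp$stem3 <- lapply(out, `[[`, "stem3")
    hp <- hp[order(-hp$n_pairs, hp$arm5_start), , drop = FALSE]
    rownames(hp) <- NULL
  }
  attr(hp, "n") <- n
  hp
}

#' Test whether a read lies within one arm of a hairpin stem
#'
#' TRUE iff some hairpin has the read interval fully inside its 5' arm
#' or fully inside its 3' arm AND at least `min_paired_frac` of the
#' read's positions are paired within that hairpin's stem.  This is the
#' automated form of the manual "one strand of the stem" inspection.
#'
#' @param hairpins output of [find_hairpins()].
#' @param read_start,read_end read interval within the folded window,
#'   1-based inclusive.
#' @param min_paired_frac minimum fraction of read positions paired in
#'   the containing arm (default 0.6).
#' @return a list: `contained` (logical), `paired_fraction` (best
#'   fraction over containing arms; 0 if no arm contains the read), and
#'   `hairpin` (row index of the best hairpin, or NA).
#' @export
stem_containment <- function(hairpins, read_start, read_end,
                             min_paired_frac = 0.6) {
  n <- attr(hairpins, "n")
  if (is.null(n)) stop("hairpins must come from find_hairpins()",
                       call. = FALSE)
  if (read_start < 1 || read_end > n || read_start > read_end)
    stop("read interval out of structure bounds", call. = FALSE)
  pos <- read_start:read_end
  best <- 0
  best_i <- NA_integer_
  for (r in seq_len(nrow(hairpins))) {
    fr <- -1
    if (read_start >= hairpins$arm5_start[r] &&
        read_end <= hairpins$arm5_end[r]) {
      fr <- mean(pos %in% hairpins$stem5[[r]])
    } else if (read_start >= hairpins$arm3_start[r] &&
               read_end <= hairpins$arm3_end[r]) {
      fr <- mean(pos %in% hairpins$stem3[[r]])
    }
    if (fr > best || (fr >= 0 && is.na(best_i))) {
      best <- max(fr, 0)
      best_i <- r
    }
  }
  list(contained = !is.na(best_i) && best >= min_paired_frac,
       paired_fraction = best,
       hairpin = best_i)
}

#' Length of the longest perfectly stacked helix
#'
#' The longest run of strictly stacked pairs (i, j), (i+1, j-1), ...;
#' used to flag long double-stranded stretches that would point to a
#' dsRNA precursor rather than a hairpin.
#'
#' @param structure an `rna_structure`.
#' @return integer helix length (0 if no pairs).
#' @export
longest_helix <- function(structure) {
  p <- structure$pairs
  opens <- which(p > seq_along(p))
  if (!length(opens)) return(0L)
  best <- 1L
  run <- 1L
  if (length(opens) > 1) {
    for (t in 2:length(opens)) {
      i <- opens[t]
      if (i == opens[t - 1] + 1L && p[i] == p[opens[t - 1]] - 1L) {
        run <- run + 1L
      } else {
        run <- 1L
      }
      best <- max(best, run)
    }
  }
  best
}
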