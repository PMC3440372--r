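# Synthetic genomes, reference sets, and two-library read sets with the
# statistical structure the analysis assumes: a degraded long-RNA
# background, mature small RNAs, hairpin-borne novel sncRNAs planted
# inside a piRNA cluster, a multi-copy decoy, a shuffled-context
# control, 3' tailing variants, and sperm-vs-testis enrichment.

#' Simulation configuration
#'
#' Defaults define the reference study conditions: a 100 kb genome with
#' a 40 kb piRNA cluster, two hairpin-borne novel sncRNAs (20-23 nt)
#' planted in the cluster, one multi-copy decoy, one shuffled-context
#' control, a degraded long-RNA background with fragments of 13-248 nt,
#' Table-2-style 3' tailing proportions, and a 150-fold sperm/testis
#' enrichment of the planted sncRNAs at one million reads per library.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param genome_length genome size in nt.
#' @param chrom_name chromosome name.
#' @param n_mirna,n_trna,n_rrna,n_mrna numbers of planted genes.
#' @param mirna_mature_len,trna_len,rrna_len,mrna_len feature lengths.
#' @param pirna_cluster_span piRNA cluster span in nt.
#' @param n_pirna piRNAs planted in the cluster (24-31 nt, 5' U,
#'   divergent orientations).
#' @param pirna_len_range piRNA length range.
#' @param n_spr planted novel sncRNA loci (each embedded in a designed
#'   hairpin inside the cluster, divergent orientations).
#' @param spr_len_range sncRNA length range.
#' @param n_decoy_multicopy sequences planted at two loci each.
#' @param decoy_len,n_control,n_repeat,repeat_len decoy/control/repeat
#'   geometry (the repeat is planted twice and annotated as `repeat`).
#' @param stem_ext5 extra stem pairs 5' of the planted read, so the read
#'   sits strictly interior to the hairpin arm.
#' @param templated_context genomic bases immediately 3' of each planted
#'   sncRNA (the source of templated 3' extensions).
#' @param loop_seq hairpin loop sequence (chosen so that no legal pair
#'   can form inside the loop).
#' @param arm_mutations substitutions placed in the complementary arm so
#'   that the planted read maps to exactly one genomic locus.
#' @param library_depth reads per library.
#' @param fragment_length_range background fragment lengths (nt).
#' @param fragment_pool_size number of distinct background fragment
#'   species (deep libraries are strongly duplicated, so the degraded
#'   background is modeled as a finite species pool with log-uniform
#'   abundances).
#' @param fragment_decay exponential decay (nt) of fragment lengths.
#' @param class_rpm reads-per-million allocated to miRNA, piRNA, decoy
#'   and control reads; the degraded background absorbs the remainder.
#' @param tail_probs distribution over 3' suffixes appended to each
#'   planted sncRNA (templated and non-templated; defaults follow the
#'   observed A-rich tailing pattern).
#' @param spr_rpm per-locus RPM of each planted sncRNA in the
#'   non-enriched library.
#' @param enrichment target abundance ratio of planted sncRNAs between
#'   the enriched and non-enriched library.
#' @param enriched_library library id receiving the enrichment.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       chrom_name = "chrS",
                       n_mirna = 5L, n_trna = 4L, n_rrna = 2L, n_mrna = 5L,
                       mirna_mature_len = 22L, trna_len = 72L,
                       rrna_len = 1500L, mrna_len = 1000L,
                       pirna_cluster_span = 40000L,
                       n_pirna = 30L, pirna_len_range = c(24L, 31L),
                       n_spr = 2L, spr_len_range = c(20L, 23L),
                       n_decoy_multicopy = 1L, decoy_len = 21L,
                       n_control = 1L,
                       n_repeat = 1L, repeat_len = 150L,
                       stem_ext5 = 8L,
                       templated_context = "TTTG",
                       loop_seq = "CTTGTT",
                       arm_mutations = 3L,
                       library_depth = 1e6,
                       fragment_length_range = c(13L, 248L),
                       fragment_pool_size = 20000L,
                       fragment_decay = 60,
                       class_rpm = c(miRNA = 1e5, piRNA = 1.5e5,
                                     decoy = 50, control = 50),
                       tail_probs = c(0.526, 0.315, 0.101, 0.021, 0.014,
                                      0.013, 0.007, 0.0015, 0.0015),
                       spr_rpm = 60,
                       enrichment = 150,
                       enriched_library = "sperm") {
  if (is.null(names(tail_probs)))
    names(tail_probs) <- c("", "A", "TT", "T", "AA", "TA", "G", "AAA", "C")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              chrom_name = chrom_name, n_mirna = n_mirna, n_trna = n_trna,
              n_rrna = n_rrna, n_mrna = n_mrna,
              mirna_mature_len = mirna_mature_len, trna_len = trna_len,
              rrna_len = rrna_len, mrna_len = mrna_len,
              pirna_cluster_span = as.integer(pirna_cluster_span),
              n_pirna = n_pirna, pirna_len_range = pirna_len_range,
              n_spr = n_spr, spr_len_range = spr_len_range,
              n_decoy_multicopy = n_decoy_multicopy, decoy_len = decoy_len,
              n_control = n_control, n_repeat = n_repeat,
              repeat_len = repeat_len, stem_ext5 = stem_ext5,
              templated_context = templated_context, loop_seq = loop_seq,
              arm_mutations = arm_mutations, library_depth = library_depth,
              fragment_length_range = fragment_length_range,
              fragment_pool_size = fragment_pool_size,
              fragment_decay = fragment_decay, class_rpm = class_rpm,
              tail_probs = tail_probs / sum(tail_probs),
              spr_rpm = spr_rpm, enrichment = enrichment,
              enriched_library = enriched_library)
  stopifnot(cfg$genome_length > cfg$pirna_cluster_span,
            cfg$fragment_length_range[1] >= 13,
            cfg$fragment_length_range[1] <= cfg$fragment_length_range[2],
            all(cfg$tail_probs >= 0), cfg$spr_rpm > 0, cfg$enrichment > 0)
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Complementary arm with `n_sub` positions facing the read switched
# from Watson-Crick to wobble partners (T faces G instead of A, G faces
# T instead of C).  The arm still pairs at full strength under the
# folder, so base-pair maximization keeps the designed stem, yet it is
# not an exact reverse complement, so the planted read keeps a single
# exact genomic locus.
wobble_arm <- function(core, read_span, n_sub) {
  cb <- strsplit(core, "")[[1]]
  n <- length(cb)
  arm <- rev(chartr("ACGT", "TGCA", cb))   # exact reverse complement
  facing <- n - seq_len(n) + 1L            # arm pos t faces core pos facing[t]
  cand <- which(facing %in% read_span & cb[facing] %in% c("T", "G"))
  if (length(cand) < n_sub)
    stop("read has too few wobble-capable bases", call. = FALSE)
  at <- cand[unique(round(seq(1, length(cand), length.out = n_sub)))]
  arm[at] <- ifelse(cb[facing[at]] == "T", "G", "T")
  paste(arm, collapse = "")
}

# Hairpin cassette in transcript orientation:
#   ext5 | read | templated_context | loop | arm (wobbled complement)
# The arm covers ext5 + read + templated_context, so the read is
# strictly interior to the stem.  `read_offset` is the 0-based offset of
# the read within the cassette.
hairpin_cassette <- function(read, cfg, shuffle_arm = FALSE) {
  ext5 <- random_seq(cfg$stem_ext5)
  core <- paste0(ext5, read, cfg$templated_context)
  span <- (nchar(ext5) + 1L):(nchar(ext5) + nchar(read))
  arm <- wobble_arm(core, span, cfg$arm_mutations)
  if (shuffle_arm)
    arm <- paste(sample(strsplit(arm, "")[[1]]), collapse = "")
  list(seq = paste0(core, cfg$loop_seq, arm),
       read_offset = nchar(ext5))
}

# Map an interval given in transcript coordinates (0-based half-open)
# into genome coordinates for a cassette planted at `at` (0-based) on
# `strand`.
transcript_to_genome <- function(at, cassette_len, a, b, strand) {
  if (strand == "+") c(at + a, at + b)
  else c(at + cassette_len - b, at + cassette_len - a)
}

#' Simulate a toy genome with planted truth
#'
#' Plants long-RNA genes, miRNA hairpins, a piRNA cluster with piRNAs
#' and hairpin-borne novel sncRNAs, a multi-copy decoy, a
#' shuffled-context control, and a two-copy repeat, then verifies the
#' planted truth: every annotated substring matches its record, each
#' planted sncRNA occurs exactly once genome-wide (either strand) and is
#' absent from every reference set, and the decoy occurs at least
#' twice.
#'
#' @param config a [sim_config()].
#' @return an object of class `spr_genome`: a list with `seqs` (named
#'   character vector of chromosome sequences), `truth` (annotation
#'   data.frame with 0-based half-open coordinates and a `seq` column
#'   holding each planted sequence in strand sense), and `features`
#'   (planted sequences by role, used to build reference sets).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    for (attempt in 1:20) {
      g <- try(build_genome_once(config), silent = TRUE)
      if (!inherits(g, "try-error")) return(g)
      if (grepl("genome too small", attr(g, "condition")$message))
        stop(attr(g, "condition"))
    }
    stop("failed to build a genome satisfying the planted-truth ",
         "constraints after 20 attempts", call. = FALSE)
  })
}

build_genome_once <- function(cfg) {
  L <- cfg$genome_length
  chrom <- cfg$chrom_name
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  span <- cfg$pirna_cluster_span
  margin <- 500L
  cl_start <- sample(seq(margin, L - span - margin), 1)
  cl_end <- cl_start + span

  occupied <- matrix(numeric(0), ncol = 2)
  place <- function(len, region) {
    lo <- if (region == "cluster") cl_start else 0L
    hi <- if (region == "cluster") cl_end else L
    for (t in 1:500) {
      at <- sample(seq(lo + 10L, hi - len - 10L), 1)
      # outside-region features must not fall into the cluster
      if (region == "outside" && at < cl_end && at + len > cl_start) next
      if (!nrow(occupied) ||
          all(at >= occupied[, 2] + 10 | at + len <= occupied[, 1] - 10)) {
        occupied <<- rbind(occupied, c(at, at + len))
        return(at)
      }
    }
    stop("genome too small to host the requested features", call. = FALSE)
  }

  truth <- list()
  features <- list()
  plant <- function(transcript, strand, at) {
    s <- if (strand == "+") transcript else revcomp(transcript)
    base[(at + 1):(at + nchar(s))] <<- strsplit(s, "")[[1]]
  }
  record <- function(label, name, start, end, strand, seq) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      name = name, score = 0, strand = strand, label = label, seq = seq,
      stringsAsFactors = FALSE)
  }

  # long-RNA genes and repeats (outside the cluster)
  gene <- function(label, n, len) {
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- random_seq(len)
      strand <- sample(c("+", "-"), 1)
      at <- place(len, "outside")
      plant(seqs[i], strand, at)
      record(label, paste0(label, "-", i), at, at + len, strand, seqs[i])
    }
    seqs
  }
  features$rrna <- gene("rRNA", cfg$n_rrna, cfg$rrna_len)
  features$mrna <- gene("mRNA", cfg$n_mrna, cfg$mrna_len)
  features$trna <- gene("tRNA", cfg$n_trna, cfg$trna_len)

  if (cfg$n_repeat > 0) {
    features$repeats <- replicate(cfg$n_repeat, random_seq(cfg$repeat_len))
    for (i in seq_len(cfg$n_repeat)) {
      for (copy in 1:2) {
        at <- place(cfg$repeat_len, "outside")
        plant(features$repeats[i], "+", at)
        record("repeat", paste0("repeat-", i, "_copy", copy),
               at, at + cfg$repeat_len, "+", features$repeats[i])
      }
    }
  } else features$repeats <- character(0)

  # miRNA hairpin genes: mature arm + imperfect star arm
  features$mirna_mature <- character(cfg$n_mirna)
  features$mirna_star <- character(cfg$n_mirna)
  for (i in seq_len(cfg$n_mirna)) {
    mature <- random_seq(cfg$mirna_mature_len)
    cas <- hairpin_cassette(mature, cfg)
    clen <- nchar(cas$seq)
    arm_start <- nchar(cas$seq) - (cfg$stem_ext5 + cfg$mirna_mature_len +
                                     nchar(cfg$templated_context)) + 1L
    star <- substr(cas$seq, arm_start, clen)
    star <- substr(star, nchar(cfg$templated_context) + 1,
                   nchar(cfg$templated_context) + cfg$mirna_mature_len)
    strand <- sample(c("+", "-"), 1)
    at <- place(clen, "outside")
    plant(cas$seq, strand, at)
    rd <- transcript_to_genome(at, clen, cas$read_offset,
                               cas$read_offset + cfg$mirna_mature_len, strand)
    record("miRNA", paste0("mir-", i), rd[1], rd[2], strand, mature)
    features$mirna_mature[i] <- mature
    features$mirna_star[i] <- star
  }

  # decoy: same sequence planted at two loci
  features$decoy <- character(cfg$n_decoy_multicopy)
  for (i in seq_len(cfg$n_decoy_multicopy)) {
    features$decoy[i] <- random_seq(cfg$decoy_len)
    for (copy in 1:2) {
      at <- place(cfg$decoy_len, "outside")
      plant(features$decoy[i], "+", at)
      record("decoy", paste0("decoy-", i, "_copy", copy),
             at, at + cfg$decoy_len, "+", features$decoy[i])
    }
  }

  # shuffled-context control: 20-23 nt read whose would-be hairpin arm
  # is shuffled, so no stem contains it
  features$control <- character(cfg$n_control)
  for (i in seq_len(cfg$n_control)) {
    len <- sample(seq(cfg$spr_len_range[1], cfg$spr_len_range[2]), 1)
    ctrl <- random_seq(len)
    cas <- hairpin_cassette(ctrl, cfg, shuffle_arm = TRUE)
    at <- place(nchar(cas$seq), "outside")
    plant(cas$seq, "+", at)
    record("control", paste0("control-", i),
           at + cas$read_offset, at + cas$read_offset + len, "+", ctrl)
    features$control[i] <- ctrl
  }

  # piRNA cluster with piRNAs and hairpin-borne novel sncRNAs
  record("piRNA_cluster", "cluster-1", cl_start, cl_end, "+", "")
  features$pirna <- character(cfg$n_pirna)
  for (i in seq_len(cfg$n_pirna)) {
    len <- sample(seq(cfg$pirna_len_range[1], cfg$pirna_len_range[2]), 1)
    pir <- paste0("T", random_seq(len - 1))  # piRNAs initiate with 5' U
    strand <- sample(c("+", "-"), 1)
    at <- place(len, "cluster")
    plant(pir, strand, at)
    record("piRNA", paste0("piR-", i), at, at + len, strand, pir)
    features$pirna[i] <- pir
  }

  features$spr <- character(cfg$n_spr)
  for (i in seq_len(cfg$n_spr)) {
    len <- sample(seq(cfg$spr_len_range[1], cfg$spr_len_range[2]), 1)
    spr <- random_seq(len)
    cas <- hairpin_cassette(spr, cfg)
    strand <- if (i %% 2 == 1) "-" else "+"   # divergent orientations
    at <- place(nchar(cas$seq), "cluster")
    plant(cas$seq, strand, at)
    rd <- transcript_to_genome(at, nchar(cas$seq), cas$read_offset,
                               cas$read_offset + len, strand)
    record("spR", paste0("spR-", i), rd[1], rd[2], strand, spr)
    features$spr[i] <- spr
  }

  genome_str <- paste(base, collapse = "")
  truth <- do.call(rbind, truth)
  g <- structure(list(seqs = setNames(genome_str, chrom), truth = truth,
                      features = features, config = cfg),
                 class = "spr_genome")
  check_planted_truth(g)
  g
}

# Verify the generator's contract; any violation aborts this attempt.
check_planted_truth <- function(g) {
  cfg <- g$config
  chr <- Biostrings::DNAString(g$seqs[[1]])
  tr <- g$truth
  for (r in seq_len(nrow(tr))) {
    if (!nzchar(tr$seq[r])) next
    got <- as.character(Biostrings::subseq(chr, tr$start[r] + 1, tr$end[r]))
    want <- if (tr$strand[r] == "+") tr$seq[r] else revcomp(tr$seq[r])
    if (got != want) stop("planted truth mismatch at ", tr$name[r])
  }
  count_both <- function(s) {
    Biostrings::countPattern(s, chr) + Biostrings::countPattern(revcomp(s), chr)
  }
  refs <- unlist(reference_seqs(g), use.names = FALSE)
  for (s in c(g$features$spr, g$features$control)) {
    if (count_both(s) != 1) stop("planted read is not unique genome-wide")
    if (any(grepl(s, refs, fixed = TRUE)) ||
        any(grepl(revcomp(s), refs, fixed = TRUE)))
      stop("planted read occurs in a reference set")
  }
  for (s in g$features$decoy)
    if (count_both(s) < 2) stop("decoy occurs fewer than 2 times")
  invisible(g)
}

reference_seqs <- function(genome) {
  f <- genome$features
  list(miRNA = c(f$mirna_mature, f$mirna_star),
       rRNA = f$rrna,
       tRNA = paste0(f$trna, "CCA"),   # mature tRNAs carry 3' CCA
       piRNA = f$pirna,
       mRNA = f$mrna)
}

#' Build per-class reference sets from a simulated genome
#'
#' tRNA references are the genomic tRNA sequences with an additional CCA
#' at the 3' end; the miRNA set contains mature and star sequences.
#' Planted novel sncRNAs are deliberately absent from every set.
#'
#' @param genome an `spr_genome`.
#' @return named list (class -> data.frame with `id`, `seq`).
#' @export
build_reference_sets <- function(genome) {
  stopifnot(inherits(genome, "spr_genome"))
  rs <- reference_seqs(genome)
  out <- lapply(names(rs), function(cl) {
    s <- rs[[cl]]
    if (!length(s)) return(NULL)
    data.frame(id = paste0(cl, "-ref-", seq_along(s)), seq = s,
               stringsAsFactors = FALSE)
  })
  names(out) <- names(rs)
  out[!vapply(out, is.null, logical(1))]
}

# Finite pool of distinct background fragment species drawn from the
# mature long RNAs (rRNA, mRNA, tRNA+CCA) and the repeat.
fragment_pool <- function(genome, cfg) {
  parents <- c(genome$features$rrna, genome$features$mrna,
               paste0(genome$features$trna, "CCA"), genome$features$repeats)
  pl <- nchar(parents)
  K <- cfg$fragment_pool_size
  fmin <- cfg$fragment_length_range[1]
  fmax <- cfg$fragment_length_range[2]
  pi <- sample.int(length(parents), K, replace = TRUE, prob = pl)
  maxl <- pmin(fmax, pl[pi])
  q <- exp(-1 / cfg$fragment_decay)
  u <- runif(K)
  len <- fmin + floor(log(1 - u * (1 - q^(maxl - fmin + 1))) / log(q))
  len <- pmin(len, maxl)
  start <- floor(runif(K) * (pl[pi] - len + 1)) + 1
  data.frame(sequence = substring(parents[pi], start, start + len - 1),
             weight = 10^runif(K, 0, 2), stringsAsFactors = FALSE)
}

# All emitted read species with per-group weights; deterministic given
# the genome and config (seeded independently of the library draw so
# both libraries share one species universe).
species_universe <- function(genome, cfg) {
  with_seed(derive_seed(cfg$seed, "universe"), {
    f <- genome$features
    bg <- fragment_pool(genome, cfg)
    sp <- list(data.frame(sequence = bg$sequence, group = "background",
                          member = "bg", w = bg$weight,
                          stringsAsFactors = FALSE))
    if (length(f$mirna_mature)) {
      wm <- 10^runif(length(f$mirna_mature), 0, 2)
      sp[[length(sp) + 1]] <- data.frame(
        sequence = c(f$mirna_mature, f$mirna_star), group = "miRNA",
        member = "m", w = c(wm, wm * 0.05), stringsAsFactors = FALSE)
    }
    if (length(f$pirna)) {
      sp[[length(sp) + 1]] <- data.frame(
        sequence = f$pirna, group = "piRNA", member = "p",
        w = 10^runif(length(f$pirna), 0, 2), stringsAsFactors = FALSE)
    }
    if (length(f$decoy)) {
      sp[[length(sp) + 1]] <- data.frame(
        sequence = f$decoy, group = "decoy", member = "d", w = 1,
        stringsAsFactors = FALSE)
    }
    if (length(f$control)) {
      sp[[length(sp) + 1]] <- data.frame(
        sequence = f$control, group = "control", member = "c", w = 1,
        stringsAsFactors = FALSE)
    }
    tails <- names(cfg$tail_probs)
    for (i in seq_along(f$spr)) {
      sp[[length(sp) + 1]] <- data.frame(
        sequence = paste0(f$spr[i], tails), group = "spr",
        member = paste0("spr-", i), w = as.numeric(cfg$tail_probs),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, sp)
  })
}

#' Simulate one sequencing library
#'
#' Emits (a) background fragments of the planted long RNAs with lengths
#' in `fragment_length_range`, (b) mature small RNAs at configured
#' abundances, and (c) for each planted sncRNA, 3'-variant reads per
#' `tail_probs` (templated and non-templated).  The enriched library's
#' sncRNA abundance is `enrichment`-fold that of the other library.
#' Deterministic under the config seed.
#'
#' @param genome an `spr_genome`.
#' @param library_id library name (e.g. `"sperm"`, `"testis"`); sncRNA
#'   enrichment applies when it equals `config$enriched_library`.
#' @param config the [sim_config()] used to build the genome.
#' @return a counts data.frame (`sequence`, `library_id`, `raw_count`).
#' @export
simulate_library <- function(genome, library_id, config) {
  stopifnot(inherits(genome, "spr_genome"))
  if (config$library_depth <= 0) stop("library depth must be > 0",
                                      call. = FALSE)
  u <- species_universe(genome, config)
  rpm <- numeric(nrow(u))
  for (grp in c("miRNA", "piRNA", "decoy", "control")) {
    sel <- u$group == grp
    if (any(sel)) rpm[sel] <- config$class_rpm[[grp]] * u$w[sel] / sum(u$w[sel])
  }
  spr_rpm <- config$spr_rpm *
    (if (identical(library_id, config$enriched_library)) config$enrichment else 1)
  for (m in unique(u$member[u$group == "spr"])) {
    sel <- u$member == m
    rpm[sel] <- spr_rpm * u$w[sel] / sum(u$w[sel])
  }
  bg <- u$group == "background"
  bg_total <- 1e6 - sum(rpm)
  if (bg_total <= 0)
    stop("configured class abundances exceed the library size", call. = FALSE)
  rpm[bg] <- bg_total * u$w[bg] / sum(u$w[bg])
  counts <- with_seed(derive_seed(config$seed, paste0("lib:", library_id)), {
    as.vector(rmultinom(1, size = config$library_depth, prob = rpm / 1e6))
  })
  agg <- rowsum(counts, u$sequence)
  keep <- agg[, 1] > 0
  out <- data.frame(sequence = rownames(agg)[keep],
                    library_id = library_id,
                    raw_count = as.numeric(agg[keep, 1]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a full dataset (genome, references, two libraries)
#'
#' @param config a [sim_config()].
#' @param libraries library ids to simulate.
#' @return a list with `genome`, `refs`, `counts` (both libraries,
#'   stacked), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             libraries = c("sperm", "testis")) {
  genome <- simulate_genome(config)
  refs <- build_reference_sets(genome)
  counts <- do.call(rbind, lapply(libraries, function(lib)
    simulate_library(genome, lib, config)))
  rownames(counts) <- NULL
  list(genome = genome, refs = refs, counts = counts, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the genome FASTA, truth BED (names prefixed by label), one
#' reference FASTA per class, the counts TSV, and the config as YAML.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "refs"), showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.bed"),
             counts = file.path(dir, "counts.tsv"),
             config = file.path(dir, "config.yaml"))
  write_fasta(setNames(dataset$genome$seqs, names(dataset$genome$seqs)),
              paths[["genome"]])
  tr <- dataset$genome$truth
  tr$name <- paste0(tr$label, ":", tr$name)
  write_bed(tr, paths[["truth"]])
  write_counts_tsv(dataset$counts, paths[["counts"]])
  for (cl in names(dataset$refs)) {
    p <- file.path(dir, "refs", paste0(cl, ".fa"))
    write_fasta(dataset$refs[[cl]]$seq |> setNames(dataset$refs[[cl]]$id), p)
    paths[paste0("ref_", cl)] <- p
  }
  cfg <- dataset$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths[["config"]])
  message("simulation written to ", normalizePath(dir),
          " (", length(paths), " files)")
  invisible(paths)
}
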