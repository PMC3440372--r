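# Shared fixtures and independent oracles.

# Small study conditions for unit tests (fast); the acceptance tests use
# the full default conditions.
tiny_config <- function(seed = 11) {
  sim_config(seed = seed,
             genome_length = 20000L,
             pirna_cluster_span = 8000L,
             n_mirna = 2L, n_trna = 2L, n_rrna = 1L, n_mrna = 2L,
             rrna_len = 800L, mrna_len = 600L,
             n_pirna = 8L,
             library_depth = 50000,
             fragment_pool_size = 1500L)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_config())
    cache
  }
})

# Naive double-strand substring scan (O(n * w)), independent of the
# Biostrings-backed search.  Finds overlapping occurrences.
brute_locate <- function(seq, genome) {
  gs <- if (inherits(genome, "spr_genome")) genome$seqs else genome
  out <- list()
  for (chrom in names(gs)) {
    s <- gs[[chrom]]
    n <- nchar(s)
    w <- nchar(seq)
    if (w > n) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp(seq)
      at <- which(vapply(seq_len(n - w + 1),
                         function(i) substr(s, i, i + w - 1) == pat,
                         logical(1)))
      if (length(at))
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = at - 1L, end = at - 1L + w,
          strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Rebuild a sim_config with some fields overridden.
within_cfg <- function(cfg, ...) {
  x <- unclass(cfg)
  args <- list(...)
  x[names(args)] <- args
  do.call(sim_config, x)
}

# One shared set of full-scale simulation runs backing the acceptance
# tests (10 seeds at the default study conditions); computed once.
acceptance_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    runs <- lapply(1:10, function(seed) {
      cfg <- sim_config(seed = seed)
      g <- simulate_genome(cfg)
      refs <- build_reference_sets(g)
      sperm <- simulate_library(g, "sperm", cfg)
      testis <- simulate_library(g, "testis", cfg)
      rep <- suppressMessages(run_discovery(sperm, g, refs, g$truth))
      rpm <- rpm_normalize(rbind(sperm, testis))
      ratio <- vapply(g$features$spr, function(s) {
        num <- rpm$rpm[rpm$sequence == s & rpm$library_id == "sperm"]
        den <- rpm$rpm[rpm$sequence == s & rpm$library_id == "testis"]
        (if (length(num)) num else 0) / (if (length(den)) den else NA_real_)
      }, numeric(1))
      first <- if (seed == 1)
        list(genome = g, refs = refs, sperm = sperm, testis = testis)
      list(recall = mean(to_rna(g$features$spr) %in%
                           rep$seq[rep$stem_loop]),
           decoy_reported = any(to_dna(rep$seq) %in% g$features$decoy),
           control_flagged = any(to_dna(rep$seq) %in% g$features$control &
                                   rep$stem_loop),
           control_reported = any(to_dna(rep$seq) %in% g$features$control),
           report = rep[, setdiff(names(rep), "seq_dna")],
           spr = g$features$spr, ratio = ratio, first = first)
    })
    cache <<- runs
    runs
  }
})
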