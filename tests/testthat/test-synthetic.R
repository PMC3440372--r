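# Generator contract: planted truth, reference sets, library structure,
# determinism.

test_that("planted truth matches the genome at every recorded locus", {
  g <- tiny_dataset()$genome
  chr <- g$seqs[[1]]
  for (r in seq_len(nrow(g$truth))) {
    tr <- g$truth[r, ]
    if (!nzchar(tr$seq)) next
    got <- substr(chr, tr$start + 1, tr$end)
    want <- if (tr$strand == "+") tr$seq else revcomp(tr$seq)
    expect_equal(got, want, info = tr$name)
  }
})

test_that("planted sncRNAs are unique genome-wide; decoys are not", {
  g <- tiny_dataset()$genome
  for (s in c(g$features$spr, g$features$control))
    expect_equal(nrow(brute_locate(s, g)), 1L, info = s)
  for (s in g$features$decoy)
    expect_gte(nrow(brute_locate(s, g)), 2L)
})

test_that("reference sets follow the class conventions", {
  ds <- tiny_dataset()
  g <- ds$genome
  # tRNA references carry the post-transcriptional 3' CCA
  expect_equal(ds$refs$tRNA$seq, paste0(g$features$trna, "CCA"))
  # miRNA set holds mature and star sequences
  expect_setequal(ds$refs$miRNA$seq,
                  c(g$features$mirna_mature, g$features$mirna_star))
  # planted sncRNAs appear in no reference set
  refs_all <- unlist(lapply(ds$refs, `[[`, "seq"))
  for (s in g$features$spr) {
    expect_false(any(grepl(s, refs_all, fixed = TRUE)))
    expect_false(any(grepl(revcomp(s), refs_all, fixed = TRUE)))
  }
})

test_that("simulated libraries respect depth, length range, and the seed", {
  ds <- tiny_dataset()
  cfg <- ds$config
  sperm <- ds$counts[ds$counts$library_id == "sperm", ]
  expect_equal(sum(sperm$raw_count), cfg$library_depth)
  expect_gte(min(nchar(sperm$sequence)), cfg$fragment_length_range[1])
  expect_lte(max(nchar(sperm$sequence)), cfg$fragment_length_range[2])
  # reproducibility: identical config + seed => identical counts
  again <- simulate_library(ds$genome, "sperm", cfg)
  rownames(sperm) <- NULL
  expect_identical(again, sperm)
  expect_error(simulate_library(ds$genome, "sperm",
                                within_cfg(cfg, library_depth = 0)),
               "depth")
})

test_that("tail_probs of 1 on the empty suffix yields only canonical reads", {
  cfg <- within_cfg(tiny_config(seed = 4), tail_probs = setNames(1, ""))
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, "sperm", cfg)
  for (s in g$features$spr) {
    at_locus <- lib$sequence[startsWith(lib$sequence, s)]
    expect_equal(at_locus, s)
  }
})

test_that("the enriched library carries more sncRNA reads", {
  ds <- tiny_dataset()
  sp <- ds$counts[ds$counts$library_id == "sperm", ]
  te <- ds$counts[ds$counts$library_id == "testis", ]
  for (s in ds$genome$features$spr) {
    n_sp <- sum(sp$raw_count[sp$sequence == s])
    n_te <- sum(te$raw_count[te$sequence == s])
    expect_gt(n_sp, n_te * 10)
  }
})

test_that("an overfull genome errors out", {
  expect_error(
    simulate_genome(sim_config(seed = 1, genome_length = 6000L,
                               pirna_cluster_span = 4000L)),
    "genome too small")
})

test_that("simulations round-trip to disk", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  paths <- suppressMessages(write_simulation(ds, dir))
  fa <- read_fasta(paths[["genome"]])
  expect_equal(setNames(fa$seq, fa$id), ds$genome$seqs)
  bed <- read_bed(paths[["truth"]])
  expect_equal(bed$start, ds$genome$truth$start)
  expect_equal(bed$label, ds$genome$truth$label)
  expect_equal(read_counts_tsv(paths[["counts"]]), ds$counts)
  refs <- read_fasta(paths[["ref_tRNA"]])
  expect_equal(refs$seq, ds$refs$tRNA$seq)
})
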