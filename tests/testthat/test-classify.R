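# Exact-match classification: index queries, genome search, hierarchy.

test_that("index queries report every containing class", {
  ds <- tiny_dataset()
  idx <- build_exact_index(ds$refs)
  mature <- ds$genome$features$mirna_mature[1]
  expect_equal(query_index(idx, mature), "miRNA")
  inner <- substr(ds$genome$features$mrna[1], 101, 118)  # 18-mer inside mRNA
  expect_equal(query_index(idx, inner), "mRNA")
  set.seed(8)
  repeat {  # a random 25-mer absent from every reference (brute check)
    probe <- random_dna(25)
    refs_all <- unlist(lapply(ds$refs, `[[`, "seq"))
    if (!any(grepl(probe, refs_all, fixed = TRUE))) break
  }
  expect_length(query_index(idx, probe), 0)
})

test_that("classification follows the declared priority order", {
  shared <- random_dna(30)
  idx <- build_exact_index(list(tRNA = c(paste0(shared, "CCA")),
                                mRNA = c(paste0("AATT", shared))))
  genome <- c(chrX = random_dna(400))
  expect_equal(classify_read(shared, idx, genome), "tRNA")
  # removing the winning set moves the label down, never up
  idx2 <- build_exact_index(list(mRNA = c(paste0("AATT", shared))))
  expect_equal(classify_read(shared, idx2, genome), "mRNA")
})

test_that("reads off the references fall back to genome categories", {
  ds <- tiny_dataset()
  g <- ds$genome
  idx <- build_exact_index(ds$refs)
  expect_equal(as.character(classify_read(g$features$spr[1], idx, g, g$truth)),
               "genomic_unannotated")
  rep_frag <- substr(g$features$repeats[1], 10, 32)
  expect_equal(as.character(classify_read(rep_frag, idx, g, g$truth)),
               "repeat_associated")
  set.seed(21)
  repeat {
    nowhere <- random_dna(25)
    if (nrow(brute_locate(nowhere, g)) == 0) break
  }
  expect_equal(as.character(classify_read(nowhere, idx, g, g$truth)),
               "unmapped")
  expect_error(classify_read("", idx, g), "empty read")
})

test_that("genome search finds all exact hits on both strands", {
  ds <- tiny_dataset()
  g <- ds$genome
  expect_equal(nrow(locate_in_genome(g$features$spr[1], g)), 1L)
  expect_equal(nrow(locate_in_genome(g$features$decoy[1], g)), 2L)
  expect_error(locate_in_genome("ACGTACGT", g), "shorter than 13")
  # oracle equivalence against a naive double-strand scan
  set.seed(13)
  probes <- c(g$features$spr, g$features$decoy, g$features$pirna[1:3],
              substr(g$features$mrna[1], 50, 70),
              replicate(5, random_dna(sample(13:25, 1))))
  for (p in probes)
    expect_equal(locate_in_genome(p, g), brute_locate(p, g), info = p)
})

test_that("a reverse-complement palindrome planted once yields one hit per strand", {
  half <- "ACGTTGCA"
  pal <- paste0(half, revcomp(half))  # 16-nt RC palindrome
  set.seed(3)
  genome <- c(chrP = paste0(random_dna(200), pal, random_dna(200)))
  hits <- locate_in_genome(pal, genome)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(200L, 200L))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("reads containing N are dropped with a message", {
  ds <- tiny_dataset()
  idx <- build_exact_index(ds$refs)
  counts <- data.frame(sequence = c("ACGTNACGTACGTT", ds$genome$features$spr[1]),
                       library_id = "sperm", raw_count = c(3, 5),
                       stringsAsFactors = FALSE)
  expect_message(out <- classify_reads(counts, idx, ds$genome),
                 "dropping 1 read")
  expect_equal(nrow(out), 1L)
})

test_that("library summaries partition the reads", {
  ds <- tiny_dataset()
  idx <- build_exact_index(ds$refs)
  sperm <- ds$counts[ds$counts$library_id == "sperm", ]
  cl <- classify_reads(sperm, idx, ds$genome, ds$genome$truth)
  expect_false(any(is.na(cl$class)))          # every read gets one label
  summ <- classify_library(cl)
  expect_equal(sum(summ$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(summ$n_reads), sum(sperm$raw_count))
  # independent per-class tally
  recount <- tapply(cl$raw_count, as.character(cl$class), sum)
  for (cls in names(recount))
    expect_equal(summ$n_reads[summ$class == cls], unname(recount[cls]))
  # a library of only miRNA reads has miRNA fraction 1
  mir <- data.frame(sequence = ds$genome$features$mirna_mature,
                    library_id = "x",
                    raw_count = 10, stringsAsFactors = FALSE)
  cm <- classify_reads(mir, idx, ds$genome)
  sm <- classify_library(cm)
  expect_equal(sm$fraction[sm$class == "miRNA"], 1)
  expect_error(classify_library(cl[0, ]), "empty")
})
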