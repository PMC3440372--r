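# Candidate pipeline: filtering, unique-locus screen, windows, the
# end-to-end report.

test_that("candidate filter applies the length window and class exclusions", {
  classified <- data.frame(
    sequence = c(random_dna(21), random_dna(19), random_dna(22),
                 random_dna(24), random_dna(20)),
    class = c("genomic_unannotated", "genomic_unannotated", "miRNA",
              "genomic_unannotated", "unmapped"),
    stringsAsFactors = FALSE)
  kept <- candidate_filter(classified)
  expect_equal(kept$sequence, classified$sequence[1])
  expect_error(candidate_filter(classified, min_len = 23, max_len = 20),
               "min_len > max_len")
})

test_that("unique-locus screen keeps exactly single-hit reads", {
  ds <- tiny_dataset()
  g <- ds$genome
  reads <- data.frame(
    sequence = c(g$features$spr[1], g$features$decoy[1], random_dna(25)),
    stringsAsFactors = FALSE)
  hits <- sprfinder:::locate_reads(reads$sequence, g)
  out <- screen_unique(reads, hits)
  expect_equal(out$sequence, g$features$spr[1])
  expect_true(all(c("chrom", "start", "end", "strand") %in% names(out)))
  expect_error(screen_unique(reads), "no genomic hits")
})

test_that("windows are flank-extended, clipped, and sense-oriented", {
  set.seed(2)
  genome <- c(chrW = random_dna(1000))
  hit <- list(chrom = "chrW", start = 500L, end = 521L, strand = "+")
  win <- extract_window(hit, genome, flank = 140)
  expect_equal(nchar(win$seq), 301L)  # 140 + 21 + 140
  expect_equal(substr(win$seq, win$read_start, win$read_end),
               substr(genome[["chrW"]], 501, 521))
  # clipping at the chromosome start
  hit2 <- list(chrom = "chrW", start = 10L, end = 31L, strand = "+")
  win2 <- extract_window(hit2, genome, flank = 140)
  expect_equal(win2$start, 0L)
  expect_equal(win2$read_start, 11L)
  # minus-strand hits present the read in sense orientation
  read <- revcomp(substr(genome[["chrW"]], 301, 321))
  hit3 <- list(chrom = "chrW", start = 300L, end = 321L, strand = "-")
  win3 <- extract_window(hit3, genome, flank = 50)
  expect_equal(substr(win3$seq, win3$read_start, win3$read_end), read)
})

test_that("piRNA-cluster overlap is half-open and strand-agnostic", {
  ann <- data.frame(chrom = "chrS", start = 100L, end = 200L,
                    name = "piRNA_cluster:c", score = 0, strand = "+",
                    label = "piRNA_cluster", stringsAsFactors = FALSE)
  expect_true(annotate_pirna_locus(list(chrom = "chrS", start = 150,
                                        end = 170), ann))
  expect_true(annotate_pirna_locus(list(chrom = "chrS", start = 199,
                                        end = 220), ann))
  expect_false(annotate_pirna_locus(list(chrom = "chrS", start = 200,
                                         end = 220), ann))
  expect_true(annotate_pirna_locus(list(chrom = "chrS", start = 150,
                                        end = 170, strand = "-"), ann))
  expect_false(annotate_pirna_locus(list(chrom = "chrX", start = 150,
                                         end = 170), ann))
})

test_that("discovery recovers planted sncRNAs and rejects decoy/control", {
  ds <- tiny_dataset()
  g <- ds$genome
  sperm <- ds$counts[ds$counts$library_id == "sperm", ]
  rep <- suppressMessages(run_discovery(sperm, g, ds$refs, g$truth))
  spr_rna <- to_rna(g$features$spr)
  expect_true(all(spr_rna %in% rep$seq))
  spr_rows <- rep[rep$seq %in% spr_rna, ]
  expect_true(all(spr_rows$stem_loop))
  expect_true(all(spr_rows$in_pirna_locus))
  expect_false(any(to_dna(rep$seq) %in% g$features$decoy))
  ctrl <- rep[to_dna(rep$seq) %in% g$features$control, ]
  expect_true(nrow(ctrl) == 0 || !any(ctrl$stem_loop))
  # screening soundness: every reported sequence is unique genome-wide
  for (s in to_dna(rep$seq))
    expect_equal(nrow(brute_locate(s, g)), 1L, info = s)
  # report bookkeeping
  expect_true(all(rep$size >= 20 & rep$size <= 23))
  expect_equal(rep$size, nchar(to_dna(rep$seq)))
  # sorted with stem-loop candidates first, then by read support
  expect_true(all(diff(rep$stem_loop) <= 0))
  expect_equal(suppressMessages(run_discovery(sperm[0, ], g, ds$refs,
                                              g$truth)),
               rep[0, ])
})

test_that("widening the length window never removes report rows", {
  ds <- tiny_dataset()
  g <- ds$genome
  sperm <- ds$counts[ds$counts$library_id == "sperm", ]
  narrow <- suppressMessages(
    run_discovery(sperm, g, ds$refs, g$truth,
                  discovery_params(min_len = 21, max_len = 22)))
  wide <- suppressMessages(
    run_discovery(sperm, g, ds$refs, g$truth,
                  discovery_params(min_len = 20, max_len = 23)))
  expect_true(all(narrow$seq %in% wide$seq))
})
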