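# RPM normalization, enrichment ratios, 3' variant calling, histograms,
# amplicon sizing.

test_that("RPM is count per million library reads", {
  counts <- data.frame(
    sequence = c("ACGTACGTACGTA", "TTTTAAAACCCCG", "ACGTACGTACGTA"),
    library_id = c("sperm", "sperm", "testis"),
    raw_count = c(599, 1e7 - 599, 0), stringsAsFactors = FALSE)
  counts <- rbind(counts,
                  data.frame(sequence = "GGGGCCCCAAAAT", library_id = "testis",
                             raw_count = 50, stringsAsFactors = FALSE))
  r <- rpm_normalize(counts)
  expect_equal(r$rpm[1], 59.9)
  expect_equal(r$rpm[3], 0)
  for (lib in c("sperm", "testis"))
    expect_equal(sum(r$rpm[r$library_id == lib]), 1e6, tolerance = 1e-6)
  bad <- counts
  bad$raw_count[bad$library_id == "testis"] <- 0
  expect_error(rpm_normalize(bad), "zero total")
})

test_that("enrichment ratios reproduce the reported formatting", {
  expect_equal(enrichment_ratio(59.9, 0.4)$label, "150")
  r <- enrichment_ratio(35.9, 69.2)
  expect_equal(r$label, "0.52")
  expect_equal(format_ratio(r$value, decimals = 1), "0.5")
  expect_equal(enrichment_ratio(7.3, 7.3)$value, 1)
  expect_equal(enrichment_ratio(5, 0)$label, "inf")
  expect_equal(enrichment_ratio(0, 0)$label, "undefined")
})

# the printed locus context and its canonical read + eight 3' variants
spr12_context <- "CAGGGTGGGCGGGTCATGGGCTTTGAGCACTG"
spr12_reads <- c("CAGGGTGGGCGGGTCATGGGC",
                 "CAGGGTGGGCGGGTCATGGGCA",
                 "CAGGGTGGGCGGGTCATGGGCTT",
                 "CAGGGTGGGCGGGTCATGGGCT",
                 "CAGGGTGGGCGGGTCATGGGCAA",
                 "CAGGGTGGGCGGGTCATGGGCTA",
                 "CAGGGTGGGCGGGTCATGGGCG",
                 "CAGGGTGGGCGGGTCATGGGCAAA",
                 "CAGGGTGGGCGGGTCATGGGCC")

test_that("3' variants split into templated prefix and non-templated suffix", {
  v <- call_3prime_variants(data.frame(sequence = spr12_reads),
                            spr12_context)
  key <- setNames(v$nontemplated_suffix, v$sequence)
  expect_equal(unname(key[spr12_reads]),
               c("", "A", "", "", "AA", "A", "G", "AAA", "C"))
  tl <- setNames(v$templated_len, v$sequence)
  expect_equal(unname(tl[spr12_reads]), c(21, 21, 23, 22, 21, 22, 21, 21, 21))
  # reconstruction identity
  expect_equal(paste0(substr(v$sequence, 1, v$templated_len),
                      v$nontemplated_suffix), v$sequence)
  # maximality: the base after each templated prefix mismatches the genome
  withsuf <- v[nzchar(v$nontemplated_suffix), ]
  expect_true(all(substr(withsuf$sequence, withsuf$templated_len + 1,
                         withsuf$templated_len + 1) !=
                  substr(spr12_context, withsuf$templated_len + 1,
                         withsuf$templated_len + 1)))
  # sorted by templated length (desc)
  expect_true(all(diff(v$templated_len) <= 0))
})

test_that("variant calling validates its inputs", {
  expect_error(call_3prime_variants(data.frame(sequence = "TAGGG"),
                                    spr12_context),
               "position 1")
  expect_error(call_3prime_variants(data.frame(sequence = strrep("CA", 40)),
                                    spr12_context),
               "context shorter")
})

test_that("variant calling spreads per-library counts", {
  rl <- data.frame(sequence = rep(spr12_reads[1:2], 2),
                   library_id = rep(c("sperm", "testis"), each = 2),
                   raw_count = c(374, 224, 2, 7), stringsAsFactors = FALSE)
  v <- call_3prime_variants(rl, spr12_context)
  expect_equal(v$count_sperm[v$sequence == spr12_reads[2]], 224)
  expect_equal(v$count_testis[v$sequence == spr12_reads[1]], 2)
})

test_that("length histograms conserve totals", {
  one <- data.frame(sequence = random_dna(21), raw_count = 5)
  expect_equal(length_histogram(one),
               data.frame(length = 21L, count = 5))
  ds <- tiny_dataset()
  sperm <- ds$counts[ds$counts$library_id == "sperm", ]
  h <- length_histogram(sperm)
  expect_equal(sum(h$count), sum(sperm$raw_count))
  expect_gte(min(h$length), ds$config$fragment_length_range[1])
  expect_lte(max(h$length), ds$config$fragment_length_range[2])
})

test_that("poly(A) RT-PCR amplicon sizes follow the primer anatomy", {
  expect_equal(predict_polya_rtpcr_amplicon(21), 121)
  expect_equal(predict_polya_rtpcr_amplicon(22), 122)  # e.g. let-7a
  expect_equal(predict_polya_rtpcr_amplicon(0), 100)   # adapter only
  # compact (T)25 notation parses identically
  compact <- sub("T{25}", "(T)_25_", RTQ_PRIMER)
  expect_equal(predict_polya_rtpcr_amplicon(21, compact), 121)
  expect_error(predict_polya_rtpcr_amplicon(21, "TTTTT"), "cannot parse")
})
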