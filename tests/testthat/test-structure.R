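# Folding, hairpin decomposition, and the stem-containment criterion.

test_that("base-pair maximization handles canonical cases", {
  expect_equal(fold_nussinov("AAAAAAA")$dotbracket, ".......")
  expect_equal(sum(fold_nussinov("GGGAAAACCC")$pairs > 0) / 2, 3)
  # frozen from enumerate_structures_bruteforce("GCGAAAGC")
  expect_equal(sum(fold_nussinov("GCGAAAGC")$pairs > 0) / 2, 2)
  expect_error(fold_nussinov("ACGB"), "illegal character")
})

test_that("folder agrees with exhaustive enumeration on short sequences", {
  set.seed(31)
  for (i in 1:60) {
    sq <- random_dna(sample(8:14, 1))
    expect_equal(sum(fold_nussinov(sq)$pairs > 0) / 2,
                 enumerate_structures_bruteforce(sq),
                 info = sq)
  }
})

test_that("brute-force enumerator handles degenerate inputs", {
  expect_equal(enumerate_structures_bruteforce("ACGT"), 0L)
  expect_equal(enumerate_structures_bruteforce(""), 0L)
  expect_error(enumerate_structures_bruteforce(strrep("A", 17)), "too long")
})

test_that("produced structures satisfy the pair-table invariants", {
  set.seed(77)
  for (i in 1:50) {
    st <- fold_nussinov(random_dna(sample(30:70, 1)))
    p <- st$pairs
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))                 # involution
    op <- idx[p[idx] > idx]
    expect_true(all(p[op] - op - 1 >= 3))              # min hairpin loop
    # nesting: dot-bracket conversion errors on crossings
    expect_silent(pairs_to_dotbracket(p))
    expect_equal(dotbracket_to_pairs(st$dotbracket), p)
  }
})

test_that("rna_structure rejects invalid pair tables", {
  expect_error(rna_structure("ACGTACGT", c(5, 6, 0, 0, 1, 2, 0, 0)),
               "pseudoknot")
  expect_error(rna_structure("ACGTAC", c(2, 0, 0, 0, 0, 0)), "involution")
})

test_that("hairpin decomposition extends stems through interruptions", {
  st <- rna_structure("GGGGAAAACCCC", dotbracket_to_pairs("((((....))))"))
  hp <- find_hairpins(st)
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$n_pairs, 4L)
  expect_equal(c(hp$arm5_start, hp$arm5_end), c(1L, 4L))
  expect_equal(c(hp$loop_start, hp$loop_end), c(5L, 8L))
  expect_equal(c(hp$arm3_start, hp$arm3_end), c(9L, 12L))

  expect_equal(nrow(find_hairpins(rna_structure("ACGU", rep(0, 4)))), 0L)

  # two helices separated by a 2-nt interruption merge into one stem
  st2 <- rna_structure("GGAAGGAAACCAACC",
                       dotbracket_to_pairs("((..((...))..))"))
  hp2 <- find_hairpins(st2)
  expect_equal(nrow(hp2), 1L)
  expect_equal(hp2$n_pairs, 4L)
  expect_equal(c(hp2$arm5_start, hp2$arm5_end), c(1L, 6L))
  expect_equal(c(hp2$arm3_start, hp2$arm3_end), c(10L, 15L))
  # but not when the interruption exceeds the tolerance
  hp3 <- find_hairpins(st2, max_internal_loop = 1)
  expect_equal(hp3$n_pairs, 2L)
})

test_that("stem containment requires full containment in one arm", {
  # perfect 21-pair hairpin: read = entire 5' arm
  arm <- random_dna(21)
  seq <- paste0(arm, "AAAA", revcomp(arm))
  st <- fold_nussinov(seq)
  hp <- find_hairpins(st)
  sc <- stem_containment(hp, 1, 21)
  expect_true(sc$contained)
  expect_equal(sc$paired_fraction, 1.0)
  # read centered on the loop
  expect_false(stem_containment(hp, 19, 28)$contained)
  # read half in the arm, half outside the hairpin
  seq2 <- paste0(random_dna(30), seq, random_dna(30))
  st2 <- fold_nussinov(seq2)
  hp2 <- find_hairpins(st2)
  expect_false(stem_containment(hp2, 20, 40)$contained)
  expect_error(stem_containment(hp, 0, 10), "out of structure bounds")
})

test_that("stem containment is monotone in min_paired_frac", {
  set.seed(19)
  for (i in 1:25) {
    st <- fold_nussinov(random_dna(80))
    hp <- find_hairpins(st)
    lo <- stem_containment(hp, 30, 50, min_paired_frac = 0.3)$contained
    hi <- stem_containment(hp, 30, 50, min_paired_frac = 0.8)$contained
    expect_true(lo || !hi)  # raising the threshold never flips FALSE->TRUE
  }
})

test_that("longest_helix counts strictly stacked pairs", {
  st <- rna_structure("GGGGAAAACCCC", dotbracket_to_pairs("((((....))))"))
  expect_equal(longest_helix(st), 4L)
  expect_equal(longest_helix(rna_structure("AAAA", rep(0, 4))), 0L)
  # independent recount from the pair table
  set.seed(5)
  for (i in 1:40) {
    st <- fold_nussinov(random_dna(60))
    p <- st$pairs
    best <- 0L
    for (s in which(p > seq_along(p))) {
      if (s > 1 && p[s - 1] == p[s] + 1) next  # not a helix start
      len <- 1L
      while (s + len <= length(p) && p[s + len] == p[s] - len &&
             p[s + len] > s + len) len <- len + 1L
      best <- max(best, len)
    }
    expect_equal(longest_helix(st), best)
  }
})
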