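test_that("MFE fold reproduces the enumerated optimum on a stem-loop", {
  f <- mfe_fold("GGGAAAACCC")
  expect_equal(f$dotbracket, "(((....)))")
  expect_equal(f$pairs, matrix(c(0L, 1L, 2L, 9L, 8L, 7L), ncol = 2))
  o <- fold_exhaustive("GGGAAAACCC")
  expect_equal(f$energy, o$energy)
  expect_equal(f$energy, -1.75)
})

test_that("sequences with no complementary bases stay unpaired at energy 0", {
  f <- mfe_fold("AAAAAAAAAA")
  expect_equal(f$energy, 0)
  expect_equal(NROW(f$pairs), 0L)
  expect_equal(f$dotbracket, "..........")
})

test_that("fold engine matches exhaustive enumeration on random sequences", {
  withr::with_seed(101, {
    for (k in 1:40) {
      s <- random_rna(1, sample(10:16, 1))
      f <- mfe_fold(s)
      o <- fold_exhaustive(s)
      expect_equal(f$energy, o$energy, info = s)
      # the traced structure must itself score the reported energy
      expect_equal(structure_energy(s, f$pairs), f$energy, info = s)
    }
  })
})

test_that("optimal energy is reverse-complement symmetric without wobbles", {
  par <- energy_params(gu = FALSE)
  withr::with_seed(102, {
    for (k in 1:20) {
      s <- random_rna(1, sample(12:20, 1))
      expect_equal(mfe_fold(s, par)$energy,
                   mfe_fold(revcomp(s), par)$energy, info = s)
    }
  })
})

test_that("appending unpairable bases never lowers the optimal energy", {
  withr::with_seed(103, {
    for (k in 1:15) {
      s <- random_seq(1, sample(12:18, 1), c("A", "C", "G")) # U-free
      e0 <- mfe_fold(s)$energy
      e1 <- mfe_fold(paste0(s, strrep("A", 6)))$energy
      expect_gte(e1, e0 - 1e-9)
    }
  })
})

test_that("fold rejects invalid alphabets", {
  expect_error(mfe_fold("ACGUXACGUA"), "alphabet")
  expect_error(duplex_mfe("ACGU", "AC-GU"), "alphabet")
})

test_that("hairpin criteria separate stem-loops from other structures", {
  s <- small_sim()
  p <- s$sim$planted[1, ]
  f <- mfe_fold(p$precursor_seq)
  hc <- hairpin_check(f, c(7, 6 + nchar(p$mature_seq)))
  expect_true(hc$is_hairpin)
  expect_equal(hc$n_stems, 1L)
  expect_equal(hc$mature_arm, "5p")
  expect_gte(hc$mature_paired_frac, 0.6)

  # no stable stem
  weak <- mfe_fold("ACGUACGUACGUACGU")
  expect_false(hairpin_check(weak, c(2, 9))$is_hairpin)

  # two designed stems joined by a linker fold into two terminal loops
  stem <- function(x) paste0(x, "AAAA", dna_to_rna(revcomp(x)))
  two <- paste0(stem("GGAAGAGGAA"), "AAAAA", stem("AGGAGAAGGA"))
  f2 <- mfe_fold(two)
  hc2 <- hairpin_check(f2, c(1, 10))
  expect_equal(hc2$n_stems, 2L)
  expect_false(hc2$is_hairpin)
})

test_that("context extension returns the flanked and single-sided windows", {
  genome <- c(chr1 = random_seq(1, 400))
  w <- extend_context(genome, list(contig = "chr1", start = 100, end = 122,
                                   strand = "+"), flank = 60)
  full <- w[w$candidate == "full", ]
  expect_equal(c(full$wstart, full$wend), c(40L, 182L))
  expect_equal(nchar(full$seq), 142L)
  expect_false(full$truncated)
  expect_equal(substr(full$seq, full$mature_start, full$mature_end),
               substr(genome[[1]], 101, 122))

  # truncation at the contig start is flagged
  wt <- extend_context(genome, list(start = 10, end = 32, strand = "+"),
                       flank = 60)
  expect_true(wt$truncated[wt$candidate == "full"])
  expect_equal(wt$wstart[wt$candidate == "full"], 0L)

  # minus-strand hits give windows on the hit strand: the mature is a forward
  # substring of the oriented window
  hit_seq <- revcomp(substr(genome[[1]], 101, 122))
  wm <- extend_context(genome, list(start = 100, end = 122, strand = "-"),
                       flank = 20)
  fullm <- wm[wm$candidate == "full", ]
  expect_equal(substr(fullm$seq, fullm$mature_start, fullm$mature_end),
               hit_seq)
})

test_that("vienna output round-trips sequence, structure and energy", {
  f <- mfe_fold("GGGGAAAACCCC")
  path <- withr::local_tempfile(fileext = ".txt")
  write_vienna(list(x = f), path)
  lines <- readLines(path)
  expect_equal(lines[1], ">x")
  expect_equal(lines[2], f$seq)
  expect_match(lines[3], sprintf("(%.2f)", f$energy), fixed = TRUE)
})
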