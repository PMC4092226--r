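test_that("identical config and seed give byte-identical genome and reads", {
  cfg <- small_cfg()
  a <- sim_genome(cfg); b <- sim_genome(cfg)
  expect_identical(a, b)
  ra <- sim_reads(a, cfg); rb <- sim_reads(b, cfg)
  expect_identical(ra, rb)
})

test_that("simulated reads conserve totals and origin labels partition them", {
  s <- small_sim()
  expect_equal(nrow(s$reads), s$cfg$read_total)
  expect_equal(nrow(s$truth), s$cfg$read_total)
  expect_true(all(s$truth$origin %in%
    c("mir-mature", "mir-star", "pirna-like", "contaminant",
      "adaptor-artifact")))
  expect_equal(sum(table(s$truth$origin)), s$cfg$read_total)
  # per-miR counts sum to the miR-derived read total
  mir_reads <- sum(s$truth$origin %in% c("mir-mature", "mir-star"))
  per_mir <- table(s$truth$source[s$truth$origin %in%
                                    c("mir-mature", "mir-star")])
  expect_equal(sum(per_mir), mir_reads)
})

test_that("empty and infeasible locus configurations behave as specified", {
  cfg0 <- sim_config(n_mirs = 0L, n_known = 0L, n_pirna_loci = 0L,
                     genome_length = 1000L, read_total = 100L, seed = 1L)
  g <- sim_genome(cfg0)
  expect_equal(nrow(g$planted), 0L)
  expect_equal(nchar(g$genome[[1]]), 1000L)
  # packing 20 ~70 nt hairpins into 1 kb cannot satisfy non-overlap
  cfg_bad <- sim_config(n_mirs = 20L, n_known = 10L, genome_length = 1000L,
                        n_pirna_loci = 0L, seed = 1L)
  expect_error(sim_genome(cfg_bad), "infeasible packing")
})

test_that("every planted precursor folds into a passing hairpin", {
  s <- small_sim()
  for (i in seq_len(nrow(s$sim$planted))) {
    p <- s$sim$planted[i, ]
    hc <- hairpin_check(mfe_fold(p$precursor_seq),
                        c(7, 6 + nchar(p$mature_seq)))
    expect_true(hc$is_hairpin, info = p$name)
    expect_gte(nchar(p$precursor_seq), 60)
    expect_lte(nchar(p$precursor_seq), 120)
  }
})

test_that("read counts follow expression weights within binomial bounds", {
  cfg <- sim_config(genome_length = 2000L, n_mirs = 2L, n_known = 2L,
                    n_pirna_loci = 0L, read_total = 10000L,
                    contaminant_fraction = 0, artifact_fraction = 0,
                    pirna_share = 0, star_fraction = 0, lowq_fraction = 0,
                    error_rate = 0, seed = 5L)
  sim <- sim_genome(cfg)
  sim$planted$expression_weight <- c(9, 1)
  rr <- sim_reads(sim, cfg)
  n1 <- sum(rr$truth$source == sim$planted$name[1])
  ci <- qbinom(c(0.005, 0.995), 10000, 0.9)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])
  # error-free reads carry the planted mature verbatim at the 5' end
  mm <- rr$truth$origin == "mir-mature"
  ins <- rr$truth$insert[mm]
  expect_true(all(substr(rr$reads$seq[mm], 1, nchar(ins)) == ins))
})

test_that("qPCR generator inverts exactly without noise and rejects bad folds", {
  ct <- sim_qpcr(c(m = 4), n_individuals = 3, noise_sd = 0, indiv_sd = 0,
                 seed = 2)
  # 2 stages x (1 miRNA + U6) x 3 individuals x 3 technical reps
  expect_equal(nrow(ct), 2L * 2L * 3L * 3L)
  r <- ddct(ct)
  expect_equal(r$summary$mean_fold, 4)
  expect_error(sim_qpcr(c(m = -1)), "positive")
})

test_that("synthetic UTR contains one planted seed site per miRNA", {
  mirs <- c(a = "UAUCACAGCCAGCUUUGAUGAGC", b = "UGGAAGACUAGUGAUUUUGUUGU")
  utr <- sim_utr(mirs, seed = 3)
  sites <- scan_seed_sites(mirs, utr)
  expect_setequal(unique(sites$mirna), names(mirs))
  planted <- attr(utr, "planted_sites")
  expect_true(all(planted$start %in% sites$start))
})
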