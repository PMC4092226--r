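mk_reads <- function(seqs, q = 35L) {
  tibble::tibble(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
                 qual = strrep(intToUtf8(q + 33L), nchar(seqs)))
}

test_that("quality filter keeps good reads and drops low-quality and N reads", {
  reads <- mk_reads(c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
                      "ACGNACGTACGTACGTACGT"))
  reads$qual[2] <- strrep(intToUtf8(10L + 33L), 20L)
  out <- quality_filter(reads, min_mean_q = 20)
  expect_equal(out$id, "r001")
})

test_that("malformed FASTQ is rejected with the record index", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), path)
  expect_error(read_fastq(path), "record 2")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(read_fastq(path), "truncated")
})

test_that("FASTQ round-trips through write and read", {
  s <- small_sim()
  reads <- s$reads[1:50, ]
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  expect_equal(as.data.frame(read_fastq(path)), as.data.frame(reads))
})

test_that("adaptor trimming recovers inserts, flags artifacts, drops orphans", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  ins <- "ACGTACGTACGTACGTACGTA"
  reads <- mk_reads(c(
    paste0(ins, ad),                       # full adaptor at the 3' end
    substr(strrep(ad, 2), 1, 36),          # adaptor-adaptor ligation
    strrep("ACGT", 9)                      # no adaptor at all
  ))
  out <- trim_adaptor(reads, ad)
  expect_equal(out$trim_status, c("trimmed", "adaptor_artifact", "no_adaptor"))
  expect_equal(out$seq[1], ins)
})

test_that("error-free simulated reads recover their planted insert exactly", {
  cfg <- sim_config(genome_length = 6000L, n_mirs = 6L, n_known = 4L,
                    n_pirna_loci = 5L, read_total = 5000L, error_rate = 0,
                    lowq_fraction = 0, seed = 19L)
  sim <- sim_genome(cfg)
  rr <- sim_reads(sim, cfg)
  out <- trim_adaptor(rr$reads, cfg$adaptor)
  real <- rr$truth$origin != "adaptor-artifact"
  expect_true(all(out$trim_status[real] == "trimmed"))
  expect_identical(out$seq[real], rr$truth$insert[real])
  expect_true(all(out$trim_status[!real] == "adaptor_artifact"))
})

test_that("length filter is inclusive at 15 and 30 and idempotent", {
  tags <- tibble::tibble(seq = strrep("A", c(14, 15, 22, 30, 31)),
                         count = 5L)
  out <- length_filter(tags)
  expect_equal(nchar(out$seq), c(15L, 22L, 30L))
  expect_identical(length_filter(out), out)
})

test_that("collapse produces deterministic counted tags and conserves reads", {
  reads <- tibble::tibble(seq = c(strrep("A", 20), strrep("A", 20),
                                  strrep("C", 20)))
  tags <- collapse_reads(reads)
  expect_equal(tags$count, c(2L, 1L))
  expect_equal(tags$seq[1], strrep("A", 20))
  expect_equal(sum(tags$count), nrow(reads))
  expect_equal(nrow(collapse_reads(reads[0, ])), 0L)

  s <- small_run()
  expect_equal(
    sum(collapse_reads(tibble::tibble(seq = small_sim()$reads$seq))$count),
    nrow(small_sim()$reads))
})

test_that("copy filter removes two-copy tags, keeps three-copy tags", {
  tags <- tibble::tibble(seq = c("A", "C", "G"), count = c(2L, 3L, 10L))
  out <- copy_filter(tags)
  expect_equal(out$count, c(3L, 10L))
  expect_identical(copy_filter(out), out)          # idempotent
  expect_identical(copy_filter(tags, min_copy = 1L), tags)
})

test_that("contaminant filter removes full-length matches up to 1 mismatch", {
  ref <- list(Rfam = tibble::tibble(name = "trna1", seq = strrep("ACGGT", 20)))
  exact <- substr(strrep("ACGGT", 20), 11, 32)
  mm1 <- exact; substr(mm1, 5, 5) <- "A"       # vs ref G at that position
  mm2 <- mm1; substr(mm2, 9, 9) <- "C"
  tags <- tibble::tibble(seq = c(exact, mm1, mm2, strrep("T", 22)))
  out <- contaminant_filter(tags, ref, mm = 1L)
  expect_equal(out$data$seq, c(mm2, strrep("T", 22)))
  expect_equal(out$removed$n_unique[out$removed$class == "Rfam"], 2L)
  # empty class is skipped with a message
  expect_message(
    contaminant_filter(tags, list(empty = tibble::tibble(name = character(),
                                                         seq = character())),
                       mm = 1L),
    "skipped")
})

test_that("length histogram counts reads and unique tags per length", {
  tags <- tibble::tibble(seq = strrep("A", 22), count = 5L)
  h <- length_histogram(tags)
  expect_equal(h$reads[h$length == 22], 5)
  expect_equal(h$unique[h$length == 22], 1)
  expect_equal(sum(h$reads), 5)
  h0 <- length_histogram(tags[0, ])
  expect_true(all(h0$reads == 0) && all(h0$unique == 0))
  expect_error(length_histogram(tibble::tibble(seq = strrep("A", 31),
                                               count = 1L)), "window")
})

test_that("the filter report is monotone and counts match the stage outputs", {
  run <- small_run()
  rep <- run$pp$report
  expect_true(all(diff(rep$reads) <= 0))
  expect_true(all(rep$unique <= rep$reads))
  expect_equal(rep$reads[rep$stage == "copy"], sum(run$pp$tags$count))
  expect_equal(rep$unique[rep$stage == "copy"], nrow(run$pp$tags))
})

test_that("planted low-quality and contaminant fractions are recovered", {
  s <- small_sim()
  rep <- small_run()$pp$report
  # quality stage drop ~ lowq_fraction of all reads
  dropped <- rep$reads[rep$stage == "raw"] - rep$reads[rep$stage == "quality"]
  ci <- qbinom(c(0.005, 0.995), s$cfg$read_total, s$cfg$lowq_fraction)
  expect_gte(dropped, ci[1]); expect_lte(dropped, ci[2])
  # contaminant removals match the planted contaminant reads that survive
  # the earlier stages (exact matching suffices at error_rate > 0 because
  # removal allows 1 mismatch)
  removed <- sum(small_run()$pp$contaminants_removed$n_reads)
  expected <- sum(s$truth$origin == "contaminant" & !s$truth$low_quality)
  expect_gt(removed, 0.9 * expected)
  expect_lte(removed, expected * 1.02 + 10)
})
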