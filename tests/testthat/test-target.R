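test_that("seed-site scan finds exact reverse complements of the seed", {
  mir <- c(m = "UAUCACAGCCAGCUUUGAUGAGC") # seed AUCACAG
  utr1 <- c(u = paste0("AAAA", "CUGUGAU", "AAAA"))
  hits <- scan_seed_sites(mir, utr1)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(4L, 11L))
  expect_equal(hits$site_seq, "CUGUGAU")
  expect_equal(hits$seed_class, "K-box")

  # no complementary 7-mer anywhere
  expect_equal(nrow(scan_seed_sites(mir, c(u = strrep("A", 50)))), 0L)

  # the same 7-mer at three positions gives three distinct spans
  utr3 <- c(u = paste0("GG", strrep(paste0("CUGUGAU", "CC"), 3)))
  h3 <- scan_seed_sites(mir, utr3)
  expect_equal(nrow(h3), 3L)
  expect_equal(dplyr::n_distinct(h3$start), 3L)
})

test_that("every reported duplex site is seed-complementary", {
  s <- small_sim()
  mirs <- setNames(dna_to_rna(s$sim$planted$mature_seq[1:5]),
                   s$sim$planted$name[1:5])
  utr <- sim_utr(mirs, seed = 21)
  tg <- scan_targets(mirs, utr)
  expect_gt(nrow(tg), 0)
  for (r in seq_len(nrow(tg))) {
    seed7 <- substr(mirs[[tg$mirna[r]]], 2, 8)
    site <- substr(utr$seq[1], tg$start[r] + 1, tg$end[r])
    expect_equal(site, dna_to_rna(revcomp(seed7)))
  }
  expect_true(all(tg$duplex_mfe <= 0))
})

test_that("duplex energy of a perfect helix equals the summed stack terms", {
  par <- energy_params()
  x <- "GGCAUCGAAC"
  y <- dna_to_rna(revcomp(x))
  d <- duplex_mfe(x, y, par)
  bx <- strsplit(x, "")[[1]]; by <- strsplit(y, "")[[1]]
  hand <- sum(vapply(1:9, function(i) {
    par$stack[paste0(bx[i], by[11 - i]), paste0(bx[i + 1], by[10 - i])]
  }, numeric(1)))
  expect_equal(d$energy, hand)
  expect_equal(NROW(d$pairs), 10L)
})

test_that("strands with no complementary bases score zero", {
  d <- duplex_mfe("AAAA", "AAAA")
  expect_equal(d$energy, 0)
  expect_equal(NROW(d$pairs), 0L)
})

test_that("duplex engine matches exhaustive enumeration on random pairs", {
  withr::with_seed(104, {
    for (k in 1:30) {
      a <- random_rna(1, sample(8:12, 1))
      b <- random_rna(1, sample(8:12, 1))
      expect_equal(duplex_mfe(a, b)$energy, duplex_exhaustive(a, b)$energy,
                   info = paste(a, b))
    }
  })
})

test_that("the perfect complement is the optimal partner", {
  withr::with_seed(105, {
    for (k in 1:10) {
      x <- random_rna(1, 10)
      e_rc <- duplex_mfe(x, dna_to_rna(revcomp(x)))$energy
      for (j in 1:5) {
        y <- random_rna(1, 10)
        expect_lte(e_rc, duplex_mfe(x, y)$energy)
      }
    }
  })
})

test_that("target ranking minimises energy with coordinate tie-breaks", {
  sites <- tibble::tibble(
    mirna = c("a", "a", "b", "c", "c"),
    utr_id = "u",
    start = c(10L, 40L, 5L, 400L, 100L),
    end = c(17L, 47L, 12L, 407L, 107L),
    seed_class = "generic",
    duplex_mfe = c(-22.1, -15.0, -25.0, -20.0, -20.0)
  )
  rk <- rank_targets(sites)
  expect_equal(rk$mirna, c("b", "a", "c"))
  expect_equal(rk$best_mfe, c(-25.0, -22.1, -20.0))
  expect_equal(rk$start[rk$mirna == "c"], 100L) # equal mfe: position wins
})

test_that("in-silico PCR reports the amplicon delimited by the primers", {
  withr::with_seed(106, {
    mid <- random_seq(1, 200)
    fwd <- "CCTCTTTCTCGTGAGTGTC"
    rev <- "ATTCTTCTAACATTTGCGT"
    tpl <- paste0(random_seq(1, 37), fwd, mid, revcomp(rev),
                  random_seq(1, 41))
    pr <- pcr_product(tpl, fwd, rev)
    expect_equal(nrow(pr), 1L)
    expect_equal(pr$length, nchar(fwd) + 200L + nchar(rev))
    expect_equal(pr$start, 37L)
    expect_true(startsWith(pr$seq, fwd))
    expect_true(endsWith(pr$seq, revcomp(rev)))
  })
})
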