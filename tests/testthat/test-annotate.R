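toy_refset <- function() {
  # one known miRNA planted in a small genome, plus a clade-only mature
  mat <- "TGAGGTAGTAGGTTGTATAGTT"
  pad <- "GCATCG"
  pre <- paste0(pad, mat, "AACCACACAAC",
                as.character(revcomp(mat)), revcomp(pad))
  genome <- c(chr1 = paste0(random_seq(1, 300), pre, random_seq(1, 300)))
  reference_set(
    species_mature = tibble::tibble(name = "esi-let-7", seq = mat),
    species_precursor = tibble::tibble(name = "esi-let-7-pre", seq = pre),
    clade_mature = tibble::tibble(name = c("cla-let-7", "cla-miR-x"),
                                  seq = c(mat, "ACGGCTAGCTAGGCTAGGCTAA")),
    genome = genome
  )
}

test_that("tags map to references and to both genome strands", {
  withr::with_seed(11, {
    rs <- toy_refset()
    mat <- rs$species_mature$seq[1]
    fwd_window <- substr(rs$genome[[1]], 151, 172)
    tags <- tibble::tibble(
      tag_id = c("t1", "t2", "t3"),
      seq = c(mat, as.character(revcomp(fwd_window)), strrep("ACGT", 6)),
      count = c(10L, 5L, 3L)
    )
    prof <- map_tags(tags, rs)
    h1 <- prof$ref_hits[prof$ref_hits$tag_id == "t1", ]
    expect_true(any(h1$ref_name == "esi-let-7" & h1$mismatches == 0))
    g2 <- prof$genome_hits[prof$genome_hits$tag_id == "t2", ]
    expect_equal(g2$strand, "-")
    expect_equal(c(g2$start, g2$end), c(150L, 172L))
    # the known precursor locus is located and flagged
    g1 <- prof$genome_hits[prof$genome_hits$tag_id == "t1", ]
    expect_true(all(g1$known_overlap))
  })
})

test_that("classification follows the five-group decision order", {
  withr::with_seed(12, {
    rs <- toy_refset()
    mat <- rs$species_mature$seq[1]
    tags <- tibble::tibble(
      tag_id = c("known", "clade_only", "nohit"),
      seq = c(mat, "ACGGCTAGCTAGGCTAGGCTAA", strrep("TGCA", 6)),
      count = c(10L, 5L, 3L)
    )
    prof <- map_tags(tags, rs)
    calls <- classify_tags(tags, prof, rs)
    expect_equal(calls$group, c(1L, 4L, NA))
    expect_equal(calls$status, c("known", "known", "unclassified"))
    expect_equal(calls$assigned_name[1], "esi-let-7")
    expect_equal(calls$assigned_name[2], "cla-miR-x")
  })
})

test_that("a genome-only tag at a hairpin locus is a group-5 novel candidate", {
  s <- small_sim()
  run <- small_run()
  novel <- s$sim$planted[!s$sim$planted$known, ]
  m <- run$ann$calls[run$ann$calls$seq %in% novel$mature_seq, ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$group == 5L))
  expect_true(all(m$status == "novel-candidate"))
  expect_true(all(grepl("^novel-", m$assigned_name)))
})

test_that("groups partition classified tags and are input-order invariant", {
  run <- small_run()
  calls <- run$ann$calls
  expect_equal(nrow(calls), nrow(small_run()$pp$tags))
  expect_true(all(is.na(calls$group) | calls$group %in% 1:5))
  expect_true(all(calls$status[is.na(calls$group)] == "unclassified"))
  expect_true(all(calls$status[!is.na(calls$group)] != "unclassified"))
  # group counts sum to classified tags
  expect_equal(sum(run$ann$group_counts$unique),
               sum(!is.na(calls$group)))

  # shuffling the tag order changes nothing but the order
  s <- small_sim()
  tags <- small_run()$pp$tags
  withr::with_seed(1, perm <- sample(nrow(tags)))
  ann2 <- annotate_tags(tags[perm, ], s$refset)
  a <- dplyr::arrange(calls, tag_id)
  b <- dplyr::arrange(ann2$calls, tag_id)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("seed families group identical seeds and split different ones", {
  calls <- tibble::tibble(
    tag_id = c("a", "b", "c"),
    seq = c("TGAGGTAGTAGGTTGTATAGTT",  # same seed as b
            "TGAGGTAGTACCAAGTCCCGGT",
            "TGACGTAGTAGGTTGTATAGTT"), # one seed mismatch
    count = 3L, group = 1L, status = "known",
    assigned_name = c("m1", "m2", "m3")
  )
  fam <- assign_family(calls)
  expect_equal(fam$family[1], fam$family[2])
  expect_false(fam$family[1] == fam$family[3])
  expect_equal(fam$family[1], "GAGGUAG")

  # planted distinct seeds are all recovered on simulated data
  s <- small_sim(); run <- small_run()
  known <- s$sim$planted[s$sim$planted$known, ]
  called <- run$ann$calls[run$ann$calls$seq %in% known$mature_seq, ]
  expect_equal(dplyr::n_distinct(called$family),
               dplyr::n_distinct(substr(known$mature_seq, 2, 8)))
})

test_that("star tags are called on the arm opposite the mature", {
  s <- small_sim(); run <- small_run()
  calls <- run$ann$calls
  known_star <- s$sim$planted$star_seq[s$sim$planted$known]
  stars <- calls[calls$seq %in% known_star, ]
  expect_gt(nrow(stars), 0)
  expect_true(all(stars$status == "star"))
  expect_true(all(stars$arm == "3p"))
  expect_true(all(grepl("\\*$", stars$assigned_name)))
  # mature-arm tags are never stars
  matures <- calls[calls$seq %in% s$sim$planted$mature_seq, ]
  expect_false(any(matures$status == "star"))
})
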