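test_that("the worked ddCt example recovers a fold change of 4", {
  r <- ddct(worked_ct())
  expect_equal(r$summary$mean_fold, 4)
  expect_equal(r$summary$se_fold, 0)
  expect_equal(unique(r$per_sample$fold[r$per_sample$stage == "MI"]), 4)
})

test_that("identical Ct across stages gives fold 1", {
  ct <- worked_ct() |> dplyr::mutate(ct = ifelse(target == "U6", 15, 20))
  r <- ddct(ct)
  expect_equal(r$summary$mean_fold, 1)
  expect_false(r$summary$significant)
})

test_that("near-null data gives fold near 1 and a non-significant test", {
  ct <- sim_qpcr(c(m = 1), n_individuals = 4, noise_sd = 0.05, seed = 31)
  r <- ddct(ct)
  expect_lt(abs(log2(r$summary$mean_fold)), 0.3)
  expect_gt(r$summary$p_value, 0.05)
})

test_that("ddCt is invariant to a shared shift of miRNA and U6 Ct values", {
  ct <- sim_qpcr(c(m = 4), n_individuals = 4, noise_sd = 0.2, seed = 32)
  r1 <- ddct(ct)
  shifted <- ct |> dplyr::mutate(ct = ct + ifelse(individual == "ind01", 3, 0))
  r2 <- ddct(shifted)
  expect_equal(r1$summary$mean_fold, r2$summary$mean_fold)
  expect_equal(r1$summary$p_value, r2$summary$p_value)
})

test_that("reference-stage folds centre at 1 and U6-less samples are dropped", {
  ct <- sim_qpcr(c(m = 4), n_individuals = 4, noise_sd = 0.2, seed = 33)
  r <- ddct(ct)
  gv <- r$per_sample[r$per_sample$stage == "GV", ]
  expect_equal(mean(gv$ddct), 0)
  expect_equal(exp(mean(log(gv$fold))), 1)

  ct_missing <- ct[!(ct$individual == "ind01" & ct$stage == "MI" &
                       ct$target == "U6"), ]
  expect_message(r2 <- ddct(ct_missing), "excluded")
  expect_equal(r2$summary$n, 3L)
  expect_error(ddct(ct |> dplyr::mutate(ct = ct + 50)), "Ct values")
})

test_that("tidy and glance summarise ddct fits", {
  r <- ddct(worked_ct())
  td <- tidy(r)
  expect_true(all(c("estimate", "p.value") %in% names(td)))
  expect_equal(td$estimate, 4)
  gl <- glance(r)
  expect_equal(gl$n_mirnas, 1L)
  expect_equal(gl$reference_stage, "GV")
})

test_that("luciferase ratios normalise to the negative-control mean", {
  rec <- tibble::tibble(
    construct = "wt",
    mimic = rep(c("NC", "m1"), each = 2),
    rep = c(1, 2, 1, 2),
    firefly = c(1000, 1000, 1000, 1000),
    renilla = c(500, 500, 1000, 1000)
  )
  r <- luciferase_ratios(rec, method = "none")
  expect_equal(unique(r$wells$rel_activity[r$wells$mimic == "NC"]), 1)
  expect_equal(unique(r$wells$rel_activity[r$wells$mimic == "m1"]), 0.5)
  expect_error(
    luciferase_ratios(rec |> dplyr::mutate(renilla = c(0, 500, 1, 1))),
    "non-positive")
})

test_that("a null luciferase plate shows no significant knockdown", {
  kd0 <- c(NC = 0, a = 0, b = 0, c = 0, d = 0)
  rec <- sim_luciferase(knockdown = kd0, seed = 12)
  r <- luciferase_ratios(rec)
  expect_gt(r$anova$p_value, 0.05)
  expect_false(any(r$comparisons$significant))
})

test_that("planted knockdowns are detected and inert mimics are not", {
  rec <- sim_luciferase(seed = 1)
  r <- luciferase_ratios(rec)
  cmp <- r$comparisons
  expect_true(all(cmp$significant[cmp$mimic %in% c("miR-2", "miR-133")]))
  expect_false(any(cmp$significant[cmp$mimic %in% c("miR-7", "miR-79")]))
  expect_lt(r$anova$p_value, 0.05)
  # estimates reflect the 40% knockdown
  expect_lt(max(cmp$estimate[cmp$mimic %in% c("miR-2", "miR-133")]), 0.8)
  td <- tidy(r)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
})
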