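make_cq <- function(construct_id, uncompeted, competed, batch = "batch1") {
  dplyr::bind_rows(
    tibble::tibble(construct_id = construct_id, condition = "uncompeted",
                   replicate = seq_along(uncompeted), batch = batch,
                   cq = uncompeted),
    tibble::tibble(construct_id = construct_id, condition = "competed",
                   replicate = seq_along(competed), batch = batch,
                   cq = competed)
  )
}

test_that("batch normalisation recentres batches and preserves differences", {
  tbl <- dplyr::bind_rows(
    make_cq("a", c(19, 21), c(23, 25), batch = "b1"),   # batch mean 22
    make_cq("a", c(17, 19), c(21, 23), batch = "b2")    # batch mean 20
  )
  norm <- normalize_batches(tbl)
  expect_equal(mean(norm$cq), mean(tbl$cq))
  expect_equal(norm$cq[norm$batch == "b1"], tbl$cq[tbl$batch == "b1"] - 1)
  expect_equal(norm$cq[norm$batch == "b2"], tbl$cq[tbl$batch == "b2"] + 1)
  # within-batch pairwise differences are exactly preserved
  for (b in c("b1", "b2")) {
    expect_equal(diff(norm$cq[norm$batch == b]), diff(tbl$cq[tbl$batch == b]))
  }
  # single batch: unchanged
  one <- make_cq("a", c(20, 21), c(24, 25))
  expect_equal(normalize_batches(one)$cq, one$cq)
})

test_that("normalising simulated batch offsets recovers the offset-free data", {
  p <- demo_protein()
  truth <- demo_truth()
  plan <- plan_refinement(p, list(start = 1, end = 11))
  with_off <- simulate_cq(plan, p, truth,
                          sim_config(noise_sd = 0, batch_offsets = c(0.7, -0.7),
                                     seed = 3))
  no_off <- simulate_cq(plan, p, truth,
                        sim_config(noise_sd = 0, batch_offsets = c(0, 0),
                                   seed = 3))
  expect_equal(normalize_batches(with_off)$cq, no_off$cq, tolerance = 1e-12)
})

test_that("delta-Cq pairs conditions and propagates the uncertainty", {
  res <- delta_cq(make_cq("a", c(20, 20), c(24, 24)))
  expect_equal(res$delta_cq_mean, 4)
  expect_equal(res$delta_cq_sd, 0)
  expect_equal(res$n_pairs, 2L)
  # 3-4-5 identity: sds 0.3 and 0.4 propagate to 0.5
  u <- c(19.7, 20, 20.3); k <- c(23.6, 24, 24.4)
  expect_equal(sd(u), 0.3); expect_equal(sd(k), 0.4)
  res2 <- delta_cq(make_cq("a", u, k))
  expect_equal(res2$delta_cq_sd, 0.5)
  expect_equal(res2$delta_cq_mean, mean(unlist(res2$replicate_deltas)))
})

test_that("constructs missing a condition are excluded with a named reason", {
  tbl <- dplyr::bind_rows(
    make_cq("a", c(20, 20), c(24, 24)),
    tibble::tibble(construct_id = "b", condition = "uncompeted",
                   replicate = 1:2, batch = "batch1", cq = c(20, 20))
  )
  res <- delta_cq(tbl)
  expect_false(res$excluded[res$construct_id == "a"])
  expect_true(res$excluded[res$construct_id == "b"])
  expect_equal(res$exclusion_reason[res$construct_id == "b"],
               "incomplete conditions")
})

test_that("delta-Cq cancels per-batch offsets through within-batch pairing", {
  p <- demo_protein()
  truth <- demo_truth()
  plan <- plan_refinement(p, list(start = 1, end = 11))
  cfg <- sim_config(noise_sd = 0.2, batch_offsets = c(1.3, -0.8), seed = 11)
  cq <- simulate_cq(plan, p, truth, cfg)
  direct <- delta_cq(cq)
  normed <- delta_cq(normalize_batches(cq))
  expect_equal(direct$delta_cq_mean, normed$delta_cq_mean, tolerance = 1e-12)
})

test_that("Tukey fence flags only high-side sd outliers", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("a", c(20.0, 20.2), c(23.0, 23.2)),
    make_cq("b", c(20.0, 20.25), c(23.0, 23.25)),
    make_cq("c", c(20.0, 20.3), c(23.0, 23.3)),
    make_cq("d", c(20.0, 20.28), c(23.0, 23.28)),
    make_cq("e", c(19.0, 21.0), c(21.0, 25.0))
  ))
  flagged <- flag_sd_outliers(res)
  expect_equal(flagged$construct_id[flagged$excluded], "e")
  expect_equal(flagged$exclusion_reason[flagged$excluded],
               "outlying sd (Tukey fence)")
  # direct fence computation agrees
  sds <- res$delta_cq_sd
  fence <- quantile(sds, 0.75, names = FALSE) +
    1.5 * diff(quantile(sds, c(0.25, 0.75), names = FALSE))
  expect_identical(flagged$excluded, sds > fence)

  # all-equal sds: IQR = 0 and nothing exceeds the fence
  eq <- res
  eq$delta_cq_sd <- rep(0.3, 5)
  expect_false(any(flag_sd_outliers(eq)$excluded))

  # monotone sds without a gap: none flagged
  mono <- res
  mono$delta_cq_sd <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_false(any(flag_sd_outliers(mono)$excluded))

  expect_warning(flag_sd_outliers(res[1:3, ]), "fewer than 4")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("null", c(20, 20.1, 19.9), c(20.05, 19.9, 20.1)),
    make_cq("hit", c(20, 20.1, 19.9), c(24.0, 24.1, 23.85))
  ))
  cmp <- compare_constructs(res, alpha = 0.1)
  deltas <- res$replicate_deltas
  tt <- stats::t.test(deltas[[2]], deltas[[1]], var.equal = TRUE)
  expect_equal(cmp$anova$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$anova$p_value, tt$p.value, tolerance = 1e-10)
  expect_true(cmp$pairwise$significant)
  expect_equal(cmp$pairwise$mean_diff,
               mean(deltas[[2]]) - mean(deltas[[1]]), tolerance = 1e-10)
})

test_that("clearly separated groups are Tukey-significant at alpha 0.1", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("zero", c(20, 20, 20), c(20, 20, 20) + c(0, 0.05, -0.05)),
    make_cq("four", c(20, 20, 20), c(24, 24.1, 23.9))
  ))
  cmp <- compare_constructs(res)
  expect_lt(cmp$anova$p_value, 1e-4)
  expect_true(all(cmp$pairwise$significant))
})

test_that("identical constant groups yield a degenerate, non-significant report", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("a", c(20, 20), c(24, 24)),
    make_cq("b", c(21, 21), c(25, 25)),
    make_cq("c", c(19, 19), c(23, 23))
  ))
  cmp <- compare_constructs(res)
  expect_true(is.na(cmp$anova$statistic))
  expect_false(any(cmp$pairwise$significant))
  expect_equal(nrow(cmp$pairwise), 3L)
})

test_that("comparison validates replication and reports offenders by name", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("a", c(20, 20), c(24, 24)),
    make_cq("solo", 20, 24.2)
  ))
  expect_error(compare_constructs(res), "solo")
  only <- delta_cq(make_cq("a", c(20, 20), c(24, 24)))
  expect_error(compare_constructs(only), "at least 2")
})

test_that("tidy and glance expose the comparison tables", {
  res <- delta_cq(dplyr::bind_rows(
    make_cq("a", c(20, 20, 20.1), c(20.1, 20, 19.95)),
    make_cq("b", c(20, 20.1, 19.9), c(23.9, 24, 24.1)),
    make_cq("c", c(20, 20.1, 19.9), c(23.8, 24.2, 24))
  ))
  cmp <- compare_constructs(res)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("construct_a", "construct_b", "mean_diff", "adjusted_p",
                     "significant"))
  expect_equal(nrow(td), 3L)
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_significant_pairs, sum(td$significant))
})

test_that("Cq tables round-trip through TSV and validate their schema", {
  tbl <- make_cq("a", c(20, 21), c(24, 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(tbl, path)
  back <- read_cq_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_error(delta_cq(tbl[0, ]), "empty")
  bad <- tbl; bad$condition[1] <- "mock"
  expect_error(delta_cq(bad), "unknown condition")
  dup <- dplyr::bind_rows(tbl, tbl[1, ])
  expect_error(normalize_batches(dup), "duplicate")
})
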