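test_that("initial partition reproduces the 31 -> 3x13 overlapping tiling", {
  p <- demo_protein()
  plan <- initial_partition(p, k = 3, segment_length = 13)
  expect_equal(plan$start_repeat, c(1L, 10L, 19L))
  expect_equal(plan$end_repeat, c(13L, 22L, 31L))
  expect_equal(plan_params(plan)$overlaps, c(4L, 4L))
  # segment 3 spans the loopout: 13 repeats + 1 pseudo-unit
  expect_equal(plan$n_units, c(13L, 13L, 14L))
})

test_that("partition overlaps are even, cover every repeat, and stay sorted", {
  expect_equal(
    as.data.frame(initial_partition(10, k = 2, segment_length = 5))[c("start_repeat", "end_repeat")],
    data.frame(start_repeat = c(1L, 6L), end_repeat = c(5L, 10L)))
  plan6 <- initial_partition(10, k = 2, segment_length = 6)
  expect_equal(plan6$start_repeat, c(1L, 5L))
  expect_equal(plan6$end_repeat, c(6L, 10L))
  expect_equal(plan_params(plan6)$overlaps, 2L)
  # property: coverage and sortedness over many feasible shapes
  for (R in c(7, 12, 23, 31)) {
    for (k in 2:4) {
      s <- ceiling((R + (k - 1) * 2) / k)
      if (k * s < R || s > R) next
      plan <- initial_partition(R, k = k, segment_length = s)
      covered <- sort(unique(unlist(Map(seq, plan$start_repeat, plan$end_repeat))))
      expect_identical(covered, seq_len(R))
      expect_true(!is.unsorted(plan$start_repeat))
      expect_equal(sum(plan_params(plan)$overlaps), k * s - R)
    }
  }
  expect_error(initial_partition(31, k = 2, segment_length = 13), "infeasible")
})

test_that("pruning distrusts negative-window edges and splits windows", {
  got <- prune_candidates(data.frame(start = c(1, 19), end = c(13, 31)),
                          data.frame(start = 10, end = 22), edge_margin = 2)
  expect_equal(got$start, c(1L, 21L))
  expect_equal(got$end, c(11L, 31L))
  expect_equal(got$n_repeats, c(11L, 11L))
  # nothing to prune
  none <- prune_candidates(data.frame(start = 1, end = 13), NULL, 5)
  expect_equal(none[c("start", "end")], tibble::tibble(start = 1L, end = 13L))
  # zero margin subtracts the whole negative window, splitting the positive
  split <- prune_candidates(data.frame(start = 1, end = 10),
                            data.frame(start = 4, end = 7), edge_margin = 0)
  expect_equal(split$start, c(1L, 8L))
  expect_equal(split$end, c(3L, 10L))
  # a positive wholly inside a trusted core yields nothing
  gone <- prune_candidates(data.frame(start = 5, end = 6),
                           data.frame(start = 2, end = 9), edge_margin = 1)
  expect_equal(nrow(gone), 0L)
})

test_that("pruned windows never contain trusted-core units and are maximal", {
  set.seed(42)
  for (rep in 1:30) {
    pos <- data.frame(start = s <- sample(1:20, 2), end = s + sample(3:10, 2))
    neg <- data.frame(start = ns <- sample(1:25, 2), end = ns + sample(2:8, 2))
    e <- sample(0:3, 1)
    got <- prune_candidates(pos, neg, e)
    core <- unlist(Map(function(a, b) if (a + e <= b - e) seq(a + e, b - e) else NULL,
                       neg$start, neg$end))
    kept <- unlist(Map(seq, got$start, got$end))
    expect_length(intersect(kept, core), 0)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] - got$end[-nrow(got)] > 1))
    }
  }
})

test_that("refinement plans match the published rounds", {
  p <- demo_protein()
  pl1 <- plan_refinement(p, list(start = 1, end = 11))
  expect_equal(plan_params(pl1)$n, 5L)
  expect_equal(nrow(pl1), 7L)
  expect_equal(pl1$construct_id[1], "1-5")
  expect_equal(pl1$construct_id[7], "7-11")
  pl3 <- plan_refinement(p, list(start = 21, end = 31))
  expect_equal(plan_params(pl3)$L, 12L)
  expect_equal(nrow(pl3), 8L)
  expect_equal(pl3$construct_id[8], "l/o-31")
  # construct count is L - n + 1 for the selected n
  expect_equal(nrow(pl3), plan_params(pl3)$L - plan_params(pl3)$n + 1L)
})

test_that("refinement length selection honours rule, tolerance and fallback", {
  p <- repeat_protein("small", 8)
  # tolerance 1 on a 5-unit region keeps only the argmax n = 2 -> 4 windows
  pl <- plan_refinement(p, list(start = 1, end = 5), tolerance = 1)
  expect_equal(plan_params(pl)$n, 2L)
  expect_equal(nrow(pl), 4L)
  expect_equal(plan_params(plan_refinement(p, list(start = 1, end = 5),
                                           rule = "max_entropy"))$n, 2L)
  expect_warning(
    too_big <- plan_refinement(p, list(start = 1, end = 3), n = 7),
    "exceeds")
  expect_equal(nrow(too_big), 1L)
  expect_equal(plan_params(too_big)$n, 3L)
})

test_that("branch step prunes on calls and emits per-region plans", {
  p <- demo_protein()
  plan1 <- initial_partition(p, k = 3, segment_length = 13)
  calls <- tibble::tibble(construct_id = plan1$construct_id,
                          verdict = c("positive", "negative", "positive"))
  plans <- branch_step(plan1, calls, p, edge_margin = 2)
  expect_length(plans, 2L)
  expect_equal(plan_params(plans[[1]])$L, 11L)
  expect_equal(plan_params(plans[[2]])$L, 12L)
  expect_equal(nrow(plans[[1]]), 7L)
  expect_equal(nrow(plans[[2]]), 8L)

  # all negative: nothing to refine
  allneg <- dplyr::mutate(calls, verdict = "negative")
  expect_message(empty <- branch_step(plan1, allneg, p), "no binding")
  expect_length(empty, 0L)

  # inconclusive carries no evidence: the two positive windows survive unpruned
  calls2 <- dplyr::mutate(calls, verdict = c("positive", "inconclusive", "positive"))
  plans2 <- branch_step(plan1, calls2, p, edge_margin = 2)
  expect_length(plans2, 2L)
  expect_equal(plan_params(plans2[[1]])$region, c(start = 1, end = 13))
  expect_equal(plan_params(plans2[[2]])$region, c(start = 19, end = 31))
})

test_that("branching a 5-unit round to 4-unit windows recovers the next tier", {
  p <- demo_protein()
  pl <- plan_refinement(p, list(start = 1, end = 11))
  # constructs overlapping a paratope at 6-10 by >= 3 units bind
  calls <- tibble::tibble(
    construct_id = pl$construct_id,
    verdict = ifelse(pl$construct_id %in% c("4-8", "5-9", "6-10", "7-11"),
                     "positive", "negative"))
  plans <- branch_step(pl, calls, p, next_n = 4, edge_margin = 2)
  expect_length(plans, 1L)
  expect_true("6-9" %in% plans[[1]]$construct_id)
  expect_equal(plan_params(plans[[1]])$n, 4L)
})

test_that("branch step validates calls", {
  p <- demo_protein()
  plan1 <- initial_partition(p, k = 3, segment_length = 13)
  expect_error(branch_step(plan1, tibble::tibble(construct_id = "1-13",
                                                 verdict = "positive"), p),
               "no verdict")
  bad <- tibble::tibble(construct_id = plan1$construct_id, verdict = "maybe")
  expect_error(branch_step(plan1, bad, p), "unknown verdict")
})
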