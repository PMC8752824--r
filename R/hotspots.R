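#' Per-unit binding support from a completed round
#'
#' Aggregates a round's per-construct statistics to the repeat units they
#' cover. A construct counts as *significant* when its mean delta-Cq is
#' positive and Tukey's HSD flags it as significantly greater than at least
#' one other construct in the round — mirroring the contrast of strong
#' versus background constructs within a round, while staying well defined
#' when the identity of the non-binders is unknown. If the round tested a
#' single construct, it is significant when its mean delta-Cq exceeds
#' `delta_floor`.
#'
#' @param plan The round's [segmentation_plan].
#' @param results [delta_cq()] output for the round.
#' @param comparison [compare_constructs()] output for the round (may be
#'   `NULL` when the plan holds a single construct).
#' @param alpha Significance level; defaults to `comparison$alpha`.
#' @param delta_floor Fallback delta-Cq floor (cycles) for single-construct
#'   rounds, default 1.
#' @return Tibble of class `unit_support` with one row per unit covered by
#'   the plan: `ord`, `label`, `n_significant`, `n_tested`,
#'   `mean_delta_cq` (mean over containing constructs). The per-construct
#'   table (with the significance flag) is attached as attribute
#'   `"constructs"`.
#' @export
unit_support <- function(plan, results, comparison = NULL, alpha = NULL,
                         delta_floor = 1) {
  missing_ids <- setdiff(plan$construct_id, results$construct_id)
  if (length(missing_ids)) {
    abort(sprintf("no delta-Cq result for construct(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  sig_ids <- significant_constructs(results, comparison, alpha = alpha,
                                    delta_floor = delta_floor)
  constructs <- as_tibble(plan) |>
    dplyr::left_join(
      dplyr::select(as_tibble(results), "construct_id", "delta_cq_mean",
                    "excluded"),
      by = "construct_id"
    ) |>
    dplyr::mutate(significant = .data$construct_id %in% sig_ids)

  ords <- seq(min(plan$start_ord), max(plan$end_ord))
  covers <- function(tbl, o) tbl$start_ord <= o & tbl$end_ord >= o
  support <- tibble(
    ord = ords,
    n_significant = vapply(ords, function(o) {
      sum(covers(constructs, o) & constructs$significant)
    }, integer(1)),
    n_tested = vapply(ords, function(o) {
      sum(covers(constructs, o) & !constructs$excluded)
    }, integer(1)),
    mean_delta_cq = vapply(ords, function(o) {
      m <- constructs$delta_cq_mean[covers(constructs, o) & !constructs$excluded]
      if (length(m)) mean(m) else NA_real_
    }, numeric(1))
  )
  ut_all <- plan_unit_labels(plan)
  support <- dplyr::mutate(support, label = ut_all[as.character(ords)],
                           .after = "ord")
  structure(support, constructs = constructs,
            class = c("unit_support", class(support)))
}

# label lookup for the ord positions referenced by a plan
plan_unit_labels <- function(plan) {
  labs <- attr(plan, "unit_labels")
  if (!is.null(labs)) return(labs)
  # reconstruct from the construct windows: every covered ord appears as
  # some window's start or end at stride 1, or is labelled by offset from
  # the enclosing window's start when all windows share a start
  ords <- seq(min(plan$start_ord), max(plan$end_ord))
  labs <- setNames(as.character(ords), as.character(ords))
  for (j in seq_len(nrow(plan))) {
    labs[as.character(plan$start_ord[j])] <- plan$start_label[j]
    labs[as.character(plan$end_ord[j])] <- plan$end_label[j]
  }
  labs
}

significant_constructs <- function(results, comparison, alpha = NULL,
                                   delta_floor = 1) {
  kept <- results[!results$excluded, ]
  if (nrow(kept) == 1L) {
    return(kept$construct_id[!is.na(kept$delta_cq_mean) &
                               kept$delta_cq_mean > delta_floor])
  }
  if (is.null(comparison)) {
    abort("`comparison` is required when more than one construct was tested.")
  }
  alpha <- alpha %||% comparison$alpha
  means <- setNames(kept$delta_cq_mean, kept$construct_id)
  pw <- comparison$pairwise
  greater_than_some <- function(id) {
    hit_a <- pw$construct_a == id & pw$adjusted_p <= alpha & pw$mean_diff < 0
    hit_b <- pw$construct_b == id & pw$adjusted_p <= alpha & pw$mean_diff > 0
    any(hit_a) || any(hit_b)
  }
  ids <- kept$construct_id
  ids[means[ids] > 0 & vapply(ids, greater_than_some, logical(1))]
}

#' Call hotspot intervals from per-unit support
#'
#' Hotspots are maximal contiguous runs of units supported by at least
#' `min_support` significant constructs. Each interval is annotated with
#' its best construct: largest mean delta-Cq, ties broken by smaller span
#' and then lower start unit. Intervals can only contain tested units, so
#' a call never extends past the round's tiling.
#'
#' @param support A [unit_support()] table.
#' @param min_support Minimum number of significant containing constructs,
#'   default 1.
#' @return Tibble of class `hotspot_call` with columns `start_ord`,
#'   `end_ord`, `start_label`, `end_label`, `n_units`, `top_construct`,
#'   `top_delta_cq`; zero rows when nothing is supported.
#' @export
call_hotspots <- function(support, min_support = 1L) {
  stopifnot(inherits(support, "unit_support"))
  min_support <- check_count(min_support, "min_support", min = 1L)
  constructs <- attr(support, "constructs")
  keep <- support$ord[support$n_significant >= min_support &
                        support$n_tested >= 1L]
  runs <- runs_to_windows(keep)
  label_of <- setNames(support$label, as.character(support$ord))
  out <- purrr::map(seq_len(nrow(runs)), function(j) {
    lo <- runs$start[j]; hi <- runs$end[j]
    cand <- constructs[constructs$significant &
                         constructs$end_ord >= lo & constructs$start_ord <= hi, ]
    cand <- cand[order(-cand$delta_cq_mean,
                       cand$end_ord - cand$start_ord,
                       cand$start_ord), ]
    tibble(start_ord = lo, end_ord = hi,
           start_label = unname(label_of[as.character(lo)]),
           end_label = unname(label_of[as.character(hi)]),
           n_units = hi - lo + 1L,
           top_construct = cand$construct_id[1],
           top_delta_cq = cand$delta_cq_mean[1])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(start_ord = integer(0), end_ord = integer(0),
                  start_label = character(0), end_label = character(0),
                  n_units = integer(0), top_construct = character(0),
                  top_delta_cq = numeric(0))
  }
  structure(res, class = c("hotspot_call", class(res)))
}
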