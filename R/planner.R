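#' @title Segmentation plans
#' @description A segmentation plan is a tibble of constructs — contiguous
#'   unit windows over a repeat protein, each tested with the protein's caps
#'   appended — plus the design parameters that produced it. Windows are
#'   stored both as ordinal positions in the protein's unit ordering
#'   (`start_ord`/`end_ord`, which count the loopout pseudo-unit) and, where
#'   defined, as repeat indices (`start_repeat`/`end_repeat`).
#' @name segmentation_plan
NULL

new_plan <- function(constructs, protein, round_id, params = list()) {
  constructs <- as_tibble(constructs)
  constructs <- dplyr::arrange(constructs, .data$start_ord)
  if (anyDuplicated(constructs[c("start_ord", "end_ord")])) {
    abort("plan constructs must be pairwise distinct windows.")
  }
  ut <- unit_table(protein)
  structure(constructs,
            round_id = round_id,
            params = params,
            protein_name = protein$name,
            unit_labels = setNames(ut$label, as.character(ut$ord)),
            class = c("segmentation_plan", class(constructs)))
}

#' @export
print.segmentation_plan <- function(x, ...) {
  cat(sprintf("Segmentation plan '%s' on %s: %d constructs\n",
              attr(x, "round_id"), attr(x, "protein_name"), nrow(x)))
  NextMethod()
}

#' Parameters recorded in a segmentation plan
#' @param plan A segmentation plan.
#' @return Named list of design parameters.
#' @export
plan_params <- function(plan) attr(plan, "params")

# build construct rows from ordinal windows
constructs_from_ord <- function(protein, starts, ends) {
  ut <- unit_table(protein)
  tibble(
    construct_id = paste(ut$label[starts], ut$label[ends], sep = "-"),
    start_ord = as.integer(starts),
    end_ord = as.integer(ends),
    start_label = ut$label[starts],
    end_label = ut$label[ends],
    n_units = as.integer(ends - starts + 1L),
    start_repeat = vapply(seq_along(starts), function(j) {
      idx <- ut$repeat_index[starts[j]:ends[j]]
      idx <- idx[!is.na(idx)]
      if (length(idx)) min(idx) else NA_integer_
    }, integer(1)),
    end_repeat = vapply(seq_along(starts), function(j) {
      idx <- ut$repeat_index[starts[j]:ends[j]]
      idx <- idx[!is.na(idx)]
      if (length(idx)) max(idx) else NA_integer_
    }, integer(1))
  )
}

#' Coarse initial partition of a repeat protein
#'
#' Splits the repeats into `k` contiguous segments of equal length `s` that
#' cover every repeat, distributing the required total overlap
#' `k*s - n_repeats` as evenly as possible over the `k - 1` junctions
#' (larger overlaps at earlier junctions on ties). Overlap between
#' neighbouring segments hedges against misfolding of the outermost repeats
#' at non-native repeat/cap interfaces.
#'
#' @param protein A [repeat_protein()] (or a bare repeat count).
#' @param k Number of segments.
#' @param segment_length Segment length `s` in repeats. If `NULL`, the
#'   smallest feasible `s` for a target `overlap` is used.
#' @param overlap Target overlap used only when `segment_length` is `NULL`.
#' @return A [segmentation_plan] of `k` constructs; the realised junction
#'   overlaps are in `plan_params(plan)$overlaps`.
#' @examples
#' leeix2 <- repeat_protein("LeEIX2", 31, loopout = list(after_repeat = 27))
#' initial_partition(leeix2, k = 3, segment_length = 13)
#' @export
initial_partition <- function(protein, k, segment_length = NULL, overlap = 4L) {
  if (!inherits(protein, "repeat_protein")) {
    protein <- repeat_protein("protein", protein)
  }
  R <- protein$n_repeats
  k <- check_count(k, "k", min = 1L)
  if (is.null(segment_length)) {
    segment_length <- ceiling((R + (k - 1L) * overlap) / k)
  }
  s <- check_count(segment_length, "segment_length", min = 1L)
  if (s > R) abort(sprintf("segment length %d exceeds the %d repeats.", s, R))
  if (k * s < R) {
    abort(sprintf("coverage infeasible: %d segments of %d repeats cannot cover %d.",
                  k, s, R))
  }
  total_overlap <- k * s - R
  if (k == 1L) {
    overlaps <- integer(0)
  } else {
    base <- total_overlap %/% (k - 1L)
    rem <- total_overlap %% (k - 1L)
    overlaps <- rep(base, k - 1L) + as.integer(seq_len(k - 1L) <= rem)
  }
  if (any(overlaps >= s)) {
    abort("coverage infeasible: junction overlap would equal a whole segment.")
  }
  starts <- cumsum(c(1L, s - overlaps))
  ends <- starts + s - 1L
  ord <- t(vapply(seq_len(k),
                  function(j) repeat_window_to_ord(protein, starts[j], ends[j]),
                  integer(2)))
  new_plan(constructs_from_ord(protein, ord[, 1], ord[, 2]),
           protein, round_id = "initial",
           params = list(k = k, segment_length = s, overlaps = overlaps))
}

#' Prune candidate regions with negative evidence
#'
#' Removes from each positive (binding) window every repeat that lies in
#' the trusted core of a negative (non-binding) window. The outermost
#' `edge_margin` repeats of a negative window are distrusted — a repeat near
#' a non-native junction may have failed to bind because of misfolding
#' rather than because it is outside the paratope — so only the core of a
#' negative window carries pruning weight. Remaining repeats are returned
#' as maximal contiguous windows in order.
#'
#' @param positives,negatives Data frames with `start`/`end` repeat indices
#'   (inclusive), one window per row.
#' @param edge_margin Number of distrusted repeats at each end of every
#'   negative window (`e >= 0`), default 2.
#' @return Tibble of candidate windows with columns `start`, `end`,
#'   `n_repeats`; possibly zero rows.
#' @examples
#' prune_candidates(
#'   positives = data.frame(start = c(1, 19), end = c(13, 31)),
#'   negatives = data.frame(start = 10, end = 22),
#'   edge_margin = 2
#' )
#' @export
prune_candidates <- function(positives, negatives, edge_margin = 2L) {
  positives <- normalize_windows(positives, "positives")
  negatives <- normalize_windows(negatives, "negatives")
  e <- check_count(edge_margin, "edge_margin", min = 0L)

  core_units <- integer(0)
  for (j in seq_len(nrow(negatives))) {
    lo <- negatives$start[j] + e
    hi <- negatives$end[j] - e
    if (lo <= hi) core_units <- union(core_units, seq(lo, hi))
  }

  out <- list()
  for (j in seq_len(nrow(positives))) {
    keep <- setdiff(seq(positives$start[j], positives$end[j]), core_units)
    out[[j]] <- runs_to_windows(keep)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start = integer(0), end = integer(0), n_repeats = integer(0)))
  }
  # merge windows arising from overlapping positives
  res <- runs_to_windows(sort(unique(unlist(
    purrr::map2(res$start, res$end, seq)))))
  dplyr::mutate(res, n_repeats = .data$end - .data$start + 1L)
}

normalize_windows <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  x <- as_tibble(as.data.frame(x))
  if (!all(c("start", "end") %in% names(x))) {
    abort(sprintf("`%s` must have `start` and `end` columns.", what))
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$start > x$end)) abort(sprintf("`%s` has a window with start > end.", what))
  x
}

# contiguous runs of a sorted integer set -> windows tibble
runs_to_windows <- function(units) {
  if (!length(units)) return(tibble(start = integer(0), end = integer(0)))
  units <- sort(unique(as.integer(units)))
  breaks <- which(diff(units) > 1L)
  starts <- units[c(1L, breaks + 1L)]
  ends <- units[c(breaks, length(units))]
  tibble(start = starts, end = ends)
}

#' Plan a stride-1 refinement round over a candidate region
#'
#' Computes the entropy profile for the region's unit count `L` (the
#' loopout pseudo-unit counts when it falls inside the region), selects the
#' sub-segment length `n` under the entropy tolerance, and emits all
#' `L - n + 1` stride-1 windows as constructs.
#'
#' The default selection rule takes the *largest* admissible length:
#' near-maximal information with the most native-like repeat context.
#' `rule = "max_entropy"` takes the entropy argmax instead, and an explicit
#' `n` overrides both (falling back to `n = L` with a warning if the region
#' is shorter).
#'
#' @param protein A [repeat_protein()].
#' @param region A window in repeat indices: data frame row or list with
#'   `start`/`end`.
#' @param tolerance Entropy tolerance passed to [admissible_lengths()].
#' @param n Optional explicit sub-segment length.
#' @param rule `"largest"` (default) or `"max_entropy"`.
#' @param round_id Plan identifier.
#' @return A [segmentation_plan] of `L - n + 1` constructs.
#' @examples
#' leeix2 <- repeat_protein("LeEIX2", 31, loopout = list(after_repeat = 27))
#' plan_refinement(leeix2, list(start = 21, end = 31))  # 12 units -> 8 windows
#' @export
plan_refinement <- function(protein, region, tolerance = 0.9, n = NULL,
                            rule = c("largest", "max_entropy"),
                            round_id = NULL) {
  stopifnot(inherits(protein, "repeat_protein"))
  rule <- match.arg(rule)
  region <- as.list(region)
  span <- repeat_window_to_ord(protein, region$start, region$end)
  L <- span[2] - span[1] + 1L
  profile <- entropy_profile(L)
  admissible <- admissible_lengths(profile, tolerance)
  if (is.null(n)) {
    n <- if (rule == "largest") max(admissible) else max_entropy_length(profile)
  } else {
    n <- check_count(n, "n", min = 1L)
    if (n > L) {
      warn(sprintf("requested n = %d exceeds region length %d; using n = %d.",
                   n, L, L))
      n <- L
    }
  }
  starts <- seq(span[1], span[2] - n + 1L)
  ends <- starts + n - 1L
  round_id <- round_id %||% sprintf("refine-%d-%d", region$start, region$end)
  new_plan(constructs_from_ord(protein, starts, ends),
           protein, round_id = round_id,
           params = list(region = c(start = region$start, end = region$end),
                         L = L, n = n, tolerance = tolerance, rule = rule,
                         admissible = admissible))
}

#' Call construct verdicts from delta-Cq results
#'
#' A pragmatic verdicting rule for between-round decisions: a construct is
#' `positive` when its mean delta-Cq reaches `floor` cycles, `negative`
#' when it does not, and `inconclusive` when it was excluded from analysis.
#' Inconclusive calls carry no evidence in later pruning — a low signal
#' cannot distinguish non-binding from misfolding.
#'
#' @param results Output of [delta_cq()].
#' @param floor Minimum mean delta-Cq (cycles) for a positive call.
#' @return Tibble with `construct_id`, `verdict`.
#' @export
binding_calls <- function(results, floor = 1) {
  tibble(
    construct_id = results$construct_id,
    verdict = dplyr::case_when(
      results$excluded ~ "inconclusive",
      results$delta_cq_mean >= floor ~ "positive",
      TRUE ~ "negative"
    )
  )
}

#' One branch-and-bound refinement step
#'
#' Given a completed round and its binding calls, derives candidate regions
#' by pruning the positive windows with the trusted cores of the negative
#' windows, then emits one stride-1 refinement plan per disjoint candidate
#' region. Inconclusive calls are ignored as evidence.
#'
#' @param plan The completed round's [segmentation_plan].
#' @param calls Data frame with `construct_id` and `verdict`
#'   (`positive`/`negative`/`inconclusive`), e.g. from [binding_calls()].
#' @param protein The [repeat_protein()] the plan was built on.
#' @param next_n Optional explicit sub-segment length for the next round.
#' @param edge_margin Distrusted repeats at negative-window ends.
#' @param tolerance Entropy tolerance for next-round length selection.
#' @return List of [segmentation_plan]s, one per candidate region (empty,
#'   with a message, when nothing bound).
#' @export
branch_step <- function(plan, calls, protein, next_n = NULL,
                        edge_margin = 2L, tolerance = 0.9) {
  calls <- as_tibble(as.data.frame(calls))
  if (!all(c("construct_id", "verdict") %in% names(calls))) {
    abort("`calls` must have `construct_id` and `verdict` columns.")
  }
  missing <- setdiff(plan$construct_id, calls$construct_id)
  if (length(missing)) {
    abort(sprintf("no verdict for construct(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(calls$verdict, c("positive", "negative", "inconclusive"))
  if (length(bad)) {
    abort(sprintf("unknown verdict(s): %s", paste(bad, collapse = ", ")))
  }
  joined <- dplyr::inner_join(as_tibble(plan), calls, by = "construct_id")
  pos <- dplyr::filter(joined, .data$verdict == "positive")
  neg <- dplyr::filter(joined, .data$verdict == "negative")
  if (nrow(pos) == 0L) {
    inform("no binding detected in this round; nothing to refine.")
    return(list())
  }
  regions <- prune_candidates(
    positives = tibble(start = pos$start_repeat, end = pos$end_repeat),
    negatives = tibble(start = neg$start_repeat, end = neg$end_repeat),
    edge_margin = edge_margin
  )
  purrr::map(seq_len(nrow(regions)), function(j) {
    plan_refinement(protein, regions[j, ], tolerance = tolerance, n = next_n)
  })
}
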