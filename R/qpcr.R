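#' Read / write a Cq table
#'
#' The exchange format is TSV with the exact header
#' `construct_id  condition  replicate  batch  cq` (extra columns are kept).
#' `condition` is `uncompeted` or `competed`.
#'
#' @param path File path.
#' @return [read_cq_table()] returns a tibble; [write_cq_table()] returns
#'   `table` invisibly.
#' @export
read_cq_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cq_table(tbl)
  tbl
}

#' @rdname read_cq_table
#' @param table A Cq table.
#' @export
write_cq_table <- function(table, path) {
  check_cq_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(table)
}

check_cq_table <- function(tbl) {
  required <- c("construct_id", "condition", "replicate", "batch", "cq")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("Cq table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0L) abort("Cq table is empty.")
  bad <- setdiff(unique(tbl$condition), c("uncompeted", "competed"))
  if (length(bad)) {
    abort(sprintf("unknown condition value(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(tbl$cq))) abort("Cq values must be finite.")
  key <- tbl[c("construct_id", "condition", "replicate", "batch")]
  if (anyDuplicated(key)) {
    abort("duplicate (construct, condition, replicate, batch) rows in Cq table.")
  }
  invisible(tbl)
}

#' Normalise Cq batches to a common global average
#'
#' Replicates measured on different days (batches) carry additive Cq
#' offsets from instrument and reagent drift. Each batch is shifted to the
#' global average Cq: `Cq' = Cq - mean(batch) + mean(all)`. The grand mean
#' and every within-batch difference are preserved exactly, so paired
#' within-batch delta-Cq values are unaffected while cross-batch means and
#' standard deviations become comparable.
#'
#' @param table A Cq table (see [read_cq_table()]).
#' @return The table with normalised `cq` values.
#' @export
normalize_batches <- function(table) {
  check_cq_table(table)
  grand <- mean(table$cq)
  table |>
    dplyr::group_by(.data$batch) |>
    dplyr::mutate(cq = .data$cq - mean(.data$cq) + grand) |>
    dplyr::ungroup()
}

#' Per-construct delta-Cq with propagated uncertainty
#'
#' For each construct, replicate delta-Cq values are formed by pairing the
#' competed and uncompeted wells by `(replicate, batch)`:
#' `dCq = Cq_competed - Cq_uncompeted`. Positive delta-Cq means competition
#' removed bound material — specific, competable binding. The summary is
#' the mean over pairs with the standard deviation propagated from the two
#' conditions, `sd = sqrt(sd_competed^2 + sd_uncompeted^2)` (per-condition
#' sds taken across replicates).
#'
#' Constructs missing one of the two conditions, or with no complete
#' `(replicate, batch)` pair, are marked excluded with reason
#' `"incomplete conditions"`.
#'
#' @param table A Cq table.
#' @return Tibble of class `delta_cq_result` with columns `construct_id`,
#'   `delta_cq_mean`, `delta_cq_sd`, `n_pairs`, `excluded`,
#'   `exclusion_reason` and list-column `replicate_deltas`.
#' @export
delta_cq <- function(table) {
  check_cq_table(table)
  wide <- table |>
    dplyr::select("construct_id", "condition", "replicate", "batch", "cq") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "cq")
  if (!"competed" %in% names(wide)) wide$competed <- NA_real_
  if (!"uncompeted" %in% names(wide)) wide$uncompeted <- NA_real_
  res <- wide |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::summarise(
      replicate_deltas = list(stats::na.omit(.data$competed - .data$uncompeted)),
      sd_competed = sd(stats::na.omit(.data$competed)),
      sd_uncompeted = sd(stats::na.omit(.data$uncompeted)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_pairs = lengths(.data$replicate_deltas),
      delta_cq_mean = vapply(.data$replicate_deltas, function(d) {
        if (length(d)) mean(d) else NA_real_
      }, numeric(1)),
      delta_cq_sd = sqrt(
        dplyr::coalesce(.data$sd_competed, 0)^2 +
          dplyr::coalesce(.data$sd_uncompeted, 0)^2
      ),
      excluded = .data$n_pairs == 0L,
      exclusion_reason = ifelse(.data$excluded, "incomplete conditions",
                                NA_character_)
    ) |>
    dplyr::select("construct_id", "delta_cq_mean", "delta_cq_sd", "n_pairs",
                  "excluded", "exclusion_reason", "replicate_deltas")
  # keep the construct ordering of the input table
  res <- res[match(unique(table$construct_id), res$construct_id), ]
  structure(res, class = c("delta_cq_result", class(res)))
}

#' Flag constructs with outlying replicate variance
#'
#' Applies the Tukey fence to the propagated delta-Cq standard deviations:
#' any construct whose sd exceeds `Q3 + k * IQR` is marked excluded (reason
#' `"outlying sd (Tukey fence)"`). Only the high side is fenced — an
#' unusually *low* variance is not a defect. With fewer than four
#' constructs the quartiles are not meaningful and nothing is flagged
#' (a warning is raised).
#'
#' @param results Output of [delta_cq()].
#' @param k Fence multiplier, default 1.5 (the conventional Tukey fence).
#' @return `results` with `excluded`/`exclusion_reason` updated.
#' @export
flag_sd_outliers <- function(results, k = 1.5) {
  sds <- results$delta_cq_sd[!results$excluded]
  if (length(sds) < 4L) {
    warn("fewer than 4 constructs: Tukey-fence outlier flagging skipped.")
    return(results)
  }
  q <- quantile(sds, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + k * (q[2] - q[1])
  hit <- !results$excluded & results$delta_cq_sd > fence
  results$excluded[hit] <- TRUE
  results$exclusion_reason[hit] <- "outlying sd (Tukey fence)"
  results
}

#' Compare construct delta-Cq distributions (ANOVA + Tukey HSD)
#'
#' Runs a single-factor ANOVA on the replicate-level delta-Cq values
#' grouped by construct, followed by Tukey's HSD on all pairs of
#' non-excluded constructs (studentized range; Tukey–Kramer adjustment for
#' unequal group sizes, as implemented by [stats::TukeyHSD()]). A pair is
#' significant when its adjusted p-value is at most `alpha`.
#'
#' When every replicate delta is identical the ANOVA F statistic is
#' undefined (zero variance everywhere); the report then carries `NA`
#' statistics and no significant pairs.
#'
#' @param results Output of [delta_cq()] (optionally after
#'   [flag_sd_outliers()]); excluded constructs are dropped.
#' @param alpha Significance level for pairwise flags, default 0.1.
#' @return An object of class `construct_comparison`: list with `anova`
#'   (one-row tibble: `statistic`, `p_value`, `df_between`, `df_within`),
#'   `pairwise` (tibble: `construct_a`, `construct_b`, `mean_diff`,
#'   `adjusted_p`, `significant`) and `alpha`. Use [tidy()] / [glance()]
#'   to extract the tables.
#' @export
compare_constructs <- function(results, alpha = 0.1) {
  kept <- results[!results$excluded, ]
  too_few_reps <- kept$construct_id[lengths(kept$replicate_deltas) < 2L]
  if (length(too_few_reps)) {
    abort(sprintf("construct(s) with fewer than 2 replicate deltas: %s",
                  paste(too_few_reps, collapse = ", ")))
  }
  if (nrow(kept) < 2L) {
    abort("need at least 2 non-excluded constructs to compare.")
  }
  long <- tibble(
    construct = factor(rep(kept$construct_id, lengths(kept$replicate_deltas)),
                       levels = kept$construct_id),
    delta = unlist(kept$replicate_deltas)
  )
  if (stats::var(long$delta) == 0) {
    pairs <- t(utils::combn(kept$construct_id, 2))
    out <- list(
      anova = tibble(statistic = NA_real_, p_value = NA_real_,
                     df_between = nrow(kept) - 1L,
                     df_within = nrow(long) - nrow(kept)),
      pairwise = tibble(construct_a = pairs[, 1], construct_b = pairs[, 2],
                        mean_diff = 0, adjusted_p = 1, significant = FALSE),
      alpha = alpha
    )
    return(structure(out, class = "construct_comparison"))
  }
  fit <- aov(delta ~ construct, data = long)
  tab <- summary(fit)[[1]]
  tukey <- TukeyHSD(fit, "construct", conf.level = 1 - alpha)$construct
  # rows come in combn order with names "b-a" (b's mean minus a's mean);
  # reconstruct the pairs from the levels because ids may themselves contain "-"
  cmb <- utils::combn(levels(long$construct), 2)
  expected <- paste(cmb[2, ], cmb[1, ], sep = "-")
  if (!identical(expected, rownames(tukey))) {
    abort("internal error: Tukey pair ordering did not match the level order.")
  }
  pairwise <- tibble(
    construct_a = cmb[1, ],
    construct_b = cmb[2, ],
    mean_diff = unname(tukey[, "diff"]),
    adjusted_p = unname(tukey[, "p adj"]),
    significant = unname(tukey[, "p adj"] <= alpha)
  )
  structure(
    list(
      anova = tibble(statistic = tab[["F value"]][1],
                     p_value = tab[["Pr(>F)"]][1],
                     df_between = tab[["Df"]][1],
                     df_within = tab[["Df"]][2]),
      pairwise = pairwise,
      alpha = alpha
    ),
    class = "construct_comparison"
  )
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat(sprintf(
    "Construct comparison: F(%d, %d) = %.3f, p = %.3g; %d/%d pairs significant at alpha = %g\n",
    x$anova$df_between, x$anova$df_within, x$anova$statistic,
    x$anova$p_value, sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' @describeIn compare_constructs Pairwise Tukey HSD table.
#' @param x A `construct_comparison`.
#' @param ... Unused.
#' @export
tidy.construct_comparison <- function(x, ...) x$pairwise

#' @describeIn compare_constructs One-row ANOVA summary.
#' @export
glance.construct_comparison <- function(x, ...) {
  dplyr::mutate(x$anova, alpha = x$alpha,
                n_significant_pairs = sum(x$pairwise$significant))
}
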