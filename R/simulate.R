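#' Define a planted ground truth for simulation
#'
#' The ground truth plants one or more paratopes (binding hotspots) on the
#' protein, each a contiguous window of repeat units. A construct binds
#' specifically when it covers at least `min_contig` contiguous units of a
#' paratope — too small an interface presents too little contact area for
#' detectable binding — with strength proportional to the covered fraction.
#'
#' @param paratopes Data frame of disjoint windows (`start`/`end` repeat
#'   indices), or `NULL`/zero rows for a null (no-binding) truth.
#' @param min_contig Minimum contiguous overlap (units) for detectable
#'   binding; default 3.
#' @param signal_scale Specific-binding strength at full paratope coverage
#'   (dimensionless), default 1.
#' @param leak Fraction of specific binding surviving competition,
#'   `0 <= leak < 1`; default 0.05.
#' @param background Nonspecific binding level `b > 0`; default 0.05.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(paratopes = NULL, min_contig = 3L, signal_scale = 1,
                         leak = 0.05, background = 0.05) {
  paratopes <- normalize_windows(paratopes, "paratopes")
  paratopes <- dplyr::arrange(paratopes, .data$start)
  if (nrow(paratopes) > 1L &&
      any(paratopes$start[-1] <= paratopes$end[-nrow(paratopes)])) {
    abort("paratopes must be disjoint.")
  }
  min_contig <- check_count(min_contig, "min_contig", min = 1L)
  if (leak < 0 || leak >= 1) abort("`leak` must be in [0, 1).")
  if (background <= 0) abort("`background` must be > 0.")
  if (signal_scale < 0) abort("`signal_scale` must be >= 0.")
  structure(list(paratopes = paratopes, min_contig = min_contig,
                 signal_scale = signal_scale, leak = leak,
                 background = background),
            class = "ground_truth")
}

#' Simulation settings for the ribosome-display qPCR readout
#'
#' @param noise_sd Standard deviation of Cq noise, in cycles.
#' @param cq_baseline Cq of a unit quantity of bound complex, in cycles.
#' @param batch_offsets Per-batch additive Cq shifts (cycles); length gives
#'   the number of batches.
#' @param n_replicates Replicates per condition per batch.
#' @param seed RNG seed fixing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(noise_sd = 0.25, cq_baseline = 20, batch_offsets = 0,
                       n_replicates = 3L, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  structure(list(noise_sd = noise_sd, cq_baseline = cq_baseline,
                 batch_offsets = as.numeric(batch_offsets),
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Specific-binding signal of a construct window
#'
#' `s = signal_scale * max_p(overlap(window, p) / |p|)` over paratopes `p`,
#' zeroed when the best contiguous overlap falls below `min_contig` units.
#' Windows and paratopes are contiguous, so the overlap is an interval
#' intersection in the protein's unit ordering.
#'
#' @param protein A [repeat_protein()].
#' @param start_ord,end_ord Construct window in ordinal unit positions.
#' @param truth A [ground_truth()].
#' @return Nonnegative scalar signal.
#' @export
specific_signal <- function(protein, start_ord, end_ord, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(truth$paratopes) == 0L) return(0)
  best <- 0
  for (j in seq_len(nrow(truth$paratopes))) {
    span <- repeat_window_to_ord(protein, truth$paratopes$start[j],
                                 truth$paratopes$end[j])
    ov <- min(end_ord, span[2]) - max(start_ord, span[1]) + 1L
    p_size <- span[2] - span[1] + 1L
    if (ov >= truth$min_contig) best <- max(best, ov / p_size)
  }
  truth$signal_scale * best
}

# bound quantities for one construct signal
bound_quantities <- function(s, truth) {
  c(uncompeted = s + truth$background,
    competed = truth$leak * s + truth$background)
}

#' Simulate a competed/uncompeted qPCR round
#'
#' For every construct, condition (uncompeted/competed), replicate and
#' batch, draws a quantification cycle
#' `Cq = cq_baseline - log2(bound) + batch_offset + N(0, noise_sd)`,
#' where the bound quantity is `s + b` uncompeted and `leak*s + b` competed
#' (perfect doubling per cycle; amplification-efficiency deviations are out
#' of scope). A `band_intensity` column proportional to `2^(-Cq)` mimics a
#' gel-band readout of the same material. Fully reproducible given
#' `cfg$seed`.
#'
#' @param plan A [segmentation_plan].
#' @param protein The [repeat_protein()] the plan was built on.
#' @param truth A [ground_truth()].
#' @param cfg A [sim_config()].
#' @return A Cq table: tibble with columns `construct_id`, `condition`,
#'   `replicate`, `batch`, `cq`, `band_intensity`.
#' @export
simulate_cq <- function(plan, protein, truth, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  signals <- vapply(seq_len(nrow(plan)), function(j) {
    specific_signal(protein, plan$start_ord[j], plan$end_ord[j], truth)
  }, numeric(1))
  n_batches <- length(cfg$batch_offsets)
  grid <- tidyr::expand_grid(
    construct_id = plan$construct_id,
    condition = c("uncompeted", "competed"),
    replicate = seq_len(cfg$n_replicates),
    batch = paste0("batch", seq_len(n_batches))
  )
  s_by_id <- setNames(signals, plan$construct_id)
  offset_by_batch <- setNames(cfg$batch_offsets,
                              paste0("batch", seq_len(n_batches)))
  bound <- ifelse(grid$condition == "uncompeted",
                  s_by_id[grid$construct_id] + truth$background,
                  truth$leak * s_by_id[grid$construct_id] + truth$background)
  set.seed(cfg$seed)
  cq <- cfg$cq_baseline - log2(bound) + offset_by_batch[grid$batch] +
    rnorm(nrow(grid), sd = cfg$noise_sd)
  dplyr::mutate(grid,
                cq = unname(cq),
                band_intensity = 2^(cfg$cq_baseline - cq))
}

#' Simulate a competitor dose-response for one construct
#'
#' At competitor level `x` in `[0, 1]` (fraction of specific binding
#' competed away), the bound quantity is `(1 - x*(1 - leak))*s + b`; levels
#' 0 and 1 reproduce the uncompeted and competed conditions of
#' [simulate_cq()]. With no noise and `s > 0`, Cq increases monotonically
#' with the level.
#'
#' @param protein A [repeat_protein()].
#' @param window Construct window in repeat indices (list or one-row data
#'   frame with `start`/`end`).
#' @param truth A [ground_truth()].
#' @param competitor_levels Numeric vector of levels in `[0, 1]`.
#' @param cfg A [sim_config()].
#' @return Tibble with `competitor_level`, `replicate`, `cq`,
#'   `band_intensity`.
#' @export
simulate_dose_response <- function(protein, window, truth,
                                   competitor_levels = seq(0, 1, by = 0.25),
                                   cfg = sim_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  if (any(competitor_levels < 0 | competitor_levels > 1)) {
    abort("`competitor_levels` must lie in [0, 1].")
  }
  window <- as.list(window)
  span <- repeat_window_to_ord(protein, window$start, window$end)
  s <- specific_signal(protein, span[1], span[2], truth)
  grid <- tidyr::expand_grid(competitor_level = competitor_levels,
                             replicate = seq_len(cfg$n_replicates))
  bound <- (1 - grid$competitor_level * (1 - truth$leak)) * s + truth$background
  set.seed(cfg$seed)
  cq <- cfg$cq_baseline - log2(bound) + rnorm(nrow(grid), sd = cfg$noise_sd)
  dplyr::mutate(grid, cq = cq, band_intensity = 2^(cfg$cq_baseline - cq))
}
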