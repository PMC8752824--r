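#' Load and validate a run configuration
#'
#' A run configuration describes one full design -> simulate -> analyse ->
#' infer campaign: the protein, the design parameters, the planted ground
#' truth for simulation, the simulator settings and the statistics
#' settings. Defaults are materialised on load, unknown keys are rejected,
#' and all validation failures are reported together.
#'
#' @param path YAML or JSON configuration file.
#' @return A validated `run_config` list with all defaults filled in.
#' @seealso [run_pipeline()], [run_demo()]
#' @export
load_run_config <- function(path) {
  validate_run_config(read_config_file(path))
}

#' @rdname load_run_config
#' @param config A configuration list (as parsed from YAML/JSON).
#' @export
validate_run_config <- function(config) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known_top <- c("protein", "design", "truth", "simulator", "stats")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) note(sprintf("unknown top-level key(s): %s",
                                    paste(unknown, collapse = ", ")))

  check_section <- function(section, allowed) {
    extra <- setdiff(names(config[[section]]), allowed)
    if (length(extra)) note(sprintf("%s: unknown key(s): %s", section,
                                    paste(extra, collapse = ", ")))
  }
  defaults <- list(
    design = list(tolerance = 0.9, overlap = 4L, segments = 3L,
                  segment_length = NULL, edge_margin = 2L,
                  selection_rule = "largest", call_floor = 1.0),
    truth = list(paratopes = NULL, min_contig = 3L, signal_scale = 1.0,
                 leak = 0.05, background = 0.05),
    simulator = list(noise_sd = 0.25, cq_baseline = 20, batch_offsets = 0,
                     n_replicates = 3L, seed = 1L),
    stats = list(alpha = 0.1, outlier_k = 1.5, min_support = 1L)
  )
  for (section in names(defaults)) {
    check_section(section, names(defaults[[section]]))
    config[[section]] <- utils::modifyList(defaults[[section]],
                                           config[[section]] %||% list())
  }

  if (is.null(config$protein)) {
    note("protein: section is required")
  } else {
    prot <- tryCatch(protein_from_list(config$protein), error = function(e) {
      note(sprintf("protein: %s", conditionMessage(e)))
      NULL
    })
  }
  d <- config$design
  if (!is.numeric(d$tolerance) || d$tolerance <= 0 || d$tolerance > 1) {
    note("design.tolerance: must be in (0, 1]")
  }
  if (!is.numeric(d$edge_margin) || d$edge_margin < 0) {
    note("design.edge_margin: must be >= 0")
  }
  if (!d$selection_rule %in% c("largest", "max_entropy")) {
    note("design.selection_rule: must be 'largest' or 'max_entropy'")
  }
  tr <- config$truth
  if (!is.null(tr$paratopes)) {
    tw <- tryCatch(dplyr::bind_rows(lapply(tr$paratopes, as_tibble)),
                   error = function(e) NULL)
    if (is.null(tw) || !all(c("start", "end") %in% names(tw))) {
      note("truth.paratopes: each entry needs start and end")
    }
  }
  if (!is.numeric(tr$leak) || tr$leak < 0 || tr$leak >= 1) {
    note("truth.leak: must be in [0, 1)")
  }
  if (!is.numeric(tr$background) || tr$background <= 0) {
    note("truth.background: must be > 0")
  }
  sim <- config$simulator
  if (!is.numeric(sim$noise_sd) || sim$noise_sd < 0) {
    note("simulator.noise_sd: must be >= 0")
  }
  if (!is.numeric(sim$n_replicates) || sim$n_replicates < 1) {
    note("simulator.n_replicates: must be >= 1")
  }
  st <- config$stats
  if (!is.numeric(st$alpha) || st$alpha <= 0 || st$alpha >= 1) {
    note("stats.alpha: must be in (0, 1)")
  }
  if (length(errors)) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  structure(config, class = "run_config")
}

config_truth <- function(config) {
  tr <- config$truth
  paratopes <- if (is.null(tr$paratopes)) NULL else
    dplyr::bind_rows(lapply(tr$paratopes, as_tibble))
  ground_truth(paratopes = paratopes, min_contig = tr$min_contig,
               signal_scale = tr$signal_scale, leak = tr$leak,
               background = tr$background)
}

#' Run the full hotspot-mapping campaign on a configuration
#'
#' Executes the complete in-silico loop on a [load_run_config()]
#' configuration: coarse overlapping partition of the protein, a simulated
#' competed/uncompeted qPCR round, verdicting, negative-evidence pruning to
#' candidate regions, an entropy-selected stride-1 refinement round per
#' region, the delta-Cq / outlier / ANOVA / Tukey analysis, and finally
#' per-unit support and hotspot interval calls. Deterministic given the
#' seed.
#'
#' @param config A `run_config` (list is validated on the way in).
#' @param out_dir Optional directory for artifacts: plan JSONs, Cq TSVs,
#'   `results.json`, `hotspots.json` and a run log; created if missing.
#' @param seed Optional override of `config$simulator$seed`.
#' @return (Invisibly) a list with the protein, plans, Cq tables, delta-Cq
#'   results, comparisons, per-unit support tables and the combined
#'   `hotspots` tibble.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  seed <- as.integer(seed %||% config$simulator$seed)
  protein <- protein_from_list(config$protein)
  truth <- config_truth(config)
  d <- config$design
  st <- config$stats

  make_cfg <- function(round_seed) {
    sim_config(noise_sd = config$simulator$noise_sd,
               cq_baseline = config$simulator$cq_baseline,
               batch_offsets = config$simulator$batch_offsets,
               n_replicates = config$simulator$n_replicates,
               seed = round_seed)
  }

  # round 1: coarse overlapping partition
  plan1 <- initial_partition(protein, k = d$segments,
                             segment_length = d$segment_length,
                             overlap = d$overlap)
  cq1 <- simulate_cq(plan1, protein, truth, make_cfg(seed))
  res1 <- delta_cq(normalize_batches(cq1))
  calls1 <- binding_calls(res1, floor = d$call_floor)

  # branch: prune with negative evidence, one refinement plan per region
  plans2 <- branch_step(plan1, calls1, protein,
                        edge_margin = d$edge_margin, tolerance = d$tolerance)

  rounds <- list()
  hotspots <- list()
  for (i in seq_along(plans2)) {
    plan <- plans2[[i]]
    rid <- attr(plan, "round_id")
    cq <- simulate_cq(plan, protein, truth, make_cfg(seed + i))
    res <- delta_cq(normalize_batches(cq))
    if (sum(!res$excluded) >= 4L) {
      res <- flag_sd_outliers(res, k = st$outlier_k)
    }
    comparison <- if (sum(!res$excluded) >= 2L) {
      compare_constructs(res, alpha = st$alpha)
    } else NULL
    support <- unit_support(plan, res, comparison, alpha = st$alpha,
                            delta_floor = d$call_floor)
    calls <- call_hotspots(support, min_support = st$min_support)
    rounds[[rid]] <- list(plan = plan, cq = cq, delta = res,
                          comparison = comparison, support = support,
                          hotspots = calls)
    if (nrow(calls)) {
      hotspots[[rid]] <- dplyr::mutate(as_tibble(calls), round_id = rid,
                                       .before = 1)
    }
  }
  hotspots <- if (length(hotspots)) dplyr::bind_rows(hotspots) else
    tibble(round_id = character(0), start_ord = integer(0),
           end_ord = integer(0), start_label = character(0),
           end_label = character(0), n_units = integer(0),
           top_construct = character(0), top_delta_cq = numeric(0))

  result <- list(protein = protein, seed = seed,
                 config_hash = rlang::hash(unclass(config)),
                 initial = list(plan = plan1, cq = cq1, delta = res1,
                                calls = calls1),
                 rounds = rounds, hotspots = hotspots)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, protein, out_dir)
  invisible(result)
}

plan_to_list <- function(plan) {
  list(round_id = attr(plan, "round_id"),
       params = attr(plan, "params"),
       constructs = as_tibble(plan)[c("construct_id", "start_ord", "end_ord",
                                      "start_label", "end_label", "n_units")])
}

write_pipeline_artifacts <- function(result, protein, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(seed = result$seed, config_hash = result$config_hash)
  wj <- function(x, file) {
    jsonlite::write_json(c(provenance, x), file.path(out_dir, file),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  wj(list(plan = plan_to_list(result$initial$plan)), "plan_initial.json")
  write_cq_table(result$initial$cq, file.path(out_dir, "cq_initial.tsv"))
  round_results <- list()
  for (rid in names(result$rounds)) {
    r <- result$rounds[[rid]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", rid)
    wj(list(plan = plan_to_list(r$plan)), sprintf("plan_%s.json", safe))
    write_cq_table(r$cq, file.path(out_dir, sprintf("cq_%s.tsv", safe)))
    round_results[[rid]] <- list(
      delta = dplyr::select(as_tibble(r$delta), -"replicate_deltas"),
      anova = if (is.null(r$comparison)) NULL else r$comparison$anova,
      pairwise = if (is.null(r$comparison)) NULL else r$comparison$pairwise
    )
    if (!is.null(protein$repeat_seqs)) {
      write_constructs_fasta(r$plan, protein,
                             file.path(out_dir, sprintf("constructs_%s.fasta", safe)))
    }
  }
  wj(list(initial_calls = result$initial$calls,
          rounds = round_results), "results.json")
  wj(list(hotspots = result$hotspots), "hotspots.json")
  writeLines(c(sprintf("lrrmap run: protein=%s seed=%d config_hash=%s",
                       protein$name, result$seed, result$config_hash),
               sprintf("rounds: initial + %d refinement", length(result$rounds)),
               sprintf("hotspots called: %d", nrow(result$hotspots))),
             file.path(out_dir, "run_log.txt"))
  invisible(result)
}

#' Run the packaged LeEIX2-style demonstration campaign
#'
#' Loads the packaged demo configuration — a 31-repeat LRR receptor with a
#' loopout pseudo-unit between repeats 27 and 28 and planted paratopes at
#' repeats 6-10 and 22-26 — and runs [run_pipeline()] on it.
#'
#' @param out_dir Optional artifact directory.
#' @param seed Optional seed override.
#' @return See [run_pipeline()].
#' @export
run_demo <- function(out_dir = NULL, seed = NULL) {
  config <- load_run_config(demo_config_path())
  run_pipeline(config, out_dir = out_dir, seed = seed)
}

#' @rdname run_demo
#' @export
demo_config_path <- function() {
  system.file("extdata", "leeix2_demo.yaml", package = "lrrmap",
              mustWork = TRUE)
}
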