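#' Define a modular repeat protein
#'
#' A repeat protein is an ordered stack of repeat units (e.g. leucine-rich
#' repeats) flanked by N- and C-terminal caps, optionally carrying a
#' non-repeat "loopout" insertion between two repeats. The loopout is
#' modelled as a single pseudo-unit that occupies one slot in the unit
#' ordering, so it counts towards region lengths during design.
#'
#' Sequences are optional: every design and statistics operation works on
#' unit indices alone; only construct assembly and FASTA export require
#' amino-acid sequences.
#'
#' @param name Protein identifier.
#' @param n_repeats Number of repeat units (positive integer).
#' @param repeat_seqs Optional character vector of per-repeat amino-acid
#'   sequences, length `n_repeats`.
#' @param ncap_seq,ccap_seq Optional cap amino-acid sequences.
#' @param loopout Optional list with `after_repeat` (the repeat index the
#'   loopout follows, in `[1, n_repeats - 1]`) and optional `seq`.
#'
#' @return An object of class `repeat_protein`.
#' @examples
#' leeix2 <- repeat_protein("LeEIX2", 31, loopout = list(after_repeat = 27))
#' unit_order(leeix2)
#' @export
repeat_protein <- function(name, n_repeats, repeat_seqs = NULL,
                           ncap_seq = NULL, ccap_seq = NULL, loopout = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  n_repeats <- check_count(n_repeats, "n_repeats", min = 1L)
  if (!is.null(repeat_seqs)) {
    repeat_seqs <- as.character(repeat_seqs)
    if (length(repeat_seqs) != n_repeats) {
      abort(sprintf("`repeat_seqs` has length %d but `n_repeats` is %d.",
                    length(repeat_seqs), n_repeats))
    }
  }
  if (!is.null(loopout)) {
    if (!is.list(loopout) || is.null(loopout$after_repeat)) {
      abort("`loopout` must be a list with an `after_repeat` field.")
    }
    loopout$after_repeat <- check_count(loopout$after_repeat, "loopout$after_repeat",
                                        min = 1L)
    if (loopout$after_repeat >= n_repeats) {
      abort("`loopout$after_repeat` must lie strictly inside the repeat ordering (between two repeats).")
    }
    loopout$seq <- if (is.null(loopout$seq)) NULL else as.character(loopout$seq)
  }
  structure(
    list(name = name, n_repeats = n_repeats, repeat_seqs = repeat_seqs,
         ncap_seq = ncap_seq, ccap_seq = ccap_seq, loopout = loopout),
    class = "repeat_protein"
  )
}

#' @export
print.repeat_protein <- function(x, ...) {
  cat(sprintf("<repeat_protein> %s: %d repeats%s%s\n", x$name, x$n_repeats,
              if (!is.null(x$loopout))
                sprintf(", loopout after repeat %d", x$loopout$after_repeat) else "",
              if (!is.null(x$repeat_seqs)) ", with sequences" else ""))
  invisible(x)
}

#' Linearised unit ordering of a repeat protein
#'
#' Returns the design units of the protein in order: repeats `1..R` with the
#' loopout pseudo-unit (label `"l/o"`) interleaved immediately after the
#' repeat it follows. Caps are not units; they are appended at assembly.
#'
#' @param protein A [repeat_protein()].
#' @return Character vector of unit labels, length `n_repeats` (+1 with a
#'   loopout).
#' @export
unit_order <- function(protein) {
  stopifnot(inherits(protein, "repeat_protein"))
  labels <- as.character(seq_len(protein$n_repeats))
  if (!is.null(protein$loopout)) {
    labels <- append(labels, "l/o", after = protein$loopout$after_repeat)
  }
  labels
}

#' Unit table of a repeat protein
#'
#' One row per design unit in order, with its ordinal position, label,
#' repeat index (`NA` for the loopout) and sequence when available.
#'
#' @inheritParams unit_order
#' @return A tibble with columns `ord`, `label`, `is_loopout`,
#'   `repeat_index`, `seq`.
#' @export
unit_table <- function(protein) {
  labels <- unit_order(protein)
  is_lo <- labels == "l/o"
  seqs <- rep(NA_character_, length(labels))
  if (!is.null(protein$repeat_seqs)) {
    seqs[!is_lo] <- protein$repeat_seqs
  }
  if (any(is_lo) && !is.null(protein$loopout$seq)) {
    seqs[is_lo] <- protein$loopout$seq
  }
  repeat_index <- rep(NA_integer_, length(labels))
  repeat_index[!is_lo] <- seq_len(protein$n_repeats)
  tibble(
    ord = seq_along(labels),
    label = labels,
    is_loopout = is_lo,
    repeat_index = repeat_index,
    seq = seqs
  )
}

#' Number of design units (repeats plus loopout pseudo-unit)
#' @inheritParams unit_order
#' @return Integer unit count.
#' @export
n_units <- function(protein) {
  protein$n_repeats + as.integer(!is.null(protein$loopout))
}

# ordinal position of a repeat index in the unit ordering
ord_of_repeat <- function(protein, i) {
  i <- as.integer(i)
  if (any(i < 1L | i > protein$n_repeats)) {
    abort(sprintf("repeat index out of range 1..%d.", protein$n_repeats))
  }
  if (is.null(protein$loopout)) i else i + as.integer(i > protein$loopout$after_repeat)
}

# a window in repeat indices -> inclusive ordinal span (loopout absorbed
# automatically when interior to the window)
repeat_window_to_ord <- function(protein, start, end) {
  stopifnot(start <= end)
  c(ord_of_repeat(protein, start), ord_of_repeat(protein, end))
}

#' Read a repeat-protein definition from YAML or JSON
#'
#' The file holds `name`, `n_repeats` and optionally `ncap_seq`, `ccap_seq`,
#' `repeat_seqs` and `loopout: {after_repeat, seq}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [repeat_protein()].
#' @export
read_repeat_protein <- function(path) {
  spec <- read_config_file(path)
  protein_from_list(spec)
}

protein_from_list <- function(spec) {
  required <- c("name", "n_repeats")
  missing <- setdiff(required, names(spec))
  if (length(missing)) {
    abort(sprintf("protein definition is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  allowed <- c(required, "repeat_seqs", "ncap_seq", "ccap_seq", "loopout")
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown protein field(s): %s", paste(unknown, collapse = ", ")))
  }
  repeat_protein(
    name = spec$name,
    n_repeats = spec$n_repeats,
    repeat_seqs = if (is.null(spec$repeat_seqs)) NULL else unlist(spec$repeat_seqs),
    ncap_seq = spec$ncap_seq,
    ccap_seq = spec$ccap_seq,
    loopout = spec$loopout
  )
}

check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  as.integer(x)
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("unsupported config format '.%s' (use YAML or JSON).", ext))
  }
}
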