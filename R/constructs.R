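#' Assemble construct amino-acid sequences
#'
#' Every testable construct is the protein's N-cap, the unit sequences of
#' one contiguous window in order, and the C-cap. The caps bury the
#' hydrophobic cores of the first and last repeats, so they are appended to
#' all constructs by default.
#'
#' @param plan A [segmentation_plan].
#' @param protein The [repeat_protein()] carrying sequences for the caps
#'   and every unit in the plan's windows.
#' @param include_caps Append `ncap_seq`/`ccap_seq`; default `TRUE`.
#' @return The plan tibble with an added `seq` column.
#' @export
assemble_constructs <- function(plan, protein, include_caps = TRUE) {
  ut <- unit_table(protein)
  seqs <- vapply(seq_len(nrow(plan)), function(j) {
    assemble_window(ut, protein, plan$start_ord[j], plan$end_ord[j],
                    include_caps)
  }, character(1))
  dplyr::mutate(as_tibble(plan), seq = seqs)
}

#' @rdname assemble_constructs
#' @param start_ord,end_ord Window in ordinal unit positions.
#' @return `assemble_construct()` returns a single amino-acid string.
#' @export
assemble_construct <- function(protein, start_ord, end_ord,
                               include_caps = TRUE) {
  assemble_window(unit_table(protein), protein, start_ord, end_ord,
                  include_caps)
}

assemble_window <- function(ut, protein, start_ord, end_ord, include_caps) {
  units <- ut[ut$ord >= start_ord & ut$ord <= end_ord, ]
  missing <- units$label[is.na(units$seq)]
  if (include_caps) {
    if (is.null(protein$ncap_seq)) missing <- c("N-cap", missing)
    if (is.null(protein$ccap_seq)) missing <- c(missing, "C-cap")
  }
  if (length(missing)) {
    abort(sprintf("sequences unavailable for unit(s): %s",
                  paste(missing, collapse = ", ")))
  }
  core <- paste(units$seq, collapse = "")
  if (include_caps) paste0(protein$ncap_seq, core, protein$ccap_seq) else core
}

#' Write plan constructs as multi-FASTA
#'
#' One amino-acid record per construct, in plan order, with header
#' `<construct_id> <protein> units <start>-<end>`; sequence lines wrapped
#' at 60 columns.
#'
#' @inheritParams assemble_constructs
#' @param path Output file path.
#' @return The assembled plan tibble, invisibly.
#' @export
write_constructs_fasta <- function(plan, protein, path, include_caps = TRUE) {
  assembled <- assemble_constructs(plan, protein, include_caps = include_caps)
  if (nrow(assembled) == 0L) {
    warn("empty construct list: writing an empty FASTA file.")
    file.create(path)
    return(invisible(assembled))
  }
  aa <- Biostrings::AAStringSet(assembled$seq)
  names(aa) <- sprintf("%s %s units %s-%s", assembled$construct_id,
                       protein$name, assembled$start_label,
                       assembled$end_label)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(assembled)
}
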