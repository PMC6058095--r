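# Readers and writers for the pipeline's plain-text formats:
# protein FASTA, sample metadata TSV, report TSVs.

HABITAT_LEVELS <- c("open_ocean", "coastal", "estuary")

#' Read protein sequences from FASTA
#'
#' The record id is the first whitespace-delimited token of the header.
#'
#' @param path FASTA file.
#' @return Data frame with columns `id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  data.frame(id = ids, sequence = as.character(aa), row.names = NULL)
}

#' Write protein sequences to FASTA
#'
#' @param records data frame with `id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read sample metadata and harmonize habitat labels
#'
#' Expects a TSV with columns `sample_id` and `habitat` (one of
#' `open_ocean`, `coastal`, `estuary`). Estuaries are a coastal subtype
#' sampled too sparsely to stand alone, so estuary records are relabeled
#' `coastal` for analysis; the original label is retained in
#' `habitat_original` for provenance.
#'
#' @param path TSV file.
#' @param merge_estuary logical; relabel estuary as coastal (default TRUE).
#' @return Data frame with `sample_id`, `habitat`, `habitat_original`.
#' @export
read_sample_metadata <- function(path, merge_estuary = TRUE) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "habitat") %in% names(md)))
  bad <- setdiff(unique(md$habitat), HABITAT_LEVELS)
  if (length(bad))
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  md$habitat_original <- md$habitat
  if (merge_estuary) md$habitat[md$habitat == "estuary"] <- "coastal"
  md
}

#' Join habitat labels onto protein records
#'
#' Records are matched to samples either through an explicit `sample_id`
#' column or, failing that, through the id prefix convention
#' `<sample_id>_<suffix>`. Records that match no sample are an error: the
#' message lists the orphan ids.
#'
#' @param records data frame with `id` (and optionally `sample_id`).
#' @param metadata output of [read_sample_metadata()].
#' @return `records` with `sample_id`, `habitat`, `habitat_original`.
#' @export
attach_habitat <- function(records, metadata) {
  stopifnot(is.data.frame(records), is.data.frame(metadata))
  if (!"sample_id" %in% names(records)) {
    records$sample_id <- sub("_[^_]*$", "", records$id)
  }
  idx <- match(records$sample_id, metadata$sample_id)
  if (anyNA(idx)) {
    orphans <- records$id[is.na(idx)]
    stop("records with no matching sample metadata: ",
         paste(head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) sprintf(" (and %d more)", length(orphans) - 10))
  }
  records$habitat <- metadata$habitat[idx]
  records$habitat_original <- metadata$habitat_original[idx]
  records
}

#' Write a report table as TSV
#'
#' Plain TSV writer used for all report outputs (comparison tables, rate
#' profiles, per-domain scores); deterministic formatting so seeded runs
#' are byte-identical.
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
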