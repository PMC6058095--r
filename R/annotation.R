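# Functional annotation: HMMER3 per-sequence hit tables, model-specific
# noise-cutoff filtering, and assignment of proteins to the NtcA-induced
# nitrogen-starvation cascade or the arginine biosynthetic pathway.

#' Genes of the two contrasted pathways
#'
#' Default gene-to-model mapping: the nine genes up-regulated through the
#' global nitrogen regulator NtcA under nitrogen starvation (NtcA itself,
#' glutamine synthetase glnA, the PII signaling protein, the urtBCDE urea
#' ABC-transporter subunits, recD, and the ammonium transporter amt1) and
#' the six arg genes of arginine biosynthesis, the metabolic control
#' up-regulated under nitrogen abundance.
#'
#' The model accessions shipped here are synthetic placeholders (one per
#' gene, `SYNM0001`...) so that synthetic hit tables and tests resolve;
#' for real hmmscan output, supply your own TSV mapping each gene to its
#' curated TIGRFAM accession(s) via [read_gene_table()].
#'
#' @return Data frame with columns `gene_symbol`, `pathway`
#'   (`ntca_induced` or `arg_biosynthesis`), `model_accession`.
#' @export
pathway_genes <- function() {
  path <- system.file("extdata", "pathway_models_synthetic.tsv",
                      package = "stoichgen")
  read_gene_table(path)
}

#' Read a gene-to-model mapping table
#'
#' @param path TSV with columns `gene_symbol`, `pathway`,
#'   `model_accession` (one row per gene-model pair).
#' @return Data frame with those columns.
#' @export
read_gene_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "pathway", "model_accession") %in% names(tab)))
  bad <- setdiff(unique(tab$pathway), c("ntca_induced", "arg_biosynthesis"))
  if (length(bad)) stop("unknown pathway label(s): ", paste(bad, collapse = ", "))
  tab
}

#' Parse an HMMER3 per-sequence hit table (`--tblout`)
#'
#' Lines starting with `#` are comments. Data lines have at least 19
#' whitespace-separated fields (the 19th onward is the free-text
#' description). For hmmscan output the target is the model and the
#' query is the protein.
#'
#' @param text file path, or character vector of lines.
#' @return Data frame with columns `query_id`, `model_accession`,
#'   `model_name`, `full_sequence_evalue`, `full_sequence_bitscore`.
#' @export
parse_hmm_table <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text) else text
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 19L)
      stop(sprintf("line %d: expected >= 19 fields, found %d", ln, length(f)))
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc))
      stop(sprintf("line %d: non-numeric E-value or bitscore", ln))
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[3], model_accession = f[2], model_name = f[1],
      full_sequence_evalue = ev, full_sequence_bitscore = sc)
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), model_accession = character(0),
                      model_name = character(0),
                      full_sequence_evalue = numeric(0),
                      full_sequence_bitscore = numeric(0)))
  do.call(rbind, rows)
}

#' Read a model noise-cutoff table
#'
#' @param path TSV with columns `model_accession`, `noise_cutoff_bits`.
#' @return Named numeric vector: model accession -> cutoff (bits).
#' @export
read_cutoff_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("model_accession", "noise_cutoff_bits") %in% names(tab)))
  setNames(as.numeric(tab$noise_cutoff_bits), tab$model_accession)
}

#' Filter hits at model-specific noise cutoffs
#'
#' Keeps hits whose full-sequence bitscore is at or above the cutoff of
#' their model (inclusive, matching HMMER's own cutoff semantics). Every
#' model occurring in `hits` must have a cutoff entry.
#'
#' @param hits output of [parse_hmm_table()].
#' @param cutoffs named numeric vector (model accession -> bits), e.g.
#'   from [read_cutoff_table()].
#' @return The surviving subset of `hits`.
#' @export
apply_noise_cutoff <- function(hits, cutoffs) {
  stopifnot(is.data.frame(hits), !is.null(names(cutoffs)))
  missing <- setdiff(unique(hits$model_accession), names(cutoffs))
  if (length(missing))
    stop("no noise cutoff for model(s): ", paste(missing, collapse = ", "))
  keep <- hits$full_sequence_bitscore >= cutoffs[hits$model_accession]
  hits[keep, , drop = FALSE]
}

#' Assign queries to pathway genes
#'
#' Each query is assigned to the gene of its highest-bitscore surviving
#' hit; ties break toward the lexicographically smallest model
#' accession. Queries whose best hit matches no model in the gene table
#' are left unassigned.
#'
#' @param hits noise-filtered hits ([apply_noise_cutoff()]).
#' @param gene_table gene-to-model mapping ([pathway_genes()] by default).
#' @return Data frame with columns `query_id`, `gene_symbol`, `pathway`.
#' @export
assign_pathway <- function(hits, gene_table = pathway_genes()) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(0), gene_symbol = character(0),
                      pathway = character(0)))
  ord <- order(hits$query_id, -hits$full_sequence_bitscore,
               hits$model_accession)
  best <- hits[ord, ][!duplicated(hits$query_id[ord]), , drop = FALSE]
  idx <- match(best$model_accession, gene_table$model_accession)
  keep <- !is.na(idx)
  data.frame(query_id = best$query_id[keep],
             gene_symbol = gene_table$gene_symbol[idx[keep]],
             pathway = gene_table$pathway[idx[keep]],
             row.names = NULL)
}
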