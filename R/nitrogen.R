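# Residue-level nitrogen scoring and sequence-level nitrogen content (Nc).
#
# Nc is the mean number of side-chain nitrogen atoms per residue:
# Nc = sum(n_i) / L, where n_i is the side-chain nitrogen count of the
# i-th residue and L the number of scorable residues. Side chains carry
# one nitrogen in Asn, Gln, Lys and Trp, two in His, three in Arg, and
# none in the remaining 14 standard amino acids.

#' Standard amino-acid alphabet (one-letter codes)
#' @keywords internal
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Ambiguity / non-scorable codes excluded from Nc
#' @keywords internal
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "*")

#' Side-chain nitrogen atom counts per standard residue
#'
#' @return Named integer vector over the 20 standard one-letter codes:
#'   N, Q, K, W map to 1; H to 2; R to 3; all others to 0. The counts
#'   total 9 over the standard alphabet.
#' @examples
#' nitrogen_table()[["R"]]  # 3
#' @export
nitrogen_table <- function() {
  tab <- setNames(integer(20), AA_STANDARD)
  tab[c("N", "Q", "K", "W")] <- 1L
  tab["H"] <- 2L
  tab["R"] <- 3L
  tab
}

.NITROGEN_TABLE <- local({
  tab <- setNames(integer(20), AA_STANDARD)
  tab[c("N", "Q", "K", "W")] <- 1L
  tab["H"] <- 2L
  tab["R"] <- 3L
  tab
})

#' Side-chain nitrogen count of residues
#'
#' Vectorized lookup of the side-chain nitrogen atom count. Lowercase
#' input is upcased. Non-standard codes (ambiguity codes `X B Z U O *`,
#' gaps, anything outside the 20-letter alphabet) yield `NA_integer_`,
#' the "ambiguous residue" signal: callers decide whether to drop or
#' fail on such positions.
#'
#' @param residue character vector of one-letter residue codes.
#' @return Integer vector; `NA` marks non-standard codes.
#' @examples
#' side_chain_nitrogen(c("R", "H", "G"))  # 3 2 0
#' @export
side_chain_nitrogen <- function(residue) {
  stopifnot(is.character(residue))
  if (any(nchar(residue) != 1L))
    stop("side_chain_nitrogen() expects single-letter codes")
  out <- .NITROGEN_TABLE[toupper(residue)]
  names(out) <- NULL
  out
}

#' Nitrogen content (Nc) of a protein sequence
#'
#' Computes Nc = sum of side-chain nitrogen counts / number of scorable
#' residues. Ambiguity codes (`X B Z U O *`) and any other non-standard
#' characters (e.g. alignment gaps) are excluded from both numerator and
#' denominator, so Nc remains a per-scorable-residue mean. Case is
#' ignored.
#'
#' @param sequence single character string of one-letter residue codes.
#' @return Object of class `"nitrogen_score"`: list with elements
#'   `value` (Nc, in `[0, 3]`) and `n_residues_counted`.
#' @examples
#' nitrogen_content("ARNDH")$value  # (0+3+1+0+2)/5 = 1.2
#' @export
nitrogen_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- .NITROGEN_TABLE[chars]
  ok <- !is.na(counts)
  if (!any(ok)) stop("unscorable sequence: no standard residues")
  structure(
    list(value = sum(counts[ok]) / sum(ok), n_residues_counted = sum(ok)),
    class = "nitrogen_score"
  )
}

#' @export
print.nitrogen_score <- function(x, ...) {
  cat(sprintf("Nc = %.6g over %d residues\n", x$value, x$n_residues_counted))
  invisible(x)
}

#' Nitrogen content over a selected set of positions
#'
#' Restricts the Nc computation to the given 1-based positions of the
#' sequence (used for rate-class- or domain-restricted scoring).
#' Ambiguity codes inside the selection are excluded as in
#' [nitrogen_content()].
#'
#' @param sequence single character string.
#' @param positions integer vector of distinct 1-based positions.
#' @return A `"nitrogen_score"` over the selected positions.
#' @export
nitrogen_content_masked <- function(sequence, positions) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  positions <- as.integer(positions)
  L <- nchar(sequence)
  if (length(positions) == 0L)
    stop("unscorable selection: empty position set")
  if (anyNA(positions) || any(positions < 1L) || any(positions > L))
    stop("positions must lie within [1, sequence length]")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]][positions]
  counts <- .NITROGEN_TABLE[chars]
  ok <- !is.na(counts)
  if (!any(ok)) stop("unscorable selection: no standard residues selected")
  structure(
    list(value = sum(counts[ok]) / sum(ok), n_residues_counted = sum(ok)),
    class = "nitrogen_score"
  )
}

#' Score a table of protein records for nitrogen content
#'
#' Bulk Nc computation over a record data frame, using Biostrings letter
#' counting (fast for metagenome-scale inputs). Sequences with no
#' scorable residue get `NA` with a warning.
#'
#' @param records data frame with at least `id` and `sequence` columns.
#' @return `records` with columns `nc` (nitrogen content) and
#'   `n_scorable` appended.
#' @export
score_proteins <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    records$nc <- numeric(0)
    records$n_scorable <- integer(0)
    return(records)
  }
  aa <- Biostrings::AAStringSet(toupper(records$sequence))
  lf <- Biostrings::letterFrequency(aa, letters = AA_STANDARD)
  n_scorable <- as.integer(rowSums(lf))
  total_n <- as.numeric(lf %*% .NITROGEN_TABLE[AA_STANDARD])
  nc <- ifelse(n_scorable > 0L, total_n / n_scorable, NA_real_)
  if (anyNA(nc)) warning("records with no scorable residues scored as NA")
  records$nc <- nc
  records$n_scorable <- n_scorable
  records
}

#' Length filter for protein records
#'
#' Keeps records strictly longer than `threshold` residues (the full
#' peptide length, gaps and ambiguity codes included), matching the
#' "longer than 100 amino acids" analysis filter.
#'
#' @param records data frame with a `sequence` column.
#' @param threshold minimum length (exclusive); default 100.
#' @return The subset of `records` with `nchar(sequence) > threshold`.
#' @export
filter_min_length <- function(records, threshold = 100L) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records),
            threshold >= 1)
  records[nchar(records$sequence) > threshold, , drop = FALSE]
}
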