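# Per-site evolutionary rate estimation.
#
# Pipeline: mask sparse alignment columns (< 10% ungapped), compute
# Poisson-corrected ("Jukes-Cantor" 20-state analogue) pairwise protein
# distances, build a neighbor-joining tree (branch lengths used as-is,
# no optimization), then estimate a posterior mean rate per column by
# empirical Bayes under the JTT model with a mean-one discrete-gamma
# rate prior. Rates are z-normalized over included columns and
# classified slow (z <= -0.75) / fast (z >= +0.75) / intermediate.

GAP_CHARS <- c("-", ".")

#' Build an alignment object from aligned sequences
#'
#' @param sequences named character vector of equal-length aligned
#'   sequences (residues and `-` gaps), or a character matrix with one
#'   row per sequence.
#' @return Object of class `"aa_alignment"`: character matrix, one row
#'   per sequence, one column per alignment column.
#' @export
alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    stopifnot(is.character(sequences), !is.null(names(sequences)))
    w <- unique(nchar(sequences))
    if (length(w) != 1L) stop("aligned rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 rows")
  class(m) <- c("aa_alignment", class(m))
  m
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (equal-length rows, `-` gaps).
#' @return An `"aa_alignment"`.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  alignment(seqs)
}

#' Column inclusion mask by ungapped fraction
#'
#' A column is excluded when fewer than `min_ungapped_fraction` of its
#' rows carry an (ungapped) amino acid; the comparison is strict, so a
#' column at exactly the threshold is included.
#'
#' @param aln an `"aa_alignment"`.
#' @param min_ungapped_fraction exclusion threshold; default 0.10.
#' @return Logical vector, `TRUE` for included columns.
#' @export
mask_columns <- function(aln, min_ungapped_fraction = 0.10) {
  stopifnot(inherits(aln, "aa_alignment"))
  ungapped <- colSums(!matrix(aln %in% GAP_CHARS, nrow(aln))) / nrow(aln)
  ungapped >= min_ungapped_fraction
}

#' Poisson-corrected distance between two aligned protein rows
#'
#' Over sites where both rows carry a standard residue, with mismatch
#' fraction `p`, the 20-state correction is
#' `d = -(19/20) * log(1 - (20/19) * p)`. At `p >= 0.95` the correction
#' diverges; the distance saturates at `max_distance` with a warning.
#'
#' @param row_i,row_j character vectors (one aligned row each).
#' @param max_distance saturation value; default 10.
#' @return Non-negative distance (expected substitutions per site).
#' @export
protein_distance <- function(row_i, row_j, max_distance = 10) {
  stopifnot(length(row_i) == length(row_j))
  ok <- toupper(row_i) %in% AA_STANDARD & toupper(row_j) %in% AA_STANDARD
  if (!any(ok)) stop("no shared ungapped sites between rows")
  p <- mean(toupper(row_i[ok]) != toupper(row_j[ok]))
  if (p >= 0.95) {
    warning(sprintf("mismatch fraction %.3f saturates the correction; ",
                    p), "distance capped at ", max_distance)
    return(max_distance)
  }
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Pairwise distance matrix for an alignment
#'
#' Vectorized all-vs-all [protein_distance()]; symmetric with zero
#' diagonal.
#'
#' @param aln an `"aa_alignment"`.
#' @param max_distance saturation value passed through.
#' @return Symmetric numeric matrix with row/col names = sequence ids.
#' @export
protein_distance_matrix <- function(aln, max_distance = 10) {
  stopifnot(inherits(aln, "aa_alignment"))
  n <- nrow(aln)
  std <- matrix(aln %in% AA_STANDARD, n)
  shared <- tcrossprod(std * 1)
  matches <- matrix(0, n, n)
  for (a in AA_STANDARD) {
    ia <- matrix(aln == a, n) * 1
    matches <- matches + tcrossprod(ia)
  }
  if (any(shared[upper.tri(shared)] == 0))
    stop("sequence pair(s) with no shared ungapped sites")
  p <- 1 - matches / shared
  sat <- p >= 0.95
  diag(sat) <- FALSE
  d <- -(19 / 20) * log(pmax(1 - (20 / 19) * p, 1e-12))
  if (any(sat)) {
    warning(sum(sat) / 2, " pair(s) at saturation; distance capped at ",
            max_distance)
    d[sat] <- max_distance
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative branch lengths (an NJ
#' artifact) are clamped to zero, and with no branch-length optimization
#' the NJ lengths are final.
#'
#' @param distances symmetric distance matrix with row/col names.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    d <- distances[1, 2]
    tr <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = c(d / 2, d / 2),
      tip.label = rownames(distances), Nnode = 1L), class = "phylo")
    return(tr)
  }
  tr <- ape::nj(distances)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Discretize a mean-one gamma rate prior
#'
#' K equal-probability categories of a gamma(alpha, alpha) distribution
#' (mean one); each category rate is the conditional mean of its
#' inter-quantile slice, renormalized so the category-weighted mean is
#' exactly one.
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories (>= 1).
#' @return Object of class `"rate_model"`: list with `alpha`, `K`,
#'   `rates` (increasing), `probs` (all `1/K`).
#' @export
discretize_gamma <- function(alpha, K) {
  stopifnot(alpha > 0, K >= 1)
  K <- as.integer(K)
  if (K == 1L) {
    return(structure(list(alpha = alpha, K = 1L, rates = 1, probs = 1),
                     class = "rate_model"))
  }
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  # E[X; a<X<b] for gamma(shape, rate=shape) = pgamma(b, shape+1) - pgamma(a, shape+1)
  upper <- pgamma(q[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(q[-(K + 1)], shape = alpha + 1, rate = alpha)
  rates <- K * (upper - lower)
  rates <- rates / mean(rates)
  structure(list(alpha = alpha, K = K, rates = rates, probs = rep(1 / K, K)),
            class = "rate_model")
}

# Prepare leaf partial-likelihood matrices and a postorder edge list.
# Returns the pieces .pruning_loglik() consumes repeatedly.
.pruning_setup <- function(aln, tree, columns = NULL) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("tree tips and alignment ids differ")
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  S <- length(columns)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  leaf_partials <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    row <- toupper(aln[tree$tip.label[i], columns])
    idx <- match(row, AA_STANDARD)
    Lm <- matrix(0, 20, S)
    known <- !is.na(idx)
    Lm[cbind(idx[known], which(known))] <- 1
    Lm[, !known] <- 1   # gap/ambiguity = missing data
    leaf_partials[[i]] <- Lm
  }
  list(tree = tree, n_tip = n_tip, S = S, leaf_partials = leaf_partials,
       columns = columns)
}

# Per-column log-likelihood at a single rate, by Felsenstein pruning
# with per-edge column rescaling (underflow-safe).
.pruning_loglik <- function(setup, model, rate) {
  tree <- setup$tree
  n_tip <- setup$n_tip
  S <- setup$S
  n_node <- tree$Nnode
  partials <- vector("list", n_tip + n_node)
  partials[seq_len(n_tip)] <- setup$leaf_partials
  logscale <- numeric(S)
  edge <- tree$edge
  elen <- pmax(tree$edge.length, 0)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]
    child <- edge[e, 2]
    P <- jtt_transition(elen[e], rate, model)
    P[P < 0] <- 0  # eigen roundoff at tiny rate*length
    contrib <- P %*% partials[[child]]
    cs <- colSums(contrib)  # any positive per-column factor is a valid rescale
    cs[cs == 0] <- 1
    contrib <- contrib / rep(cs, each = 20)
    logscale <- logscale + log(cs)
    if (is.null(partials[[parent]])) partials[[parent]] <- contrib
    else partials[[parent]] <- partials[[parent]] * contrib
  }
  root <- edge[nrow(edge), 1]
  log(colSums(model$pi * partials[[root]])) + logscale
}

#' Likelihood of one alignment column at a fixed rate
#'
#' Felsenstein pruning over the tree, with gaps and ambiguity codes
#' treated as missing data (all-ones partial vectors) and the root
#' weighted by the model's equilibrium frequencies; under a reversible
#' model the root placement is immaterial.
#'
#' @param column named character vector: residue (or gap) per tip label.
#' @param tree a `phylo` tree whose tips name the column entries.
#' @param model a `"substitution_model"`.
#' @param rate site rate multiplier.
#' @return The column likelihood (not log).
#' @export
site_likelihood <- function(column, tree, model = jtt_model(), rate = 1) {
  stopifnot(!is.null(names(column)))
  if (length(column) == 1L) {
    idx <- match(toupper(column), AA_STANDARD)
    return(if (is.na(idx)) 1 else unname(model$pi[idx]))
  }
  aln <- alignment(matrix(toupper(column), ncol = 1,
                          dimnames = list(names(column), NULL)))
  setup <- .pruning_setup(aln, tree)
  exp(.pruning_loglik(setup, model, rate))
}

#' Per-column log-likelihoods under each rate category
#'
#' @param aln an `"aa_alignment"`.
#' @param tree a `phylo` over the alignment ids.
#' @param model a `"substitution_model"`.
#' @param rate_model a `"rate_model"` from [discretize_gamma()].
#' @param columns integer vector of columns to evaluate (default all).
#' @return K x length(columns) matrix of log-likelihoods.
#' @export
site_category_logliks <- function(aln, tree, model, rate_model,
                                  columns = NULL) {
  setup <- .pruning_setup(aln, tree, columns)
  t(vapply(rate_model$rates,
           function(r) .pruning_loglik(setup, model, r),
           numeric(setup$S)))
}

.logsumexp_cols <- function(M) {
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(sweep(M, 2, mx))))
}

#' Empirical-Bayes posterior mean rate per column
#'
#' For column s, `r_hat_s = sum_k r_k p_k L_s(r_k) / sum_k p_k L_s(r_k)`
#' with the discrete-gamma categories as the prior. Computation is in
#' log space throughout, so category-likelihood underflow cannot occur.
#'
#' @inheritParams site_category_logliks
#' @param included logical column mask (from [mask_columns()]); excluded
#'   columns get `NA`.
#' @return Numeric vector of length `ncol(aln)`: posterior mean rate per
#'   column, `NA` where excluded.
#' @export
posterior_mean_rates <- function(aln, tree, model = jtt_model(),
                                 rate_model = discretize_gamma(1, 16),
                                 included = NULL) {
  if (is.null(included)) included <- rep(TRUE, ncol(aln))
  stopifnot(length(included) == ncol(aln))
  out <- rep(NA_real_, ncol(aln))
  cols <- which(included)
  if (!length(cols)) return(out)
  ll <- site_category_logliks(aln, tree, model, rate_model, cols)
  lw <- ll + log(rate_model$probs)        # recycled down columns of K x S
  mx <- apply(lw, 2, max)
  w <- exp(sweep(lw, 2, mx))
  w <- sweep(w, 2, colSums(w), "/")
  out[cols] <- as.numeric(crossprod(w, rate_model$rates))
  out
}

#' Maximum-likelihood gamma shape over a grid
#'
#' Maximizes the marginal log-likelihood
#' `sum_s log sum_k p_k L_s(r_k)` over candidate shapes. A maximum at
#' either grid edge is returned with a warning (the likelihood may be
#' monotone).
#'
#' @inheritParams site_category_logliks
#' @param grid candidate alpha values; default 25 log-spaced points in
#'   `[0.1, 5]`.
#' @param K number of rate categories; default 16.
#' @param included logical column mask; excluded columns are ignored.
#' @return The grid value maximizing the marginal likelihood, with
#'   attribute `"loglik"` (the profile over the grid).
#' @export
estimate_alpha <- function(aln, tree, model = jtt_model(),
                           grid = exp(seq(log(0.1), log(5), length.out = 25)),
                           K = 16, included = NULL) {
  if (is.null(included)) included <- rep(TRUE, ncol(aln))
  cols <- which(included)
  setup <- .pruning_setup(aln, tree, cols)
  prof <- vapply(grid, function(a) {
    rm <- discretize_gamma(a, K)
    ll <- t(vapply(rm$rates, function(r) .pruning_loglik(setup, model, r),
                   numeric(setup$S)))
    sum(.logsumexp_cols(ll + log(rm$probs)))
  }, numeric(1))
  best <- which.max(prof)
  if (best %in% c(1L, length(grid)))
    warning("alpha maximum at grid boundary (", signif(grid[best], 3),
            "); likelihood may be monotone")
  structure(grid[best], loglik = prof)
}

#' Z-score normalization of site rates
#'
#' Centers and scales rates over the non-missing (included) columns so
#' the mean score is 0 and the standard deviation 1. The population
#' (1/n) standard deviation is used, so two included columns normalize
#' to exactly -1 and +1. A degenerate profile (zero variance) maps to
#' all-zero scores.
#'
#' @param rates numeric vector of posterior mean rates (`NA` allowed for
#'   excluded columns).
#' @return Z-scores, `NA` preserved.
#' @export
normalize_scores <- function(rates) {
  ok <- !is.na(rates)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 included columns to normalize")
  mu <- mean(rates[ok])
  s <- sqrt(sum((rates[ok] - mu)^2) / n)
  z <- rates
  z[ok] <- if (s == 0) 0 else (rates[ok] - mu) / s
  z
}

#' Classify sites by normalized rate score
#'
#' Cutoffs are inclusive: `z <= slow_cutoff` is slow, `z >= fast_cutoff`
#' fast, anything between intermediate.
#'
#' @param z z-scores from [normalize_scores()] (`NA` allowed).
#' @param slow_cutoff default -0.75.
#' @param fast_cutoff default +0.75.
#' @return Character vector in `{slow, intermediate, fast}`; `NA`
#'   preserved.
#' @export
classify_sites <- function(z, slow_cutoff = -0.75, fast_cutoff = 0.75) {
  stopifnot(slow_cutoff < fast_cutoff)
  out <- ifelse(z <= slow_cutoff, "slow",
                ifelse(z >= fast_cutoff, "fast", "intermediate"))
  out[is.na(z)] <- NA_character_
  out
}

#' Full per-column rate profile for an alignment
#'
#' Convenience wrapper running the whole estimation: column masking,
#' pairwise distances, NJ tree (unless one is supplied), gamma shape
#' estimation (unless fixed), posterior mean rates, normalization and
#' classification.
#'
#' @param aln an `"aa_alignment"`.
#' @param tree optional `phylo`; reconstructed by NJ when `NULL`.
#' @param model substitution model.
#' @param K rate categories; default 16.
#' @param alpha fixed gamma shape, or `NULL` to estimate by grid ML.
#' @param alpha_grid grid for [estimate_alpha()].
#' @param min_ungapped_fraction column mask threshold.
#' @param slow_cutoff,fast_cutoff classification cutoffs.
#' @return Object of class `"site_rate_profile"`: data frame with
#'   columns `column`, `included`, `rate`, `z`, `class`; attributes
#'   `alpha` and `tree`.
#' @export
site_rate_profile <- function(aln, tree = NULL, model = jtt_model(),
                              K = 16, alpha = NULL,
                              alpha_grid = exp(seq(log(0.1), log(5),
                                                   length.out = 25)),
                              min_ungapped_fraction = 0.10,
                              slow_cutoff = -0.75, fast_cutoff = 0.75) {
  included <- mask_columns(aln, min_ungapped_fraction)
  if (is.null(tree)) tree <- nj_tree(protein_distance_matrix(aln))
  if (is.null(alpha))
    alpha <- as.numeric(estimate_alpha(aln, tree, model, alpha_grid, K,
                                       included))
  rm <- discretize_gamma(alpha, K)
  rates <- posterior_mean_rates(aln, tree, model, rm, included)
  z <- normalize_scores(rates)
  prof <- data.frame(column = seq_len(ncol(aln)), included = included,
                     rate = rates, z = z,
                     class = classify_sites(z, slow_cutoff, fast_cutoff))
  structure(prof, alpha = alpha, tree = tree,
            class = c("site_rate_profile", "data.frame"))
}

#' Write / read a rate profile TSV
#'
#' @param profile a `"site_rate_profile"` (or compatible data frame).
#' @param path TSV path.
#' @return `path` invisibly (writer); the profile data frame (reader).
#' @export
write_rate_profile <- function(profile, path) {
  write_report_tsv(as.data.frame(profile)[
    , c("column", "included", "rate", "z", "class")], path)
}

#' @rdname write_rate_profile
#' @export
read_rate_profile <- function(path) {
  prof <- read.delim(path, stringsAsFactors = FALSE)
  structure(prof, class = c("site_rate_profile", "data.frame"))
}

#' Map column rate classes onto an ungapped sequence
#'
#' Each ungapped position of the chosen row inherits the class of its
#' alignment column; positions falling in excluded columns carry `NA`
#' class and are omitted from masked nitrogen scoring.
#'
#' @param aln an `"aa_alignment"`.
#' @param sequence_id row to map.
#' @param profile a `"site_rate_profile"` for `aln`.
#' @return Data frame with one row per ungapped residue: `position`
#'   (1-based on the ungapped sequence), `column`, `residue`, `z`,
#'   `class`.
#' @export
map_rates_to_sequence <- function(aln, sequence_id, profile) {
  if (!sequence_id %in% rownames(aln))
    stop("unknown sequence id: ", sequence_id)
  row <- aln[sequence_id, ]
  ungapped <- which(!(row %in% GAP_CHARS))
  data.frame(position = seq_along(ungapped), column = ungapped,
             residue = row[ungapped],
             z = profile$z[ungapped], class = profile$class[ungapped],
             row.names = NULL)
}
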