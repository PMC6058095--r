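# Seeded synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes: two habitat
# groups whose amino-acid frequency profiles differ by a controlled
# relative difference in expected nitrogen content; membrane proteins
# with segmental topology; gene-family alignments evolved along a known
# tree with gamma-distributed site rates; and habitat-dependent
# composition shifts localized at designated fast-evolving sites. All
# randomness flows from one master seed through named substreams.

N_BEARING <- c("N", "Q", "K", "W", "H", "R")

#' Expected nitrogen content of a frequency profile
#'
#' @param frequencies named frequency vector over the standard alphabet.
#' @return `sum(freq * side-chain N count)`.
#' @export
expected_nc <- function(frequencies) {
  stopifnot(all(AA_STANDARD %in% names(frequencies)))
  sum(frequencies[AA_STANDARD] * .NITROGEN_TABLE[AA_STANDARD]) /
    sum(frequencies[AA_STANDARD])
}

.tilt_profile <- function(baseline, factor) {
  f <- baseline
  f[N_BEARING] <- f[N_BEARING] * factor
  f / sum(f)
}

#' Coastal and open-ocean amino-acid profiles at a target effect size
#'
#' The coastal profile is the baseline; the open-ocean profile
#' multiplies the frequencies of the six nitrogen-bearing residues
#' (N, Q, K, W, H, R) by a common tilt factor and renormalizes. The
#' factor is found by bisection so that the relative difference in
#' expected Nc, `100 * (Nc_open - Nc_coastal) / Nc_coastal`, matches
#' `target_rel_diff_percent` within 1e-6.
#'
#' @param baseline named baseline frequencies; default JTT equilibrium.
#' @param target_rel_diff_percent target percent difference
#'   (|target| < 50; negative = open ocean nitrogen-poorer).
#' @return List with elements `coastal` and `open_ocean`, each a list
#'   `(frequencies, habitat, expected_nc)` of class
#'   `"environment_profile"`.
#' @export
make_environment_profiles <- function(baseline = jtt_frequencies(),
                                      target_rel_diff_percent = -5) {
  stopifnot(abs(target_rel_diff_percent) < 50,
            all(AA_STANDARD %in% names(baseline)), all(baseline > 0))
  baseline <- baseline[AA_STANDARD] / sum(baseline[AA_STANDARD])
  nc0 <- expected_nc(baseline)
  target_nc <- nc0 * (1 + target_rel_diff_percent / 100)
  g <- function(f) expected_nc(.tilt_profile(baseline, f)) - target_nc
  lo <- 1e-9; hi <- 1
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0)
    stop("unattainable target relative difference")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  open_f <- .tilt_profile(baseline, (lo + hi) / 2)
  if (abs(relative_difference(expected_nc(open_f), nc0) -
          target_rel_diff_percent) > 1e-6)
    stop("bisection failed to reach the target within 1e-6")
  mk <- function(f, hab) structure(
    list(frequencies = f, habitat = hab, expected_nc = expected_nc(f)),
    class = "environment_profile")
  list(coastal = mk(baseline, "coastal"),
       open_ocean = mk(open_f, "open_ocean"))
}

.sample_residues <- function(n, frequencies) {
  paste(sample(AA_STANDARD, n, replace = TRUE,
               prob = frequencies[AA_STANDARD]), collapse = "")
}

#' Sample a proteome of i.i.d.-residue proteins from a profile
#'
#' @param profile an `"environment_profile"` (or named frequency
#'   vector).
#' @param n_sequences number of proteins.
#' @param length_range integer `(min, max)` for uniform lengths; the
#'   default minimum of 101 passes the `> 100` length filter by
#'   construction.
#' @param seed optional seed.
#' @param id_prefix prefix for generated ids.
#' @return Data frame with `id`, `sequence`.
#' @export
sample_proteome <- function(profile, n_sequences,
                            length_range = c(101L, 500L), seed = NULL,
                            id_prefix = "syn") {
  freqs <- if (inherits(profile, "environment_profile"))
    profile$frequencies else profile
  if (n_sequences == 0L)
    return(data.frame(id = character(0), sequence = character(0)))
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_sequences,
                   replace = TRUE)
    all_res <- sample(AA_STANDARD, sum(lens), replace = TRUE,
                      prob = freqs[AA_STANDARD])
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    seqs <- vapply(seq_len(n_sequences), function(i)
      paste(all_res[starts[i]:ends[i]], collapse = ""), character(1))
    data.frame(id = sprintf("%s%05d", id_prefix, seq_len(n_sequences)),
               sequence = seqs)
  })
}

#' Default transmembrane-segment residue profile
#'
#' Enriched in the hydrophobic residues that populate membrane-spanning
#' helices; tryptophan retains a small weight, so TM domains carry a
#' little side-chain nitrogen, as real ones do.
#'
#' @return Named frequency vector over the standard alphabet.
#' @export
default_tm_profile <- function() {
  w <- setNames(rep(0.004, 20), AA_STANDARD)
  w[c("A", "I", "L", "V", "F", "M", "G")] <-
    c(0.13, 0.14, 0.20, 0.14, 0.11, 0.05, 0.09)
  w["W"] <- 0.02
  w["C"] <- 0.02
  w / sum(w)
}

#' Simulate one membrane protein with known topology
#'
#' Assembles the sequence segment-wise: an optional signal peptide,
#' then alternating loops (from `loop_profile`) and transmembrane
#' helices (from `tm_profile`), starting on a random or given side. The
#' emitted Phobius short-format line re-parses to the true annotation.
#'
#' @param id protein id.
#' @param n_tm number of transmembrane segments (>= 1).
#' @param loop_profile frequency profile for loop (and signal) residues.
#' @param tm_profile frequency profile for TM residues.
#' @param tm_length_range,loop_length_range uniform integer ranges;
#'   defaults 15-30 and 5-80.
#' @param signal logical: prepend a signal peptide (length 18-25).
#' @param first_side `"i"`, `"o"`, or `NULL` for random.
#' @param seed optional seed.
#' @return List with `record` (data frame `id`, `sequence`),
#'   `annotation` (a `"topology_annotation"`), and `line` (Phobius
#'   short-format string).
#' @export
simulate_membrane_protein <- function(id, n_tm, loop_profile,
                                      tm_profile = default_tm_profile(),
                                      tm_length_range = c(15L, 30L),
                                      loop_length_range = c(5L, 80L),
                                      signal = FALSE, first_side = NULL,
                                      seed = NULL) {
  stopifnot(n_tm >= 1L)
  lp <- if (inherits(loop_profile, "environment_profile"))
    loop_profile$frequencies else loop_profile
  with_seed(seed, {
    if (is.null(first_side)) first_side <- sample(c("i", "o"), 1)
    kinds <- character(0); lens <- integer(0)
    if (signal) {
      kinds <- "signal"; lens <- sample(18:25, 1)
    }
    side <- first_side
    for (k in seq_len(n_tm)) {
      kinds <- c(kinds, .letter_side[[side]], "transmembrane")
      lens <- c(lens,
                sample(seq(loop_length_range[1], loop_length_range[2]), 1),
                sample(seq(tm_length_range[1], tm_length_range[2]), 1))
      side <- setdiff(c("i", "o"), side)
    }
    kinds <- c(kinds, .letter_side[[side]])
    lens <- c(lens, sample(seq(loop_length_range[1], loop_length_range[2]), 1))
    pieces <- vapply(seq_along(kinds), function(k) {
      prof <- if (kinds[k] == "transmembrane") tm_profile else lp
      .sample_residues(lens[k], prof)
    }, character(1))
    ends <- cumsum(lens)
    seg <- data.frame(kind = kinds, start = c(1L, head(ends, -1L) + 1L),
                      end = ends)
    ann <- topology_annotation(id, seg)
    list(record = data.frame(id = id, sequence = paste(pieces, collapse = "")),
         annotation = ann,
         line = write_phobius_short(list(ann)))
  })
}

#' Simulate a pure-birth (Yule) tree
#'
#' Branch lengths are rescaled so the mean root-to-tip path equals
#' `divergence` expected substitutions per site.
#'
#' @param n_taxa number of tips (>= 2).
#' @param divergence target mean root-to-tip depth; default 1.
#' @param seed optional seed.
#' @param tip_labels optional tip names (default `t1..tn`).
#' @return A `phylo` tree.
#' @export
simulate_yule_tree <- function(n_taxa, divergence = 1, seed = NULL,
                               tip_labels = NULL) {
  stopifnot(n_taxa >= 2L)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- mean(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
  tr$edge.length <- tr$edge.length * divergence / depth
  if (!is.null(tip_labels)) tr$tip.label <- tip_labels
  tr
}

#' Simulate a gap-free alignment along a tree with gamma site rates
#'
#' Each column draws a true rate from a mean-one gamma(`alpha`)
#' distribution; the root state is drawn from the model's equilibrium
#' frequencies and descendants evolve through
#' `P(rate * branch length)` under the substitution model. Afterwards,
#' at designated sites (the top `designated_fraction` of the true rate
#' distribution), tips labeled `open_ocean` swap nitrogen-bearing
#' residues to `swap_to` with probability `swap_prob`, creating a
#' nitrogen-content deficit localized in fast-evolving sites.
#'
#' @param tree a `phylo` tree.
#' @param model substitution model; default [jtt_model()].
#' @param alpha gamma shape of the true rate distribution.
#' @param n_columns alignment columns.
#' @param habitat optional named vector (tip label -> habitat) steering
#'   the swap; `NULL` disables the effect.
#' @param designated_fraction fraction of columns designated as effect
#'   carriers (taken from the top of the true rate distribution).
#' @param swap_prob per-residue swap probability at designated sites in
#'   open-ocean tips. The expected local Nc deficit at designated sites
#'   equals `swap_prob` (as a fraction) when `swap_to` carries no
#'   side-chain nitrogen.
#' @param swap_to replacement residue; default `"S"`.
#' @param seed optional seed.
#' @return List with `alignment` (an `"aa_alignment"`), `true_rates`
#'   (per column), and `designated` (logical per column).
#' @export
simulate_alignment <- function(tree, model = jtt_model(), alpha = 0.7,
                               n_columns, habitat = NULL,
                               designated_fraction = 0, swap_prob = 0,
                               swap_to = "S", seed = NULL) {
  stopifnot(alpha > 0, n_columns >= 1)
  with_seed(seed, {
    tree <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    S <- as.integer(n_columns)
    rates <- rgamma(S, shape = alpha, rate = alpha)
    states <- matrix(NA_integer_, n_tip + tree$Nnode, S)
    root <- n_tip + 1L
    states[root, ] <- sample.int(20L, S, replace = TRUE, prob = model$pi)
    cum_tri <- upper.tri(diag(20), diag = TRUE) * 1
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_eff <- max(tree$edge.length[e], 0) * rates
      E <- exp(outer(t_eff, model$eval))            # S x 20
      P <- (model$evec[states[parent, ], , drop = FALSE] * E) %*% model$ivec
      P[P < 0] <- 0
      Cum <- P %*% cum_tri
      u <- runif(S) * Cum[, 20]
      states[child, ] <- pmin(20L, as.integer(rowSums(Cum < u)) + 1L)
    }
    m <- matrix(AA_STANDARD[states[seq_len(n_tip), ]], n_tip, S,
                dimnames = list(tree$tip.label, NULL))
    designated <- rep(FALSE, S)
    if (designated_fraction > 0) {
      n_des <- max(1L, round(designated_fraction * S))
      designated[order(rates, decreasing = TRUE)[seq_len(n_des)]] <- TRUE
    }
    if (!is.null(habitat) && swap_prob > 0 && any(designated)) {
      open_tips <- names(habitat)[habitat == "open_ocean"]
      sub <- m[open_tips, designated, drop = FALSE]
      hit <- sub %in% N_BEARING & runif(length(sub)) < swap_prob
      sub[matrix(hit, nrow(sub))] <- swap_to
      m[open_tips, designated] <- sub
    }
    list(alignment = alignment(m), true_rates = rates,
         designated = designated)
  })
}
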