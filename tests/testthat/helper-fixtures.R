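# Shared fixtures: independent oracles and small random generators.
# Oracles are deliberately written as naive re-derivations, not calls
# into the package code paths they check.

# Naive per-character nitrogen-content oracle (printed residue table).
oracle_nc <- function(sequence) {
  tab <- c(N = 1, Q = 1, K = 1, W = 1, H = 2, R = 3,
           A = 0, D = 0, C = 0, E = 0, G = 0, I = 0, L = 0, M = 0,
           F = 0, P = 0, S = 0, T = 0, Y = 0, V = 0)
  total <- 0; n <- 0
  for (ch in strsplit(toupper(sequence), "")[[1]]) {
    if (ch %in% names(tab)) {
      total <- total + tab[[ch]]
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  total / n
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random valid topology annotation (loops >= 1 residue so the written
# prediction string is unambiguous).
random_annotation <- function(id = "p1") {
  n_tm <- sample(0:4, 1)
  signal <- runif(1) < 0.3
  kinds <- character(0); lens <- integer(0)
  if (signal) { kinds <- "signal"; lens <- sample(10:25, 1) }
  side <- sample(c("cytoplasmic", "periplasmic_extracellular"), 1)
  other <- function(s) setdiff(c("cytoplasmic", "periplasmic_extracellular"), s)
  if (n_tm == 0) {
    kinds <- c(kinds, side); lens <- c(lens, sample(30:120, 1))
  } else {
    for (k in seq_len(n_tm)) {
      kinds <- c(kinds, side, "transmembrane")
      lens <- c(lens, sample(1:60, 1), sample(15:30, 1))
      side <- other(side)
    }
    kinds <- c(kinds, side); lens <- c(lens, sample(1:60, 1))
  }
  ends <- cumsum(lens)
  topology_annotation(id, data.frame(
    kind = kinds, start = c(1L, head(ends, -1L) + 1L), end = ends))
}

# Brute-force column likelihood: sum over every assignment of states to
# the internal nodes of a (small) rooted tree.
brute_force_likelihood <- function(column, tree, model, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  leaf_states <- match(toupper(column[tree$tip.label]), AA20)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    jtt_transition(tree$edge.length[e], rate, model))
  grid <- as.matrix(expand.grid(rep(list(1:20), n_node)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    states <- c(leaf_states, grid[g, ])
    pr <- model$pi[grid[g, 1]]   # node n_tip + 1 is the root
    for (e in seq_len(nrow(tree$edge))) {
      pa <- states[tree$edge[e, 1]]
      ch <- states[tree$edge[e, 2]]
      if (is.na(ch)) next        # missing leaf: sums out to 1
      pr <- pr * Ps[[e]][pa, ch]
    }
    total <- total + pr
  }
  unname(total)
}

# Small study configuration for fast end-to-end tests.
tiny_study_config <- function(...) {
  study_config(
    n_nonmembrane_per_habitat = 120L,
    n_membrane_per_habitat = 40L,
    length_range = c(101L, 160L),
    gene_n_per_habitat = 16L,
    gene_n_columns = 200L,
    genes = data.frame(gene = c("NtcA", "argF"),
                       pathway = c("ntca_induced", "arg_biosynthesis"),
                       swap_prob = c(0.5, 0)),
    ...)
}
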