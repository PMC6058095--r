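# The Jones-Taylor-Thornton (JTT) amino-acid substitution model.
#
# The 190 relative exchangeabilities (lower triangle, order
# ARNDCQEGHILKMFPSTWYV) and the equilibrium frequencies are the standard
# published JTT values (the integer-scaled dialect distributed with
# phylogenetics software). The instantaneous rate matrix Q is assembled
# as Q_ij = s_ij * pi_j (i != j), rows summing to zero, and rescaled so
# the expected substitution rate at equilibrium is one: branch lengths
# are then in expected substitutions per site.

.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378,
  475, 9, 11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44,
  5, 74, 101, 64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263,
  30, 10, 15, 503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26,
  15, 4, 15, 59, 38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14,
  223, 42, 115, 209, 62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53,
  51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45,
  23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33, 40,
  115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961,
  14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8,
  14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285,
  118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQ <- c(
  0.0767479233, 0.0516909483, 0.0426449574, 0.0515439485,
  0.0198029802, 0.0407519592, 0.0618299382, 0.0731519268,
  0.0229439771, 0.0537609462, 0.0919039081, 0.0586759413,
  0.0238259762, 0.0401259599, 0.0509009491, 0.0687649312,
  0.0585649414, 0.0142609857, 0.0321019679, 0.0660049340)

#' Equilibrium amino-acid frequencies of the JTT model
#'
#' @return Named numeric vector over ARNDCQEGHILKMFPSTWYV, summing to 1.
#' @export
jtt_frequencies <- function() {
  f <- .JTT_FREQ / sum(.JTT_FREQ)
  names(f) <- AA_STANDARD
  f
}

#' Build the JTT substitution model
#'
#' Assembles the 20x20 instantaneous rate matrix from the JTT
#' exchangeabilities and equilibrium frequencies, rescaled to one
#' expected substitution per site per unit branch length. The
#' pi-symmetrized eigendecomposition is precomputed and cached on the
#' object, so transition matrices for arbitrary branch lengths and rates
#' are cheap.
#'
#' @param frequencies optional replacement equilibrium frequencies
#'   (named over the standard alphabet, summing to 1).
#' @return Object of class `"substitution_model"` with elements `Q`,
#'   `pi`, and the eigendecomposition (`evec`, `ivec`, `eval`).
#' @export
jtt_model <- function(frequencies = jtt_frequencies()) {
  stopifnot(length(frequencies) == 20L, all(frequencies > 0))
  pi <- as.numeric(frequencies) / sum(frequencies)
  S <- matrix(0, 20, 20, dimnames = list(AA_STANDARD, AA_STANDARD))
  S[lower.tri(S)] <- .JTT_EXCH
  S <- S + t(S)
  Q <- S * rep(pi, each = 20)      # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))         # expected rate at equilibrium
  Q <- Q / mu
  # symmetric form B = D^{1/2} Q D^{-1/2}, D = diag(pi); real eigensystem
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2              # enforce symmetry numerically
  eig <- eigen(B, symmetric = TRUE)
  evec <- eig$vectors / d          # rows scaled back: U = D^{-1/2} V
  ivec <- t(eig$vectors * d)       # U^{-1} = V' D^{1/2}
  structure(list(Q = Q, pi = setNames(pi, AA_STANDARD),
                 evec = evec, ivec = ivec, eval = eig$values),
            class = "substitution_model")
}

#' Transition probability matrix under the JTT model
#'
#' `P(t, r) = exp(Q * r * t)` computed from the cached symmetric
#' eigendecomposition; rows sum to one.
#'
#' @param branch_length branch length `t >= 0` (expected substitutions
#'   per site at rate 1).
#' @param rate site rate multiplier `r >= 0` (default 1).
#' @param model a `"substitution_model"` from [jtt_model()].
#' @return 20x20 transition probability matrix.
#' @export
jtt_transition <- function(branch_length, rate = 1, model = jtt_model()) {
  stopifnot(branch_length >= 0, rate >= 0,
            inherits(model, "substitution_model"))
  t_eff <- branch_length * rate
  P <- model$evec %*% (exp(model$eval * t_eff) * model$ivec)
  dimnames(P) <- dimnames(model$Q)
  P
}
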