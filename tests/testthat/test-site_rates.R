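jtt <- jtt_model()

test_that("column masking excludes columns under 10% ungapped", {
  rows <- replicate(20, strrep("-", 3))
  rows[1] <- "A--"          # col 1: 1/20 = 5% ungapped
  rows[2] <- "-R-"          # col 2 gets 2/20 = 10%
  rows[3] <- "-K-"
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- sprintf("s%d", 1:20)
  aln <- alignment(m)
  inc <- mask_columns(aln)
  expect_false(inc[1])      # 5% < 10% -> excluded
  expect_true(inc[2])       # exactly 10% -> included
  expect_false(inc[3])
  full <- alignment(c(a = "ARN", b = "ARN"))
  expect_true(all(mask_columns(full)))
})

test_that("the 20-state Poisson-corrected distance matches its closed form", {
  a <- strsplit(strrep("A", 100), "")[[1]]
  expect_equal(protein_distance(a, a), 0)
  b <- a; b[1:19] <- "R"    # p = 0.19
  expect_equal(protein_distance(a, b), -(19 / 20) * log(1 - (20 / 19) * 0.19),
               tolerance = 1e-12)
  expect_equal(protein_distance(a, b), 0.2120, tolerance = 1e-3)
  b95 <- a; b95[1:95] <- "R"
  expect_warning(d <- protein_distance(a, b95), "capped")
  expect_equal(d, 10)
  g1 <- c("A", "-"); g2 <- c("-", "A")
  expect_error(protein_distance(g1, g2), "no shared")
})

test_that("the distance matrix agrees with the pairwise function", {
  set.seed(8)
  m <- matrix(sample(c(AA20, "-"), 8 * 60, replace = TRUE,
                     prob = c(rep(0.0475, 20), 0.05)), 8, 60)
  rownames(m) <- sprintf("s%d", 1:8)
  aln <- alignment(m)
  # unrelated random rows sit near saturation: both paths must cap alike
  D <- suppressWarnings(protein_distance_matrix(aln))
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 8))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(D[i, j],
                 suppressWarnings(protein_distance(m[i, ], m[j, ])),
                 tolerance = 1e-12)
})

test_that("neighbor joining recovers additive trees exactly", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(sum(t2$edge.length), 3)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    njt <- nj_tree(ape::cophenetic.phylo(tr))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), njt), 0)
    expect_lt(phangorn::KF.dist(ape::unroot(tr), njt), 1e-9)
    expect_true(all(njt$edge.length >= 0))
  }
})

test_that("the JTT rate matrix is a proper reversible generator", {
  expect_equal(max(abs(rowSums(jtt$Q))), 0, tolerance = 1e-12)
  expect_equal(sum(jtt$pi), 1, tolerance = 1e-12)
  expect_equal(-sum(jtt$pi * diag(jtt$Q)), 1, tolerance = 1e-12)
  flux <- jtt$pi * jtt$Q
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-12)
})

test_that("embedded JTT constants match an independent reference", {
  ref <- local({
    phangorn:::getModelAA("JTT", bf = TRUE, Q = TRUE)
    list(exch = Q, freq = bf)
  })
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- ref$exch
  S <- S + t(S)
  piref <- ref$freq / sum(ref$freq)
  Qref <- S * rep(piref, each = 20)
  diag(Qref) <- -rowSums(Qref)
  Qref <- Qref / -sum(piref * diag(Qref))
  expect_equal(unname(jtt$Q), unname(Qref), tolerance = 1e-8)
  expect_equal(unname(jtt$pi), unname(piref), tolerance = 1e-8)
})

test_that("transition matrices satisfy the semigroup and ergodic limits", {
  expect_equal(jtt_transition(0, 1, jtt), diag(20), tolerance = 1e-12,
               ignore_attr = TRUE)
  Pbig <- jtt_transition(500, 1, jtt)
  expect_equal(max(abs(sweep(Pbig, 2, jtt$pi))), 0, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:10) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    lhs <- jtt_transition(t1, 1, jtt) %*% jtt_transition(t2, 1, jtt)
    expect_equal(max(abs(lhs - jtt_transition(t1 + t2, 1, jtt))), 0,
                 tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(jtt_transition(0.37, 1.8, jtt))), rep(1, 20),
               tolerance = 1e-12)
})

test_that("discrete gamma categories have the right conditional means", {
  expect_equal(discretize_gamma(2, 1)$rates, 1)
  r100 <- discretize_gamma(100, 4)$rates
  expect_true(all(abs(r100 - 1) < 0.2))
  # quadrature oracle at alpha = 1 (exponential)
  rm <- discretize_gamma(1, 4)
  q <- qgamma(seq(0, 1, length.out = 5), 1, 1)
  oracle <- vapply(1:4, function(k) {
    4 * integrate(function(x) x * dgamma(x, 1, 1), q[k], q[k + 1],
                  rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(rm$rates, oracle / mean(oracle), tolerance = 1e-6)
  for (a in c(0.2, 0.7, 3)) {
    rmk <- discretize_gamma(a, 16)
    expect_equal(sum(rmk$rates * rmk$probs), 1, tolerance = 1e-12)
    expect_true(all(diff(rmk$rates) > 0))
  }
})

test_that("pruning matches closed forms and exhaustive enumeration", {
  # single leaf: equilibrium frequency
  t1 <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       edge.length = 0.3, tip.label = "a", Nnode = 1L),
                  class = "phylo")
  expect_equal(site_likelihood(c(a = "R"), t1, jtt), unname(jtt$pi["R"]))
  # two leaves: sum_i pi_i P_ia P_ib
  t2 <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                       edge.length = c(0.2, 0.5),
                       tip.label = c("a", "b"), Nnode = 1L),
                  class = "phylo")
  r <- 1.4
  Pa <- jtt_transition(0.2, r, jtt); Pb <- jtt_transition(0.5, r, jtt)
  closed <- sum(jtt$pi * Pa[, "A"] * Pb[, "W"])
  expect_equal(site_likelihood(c(a = "A", b = "W"), t2, jtt, r), closed,
               tolerance = 1e-14)
  # 4 taxa vs brute force over all internal state assignments
  set.seed(31)
  for (i in 1:5) {
    tr <- ape::rtree(4)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.2)
    col <- setNames(sample(AA20, 4, replace = TRUE), tr$tip.label)
    rate <- runif(1, 0.2, 2)
    expect_equal(site_likelihood(col, tr, jtt, rate),
                 brute_force_likelihood(col, tr, jtt, rate),
                 tolerance = 1e-12)
  }
  # gap treated as missing data
  col <- setNames(c("A", "R", "-", "N"), tr$tip.label)
  expect_equal(site_likelihood(col, tr, jtt, 1),
               brute_force_likelihood(col, tr, jtt, 1), tolerance = 1e-12)
})

test_that("halving rates while doubling branch lengths leaves likelihoods fixed", {
  set.seed(14)
  tr <- simulate_yule_tree(8, seed = 2)
  sim <- simulate_alignment(tr, jtt, alpha = 1, n_columns = 30, seed = 3)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  l1 <- site_category_logliks(sim$alignment, tr, jtt,
                              discretize_gamma(1, 1))
  l2 <- site_category_logliks(sim$alignment, tr2, jtt,
                              structure(list(alpha = 1, K = 1L, rates = 0.5,
                                             probs = 1),
                                        class = "rate_model"))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("posterior mean rates are convex, monotone and exact for K = 1", {
  set.seed(17)
  tr <- simulate_yule_tree(12, seed = 5)
  sim <- simulate_alignment(tr, jtt, alpha = 0.7, n_columns = 40, seed = 6)
  r1 <- posterior_mean_rates(sim$alignment, tr, jtt, discretize_gamma(1, 1))
  expect_equal(r1, rep(1, 40))
  rm <- discretize_gamma(0.7, 8)
  r8 <- posterior_mean_rates(sim$alignment, tr, jtt, rm)
  expect_true(all(r8 >= min(rm$rates) - 1e-12))
  expect_true(all(r8 <= max(rm$rates) + 1e-12))
  # conserved column slower than a scrambled one on the same tree
  cons <- alignment(matrix("A", 12, 2,
                           dimnames = list(tr$tip.label, NULL)))
  cons[, 2] <- sample(AA20, 12, replace = TRUE)
  rc <- posterior_mean_rates(cons, tr, jtt, rm)
  expect_lt(rc[1], rc[2])
})

test_that("grid ML recovers the simulating gamma shape", {
  tr <- simulate_yule_tree(40, seed = 41)
  sim <- simulate_alignment(tr, jtt, alpha = 0.5, n_columns = 400, seed = 42)
  njt <- nj_tree(protein_distance_matrix(sim$alignment))
  a <- suppressWarnings(estimate_alpha(sim$alignment, njt, jtt, K = 16))
  expect_gte(as.numeric(a), 0.3)
  expect_lte(as.numeric(a), 0.8)
  expect_warning(
    estimate_alpha(sim$alignment, njt, jtt, grid = c(2, 3), K = 4),
    "boundary")
})

test_that("score normalization and classification follow the z conventions", {
  expect_equal(normalize_scores(c(1, 3)), c(-1, 1))
  expect_equal(normalize_scores(rep(2, 5)), rep(0, 5))
  set.seed(9)
  r <- c(rgamma(50, 1), NA, NA)
  z <- normalize_scores(r)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z[1:50]^2)), 1, tolerance = 1e-12)  # population sd
  expect_true(all(is.na(z[51:52])))
  expect_error(normalize_scores(c(1, NA)), "at least 2")
  expect_equal(classify_sites(c(-0.75, 0, 0.75, 2.1, -2, NA)),
               c("slow", "intermediate", "fast", "fast", "slow", NA))
})

test_that("rate classes map onto ungapped sequence positions", {
  aln <- alignment(c(a = "A-C", b = "AAC", c = "A-C", d = "AAC",
                     e = "A-C", f = "A-C", g = "A-C", h = "A-C",
                     i = "A-C", j = "A-C", k = "A-C", l = "A-C"))
  prof <- data.frame(column = 1:3, included = c(TRUE, FALSE, TRUE),
                     rate = c(1, NA, 1), z = c(-1, NA, 1),
                     class = c("slow", NA, "fast"))
  mp_b <- map_rates_to_sequence(aln, "b", prof)
  expect_equal(nrow(mp_b), 3L)
  expect_equal(mp_b$class, c("slow", NA, "fast"))
  expect_equal(sum(!is.na(mp_b$class)), 2L)
  mp_a <- map_rates_to_sequence(aln, "a", prof)
  expect_equal(mp_a$position, 1:2)
  expect_equal(mp_a$class, c("slow", "fast"))
  expect_error(map_rates_to_sequence(aln, "zz", prof), "unknown")
})
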