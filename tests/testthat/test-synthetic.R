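test_that("environment profiles hit the target Nc difference by bisection", {
  p0 <- make_environment_profiles(target_rel_diff_percent = 0)
  expect_equal(p0$open_ocean$frequencies, p0$coastal$frequencies,
               tolerance = 1e-9)
  uni <- setNames(rep(0.05, 20), AA20)
  p5 <- make_environment_profiles(uni, target_rel_diff_percent = -5)
  expect_equal(p5$open_ocean$expected_nc / p5$coastal$expected_nc, 0.95,
               tolerance = 1e-6)
  expect_equal(sum(p5$open_ocean$frequencies), 1, tolerance = 1e-12)
  expect_true(all(p5$open_ocean$frequencies >= 0))
  expect_error(make_environment_profiles(uni, -100))
  # expected Nc is the frequency-weighted side-chain count
  expect_equal(expected_nc(uni),
               sum(0.05 * c(1, 1, 1, 1, 2, 3)))  # N Q K W H R
})

test_that("sampled proteomes converge to the profile expectation", {
  profs <- make_environment_profiles(target_rel_diff_percent = -5)
  recs <- sample_proteome(profs$open_ocean, 2000, c(101, 300), seed = 10)
  expect_equal(nrow(recs), 2000L)
  expect_true(all(nchar(recs$sequence) > 100))
  scored <- score_proteins(recs)
  se <- sem(scored$nc)
  expect_lt(abs(mean(scored$nc) - profs$open_ocean$expected_nc), 3 * se)
  expect_equal(nrow(sample_proteome(profs$coastal, 0)), 0L)
  again <- sample_proteome(profs$open_ocean, 2000, c(101, 300), seed = 10)
  expect_identical(recs, again)
})

test_that("simulated membrane proteins re-parse to their true topology", {
  profs <- make_environment_profiles(target_rel_diff_percent = -5)
  set.seed(77)
  for (i in 1:20) {
    mp <- simulate_membrane_protein(
      sprintf("mp%d", i), n_tm = sample(1:5, 1),
      loop_profile = profs$coastal,
      loop_length_range = c(20L, 60L),
      tm_length_range = c(20L, 30L),  # TM domain itself must clear the filter
      signal = runif(1) < 0.5, seed = i)
    L <- nchar(mp$record$sequence)
    expect_equal(max(mp$annotation$segments$end), L)
    back <- parse_phobius_short(mp$line,
                                setNames(L, mp$record$id))[[1]]
    expect_equal(back$segments, mp$annotation$segments)
    dom <- dissect_domains(mp$record$sequence, mp$annotation)
    expect_true(filter_domain_sizes(dom, 20))  # loops >= 20 by construction
  }
  # a TM profile without nitrogen-bearing residues gives a zero-N TM domain
  tmp <- setNames(rep(0, 20), AA20)
  tmp[c("A", "L", "V", "I", "F", "G")] <- 1 / 6
  mp0 <- simulate_membrane_protein("z", 2, profs$coastal, tm_profile = tmp,
                                   seed = 4)
  dom0 <- dissect_domains(mp0$record$sequence, mp0$annotation)
  expect_equal(nitrogen_content(dom0$transmembrane)$value, 0)
})

test_that("Yule trees have the requested size and depth", {
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  t40 <- simulate_yule_tree(40, divergence = 1, seed = 2)
  expect_equal(length(t40$tip.label), 40L)
  expect_equal(ape::unroot(t40)$Nnode, 38L)  # unrooted binary internals
  depths <- ape::node.depth.edgelength(t40)[1:40]
  expect_equal(mean(depths), 1, tolerance = 1e-9)
  expect_identical(ape::write.tree(simulate_yule_tree(40, seed = 2)),
                   ape::write.tree(t40))
})

test_that("alignment simulation localizes the effect at designated sites", {
  tr <- simulate_yule_tree(16, seed = 31)
  habs <- setNames(rep(c("open_ocean", "coastal"), 8), tr$tip.label)
  null_sim <- simulate_alignment(tr, alpha = 0.7, n_columns = 60,
                                 habitat = habs, designated_fraction = 0.2,
                                 swap_prob = 0, seed = 32)
  eff_sim <- simulate_alignment(tr, alpha = 0.7, n_columns = 60,
                                habitat = habs, designated_fraction = 0.2,
                                swap_prob = 1, seed = 32)
  expect_true(all(mask_columns(eff_sim$alignment)))  # gap-free
  expect_equal(sum(eff_sim$designated), 12L)
  expect_identical(null_sim$true_rates, eff_sim$true_rates)
  coastal_tips <- names(habs)[habs == "coastal"]
  open_tips <- names(habs)[habs == "open_ocean"]
  # coastal rows untouched by the swap
  expect_identical(eff_sim$alignment[coastal_tips, ],
                   null_sim$alignment[coastal_tips, ])
  # open rows differ only inside designated columns
  diff_cols <- which(colSums(eff_sim$alignment[open_tips, ] !=
                             null_sim$alignment[open_tips, ]) > 0)
  expect_true(all(diff_cols %in% which(eff_sim$designated)))
  # with swap_prob 1 every N-bearing open residue at designated sites is gone
  sub <- eff_sim$alignment[open_tips, eff_sim$designated]
  expect_false(any(sub %in% c("N", "Q", "K", "W", "H", "R")))
  # designated sites come from the top of the true rate distribution
  expect_gte(min(null_sim$true_rates[null_sim$designated]),
             max(null_sim$true_rates[!null_sim$designated]) * 0.999)
})

test_that("a generated study round-trips through the loaders byte-identically", {
  dir1 <- file.path(tempdir(), "study_rt1")
  dir2 <- file.path(tempdir(), "study_rt2")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- tiny_study_config()
  st1 <- generate_study(cfg, dir1, seed = 99)
  generate_study(cfg, dir2, seed = 99)
  files <- list.files(dir1, recursive = TRUE)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
  }
  # loaders accept everything the generator wrote
  st <- load_study(dir1)
  expect_equal(sort(names(st$genes)), c("argF", "NtcA")[order(c("argF", "NtcA"))])
  expect_true(all(st$records$habitat %in% c("open_ocean", "coastal")))
  expect_true(any(st$metadata$habitat_original == "estuary"))
  expect_false(any(st$metadata$habitat == "estuary"))
  expect_equal(length(st$annotations), nrow(st$records))
  expect_equal(st$manifest$seed, 99L)
  expect_equal(st$manifest$target_rel_diff_percent, -5)
  # hit filtering keeps exactly the planted gene members
  kept <- apply_noise_cutoff(st$hits, st$cutoffs)
  asg <- assign_pathway(kept)
  expect_setequal(asg$query_id,
                  unlist(lapply(st$genes, function(g) names(g$habitat)),
                         use.names = FALSE))
  unlink(c(dir1, dir2), recursive = TRUE)
})
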