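test_that("Phobius short-format predictions parse to tiling segments", {
  anns <- parse_phobius_short(
    c("seq1 0 0 o",
      "seq2 1 0 i12-31o",
      "seq3 2 0 o5-24i30-49o"),
    c(seq1 = 50L, seq2 = 40L, seq3 = 60L))
  expect_equal(anns$seq1$segments$kind, "periplasmic_extracellular")
  expect_equal(anns$seq1$segments$end, 50L)
  expect_equal(anns$seq1$tm_count, 0L)

  s2 <- anns$seq2$segments
  expect_equal(s2$kind, c("cytoplasmic", "transmembrane",
                          "periplasmic_extracellular"))
  expect_equal(s2$start, c(1L, 12L, 32L))
  expect_equal(s2$end, c(11L, 31L, 40L))

  s3 <- anns$seq3$segments
  expect_equal(s3$kind[c(2, 4)], rep("transmembrane", 2))
  expect_equal(s3$start, c(1L, 5L, 25L, 30L, 50L))
  expect_equal(s3$end, c(4L, 24L, 29L, 49L, 60L))
  expect_equal(anns$seq3$tm_count, 2L)
})

test_that("signal-peptide prefixes become a leading signal segment", {
  ann <- parse_phobius_short("s 1 Y n1-15c20/21i25-44o", c(s = 60L))[[1]]
  expect_equal(ann$segments$kind[1], "signal")
  expect_equal(ann$segments$end[1], 20L)
  expect_equal(ann$segments$start[2], 21L)
})

test_that("malformed predictions fail with the offending line number", {
  lens <- c(a = 50L, b = 50L, c = 50L)
  expect_error(
    parse_phobius_short(c("a 0 0 o", "b 1 0 i12&31o", "c 0 0 i"), lens),
    "line 2")
  expect_error(parse_phobius_short("a 2 0 i12-31o", lens), "disagrees")
  expect_error(parse_phobius_short("a 1 0 i12-31o", c(a = 20L)), "length")
  expect_error(parse_phobius_short("a 1 0 12-31o", lens), "side letter")
})

test_that("membrane classification and TM multiplicity follow TM count", {
  lens <- c(m0 = 60L, m1 = 60L, m7 = 300L)
  pred7 <- "i5-24o45-64i85-104o125-144i165-184o205-224i245-264o"
  anns <- parse_phobius_short(
    c("m0 0 0 i", "m1 1 0 i12-31o", paste("m7 7 0", pred7)), lens)
  expect_false(classify_membrane(anns$m0))
  expect_true(classify_membrane(anns$m1))
  expect_true(classify_membrane(anns$m7))
  expect_equal(tm_multiplicity(anns$m1), "single_tm")
  expect_equal(tm_multiplicity(anns$m7), "multi_tm")
  expect_error(tm_multiplicity(anns$m0), "not a membrane protein")
})

test_that("domain dissection partitions the sequence and drops signals", {
  seq40 <- paste(rep(c("A", "R"), 20), collapse = "")
  ann <- parse_phobius_short("p 1 0 i12-31o", c(p = 40L))[[1]]
  dom <- dissect_domains(seq40, ann)
  expect_equal(dom$cytoplasmic, substr(seq40, 1, 11))
  expect_equal(dom$transmembrane, substr(seq40, 12, 31))
  expect_equal(dom$periplasmic_extracellular, substr(seq40, 32, 40))
  expect_equal(sum(nchar(unlist(dom))), 40L)

  sig <- parse_phobius_short("q 1 Y n1-15c20/21i25-44o", c(q = 60L))[[1]]
  seq60 <- strrep("K", 60)
  dsig <- dissect_domains(seq60, sig)
  expect_equal(nchar(dsig$cytoplasmic), 4L)       # 21-24
  expect_equal(nchar(dsig$transmembrane), 20L)    # 25-44
  expect_equal(nchar(dsig$periplasmic_extracellular), 16L)  # 45-60
  expect_equal(sum(nchar(unlist(dsig))), 60L - 20L)  # signal removed

  non_mem <- parse_phobius_short("r 0 0 o", c(r = 30L))[[1]]
  expect_error(dissect_domains(strrep("A", 30), non_mem),
               "not a membrane protein")
  expect_error(dissect_domains(strrep("A", 10), ann), "length")
})

test_that("domain-size filter is inclusive at 20 residues per domain", {
  mk <- function(a, b, c) list(cytoplasmic = strrep("A", a),
                               transmembrane = strrep("L", b),
                               periplasmic_extracellular = strrep("G", c))
  expect_false(filter_domain_sizes(mk(19, 40, 60)))
  expect_true(filter_domain_sizes(mk(20, 20, 61)))
  expect_false(filter_domain_sizes(mk(0, 30, 90)))
})

test_that("writer then parser is the identity on random annotations", {
  set.seed(99)
  for (i in 1:200) {
    ann <- random_annotation(sprintf("p%d", i))
    L <- max(ann$segments$end)
    line <- write_phobius_short(list(ann))
    back <- parse_phobius_short(line, setNames(L, ann$protein_id))[[1]]
    expect_equal(back$segments, ann$segments)
    expect_equal(back$tm_count, ann$tm_count)
  }
})

test_that("mirrored annotations swap the side domains but not the TM domain", {
  seq60 <- random_protein(60)
  a1 <- parse_phobius_short("x 2 0 i5-24o30-49i", c(x = 60L))[[1]]
  a2 <- parse_phobius_short("x 2 0 o5-24i30-49o", c(x = 60L))[[1]]
  d1 <- dissect_domains(seq60, a1)
  d2 <- dissect_domains(seq60, a2)
  expect_equal(d1$transmembrane, d2$transmembrane)
  expect_equal(d1$cytoplasmic, d2$periplasmic_extracellular)
  expect_equal(d1$periplasmic_extracellular, d2$cytoplasmic)
})
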