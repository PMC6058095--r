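# Whole-study generation: writes every input format the pipeline reads
# (FASTA, metadata TSV, Phobius short text, HMMER3-style hit table,
# cutoff TSV, per-gene aligned FASTA + Newick trees, truth TSVs, YAML
# manifest), all reproducible from one master seed.

#' Default synthetic study configuration
#'
#' The defaults define the study conditions every simulation-based test
#' runs under: a -5% open-ocean Nc deficit; roughly 12% membrane
#' proteins; an NtcA-cascade gene carrying a fast-site-localized -5%
#' deficit contrasted with a null arg-pathway gene; gene families of
#' 160 sequences per habitat over 1600 columns with gamma(0.7) site
#' rates. See the package vignette for the rationale (including the
#' power analysis behind the gene-family sizes).
#'
#' @param ... named overrides of any default.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(...) {
  cfg <- list(
    target_rel_diff_percent = -5,
    n_nonmembrane_per_habitat = 2000L,
    n_membrane_per_habitat = 270L,
    length_range = c(101L, 500L),
    tm_count_probs = c(0.4, 0.12, 0.12, 0.12, 0.08, 0.08, 0.08),
    tm_length_range = c(15L, 30L),
    loop_length_range = c(5L, 80L),
    signal_prob = 0.3,
    samples = list(open_ocean = c("OOS01", "OOS02", "OOS03"),
                   coastal = c("COS01", "COS02"),
                   estuary = "EST01"),
    genes = data.frame(
      gene = c("NtcA", "argF"),
      pathway = c("ntca_induced", "arg_biosynthesis"),
      swap_prob = c(0.05, 0)),
    gene_n_per_habitat = 160L,
    gene_n_columns = 1600L,
    gene_alpha = 0.7,
    gene_divergence = 1.0,
    designated_fraction = 0.20,
    swap_to = "S",
    noise_cutoff_bits = 25)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

.assign_samples <- function(ids, habitat, samples) {
  pool <- if (habitat == "open_ocean") samples$open_ocean
          else c(samples$coastal, samples$estuary)
  sample(pool, length(ids), replace = TRUE)
}

.hmm_line <- function(model_name, accession, query, evalue, score) {
  sprintf(paste0("%-20s %-10s %-28s -  %9.2g %8.1f %6.1f  %9.2g %8.1f",
                 " %6.1f   1.0  1  0  0  1  1  1  1 synthetic hit"),
          model_name, accession, query, evalue, score, 0.1, evalue, score,
          0.1)
}

#' Generate a complete synthetic study on disk
#'
#' Writes all pipeline inputs plus truth files into `dir` and returns
#' the in-memory study object. Regenerating with the same master seed
#' is byte-identical. On error, files created by the partial run are
#' removed.
#'
#' @param config a [study_config()].
#' @param dir output directory (created; must not exist or be empty).
#' @param seed master seed; all stage substreams derive from it.
#' @return Invisibly, the study object (as [load_study()] returns).
#' @export
generate_study <- function(config = study_config(), dir, seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  created <- !dir.exists(dir)
  if (!created && length(list.files(dir)))
    stop("output directory exists and is not empty: ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE))

  profiles <- make_environment_profiles(
    target_rel_diff_percent = config$target_rel_diff_percent)
  tm_profiles <- make_environment_profiles(
    baseline = default_tm_profile(),
    target_rel_diff_percent = config$target_rel_diff_percent)

  ## sample metadata (estuary kept distinct on disk; merged at load time)
  md <- data.frame(
    sample_id = unlist(config$samples, use.names = FALSE),
    habitat = rep(names(config$samples),
                  lengths(config$samples)))
  write_report_tsv(md, file.path(dir, "metadata.tsv"))

  records <- list(); annotations <- list()
  for (hab in c("open_ocean", "coastal")) {
    prof <- profiles[[hab]]
    ## non-membrane proteins
    nm <- with_seed(substream_seed(seed, paste0("proteome_", hab)), {
      recs <- sample_proteome(prof, config$n_nonmembrane_per_habitat,
                              config$length_range,
                              id_prefix = paste0(substr(hab, 1, 2), "nm"))
      recs$id <- paste0(.assign_samples(recs$id, hab, config$samples),
                        "_", recs$id)
      recs
    })
    for (i in seq_len(nrow(nm))) {
      annotations[[nm$id[i]]] <- topology_annotation(
        nm$id[i], data.frame(kind = "periplasmic_extracellular",
                             start = 1L, end = nchar(nm$sequence[i])))
    }
    records[[length(records) + 1L]] <- nm
    ## membrane proteins
    mem <- with_seed(substream_seed(seed, paste0("membrane_", hab)), {
      n <- config$n_membrane_per_habitat
      tms <- sample(seq_along(config$tm_count_probs), n, replace = TRUE,
                    prob = config$tm_count_probs)
      sigs <- runif(n) < config$signal_prob
      sams <- .assign_samples(seq_len(n), hab, config$samples)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        out[[i]] <- simulate_membrane_protein(
          id = sprintf("%s_%smem%05d", sams[i], substr(hab, 1, 2), i),
          n_tm = tms[i], loop_profile = prof,
          tm_profile = tm_profiles[[hab]]$frequencies,
          tm_length_range = config$tm_length_range,
          loop_length_range = config$loop_length_range,
          signal = sigs[i])
      }
      out
    })
    records[[length(records) + 1L]] <-
      do.call(rbind, lapply(mem, `[[`, "record"))
    for (m in mem) annotations[[m$annotation$protein_id]] <- m$annotation
  }
  records <- do.call(rbind, records)
  write_protein_fasta(records, file.path(dir, "proteins.fasta"))
  annotations <- annotations[records$id]
  write_phobius_short(annotations, file.path(dir, "phobius.txt"))

  ## gene families: trees, alignments, truth, hit tables
  gene_table <- pathway_genes()
  hit_lines <- c("#                                            --- full sequence ---- --- best 1 domain ---- description",
                 "# target name        accession  query name                   -    E-value  score   bias    E-value  score   bias   exp reg clu ov env dom rep inc")
  cutoff_rows <- list(); gene_aln <- list(); gene_meta <- list()
  for (g in seq_len(nrow(config$genes))) {
    gene <- config$genes$gene[g]
    acc <- gene_table$model_accession[match(gene, gene_table$gene_symbol)]
    if (is.na(acc)) stop("gene not in pathway table: ", gene)
    n_hab <- config$gene_n_per_habitat
    tree <- simulate_yule_tree(
      2L * n_hab, divergence = config$gene_divergence,
      seed = substream_seed(seed, paste0("tree_", gene)))
    habs <- with_seed(substream_seed(seed, paste0("labels_", gene)), {
      h <- sample(rep(c("open_ocean", "coastal"), n_hab))
      sams <- vapply(h, function(x) .assign_samples("x", x, config$samples),
                     character(1))
      tree$tip.label <- sprintf("%s_%s%04d", sams, gene,
                                seq_len(2L * n_hab))
      setNames(h, tree$tip.label)
    })
    sim <- simulate_alignment(
      tree, alpha = config$gene_alpha, n_columns = config$gene_n_columns,
      habitat = habs, designated_fraction = config$designated_fraction,
      swap_prob = config$genes$swap_prob[g], swap_to = config$swap_to,
      seed = substream_seed(seed, paste0("aln_", gene)))
    aln_rec <- data.frame(
      id = rownames(sim$alignment),
      sequence = apply(unclass(sim$alignment), 1, paste, collapse = ""))
    write_protein_fasta(aln_rec, file.path(dir, "genes",
                                           paste0(gene, ".afa")))
    ape::write.tree(tree, file.path(dir, "genes", paste0(gene, ".nwk")))
    write_report_tsv(
      data.frame(column = seq_along(sim$true_rates),
                 true_rate = sim$true_rates,
                 designated = sim$designated),
      file.path(dir, "truth", paste0("rates_", gene, ".tsv")))
    ## hit table rows: members above cutoff, decoys below
    sc <- with_seed(substream_seed(seed, paste0("hits_", gene)), {
      member <- config$noise_cutoff_bits + 5 +
        round(runif(length(habs), 0, 200), 1)
      decoy_ids <- sample(records$id, 5)
      decoy <- round(runif(5, 1, config$noise_cutoff_bits - 1), 1)
      list(member = member, decoy_ids = decoy_ids, decoy = decoy)
    })
    hit_lines <- c(hit_lines,
      .hmm_line(gene, acc, names(habs), 1e-20, sc$member),
      .hmm_line(gene, acc, sc$decoy_ids, 0.5, sc$decoy))
    cutoff_rows[[gene]] <- data.frame(model_accession = acc,
                                      noise_cutoff_bits = config$noise_cutoff_bits)
    gene_aln[[gene]] <- sim$alignment
    gene_meta[[gene]] <- list(tree = tree, habitat = habs,
                              true_rates = sim$true_rates,
                              designated = sim$designated)
  }
  writeLines(hit_lines, file.path(dir, "hits.tbl"))
  write_report_tsv(do.call(rbind, cutoff_rows), file.path(dir, "cutoffs.tsv"))

  manifest <- list(
    seed = as.integer(seed),
    target_rel_diff_percent = config$target_rel_diff_percent,
    expected_nc = list(coastal = profiles$coastal$expected_nc,
                       open_ocean = profiles$open_ocean$expected_nc),
    config = unclass(config)[setdiff(names(config), "genes")],
    genes = as.list(setNames(config$genes$swap_prob, config$genes$gene)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))

  ok <- TRUE
  invisible(load_study(dir))
}

#' Load a study directory
#'
#' Reads every file [generate_study()] writes (or equivalently formatted
#' real data: FASTA + metadata + Phobius short output + hmmscan tblout +
#' cutoff TSV + per-gene aligned FASTA) into one study object.
#'
#' @param dir study directory.
#' @return List with `records` (habitat-joined, estuary merged into
#'   coastal), `annotations`, `hits`, `cutoffs`, `genes` (per gene:
#'   `alignment`, `habitat`, and truth when present), `manifest`.
#' @export
load_study <- function(dir) {
  records <- read_protein_fasta(file.path(dir, "proteins.fasta"))
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  records <- attach_habitat(records, md)
  lens <- setNames(nchar(records$sequence), records$id)
  annotations <- parse_phobius_short(file.path(dir, "phobius.txt"), lens)
  hits <- parse_hmm_table(file.path(dir, "hits.tbl"))
  cutoffs <- read_cutoff_table(file.path(dir, "cutoffs.tsv"))
  gene_files <- list.files(file.path(dir, "genes"), pattern = "\\.afa$")
  genes <- list()
  for (f in gene_files) {
    gene <- sub("\\.afa$", "", f)
    aln <- read_alignment(file.path(dir, "genes", f))
    grecs <- data.frame(id = rownames(aln))
    grecs <- attach_habitat(grecs, md)
    truth_path <- file.path(dir, "truth", paste0("rates_", gene, ".tsv"))
    truth <- if (file.exists(truth_path))
      read.delim(truth_path, stringsAsFactors = FALSE) else NULL
    nwk <- file.path(dir, "genes", paste0(gene, ".nwk"))
    genes[[gene]] <- list(
      alignment = aln,
      habitat = setNames(grecs$habitat, grecs$id),
      tree = if (file.exists(nwk)) ape::read.tree(nwk) else NULL,
      truth = truth)
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path))
    yaml::read_yaml(manifest_path) else NULL
  list(records = records, metadata = md, annotations = annotations,
       hits = hits, cutoffs = cutoffs, genes = genes, manifest = manifest,
       dir = dir)
}
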