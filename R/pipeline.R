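# End-to-end orchestration: overall membrane/non-membrane contrast,
# per-domain contrast, and rate-class-stratified per-gene contrasts,
# with a config holding every analysis constant.

#' Default run configuration
#'
#' Collects the analysis constants: the `> 100` residue length filter,
#' the `>= 20` residue per-domain filter, the `< 10%` ungapped column
#' exclusion, the discrete-gamma settings, the `+/- 0.75` rate-class
#' cutoffs, and the test settings (one-sided "open ocean poorer" by
#' default; the pathway scan uses the two-sided variant).
#'
#' @param ... named overrides.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_length = 100L,
    min_per_domain = 20L,
    min_ungapped_fraction = 0.10,
    K = 16L,
    alpha = NULL,              # NULL = estimate by grid ML
    alpha_grid = exp(seq(log(0.1), log(5), length.out = 25)),
    slow_cutoff = -0.75,
    fast_cutoff = 0.75,
    alternative = "less",
    rate_alternative = "two_sided",
    method = "normal_approx",
    n_permutations = 10000L,
    seed = NULL)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Overall membrane / non-membrane comparison
#'
#' Scores all proteins passing the length filter, splits them by
#' membrane classification, and contrasts open-ocean vs coastal Nc
#' within each class.
#'
#' @param study study object from [load_study()] / [generate_study()].
#' @param config a [run_config()].
#' @return Data frame with one `"group_comparison"` row per membrane
#'   class (`non_membrane`, `membrane`).
#' @export
run_overall_comparison <- function(study, config = run_config()) {
  recs <- filter_min_length(study$records, config$min_length)
  recs <- score_proteins(recs)
  missing_ann <- setdiff(recs$id, names(study$annotations))
  if (length(missing_ann))
    stop("records with no topology annotation: ",
         paste(head(missing_ann, 5), collapse = ", "))
  is_mem <- vapply(study$annotations[recs$id], classify_membrane, logical(1))
  message(sprintf("overall: %d records after length filter (%d membrane)",
                  nrow(recs), sum(is_mem)))
  rows <- lapply(c(non_membrane = FALSE, membrane = TRUE), function(m) {
    compare_groups(recs[is_mem == m, ], stratum = if (m) "membrane" else
                   "non_membrane",
                   alternative = config$alternative, method = config$method,
                   n_permutations = config$n_permutations,
                   seed = config$seed)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-domain comparison for membrane proteins
#'
#' Dissects each membrane protein passing the length and per-domain
#' size filters into cytoplasmic / transmembrane /
#' periplasmic-extracellular domains and contrasts per-domain Nc
#' between habitats within each domain kind x TM multiplicity stratum.
#' A stratum whose coastal mean is zero reports `NA` relative
#' difference.
#'
#' @inheritParams run_overall_comparison
#' @return Data frame of comparison rows (up to 6 strata), with
#'   `domain_kind` and `tm_multiplicity` columns.
#' @export
run_domain_comparison <- function(study, config = run_config()) {
  recs <- filter_min_length(study$records, config$min_length)
  anns <- study$annotations[recs$id]
  is_mem <- vapply(anns, classify_membrane, logical(1))
  recs <- recs[is_mem, , drop = FALSE]
  per_domain <- list()
  kept <- 0L
  for (i in seq_len(nrow(recs))) {
    ann <- study$annotations[[recs$id[i]]]
    dom <- dissect_domains(recs$sequence[i], ann)
    if (!filter_domain_sizes(dom, config$min_per_domain)) next
    kept <- kept + 1L
    for (kind in names(dom)) {
      sc <- nitrogen_content(dom[[kind]])
      per_domain[[length(per_domain) + 1L]] <- data.frame(
        id = recs$id[i], habitat = recs$habitat[i],
        tm_multiplicity = tm_multiplicity(ann), domain_kind = kind,
        domain_length = nchar(dom[[kind]]), nc = sc$value)
    }
  }
  message(sprintf("domains: %d/%d membrane proteins pass the %d-aa filter",
                  kept, nrow(recs), config$min_per_domain))
  tab <- do.call(rbind, per_domain)
  out <- list()
  for (mult in c("single_tm", "multi_tm")) {
    for (kind in c("cytoplasmic", "transmembrane",
                   "periplasmic_extracellular")) {
      sub <- tab[tab$tm_multiplicity == mult & tab$domain_kind == kind, ]
      row <- tryCatch(
        compare_groups(sub, stratum = paste(mult, kind, sep = "/"),
                       alternative = config$alternative,
                       method = config$method,
                       n_permutations = config$n_permutations,
                       seed = config$seed),
        error = function(e) NULL)
      if (is.null(row)) next
      if (row$mean_coastal == 0) row$rel_diff_percent <- NA_real_
      row$tm_multiplicity <- mult
      row$domain_kind <- kind
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Rate-class-stratified comparison per gene family
#'
#' For each gene alignment: estimates the per-column rate profile
#' ([site_rate_profile()]), maps classes onto each ungapped sequence,
#' computes per-sequence Nc masked to fast and to slow residues, and
#' contrasts habitats within each class. Genes (or classes) with fewer
#' than 2 sequences per group, or with no sites in a class, are
#' reported without a test (`NA` p-value) and flagged by a warning.
#'
#' @inheritParams run_overall_comparison
#' @param genes optional character vector restricting the gene set.
#' @return Data frame: one row per gene x rate class with the
#'   comparison fields plus `gene`, `class`, `n_sites`.
#' @export
run_rate_stratified_comparison <- function(study, config = run_config(),
                                           genes = NULL) {
  gene_set <- if (is.null(genes)) names(study$genes) else genes
  out <- list()
  for (gene in gene_set) {
    gd <- study$genes[[gene]]
    prof <- site_rate_profile(
      gd$alignment, model = jtt_model(), K = config$K,
      alpha = config$alpha, alpha_grid = config$alpha_grid,
      min_ungapped_fraction = config$min_ungapped_fraction,
      slow_cutoff = config$slow_cutoff, fast_cutoff = config$fast_cutoff)
    for (cls in c("fast", "slow")) {
      n_sites <- sum(prof$class == cls, na.rm = TRUE)
      vals <- lapply(rownames(gd$alignment), function(id) {
        mp <- map_rates_to_sequence(gd$alignment, id, prof)
        sel <- mp$position[!is.na(mp$class) & mp$class == cls]
        if (!length(sel)) return(NULL)
        seqr <- paste(mp$residue, collapse = "")
        nc <- tryCatch(nitrogen_content_masked(seqr, sel)$value,
                       error = function(e) NA_real_)
        data.frame(id = id, habitat = unname(gd$habitat[id]), nc = nc)
      })
      vals <- do.call(rbind, vals)
      row <- if (is.null(vals) || n_sites == 0L) NULL else tryCatch(
        compare_groups(vals, stratum = paste(gene, cls, sep = "/"),
                       alternative = config$rate_alternative,
                       method = config$method,
                       n_permutations = config$n_permutations,
                       seed = config$seed, n_sites = n_sites),
        error = function(e) NULL)
      if (is.null(row)) {
        warning(sprintf("gene %s, class %s: insufficient data; no test run",
                        gene, cls))
        row <- data.frame(stratum = paste(gene, cls, sep = "/"),
                          N_open = NA_integer_, N_coastal = NA_integer_,
                          mean_open = NA_real_, mean_coastal = NA_real_,
                          sem_open = NA_real_, sem_coastal = NA_real_,
                          rel_diff_percent = NA_real_, p_value = NA_real_,
                          test = config$method,
                          alternative = config$rate_alternative,
                          n_sites = n_sites)
      }
      row$gene <- gene
      row$class <- cls
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full pipeline on a study directory
#'
#' Loads the study, runs the three comparisons, and writes the three
#' figure-analogue report TSVs (`overall.tsv`, `domains.tsv`,
#' `rate_classes.tsv`) plus a run manifest into `out_dir`.
#'
#' @param study_dir input study directory ([load_study()] formats).
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @return Invisibly, a list of the three report data frames.
#' @export
run_all <- function(study_dir, out_dir, config = run_config()) {
  study <- load_study(study_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  overall <- run_overall_comparison(study, config)
  domains <- run_domain_comparison(study, config)
  rates <- run_rate_stratified_comparison(study, config)
  write_report_tsv(overall, file.path(out_dir, "overall.tsv"))
  write_report_tsv(domains, file.path(out_dir, "domains.tsv"))
  write_report_tsv(rates, file.path(out_dir, "rate_classes.tsv"))
  yaml::write_yaml(list(study_dir = study_dir,
                        config = unclass(config)[
                          !vapply(config, is.null, logical(1))]),
                   file.path(out_dir, "run_manifest.yaml"))
  invisible(list(overall = overall, domains = domains,
                 rate_classes = rates))
}
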