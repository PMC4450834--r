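# File-to-file pipeline commands over a validated run configuration. These
# are the programmatic surface behind the command-line front-end shipped in
# inst/cli/ontosim.R.

#' Validate a pipeline run configuration
#'
#' Collects paths and parameters for the file-based pipeline commands and
#' enforces their cross-dependencies: the generic and specific weighting
#' schemes need a count source (corpus or recorded count table) and a
#' disease query group, and the specific scheme additionally needs the
#' report table whose contents drive the per-report weights.
#'
#' @param ontology Path to the hierarchy file (TSV edge list or OBO).
#' @param synonyms Optional path to a synonym table.
#' @param reports Optional path to a report table.
#' @param corpus,counts Optional paths to an abstract corpus / recorded count
#'   table (at most one is used; `corpus` wins).
#' @param scheme Weighting scheme: `"equal"`, `"generic"` or `"specific"`.
#' @param level Feature-concept level (default 4).
#' @param k Regularization exponent (default 10).
#' @param k_values Sweep exponents for [run_sweep_k()] (default 0:12).
#' @param disease_terms Character vector naming the disease and its synonyms.
#' @param out_dir Output directory (created if missing).
#' @param root_level Level convention for the root concept (default 0).
#' @param compare_scheme Optional second scheme for [run_evaluate()]; when
#'   set, both schemes are scored and their AUROCs compared.
#' @param seed Optional seed forwarded to any randomized step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ontology, synonyms = NULL, reports = NULL,
                       corpus = NULL, counts = NULL,
                       scheme = c("equal", "generic", "specific"),
                       level = 4, k = 10, k_values = 0:12,
                       disease_terms = character(0), out_dir = ".",
                       root_level = 0, compare_scheme = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  cfg <- list(
    ontology = ontology, synonyms = synonyms, reports = reports,
    corpus = corpus, counts = counts, scheme = scheme, level = level,
    k = k, k_values = k_values,
    disease_terms = as.character(disease_terms), out_dir = out_dir,
    root_level = root_level, compare_scheme = compare_scheme, seed = seed
  )
  check_k(k)
  for (p in c("ontology", "synonyms", "reports", "corpus", "counts")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort_ontosim(sprintf("Configured %s path does not exist: %s",
                            p, cfg[[p]]), "config")
    }
  }
  needs_counts <- union(scheme, cfg$compare_scheme %||% character(0))
  needs_counts <- setdiff(needs_counts, "equal")
  if (length(needs_counts) > 0) {
    if (is.null(cfg$corpus) && is.null(cfg$counts)) {
      abort_ontosim(
        sprintf("Scheme '%s' needs a count source (`corpus` or `counts`).",
                needs_counts[1]), "config"
      )
    }
    if (length(cfg$disease_terms) == 0) {
      abort_ontosim(
        sprintf("Scheme '%s' needs `disease_terms`.", needs_counts[1]),
        "config"
      )
    }
  }
  if ("specific" %in% needs_counts && is.null(cfg$reports)) {
    abort_ontosim("Scheme 'specific' needs a `reports` table.", "config")
  }
  if (!is.null(cfg$compare_scheme) &&
      !cfg$compare_scheme %in% c("equal", "generic", "specific")) {
    abort_ontosim("`compare_scheme` must be equal, generic or specific.",
                  "config")
  }
  structure(cfg, class = "run_config")
}

load_inputs <- function(cfg, need_reports = FALSE) {
  ont <- read_ontology(cfg$ontology, synonym_path = cfg$synonyms)
  space <- feature_space(ont, level = cfg$level, root_level = cfg$root_level)
  rep_tbl <- if (!is.null(cfg$reports)) read_reports(cfg$reports) else NULL
  if (need_reports && is.null(rep_tbl)) {
    abort_ontosim("This command needs a `reports` table.", "config")
  }
  provider <- if (!is.null(cfg$corpus)) {
    corpus_count_provider(cfg$corpus)
  } else if (!is.null(cfg$counts)) {
    table_count_provider(cfg$counts)
  } else NULL
  disease <- if (length(cfg$disease_terms) > 0) {
    query_group(cfg$disease_terms)
  } else NULL
  list(ont = ont, space = space, reports = rep_tbl, provider = provider,
       disease = disease)
}

scheme_weights <- function(scheme, inp) {
  switch(scheme,
    equal = equal_weights(inp$space),
    generic = generic_weights(inp$space, inp$ont, inp$disease, inp$provider),
    specific = specific_weights(inp$reports, inp$space, inp$ont,
                                inp$disease, inp$provider)
  )
}

out_path <- function(cfg, file) {
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  file.path(cfg$out_dir, file)
}

#' Compute and write feature-concept weights
#'
#' Writes `weights.tsv` (`feature_id`, `scheme`, `p`, plus `report_id` for
#' the specific scheme) and, when a count source is configured, a
#' `ranked_terms.tsv` table of extracted terms (specific scheme) or feature
#' concepts (generic scheme) sorted by conditional probability.
#'
#' @param config A [run_config()].
#' @return The weight tibble, invisibly.
#' @export
run_weights <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_inputs(config, need_reports = config$scheme == "specific")
  w <- scheme_weights(config$scheme, inp)
  cols <- intersect(c("report_id", "feature_id", "scheme", "p"), names(w))
  readr::write_tsv(w[, cols], out_path(config, "weights.tsv"))
  if (!is.null(inp$provider) && !is.null(inp$disease)) {
    term_ids <- if (config$scheme == "specific") {
      unique(unlist(inp$reports$term_ids))
    } else {
      inp$space$feature_id
    }
    ranked <- rank_terms(term_probability(inp$ont, term_ids, inp$disease,
                                          inp$provider))
    readr::write_tsv(ranked, out_path(config, "ranked_terms.tsv"))
  }
  invisible(w)
}

#' Score all report pairs and write the similarity table
#'
#' Writes `similarities.tsv` with one row per unordered report pair
#' (`id_a`, `id_b`, `score`).
#'
#' @param config A [run_config()].
#' @return The score tibble, invisibly.
#' @export
run_similarity <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_inputs(config, need_reports = TRUE)
  w <- scheme_weights(config$scheme, inp)
  sc <- pairwise_similarities(inp$reports, inp$space, inp$ont, w,
                              k = config$k)
  readr::write_tsv(sc, out_path(config, "similarities.tsv"))
  invisible(sc)
}

#' Evaluate diagnosis co-occurrence prediction and write ROC outputs
#'
#' Scores the cohort under the configured scheme, labels all pairs, and
#' writes `roc_summary.json` (AUROC, confidence interval, class sizes),
#' `roc_curve.tsv` (threshold sweep points) and, when `compare_scheme` is
#' configured, `comparison.json` with both AUROCs and the DeLong p-value.
#'
#' @param config A [run_config()].
#' @return The `roc_result`, invisibly (with the comparison attached as
#'   attribute `comparison` when one was computed).
#' @export
run_evaluate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_inputs(config, need_reports = TRUE)
  labels <- label_pairs(inp$reports)
  if (length(unique(labels$label)) < 2) {
    abort_ontosim("Single-class cohort: ROC evaluation is undefined.",
                  "degenerate_roc")
  }
  w <- scheme_weights(config$scheme, inp)
  sc <- pairwise_similarities(inp$reports, inp$space, inp$ont, w,
                              k = config$k)
  roc <- roc_auroc(sc, labels)
  jsonlite::write_json(
    as.list(glance(roc)),
    out_path(config, "roc_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(tidy(roc), out_path(config, "roc_curve.tsv"))
  if (!is.null(config$compare_scheme)) {
    w2 <- scheme_weights(config$compare_scheme, inp)
    sc2 <- pairwise_similarities(inp$reports, inp$space, inp$ont, w2,
                                 k = config$k)
    cmp <- compare_auroc(sc, sc2, labels)
    out <- c(list(scheme_a = config$scheme,
                  scheme_b = config$compare_scheme),
             as.list(glance(cmp)))
    jsonlite::write_json(out, out_path(config, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(roc, "comparison") <- cmp
  }
  invisible(roc)
}

#' Sweep the regularization exponent and write the sweep table
#'
#' Writes `sweep.tsv` (`k`, `auroc`) and `sweep.json` with the chosen k.
#'
#' @param config A [run_config()].
#' @return The `k_sweep`, invisibly.
#' @export
run_sweep_k <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_inputs(config, need_reports = TRUE)
  w <- scheme_weights(config$scheme, inp)
  sw <- sweep_k(inp$reports, inp$space, inp$ont, w,
                k_values = config$k_values)
  readr::write_tsv(tidy(sw), out_path(config, "sweep.tsv"))
  jsonlite::write_json(as.list(glance(sw)), out_path(config, "sweep.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sw)
}

#' Generate a synthetic study (ontology, cohort, corpus) on disk
#'
#' Emits the exact file formats the other commands consume:
#' `ontology.tsv` + `synonyms.tsv`, `reports.tsv`, and `corpus.tsv`, all
#' derived from one seed.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed driving all three generators.
#' @param depth,branching,multi_parent_prob Hierarchy shape; see
#'   [simulate_ontology()].
#' @param n_per_label,terms_per_report,panel_concentration,empty_report_prob
#'   Cohort shape; see [simulate_cohort()].
#' @param panel_overlap Fraction of panel concepts shared between labels.
#' @param labels Diagnosis labels.
#' @param disease_terms Disease query group embedded in the corpus.
#' @param n_abstracts,disease_prob,p_given_disease,p_given_background Corpus
#'   model; see [simulate_corpus()].
#' @return Invisible list with the generated objects and file paths.
#' @export
run_simulate <- function(out_dir, seed = 1, depth = 6, branching = 2,
                         multi_parent_prob = 0.1,
                         labels = c("HCC", "NAD"), n_per_label = c(59, 53),
                         terms_per_report = 3, panel_concentration = 1.5,
                         empty_report_prob = 0.1, panel_overlap = 0,
                         disease_terms = c("hepatocellular carcinoma", "HCC"),
                         n_abstracts = 2000, disease_prob = 0.5,
                         p_given_disease = 0.1, p_given_background = 0.02) {
  seeds <- derive_seeds(seed, 4)
  ont <- simulate_ontology(depth = depth, branching = branching,
                           multi_parent_prob = multi_parent_prob,
                           seed = seeds[1])
  panels <- make_panels(ont, labels = labels, overlap = panel_overlap,
                        seed = seeds[2])
  cohort <- simulate_cohort(ont, panels, n_per_label = n_per_label,
                            terms_per_report = terms_per_report,
                            panel_concentration = panel_concentration,
                            empty_report_prob = empty_report_prob,
                            seed = seeds[3])
  vocab <- sort_c(unique(unlist(panels)))
  corpus <- simulate_corpus(ont, query_group(disease_terms), vocab,
                            n_abstracts = n_abstracts,
                            disease_prob = disease_prob,
                            p_given_disease = p_given_disease,
                            p_given_background = p_given_background,
                            seed = seeds[4])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    ontology = file.path(out_dir, "ontology.tsv"),
    synonyms = file.path(out_dir, "synonyms.tsv"),
    reports = file.path(out_dir, "reports.tsv"),
    corpus = file.path(out_dir, "corpus.tsv")
  )
  write_ontology(ont, paths$ontology, synonym_path = paths$synonyms)
  write_reports(cohort, paths$reports)
  write_corpus(corpus, paths$corpus)
  invisible(list(ontology = ont, panels = panels, reports = cohort,
                 corpus = corpus, paths = paths))
}

# spreads one user seed into independent sub-seeds, kept below 2^31
derive_seeds <- function(seed, n) {
  (as.integer(seed) * 1009L + 7L * seq_len(n)) %% 2147483629L
}
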