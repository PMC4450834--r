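# Seeded generators for ontologies, report cohorts and abstract corpora with
# planted ground truth, so every stage of the pipeline is testable without
# access to a real terminology, hospital reports, or a literature index.

#' Simulate a rooted is-a ontology
#'
#' Grows a concept hierarchy level by level below a single root. The number
#' of concepts at each level is Poisson with mean `branching` times the size
#' of the level above (at least 1), each concept takes a uniformly sampled
#' primary parent on the level above, and with probability
#' `multi_parent_prob` gains a second distinct parent on the same level
#' (keeping the level structure exact while making the graph a genuine DAG
#' rather than a tree). Each concept receives 0-3 synthetic synonyms.
#'
#' @param depth Number of levels below the root (>= 1).
#' @param branching Mean children-per-concept growth factor (>= 1).
#' @param multi_parent_prob Probability a concept has a second parent.
#' @param max_synonyms Maximum synthetic synonyms per concept (0-3 default
#'   range; set 0 for none).
#' @param seed Optional RNG seed; a fixed seed gives a byte-identical
#'   hierarchy.
#' @return An [ontology()] object with concept ids `C0000`, `C0001`, ... and
#'   phrase-like preferred names usable in simulated abstracts.
#' @export
simulate_ontology <- function(depth = 6, branching = 2,
                              multi_parent_prob = 0.1, max_synonyms = 3,
                              seed = NULL) {
  if (!is.numeric(depth) || depth < 1 || depth != floor(depth)) {
    abort_ontosim("`depth` must be a positive integer.", "validation")
  }
  if (!is.numeric(branching) || branching < 1) {
    abort_ontosim("`branching` must be >= 1.", "validation")
  }
  if (multi_parent_prob < 0 || multi_parent_prob > 1) {
    abort_ontosim("`multi_parent_prob` must lie in [0, 1].", "validation")
  }
  with_seed_if(seed, {
    counter <- 0L
    new_ids <- function(n) {
      out <- sprintf("C%04d", counter + seq_len(n) - 1L)
      counter <<- counter + n
      out
    }
    root <- new_ids(1)
    prev <- root
    edges <- list()
    for (l in seq_len(depth)) {
      # floor of 2 keeps every level usable as a feature slice: a real
      # terminology never pinches to a single concept mid-hierarchy
      n_l <- max(2L, rpois(1, branching * length(prev)))
      ids <- new_ids(n_l)
      primary <- sample(prev, n_l, replace = TRUE)
      edges[[length(edges) + 1L]] <- tibble(child_id = ids,
                                            parent_id = primary)
      if (length(prev) >= 2 && multi_parent_prob > 0) {
        extra <- runif(n_l) < multi_parent_prob
        if (any(extra)) {
          second <- vapply(which(extra), function(i) {
            sample(setdiff(prev, primary[i]), 1)
          }, character(1))
          edges[[length(edges) + 1L]] <- tibble(child_id = ids[extra],
                                                parent_id = second)
        }
      }
      prev <- ids
    }
    all_ids <- sprintf("C%04d", seq_len(counter) - 1L)
    nms <- tibble(
      concept_id = all_ids,
      preferred_name = sprintf("finding %d", seq_along(all_ids) - 1L)
    )
    syn <- NULL
    if (max_synonyms > 0) {
      n_syn <- sample(0:max_synonyms, length(all_ids), replace = TRUE)
      syn <- tibble(
        concept_id = rep(all_ids, n_syn),
        synonym = unlist(purrr::map2(
          seq_along(all_ids) - 1L, n_syn,
          function(i, k) sprintf("finding %d variant %d", i, seq_len(k))
        ))
      )
    }
    ontology(bind_rows(edges), synonyms = syn, names = nms)
  })
}

#' Split deep concepts into per-label term panels
#'
#' Utility for cohort simulation. Because every report is projected onto
#' feature concepts at a fixed level, inter-patient signal only exists when
#' diagnosis labels differ in *which feature subtrees* their terms fall
#' under, not merely in which individual terms they use. This helper
#' therefore partitions the feature concepts (level `feature_level`) between
#' the labels, with a controllable fraction of subtrees shared by all
#' labels, and builds each label's panel from the strict descendants of its
#' feature concepts. Terms descending from feature concepts assigned to
#' several different labels are dropped so disjoint panels stay disjoint
#' after projection. Overlap 0 plants a strong signal (same-label reports
#' hit the same feature subtrees); overlap 1 makes all panels identical and
#' plants none.
#'
#' @param ont An [ontology()].
#' @param labels Character vector of diagnosis labels (>= 2).
#' @param overlap Fraction in `[0, 1]` of feature subtrees shared by all
#'   panels.
#' @param feature_level Level of the feature concepts whose subtrees are
#'   partitioned (default 4); panel terms sit strictly below it.
#' @param seed Optional RNG seed.
#' @return Named list of character vectors of concept ids, one per label.
#' @export
make_panels <- function(ont, labels = c("HCC", "NAD"), overlap = 0,
                        feature_level = 4, seed = NULL) {
  stopifnot(inherits(ont, "ontology"), length(labels) >= 2)
  if (overlap < 0 || overlap > 1) {
    abort_ontosim("`overlap` must lie in [0, 1].", "validation")
  }
  feats <- names(ont$levels)[ont$levels == feature_level]
  terms <- names(ont$levels)[ont$levels > feature_level]
  if (length(feats) < length(labels) || length(terms) < length(labels)) {
    abort_ontosim(
      "Too few feature concepts or descendant terms to form panels.",
      "validation"
    )
  }
  dmat <- semantic_distance_matrix(ont, terms, feats)
  with_seed_if(seed, {
    feats <- sample(feats)
    n_shared <- round(overlap * length(feats))
    owner <- rep_len(seq_along(labels), length(feats))
    owner[seq_len(n_shared)] <- 0L          # 0 = shared by all labels
    panels <- lapply(seq_along(labels), function(i) {
      keep <- vapply(terms, function(tm) {
        anc <- owner[is.finite(dmat[tm, feats])]
        length(anc) > 0 && all(anc %in% c(0L, i))
      }, logical(1))
      sort_c(terms[keep])
    })
    panels <- setNames(panels, labels)
    if (any(lengths(panels) == 0)) {
      abort_ontosim(
        "A label received an empty term panel; use a deeper or wider hierarchy.",
        "validation"
      )
    }
    panels
  })
}

#' Simulate a report cohort with label-specific term panels
#'
#' Generates one record per report: an id, a diagnosis label, and a set of
#' extracted concept ids sampled from that label's term panel. Label-specific
#' panels induce true inter-patient signal, so pairs of same-label reports
#' score higher in expectation; identical panels give a null cohort. A
#' configurable fraction of reports carries no extracted terms at all,
#' mimicking scans with no recorded findings.
#'
#' @param ont An [ontology()]; panel concepts must exist in it.
#' @param panels Named list of concept-id vectors, one per diagnosis label
#'   (see [make_panels()]).
#' @param n_per_label Integer vector of cohort sizes, recycled over the panel
#'   labels (default `c(59, 53)`, a two-label cohort).
#' @param terms_per_report Mean number of extracted terms in a non-empty
#'   report (Poisson with minimum 1, default 3).
#' @param panel_concentration Zipf exponent shaping how unevenly a label's
#'   reports use its panel: sampling weight of the r-th panel term is
#'   r^-panel_concentration. The default 1.5 mimics the heavy-tailed
#'   frequency of clinical findings (a few very common findings recur in
#'   most same-diagnosis reports); 0 gives uniform use of the panel.
#' @param empty_report_prob Probability a report has no extracted terms
#'   (default 0.1).
#' @param seed Optional RNG seed.
#' @return A reports tibble (`report_id`, `diagnosis`, `term_ids`).
#' @export
simulate_cohort <- function(ont, panels, n_per_label = c(59, 53),
                            terms_per_report = 3, panel_concentration = 1.5,
                            empty_report_prob = 0.1, seed = NULL) {
  stopifnot(inherits(ont, "ontology"), is.list(panels),
            !is.null(names(panels)))
  check_concepts(ont, unlist(panels))
  if (empty_report_prob < 0 || empty_report_prob > 1) {
    abort_ontosim("`empty_report_prob` must lie in [0, 1].", "validation")
  }
  if (panel_concentration < 0) {
    abort_ontosim("`panel_concentration` must be non-negative.", "validation")
  }
  labels <- names(panels)
  n_per_label <- rep_len(as.integer(n_per_label), length(labels))
  with_seed_if(seed, {
    rows <- purrr::map2(labels, n_per_label, function(lab, n) {
      panel <- panels[[lab]]
      w <- seq_along(panel)^(-panel_concentration)
      terms <- purrr::map(seq_len(n), function(i) {
        if (runif(1) < empty_report_prob) return(character(0))
        k <- max(1L, rpois(1, terms_per_report))
        sample(panel, min(k, length(panel)), prob = w)
      })
      tibble(diagnosis = lab, term_ids = terms)
    })
    out <- bind_rows(rows)
    out$report_id <- sprintf("R%04d", seq_len(nrow(out)))
    reports(out[, c("report_id", "diagnosis", "term_ids")])
  })
}

#' Simulate an abstract corpus with a planted co-mention model
#'
#' Generates abstracts under an abstract-level Bernoulli model: each abstract
#' mentions the disease with probability `disease_prob`; conditional on
#' disease status, each vocabulary term is mentioned independently with its
#' planted conditional probability. Mentions are embedded as whole phrases
#' (randomly the preferred name or a synonym), so corpus counting recovers
#' the planted conditionals up to binomial noise: the estimator of
#' P(term | disease) from such a corpus is consistent with standard error
#' sqrt(p (1 - p) / n_disease).
#'
#' @param ont An [ontology()]; vocabulary names and synonyms come from it.
#' @param disease A [query_group()] of disease names; these are embedded
#'   verbatim and must not collide with concept names.
#' @param vocabulary Character vector of concept ids to embed.
#' @param n_abstracts Number of abstracts (>= 1).
#' @param disease_prob Probability an abstract mentions the disease.
#' @param p_given_disease Named numeric vector of planted
#'   P(term | disease mentioned), recycled if scalar (default 0.1).
#' @param p_given_background Planted P(term | disease not mentioned),
#'   recycled if scalar (default 0.02).
#' @param seed Optional RNG seed.
#' @return A corpus tibble (`abstract_id`, `text`).
#' @export
simulate_corpus <- function(ont, disease, vocabulary, n_abstracts = 1000,
                            disease_prob = 0.5, p_given_disease = 0.1,
                            p_given_background = 0.02, seed = NULL) {
  stopifnot(inherits(ont, "ontology"), n_abstracts >= 1)
  disease <- as_query_group(disease)
  vocabulary <- unique(as.character(vocabulary))
  check_concepts(ont, vocabulary)
  expand <- function(p) {
    if (is.null(names(p))) {
      setNames(rep_len(p, length(vocabulary)), vocabulary)
    } else {
      missing <- setdiff(vocabulary, names(p))
      if (length(missing) > 0) {
        abort_ontosim("Planted probabilities missing for some terms.",
                      "validation")
      }
      p[vocabulary]
    }
  }
  p_dis <- expand(p_given_disease)
  p_bg <- expand(p_given_background)
  if (any(c(p_dis, p_bg, disease_prob) < 0) ||
      any(c(p_dis, p_bg, disease_prob) > 1)) {
    abort_ontosim("All planted probabilities must lie in [0, 1].",
                  "validation")
  }
  groups <- lapply(vocabulary, function(id) concept_group(ont, id))
  with_seed_if(seed, {
    has_dis <- runif(n_abstracts) < disease_prob
    texts <- vapply(seq_len(n_abstracts), function(i) {
      p <- if (has_dis[i]) p_dis else p_bg
      hit <- runif(length(vocabulary)) < p
      mentions <- vapply(which(hit), function(j) {
        sample(unclass(groups[[j]]), 1)
      }, character(1))
      parts <- "Case report."
      if (has_dis[i]) {
        parts <- c(parts,
                   sprintf("The study concerns %s.",
                           sample(unclass(disease), 1)))
      }
      if (length(mentions) > 0) {
        parts <- c(parts, sprintf("Imaging showed %s.",
                                  paste(mentions, collapse = ", ")))
      } else {
        parts <- c(parts, "No notable observations were recorded.")
      }
      paste(parts, collapse = " ")
    }, character(1))
    tibble(abstract_id = sprintf("A%06d", seq_len(n_abstracts)),
           text = texts)
  })
}
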