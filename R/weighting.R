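#' Build a query group of a name and its synonyms
#'
#' A query group is the OR-clause of a literature search: a concept's
#' preferred name together with its synonyms. Empty strings are dropped and
#' duplicates are removed case-insensitively (first spelling wins).
#'
#' @param ... Character vectors of names, concatenated.
#' @return A character vector of class `query_group`.
#' @export
query_group <- function(...) {
  x <- trimws(as.character(c(...)))
  x <- x[nzchar(x)]
  if (length(x) == 0) {
    abort_ontosim("A query group needs at least one non-empty name.",
                  "validation")
  }
  x <- x[!duplicated(tolower(x))]
  structure(x, class = "query_group")
}

as_query_group <- function(x) {
  if (inherits(x, "query_group")) x else query_group(x)
}

group_key <- function(g) tolower(trimws(g[[1]]))

#' Abstract-count provider backed by a local corpus
#'
#' Returns a provider that counts, for any query group, the number of
#' abstracts containing at least one of the group's names as a
#' case-insensitive whole-phrase match (word-boundary anchored), and joint
#' counts of abstracts containing names from both of two groups. Each abstract
#' is counted at most once per group. This is a local stand-in for a
#' literature search engine's hit counts.
#'
#' @param corpus Either a path to a TSV corpus (`abstract_id<TAB>text`, see
#'   [read_corpus()]) or a tibble with those columns.
#' @return An object of class `count_provider` with elements
#'   `count(group)` and `count_joint(group_a, group_b)`, plus `n_abstracts`.
#' @export
#' @examples
#' prov <- corpus_count_provider(
#'   tibble::tibble(abstract_id = "a1", text = "HCC with dysplastic nodule")
#' )
#' prov$count(query_group("dysplastic nodule"))  # 1
corpus_count_provider <- function(corpus) {
  if (is.character(corpus) && length(corpus) == 1) {
    corpus <- read_corpus(corpus)
  }
  corpus <- as_tibble(corpus)
  if (!all(c("abstract_id", "text") %in% names(corpus)) ||
      nrow(corpus) == 0) {
    abort_ontosim("Corpus needs >= 1 row with columns abstract_id, text.",
                  "format")
  }
  texts <- as.character(corpus$text)

  cache <- new.env(parent = emptyenv())
  match_mask <- function(group) {
    group <- as_query_group(group)
    key <- paste(sort(tolower(group)), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pat <- paste0(
      "\\b(?:", paste(stringr::str_escape(group), collapse = "|"), ")\\b"
    )
    cache[[key]] <- stringr::str_detect(
      texts, stringr::regex(pat, ignore_case = TRUE)
    )
    cache[[key]]
  }

  structure(
    list(
      count = function(group) sum(match_mask(group)),
      count_joint = function(group_a, group_b) {
        sum(match_mask(group_a) & match_mask(group_b))
      },
      n_abstracts = length(texts)
    ),
    class = "count_provider"
  )
}

#' Abstract-count provider backed by a recorded count table
#'
#' Replays counts recorded from any literature index (for example a manual
#' search session). The table has rows `key_a<TAB>key_b<TAB>n`; the reserved
#' key `*` marks marginal counts, so `(x, *, n)` stores the marginal count of
#' group `x` and `(x, y, n)` the joint count of `x` and `y`. Groups are keyed
#' by their first (preferred) name, lower-cased. Joint counts exceeding either
#' recorded marginal are rejected.
#'
#' @param table Path to the TSV count table, or a data frame with columns
#'   `key_a`, `key_b`, `n`.
#' @return A `count_provider` (see [corpus_count_provider()]); unknown keys
#'   raise a lookup error.
#' @export
table_count_provider <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- read_count_table(table)
  }
  table <- as_tibble(table)
  if (!all(c("key_a", "key_b", "n") %in% names(table))) {
    abort_ontosim("Count table needs columns key_a, key_b, n.", "format")
  }
  table$key_a <- tolower(trimws(as.character(table$key_a)))
  table$key_b <- tolower(trimws(as.character(table$key_b)))
  table$n <- as.numeric(table$n)
  if (any(is.na(table$n) | table$n < 0 | table$n != floor(table$n))) {
    abort_ontosim("Counts must be non-negative integers.", "validation")
  }
  marg_tbl <- table[table$key_a == "*" | table$key_b == "*", ]
  marg_key <- ifelse(marg_tbl$key_a == "*", marg_tbl$key_b, marg_tbl$key_a)
  marginals <- setNames(marg_tbl$n, marg_key)
  if (anyDuplicated(marg_key)) {
    abort_ontosim("Duplicate marginal rows in count table.", "validation")
  }
  joint_tbl <- table[table$key_a != "*" & table$key_b != "*", ]
  jkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  joints <- setNames(joint_tbl$n, jkey(joint_tbl$key_a, joint_tbl$key_b))

  for (i in seq_len(nrow(joint_tbl))) {
    for (k in c(joint_tbl$key_a[i], joint_tbl$key_b[i])) {
      if (k %in% names(marginals) && joint_tbl$n[i] > marginals[[k]]) {
        abort_ontosim(
          sprintf("Joint count %d of (%s, %s) exceeds marginal %d of '%s'.",
                  joint_tbl$n[i], joint_tbl$key_a[i], joint_tbl$key_b[i],
                  marginals[[k]], k),
          "validation"
        )
      }
    }
  }

  lookup_marginal <- function(group) {
    k <- group_key(as_query_group(group))
    if (!k %in% names(marginals)) {
      abort_ontosim(sprintf("No marginal count recorded for '%s'.", k),
                    "lookup")
    }
    marginals[[k]]
  }
  lookup_joint <- function(ga, gb) {
    ka <- group_key(as_query_group(ga)); kb <- group_key(as_query_group(gb))
    k <- jkey(ka, kb)
    if (!k %in% names(joints)) {
      abort_ontosim(sprintf("No joint count recorded for ('%s', '%s').",
                            ka, kb), "lookup")
    }
    joints[[k]]
  }

  structure(
    list(count = lookup_marginal, count_joint = lookup_joint,
         table = table),
    class = "count_provider"
  )
}

#' Read / write a recorded count table
#'
#' @param path TSV path with columns `key_a`, `key_b`, `n`; `*` is the
#'   reserved marginal key.
#' @return `read_count_table()` returns the tibble; `write_count_table()`
#'   returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    abort_ontosim(sprintf("Count table not found: %s", path), "io")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    key_a = readr::col_character(), key_b = readr::col_character(),
    n = readr::col_double()
  ))
  as_tibble(tbl)
}

#' @rdname read_count_table
#' @param table Data frame with columns `key_a`, `key_b`, `n`.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(as_tibble(table)[, c("key_a", "key_b", "n")], path)
  invisible(path)
}

# shared denominator check for Eq.-style conditional probabilities
disease_marginal <- function(provider, disease) {
  denom <- provider$count(as_query_group(disease))
  if (denom <= 0) {
    abort_ontosim(
      "Disease group matches no abstracts: conditional probabilities are undefined.",
      "undefined_denominator"
    )
  }
  denom
}

#' Equal feature-concept weights
#'
#' The baseline scheme: every feature concept gets conditional probability
#' p = 1, so the feature vector reduces to the unweighted edge-count form.
#'
#' @param space A [feature_space()].
#' @return A weight tibble with columns `feature_id`, `p`, `scheme`.
#' @export
equal_weights <- function(space) {
  stopifnot(inherits(space, "feature_space"), nrow(space) > 0)
  tibble(feature_id = space$feature_id, p = 1, scheme = "equal")
}

#' Generic literature-derived feature-concept weights
#'
#' Estimates, for each feature concept, the conditional probability of the
#' concept given the disease as the ratio of the number of abstracts
#' co-mentioning the feature concept (or a synonym) and the disease (or a
#' synonym) to the number of abstracts mentioning the disease. Weights are
#' shared by all reports.
#'
#' @param space A [feature_space()].
#' @param ont The [ontology()] supplying feature-concept names and synonyms.
#' @param disease A [query_group()] for the disease of interest.
#' @param provider A `count_provider`.
#' @return A weight tibble with columns `feature_id`, `p`, `scheme`.
#' @export
generic_weights <- function(space, ont, disease, provider) {
  stopifnot(inherits(space, "feature_space"), inherits(ont, "ontology"),
            inherits(provider, "count_provider"))
  disease <- as_query_group(disease)
  denom <- disease_marginal(provider, disease)
  p <- purrr::map_dbl(space$feature_id, function(fid) {
    provider$count_joint(concept_group(ont, fid), disease) / denom
  })
  tibble(feature_id = space$feature_id, p = p, scheme = "generic")
}

#' Conditional probability of extracted terms given a disease
#'
#' For each extracted term, the ratio of abstracts co-mentioning the term (or
#' a synonym) and the disease (or a synonym) to abstracts mentioning the
#' disease.
#'
#' @param ont The [ontology()] supplying term names and synonyms.
#' @param term_ids Character vector of extracted concept ids.
#' @param disease A [query_group()].
#' @param provider A `count_provider`.
#' @return A tibble with columns `term_id`, `name`, `q` (each q in `[0, 1]`).
#' @export
term_probability <- function(ont, term_ids, disease, provider) {
  stopifnot(inherits(ont, "ontology"), inherits(provider, "count_provider"))
  term_ids <- unique(as.character(term_ids))
  check_concepts(ont, term_ids)
  disease <- as_query_group(disease)
  denom <- disease_marginal(provider, disease)
  q <- purrr::map_dbl(term_ids, function(tid) {
    provider$count_joint(concept_group(ont, tid), disease) / denom
  })
  tibble(
    term_id = term_ids,
    name = ont$concepts$preferred_name[match(term_ids,
                                             ont$concepts$concept_id)],
    q = q
  )
}

#' Report-specific feature-concept weights
#'
#' For each report and feature concept, collects the report's extracted terms
#' that are descendants of (or equal to) the feature concept, estimates each
#' term's conditional probability given the disease ([term_probability()]),
#' and averages them. A feature concept with no extracted descendant term in
#' a report gets weight 0 (the corresponding vector element is already 0).
#' Unlike [generic_weights()], these weights vary from report to report.
#'
#' @param reports A reports tibble (see [reports()]): one or more reports.
#' @inheritParams generic_weights
#' @return A weight tibble with columns `report_id`, `feature_id`, `p`,
#'   `scheme`.
#' @export
specific_weights <- function(reports, space, ont, disease, provider) {
  reports <- ontosim::reports(reports)
  stopifnot(inherits(space, "feature_space"))
  all_terms <- unique(unlist(reports$term_ids))
  check_concepts(ont, all_terms)
  qtab <- if (length(all_terms) > 0) {
    term_probability(ont, all_terms, disease, provider)
  } else {
    disease_marginal(provider, disease)   # still enforce the precondition
    tibble(term_id = character(0), name = character(0), q = numeric(0))
  }
  qv <- setNames(qtab$q, qtab$term_id)
  dmat <- semantic_distance_matrix(ont, all_terms, space$feature_id)

  rows <- purrr::map(seq_len(nrow(reports)), function(r) {
    terms <- reports$term_ids[[r]]
    p <- purrr::map_dbl(space$feature_id, function(fid) {
      desc <- terms[is.finite(dmat[terms, fid])]
      if (length(desc) == 0) 0 else mean(qv[desc])
    })
    tibble(report_id = reports$report_id[r],
           feature_id = space$feature_id, p = p, scheme = "specific")
  })
  bind_rows(rows)
}

#' Rank terms by conditional probability
#'
#' Sorts term weights in descending order of conditional probability, breaking
#' ties lexicographically by term id so the ranking is stable across runs.
#'
#' @param term_weights A tibble with columns `term_id` and `q` (for example
#'   from [term_probability()]).
#' @return The input with a leading `rank` column, sorted.
#' @export
rank_terms <- function(term_weights) {
  tw <- as_tibble(term_weights)
  if (!all(c("term_id", "q") %in% names(tw))) {
    abort_ontosim("Term weights need columns term_id, q.", "format")
  }
  if (any(tw$q < 0 | tw$q > 1)) {
    abort_ontosim("Term probabilities must lie in [0, 1].", "validation")
  }
  ord <- order(-tw$q, tw$term_id, method = "radix")
  out <- tw[ord, , drop = FALSE]
  out <- mutate(out, rank = row_number())
  select(out, "rank", dplyr::everything())
}
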