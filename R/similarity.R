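# Weighted, regularized ontological feature vectors and the modified
# direction cosine.

# checks a weight table against a feature space; returns scheme
validate_weights <- function(weights, space) {
  weights <- as_tibble(weights)
  if (!all(c("feature_id", "p") %in% names(weights))) {
    abort_ontosim("Weights need columns feature_id, p.", "format")
  }
  if (any(weights$p < 0 | weights$p > 1 | is.na(weights$p))) {
    abort_ontosim("Weights must lie in [0, 1].", "validation")
  }
  scheme <- if ("scheme" %in% names(weights)) weights$scheme[1] else "equal"
  split_by <- if ("report_id" %in% names(weights) &&
                  !all(is.na(weights$report_id))) "report_id" else NULL
  check_cover <- function(w) {
    missing <- setdiff(space$feature_id, w$feature_id)
    if (length(missing) > 0) {
      abort_ontosim(
        sprintf("Weights missing for feature concept(s): %s.",
                paste(head(missing, 5), collapse = ", ")),
        "contract"
      )
    }
  }
  if (is.null(split_by)) check_cover(weights) else {
    purrr::walk(split(weights, weights$report_id), check_cover)
  }
  list(weights = weights, scheme = scheme, per_report = !is.null(split_by))
}

# weight vector (ordered by space) for one report under a validated table
weights_for <- function(vw, space, report_id) {
  w <- vw$weights
  if (vw$per_report) {
    if (is.null(report_id) || !report_id %in% w$report_id) {
      abort_ontosim(
        sprintf("Specific weights carry no entry for report '%s'.",
                report_id %||% "<missing>"),
        "contract"
      )
    }
    w <- w[w$report_id == report_id, ]
  }
  unname(setNames(w$p, w$feature_id)[space$feature_id])
}

# minimum semantic distance from a term set to each feature (Inf if none)
min_distances <- function(dmat, terms, feature_ids) {
  if (length(terms) == 0) {
    return(rep(Inf, length(feature_ids)))
  }
  sub <- dmat[terms, feature_ids, drop = FALSE]
  apply(sub, 2, min)
}

#' Build the regularized ontological feature vector of a report
#'
#' Each element is a = sqrt(p) / (1 + s), where p is the feature concept's
#' weight and s the minimum edge-count semantic distance from the report's
#' extracted terms to the feature concept; when no extracted term descends
#' from the feature concept (s infinite, including the empty report) the
#' element is 0. A regularization constant delta = 10^-k is appended as a
#' final element so that vectors keep a positive norm and similarity stays
#' defined for reports with few or no extracted terms.
#'
#' @param term_ids Character vector of the report's extracted concept ids
#'   (may be empty).
#' @param space A [feature_space()].
#' @param ont An [ontology()].
#' @param weights A weight tibble (`feature_id`, `p`, optionally `scheme` and
#'   `report_id`); report-specific weight tables require `report_id`.
#' @param k Non-negative integer regularization exponent; delta = 10^-k.
#' @param report_id Needed when `weights` are report-specific, to pick that
#'   report's weights.
#' @return A named numeric vector of class `onto_vector`: the feature
#'   elements in feature-space order followed by `.delta`.
#' @export
build_feature_vector <- function(term_ids, space, ont, weights, k = 10,
                                 report_id = NULL) {
  stopifnot(inherits(space, "feature_space"), inherits(ont, "ontology"))
  check_k(k)
  vw <- validate_weights(weights, space)
  term_ids <- unique(as.character(term_ids))
  check_concepts(ont, term_ids)
  dmat <- semantic_distance_matrix(ont, term_ids, space$feature_id)
  smin <- min_distances(dmat, term_ids, space$feature_id)
  p <- weights_for(vw, space, report_id)
  a <- sqrt(p) / (1 + smin)          # 1/(1+Inf) = 0: unreachable features
  delta <- 10^(-k)
  structure(
    setNames(c(a, delta), c(space$feature_id, ".delta")),
    class = "onto_vector", k = k,
    space = space$feature_id
  )
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != floor(k)) {
    abort_ontosim("`k` must be a single non-negative integer.", "validation")
  }
}

#' Modified direction cosine between two feature vectors
#'
#' The cosine of the angle between two delta-augmented feature vectors. The
#' appended regularization element keeps both norms positive, so the score is
#' always defined and strictly positive; two empty reports score 1 (their
#' vectors both reduce to the delta element).
#'
#' @param q,d Vectors built by [build_feature_vector()] over the same feature
#'   space with the same `k`.
#' @return A similarity score in (0, 1].
#' @export
mdc_similarity <- function(q, d) {
  if (!inherits(q, "onto_vector") || !inherits(d, "onto_vector")) {
    abort_ontosim("Both arguments must be built by build_feature_vector().",
                  "contract")
  }
  if (!identical(attr(q, "space"), attr(d, "space")) ||
      !identical(attr(q, "k"), attr(d, "k"))) {
    abort_ontosim(
      "Vectors disagree on feature space or regularization constant.",
      "contract"
    )
  }
  sum(q * d) / (sqrt(sum(q^2)) * sqrt(sum(d^2)))
}

# rows = reports (in given order), cols = features + delta
feature_matrix <- function(reports, space, ont, weights, k) {
  vw <- validate_weights(weights, space)
  all_terms <- unique(unlist(reports$term_ids))
  check_concepts(ont, all_terms)
  dmat <- semantic_distance_matrix(ont, all_terms, space$feature_id)
  rows <- lapply(seq_len(nrow(reports)), function(r) {
    smin <- min_distances(dmat, reports$term_ids[[r]], space$feature_id)
    p <- weights_for(vw, space, reports$report_id[r])
    sqrt(p) / (1 + smin)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- reports$report_id
  cbind(m, .delta = 10^(-k))
}

cosine_pairs <- function(m, ids) {
  g <- m %*% t(m)
  nrm <- sqrt(diag(g))
  idx <- which(upper.tri(g), arr.ind = TRUE)
  tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    score = g[idx] / (nrm[idx[, 1]] * nrm[idx[, 2]])
  )
}

#' Pairwise similarity scores for a report cohort
#'
#' Builds every report's regularized feature vector and scores all unordered
#' distinct report pairs with the modified direction cosine: C(R, 2) rows for
#' R reports, no self-pairs, no duplicates. Under a report-specific weight
#' table each report's vector uses its own weights.
#'
#' @param reports A reports tibble (see [reports()]), at least two rows.
#' @inheritParams build_feature_vector
#' @return A tibble `id_a`, `id_b`, `score` with `id_a < id_b`
#'   lexicographically; row order follows sorted report ids, so the result is
#'   invariant to the input order of the cohort.
#' @export
pairwise_similarities <- function(reports, space, ont, weights, k = 10) {
  reports <- ontosim::reports(reports)
  check_k(k)
  if (nrow(reports) < 2) {
    abort_ontosim("Need at least two reports to form pairs.", "validation")
  }
  reports <- reports[order(reports$report_id, method = "radix"), ]
  m <- feature_matrix(reports, space, ont, weights, k)
  cosine_pairs(m, reports$report_id)
}
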