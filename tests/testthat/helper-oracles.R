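# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own computational paths (igraph, rank formulas),
# so tests compare two independent routes to the same quantity.

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(...) {
  system.file("extdata", ..., package = "ontosim", mustWork = TRUE)
}

fragment_ontology <- function() {
  read_ontology(extdata("liver_fragment_edges.tsv"),
                synonym_path = extdata("liver_fragment_synonyms.tsv"))
}

# --- brute-force semantic distance: exhaustive enumeration of simple upward
# paths over a raw edge list (child -> parent), no graph library involved
bf_distance <- function(edges, from, to) {
  if (from == to) return(0)
  parents_of <- split(edges$parent_id, edges$child_id)
  best <- Inf
  walk <- function(node, depth, seen) {
    for (p in parents_of[[node]] %||% character(0)) {
      if (p %in% seen) next
      if (p == to) {
        best <<- min(best, depth + 1)
      } else {
        walk(p, depth + 1, c(seen, p))
      }
    }
  }
  walk(from, 0, from)
  best
}

bf_level <- function(edges, node) {
  roots <- setdiff(unique(edges$parent_id), unique(edges$child_id))
  bf_distance(edges, node, roots[1])
}

# random single-root DAG on n nodes: node i > 1 takes 1-2 parents among
# earlier nodes, so node 1 is the unique root
random_dag_edges <- function(n, seed) {
  withr::with_seed(seed, {
    rows <- lapply(2:n, function(i) {
      k <- sample(1:min(2, i - 1), 1)
      data.frame(child_id = paste0("n", i),
                 parent_id = paste0("n", sample(i - 1, k)))
    })
    do.call(rbind, rows)
  })
}

# --- brute-force AUROC: mean over all (pos, neg) pairs
bf_auroc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# trapezoid area under an (fpr, tpr) polyline
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

# --- naive whole-phrase corpus scan, implemented without regex: lowercase
# fixed-string search plus manual word-boundary checks
naive_count <- function(texts, names) {
  is_word <- function(ch) grepl("[a-z0-9_]", ch)
  hit_one <- function(text, name) {
    text <- tolower(text); name <- tolower(name)
    start <- 1
    repeat {
      i <- regexpr(name, substr(text, start, nchar(text)), fixed = TRUE)
      if (i == -1) return(FALSE)
      pos <- start + i - 1
      before <- if (pos == 1) "" else substr(text, pos - 1, pos - 1)
      after_i <- pos + nchar(name)
      after <- if (after_i > nchar(text)) "" else substr(text, after_i, after_i)
      if ((before == "" || !is_word(before)) &&
          (after == "" || !is_word(after))) {
        return(TRUE)
      }
      start <- pos + 1
    }
  }
  sum(vapply(texts, function(tx) {
    any(vapply(names, function(nm) hit_one(tx, nm), logical(1)))
  }, logical(1)))
}

# small cohort tibble builder
make_reports <- function(ids, diagnoses, terms) {
  reports(tibble::tibble(report_id = ids, diagnosis = diagnoses,
                         term_ids = terms))
}

# delta-domination fixture: the liver label mixes heavy reports (two exact
# feature hits, large vector norm) with light ones (a single distant term,
# small norm). At k = 0 the unit delta makes the score norm-sensitive, so a
# light-liver vs spleen mismatch outscores a heavy-light liver match; at
# k >= 2 the delta influence vanishes and the labels separate perfectly.
delta_domination_cohort <- function() {
  ont <- fragment_ontology()
  heavy <- replicate(4, c("liver finding", "fatty liver"), simplify = FALSE)
  light <- replicate(4, "cirrhosis of liver", simplify = FALSE)
  spleen <- replicate(8, "splenomegaly", simplify = FALSE)
  coh <- make_reports(
    sprintf("P%02d", 1:16),
    c(rep("LIV", 8), rep("SPL", 8)),
    c(heavy, light, spleen)
  )
  list(ont = ont, space = feature_space(ont, 4), cohort = coh)
}
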