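test_that("query groups drop empties and case-insensitive duplicates", {
  g <- query_group("HCC", "hcc", " Hepatocellular carcinoma ", "")
  expect_equal(unclass(g), c("HCC", "Hepatocellular carcinoma"))
  expect_error(query_group("", ""), class = "ontosim_error_validation")
})

test_that("the corpus provider counts whole-phrase matches once per abstract", {
  prov <- corpus_count_provider(
    tibble::tibble(abstract_id = "a1", text = "HCC with dysplastic nodule")
  )
  expect_equal(prov$count(query_group("dysplastic nodule")), 1)
  expect_equal(prov$count(query_group("cirrhosis")), 0)
  # word-boundary anchoring: no match inside a longer word
  prov2 <- corpus_count_provider(tibble::tibble(
    abstract_id = c("a", "b"),
    text = c("marked splenomegalyx seen", "nodule, nodule and NODULE")
  ))
  expect_equal(prov2$count(query_group("splenomegaly")), 0)
  expect_equal(prov2$count(query_group("nodule")), 1)
  expect_error(corpus_count_provider(tibble::tibble()),
               class = "ontosim_error_format")
})

test_that("corpus counts agree with an independent naive scan", {
  ont <- simulate_ontology(depth = 4, branching = 2, seed = 5)
  dis <- query_group("hepatocellular carcinoma", "HCC")
  vocab <- utils::head(names(ont$levels)[ont$levels >= 2], 8)
  corp <- simulate_corpus(ont, dis, vocab, n_abstracts = 200,
                          disease_prob = 0.4, p_given_disease = 0.4,
                          p_given_background = 0.15, seed = 6)
  prov <- corpus_count_provider(corp)
  groups <- c(list(dis), lapply(vocab, function(id) {
    i <- match(id, ont$concepts$concept_id)
    query_group(ont$concepts$preferred_name[i], ont$concepts$synonyms[[i]])
  }))
  for (g in groups) {
    expect_equal(prov$count(g), naive_count(corp$text, unclass(g)))
  }
  # joint counts against the oracle too
  for (g in groups[-1]) {
    both <- vapply(corp$text, function(tx) {
      naive_count(tx, unclass(g)) > 0 && naive_count(tx, unclass(dis)) > 0
    }, logical(1))
    expect_equal(prov$count_joint(g, dis), sum(both))
  }
})

test_that("the table provider replays counts and enforces the invariant", {
  tab <- tibble::tibble(
    key_a = c("hcc", "termx", "termx"),
    key_b = c("*", "*", "hcc"),
    n = c(10, 8, 5)
  )
  prov <- table_count_provider(tab)
  expect_equal(prov$count(query_group("HCC")), 10)
  expect_equal(prov$count_joint(query_group("termx"), query_group("hcc")), 5)
  # symmetry of the joint lookup
  expect_equal(prov$count_joint(query_group("hcc"), query_group("termx")), 5)
  expect_error(prov$count(query_group("unknown")),
               class = "ontosim_error_lookup")
  bad <- tab; bad$n[3] <- 12
  expect_error(table_count_provider(bad),
               class = "ontosim_error_validation")
  # round-trip through disk preserves every count
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  prov2 <- table_count_provider(path)
  expect_identical(prov2$count(query_group("termx")),
                   prov$count(query_group("termx")))
  expect_identical(prov2$count_joint(query_group("termx"), query_group("hcc")),
                   prov$count_joint(query_group("termx"), query_group("hcc")))
})

test_that("equal weighting gives every feature concept p = 1", {
  ont <- fragment_ontology()
  w <- equal_weights(feature_space(ont, 4))
  expect_equal(w$p, c(1, 1, 1))
  w0 <- equal_weights(feature_space(ont, 0))
  expect_equal(w0$p, 1)
})

test_that("generic weights are joint/marginal abstract-count ratios", {
  ont <- fragment_ontology()
  sp <- feature_space(ont, 4)
  dis <- query_group("HCC", "hepatocellular carcinoma")
  prov <- corpus_count_provider(extdata("toy_corpus.tsv"))
  w <- generic_weights(sp, ont, dis, prov)
  # hand-counted on the 12-abstract fixture: disease marginal 7;
  # fatty liver co-mentions in a04, a10; the other features never appear
  expect_equal(w$p[w$feature_id == "fatty liver"], 2 / 7)
  expect_equal(w$p[w$feature_id == "liver finding"], 0)
  expect_equal(w$p[w$feature_id == "abdominal organ finding"], 0)
  expect_true(all(w$scheme == "generic"))
  # degenerate numerator/denominator cases via a recorded table
  tab <- table_count_provider(tibble::tibble(
    key_a = c("d", "abdominal organ finding", "fatty liver",
              "liver finding"),
    key_b = c("*", "d", "d", "d"),
    n = c(5, 5, 0, 2)
  ))
  w2 <- generic_weights(sp, ont, query_group("d"), tab)
  expect_equal(w2$p, c(1, 0, 2 / 5))
  empty <- corpus_count_provider(
    tibble::tibble(abstract_id = "x", text = "nothing relevant")
  )
  expect_error(generic_weights(sp, ont, dis, empty),
               class = "ontosim_error_undefined_denominator")
})

test_that("term probabilities are exact count ratios bounded by 1", {
  ont <- fragment_ontology()
  dis <- query_group("d")
  tab <- table_count_provider(tibble::tibble(
    key_a = c("d", "cirrhosis of liver", "splenomegaly"),
    key_b = c("*", "d", "d"),
    n = c(500, 467, 0)
  ))
  q <- term_probability(ont, c("cirrhosis of liver", "splenomegaly"), dis, tab)
  expect_equal(q$q, c(467 / 500, 0))
  expect_equal(q$q[1], 0.934)
  # property: q <= 1 for any corpus, by the provider's joint <= marginal
  ont2 <- simulate_ontology(depth = 3, branching = 2, seed = 3)
  vocab <- names(ont2$levels)[ont2$levels >= 1]
  for (seed in 1:25) {
    corp <- simulate_corpus(ont2, dis, vocab, n_abstracts = 30,
                            disease_prob = 0.6, p_given_disease = 0.5,
                            p_given_background = 0.3, seed = seed)
    prov <- corpus_count_provider(corp)
    qq <- term_probability(ont2, vocab, dis, prov)$q
    expect_true(all(qq >= 0 & qq <= 1))
  }
})

test_that("specific weights average descendant-term probabilities per report", {
  ont <- fragment_ontology()
  sp <- feature_space(ont, 4)
  dis <- query_group("d")
  tab <- table_count_provider(tibble::tibble(
    key_a = c("d", "cirrhosis of liver", "hepatic fibrosis", "splenomegaly",
              "fatty liver"),
    key_b = c("*", "d", "d", "d", "d"),
    n = c(1000, 513, 200, 400, 82)
  ))
  coh <- make_reports(
    c("R1", "R2", "R3"), c("HCC", "HCC", "NAD"),
    list(c("cirrhosis of liver", "hepatic fibrosis", "splenomegaly"),
         c("cirrhosis of liver"), character(0))
  )
  w <- specific_weights(coh, sp, ont, dis, tab)
  get <- function(r, f) w$p[w$report_id == r & w$feature_id == f]
  # R1: two descendants of liver finding, averaged; one under the organ branch
  expect_equal(get("R1", "liver finding"), (0.513 + 0.2) / 2)
  expect_equal(get("R1", "abdominal organ finding"), 0.4)
  expect_equal(get("R1", "fatty liver"), 0)
  # R2: single descendant -> the feature weight is that term's probability
  expect_equal(get("R2", "liver finding"), 0.513)
  # R3: empty report -> every weight 0
  expect_true(all(w$p[w$report_id == "R3"] == 0))
  # weights differ between reports; generic ones cannot
  expect_false(identical(w$p[w$report_id == "R1"], w$p[w$report_id == "R2"]))
})

test_that("generic and specific weighting coincide on a one-term-per-feature cohort", {
  # each feature concept has exactly one extracted descendant term whose
  # name (hence query group) equals the feature concept's name
  edges <- tibble::tibble(
    child_id = c("F1", "F2", "T1", "T2"),
    parent_id = c("ROOT", "ROOT", "F1", "F2")
  )
  nms <- tibble::tibble(
    concept_id = c("ROOT", "F1", "F2", "T1", "T2"),
    preferred_name = c("root", "alpha sign", "beta sign",
                       "alpha sign", "beta sign")
  )
  ont <- ontology(edges, names = nms)
  sp <- feature_space(ont, 1)
  dis <- query_group("the disease")
  corp <- tibble::tibble(
    abstract_id = sprintf("a%d", 1:6),
    text = c("the disease with alpha sign", "the disease only",
             "the disease and beta sign", "alpha sign alone",
             "the disease with alpha sign again", "beta sign alone")
  )
  prov <- corpus_count_provider(corp)
  coh <- make_reports("R1", "X", list(c("T1", "T2")))
  wg <- generic_weights(sp, ont, dis, prov)
  ws <- specific_weights(coh, sp, ont, dis, prov)
  expect_equal(ws$p[match(wg$feature_id, ws$feature_id)], wg$p)
})

test_that("estimated weights recover a planted conditional probability", {
  ont <- simulate_ontology(depth = 4, branching = 2, seed = 7)
  dis <- query_group("hepatocellular carcinoma", "HCC")
  vocab <- names(ont$levels)[ont$levels >= 2][1:4]
  corp <- simulate_corpus(ont, dis, vocab, n_abstracts = 1500,
                          disease_prob = 1, p_given_disease = 0.3,
                          p_given_background = 0, seed = 8)
  prov <- corpus_count_provider(corp)
  q <- term_probability(ont, vocab, dis, prov)$q
  se <- sqrt(0.3 * 0.7 / 1500)
  expect_true(all(abs(q - 0.3) <= 3 * se))
})

test_that("terms rank by descending probability with lexicographic ties", {
  tw <- tibble::tibble(term_id = c("a", "b"), q = c(0.1, 0.9))
  expect_equal(rank_terms(tw)$term_id, c("b", "a"))
  ties <- tibble::tibble(term_id = c("z", "m", "a"), q = c(0.5, 0.5, 0.5))
  expect_equal(rank_terms(ties)$term_id, c("a", "m", "z"))
  expect_equal(rank_terms(ties)$rank, 1:3)
  # agreement with an oracle comparison sort on random weights
  set.seed(42)
  rnd <- tibble::tibble(term_id = sprintf("t%02d", 1:10),
                        q = round(runif(10), 2))
  oracle <- rnd[order(-rnd$q, rnd$term_id), ]
  expect_equal(rank_terms(rnd)$term_id, oracle$term_id)
  expect_error(rank_terms(tibble::tibble(term_id = "a", q = 1.2)),
               class = "ontosim_error_validation")
})
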