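test_that("pair labels count matches and mismatches correctly", {
  coh <- make_reports(c("a", "b"), c("HCC", "HCC"), list("x", "x"))
  # two same-label reports: one match, no mismatch (no usable ROC)
  expect_warning(lp <- label_pairs(coh),
                 class = "ontosim_warning_single_class")
  expect_equal(nrow(lp), 1)
  expect_equal(sum(lp$label == "match"), 1)
  # three labels {A, A, B, C}: 1 match, 5 mismatches (exhaustive count)
  coh2 <- make_reports(sprintf("r%d", 1:4), c("A", "A", "B", "C"),
                       replicate(4, character(0), simplify = FALSE))
  lp2 <- label_pairs(coh2)
  expect_equal(nrow(lp2), 6)
  expect_equal(sum(lp2$label == "match"), 1)
  expect_equal(sum(lp2$label == "mismatch"), 5)
})

test_that("match + mismatch counts always total C(R, 2)", {
  ont <- simulate_ontology(depth = 5, branching = 2, seed = 21)
  panels <- make_panels(ont, overlap = 0.5, seed = 22)
  for (n in list(c(3, 4), c(10, 7), c(5, 5))) {
    coh <- simulate_cohort(ont, panels, n_per_label = n, seed = sum(n))
    lp <- label_pairs(coh)
    expect_equal(nrow(lp), choose(sum(n), 2))
    expect_equal(sum(lp$label == "match"), sum(choose(n, 2)))
  }
})

test_that("AUROC hits its closed-form fixed points", {
  lp <- tibble::tibble(
    id_a = "a", id_b = sprintf("b%d", 1:8),
    label = rep(c("match", "mismatch"), each = 4)
  )
  sep <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b,
                        score = c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.3, 0.15))
  expect_equal(roc_auroc(sep, lp)$auroc, 1)
  ties <- dplyr::mutate(sep, score = 0.5)
  expect_equal(roc_auroc(ties, lp)$auroc, 0.5)
  one_class <- dplyr::mutate(lp, label = "match")
  expect_error(roc_auroc(sep, one_class),
               class = "ontosim_error_degenerate_roc")
  expect_error(roc_auroc(sep[-1, ], lp), class = "ontosim_error_coverage")
})

test_that("rank AUROC equals the brute-force pair statistic and pROC", {
  set.seed(77)
  for (i in 1:5) {
    n_pos <- 14; n_neg <- 16
    sc <- round(runif(n_pos + n_neg), 1)   # rounding forces ties
    lp <- tibble::tibble(
      id_a = "q", id_b = sprintf("r%02d", seq_along(sc)),
      label = rep(c("match", "mismatch"), c(n_pos, n_neg))
    )
    scores <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b, score = sc)
    r <- roc_auroc(scores, lp)
    expect_equal(r$auroc, bf_auroc(sc[1:n_pos], sc[-(1:n_pos)]))
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = lp$label, predictor = sc, levels = c("mismatch", "match"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(r$auroc, proc_auc)
    # the emitted curve integrates back to the rank statistic
    expect_equal(trapezoid_area(r$curve), r$auroc, tolerance = 1e-9)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
                 c(fpr = 1, tpr = 1))
    # score reversal mirrors the area
    rev <- dplyr::mutate(scores, score = 1 - score)
    expect_equal(roc_auroc(rev, lp)$auroc, 1 - r$auroc)
  }
})

test_that("confidence intervals bracket the AUROC and shrink with n", {
  make <- function(n) {
    lp <- tibble::tibble(
      id_a = "q", id_b = sprintf("r%04d", 1:(2 * n)),
      label = rep(c("match", "mismatch"), each = n)
    )
    set.seed(n)
    sc <- c(rnorm(n, 1), rnorm(n, 0))
    roc_auroc(tibble::tibble(id_a = lp$id_a, id_b = lp$id_b, score = sc), lp)
  }
  r1 <- make(30); r2 <- make(300)
  expect_true(r1$ci_low <= r1$auroc && r1$auroc <= r1$ci_high)
  expect_lt(r2$ci_high - r2$ci_low, r1$ci_high - r1$ci_low)
})

test_that("the DeLong comparison is rank-invariant and matches pROC", {
  set.seed(5)
  n <- 60
  lp <- tibble::tibble(
    id_a = "q", id_b = sprintf("r%03d", 1:n),
    label = rep(c("match", "mismatch"), each = n / 2)
  )
  base <- c(rnorm(n / 2, 0.8), rnorm(n / 2, 0))
  other <- base + rnorm(n, sd = 0.8)
  sa <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b, score = base)
  sb <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b, score = other)
  cmp <- compare_auroc(sa, sb, lp)
  # identical and monotone-transformed scores: no difference, p = 1
  self <- compare_auroc(sa, sa, lp)
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)
  mono <- dplyr::mutate(sa, score = exp(3 * score))
  expect_equal(compare_auroc(sa, mono, lp)$difference, 0)
  # against pROC's paired DeLong test
  ra <- pROC::roc(lp$label, sa$score, levels = c("mismatch", "match"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(lp$label, sb$score, levels = c("mismatch", "match"),
                  direction = "<", quiet = TRUE)
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(pt$p.value), tolerance = 1e-10)
  expect_equal(cmp$difference, as.numeric(pt$estimate[1] - pt$estimate[2]),
               tolerance = 1e-12)
  # mismatched pair sets are refused
  expect_error(compare_auroc(sa, sb[-1, ], lp),
               class = "ontosim_error_coverage")
})

test_that("the DeLong test detects a planted AUROC gap", {
  # planted gap of 0.10 between two normal-shift score models, 500/500
  mu_a <- sqrt(2) * qnorm(0.75)
  mu_b <- sqrt(2) * qnorm(0.65)
  n <- 500
  lp <- tibble::tibble(
    id_a = "q", id_b = sprintf("r%04d", 1:(2 * n)),
    label = rep(c("match", "mismatch"), each = n)
  )
  set.seed(123)
  rejections <- vapply(1:200, function(i) {
    sa <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b,
                         score = c(rnorm(n, mu_a), rnorm(n)))
    sb <- tibble::tibble(id_a = lp$id_a, id_b = lp$id_b,
                         score = c(rnorm(n, mu_b), rnorm(n)))
    compare_auroc(sa, sb, lp)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("sweeping k finds the plateau and honors the tie rule", {
  fix <- delta_domination_cohort()
  eq <- equal_weights(fix$space)
  sw <- sweep_k(fix$cohort, fix$space, fix$ont, eq, k_values = c(0, 2, 6, 10))
  res <- sw$results
  expect_lt(res$auroc[res$k == 0], res$auroc[res$k == 2])
  # plateau: large-k AUROCs agree and the smallest plateau member is chosen
  expect_equal(res$auroc[res$k == 6], res$auroc[res$k == 10],
               tolerance = 1e-9)
  expect_gte(sw$chosen_k, 1)
  expect_equal(sw$chosen_k,
               min(res$k[res$auroc >= max(res$auroc) - 1e-3]))
  single <- sweep_k(fix$cohort, fix$space, fix$ont, eq, k_values = 7)
  expect_equal(single$chosen_k, 7L)
  # identical AUROC across all k -> smallest swept k wins
  flat <- make_reports(c("e1", "e2", "f1"), c("A", "A", "B"),
                       replicate(3, character(0), simplify = FALSE))
  swf <- sweep_k(flat, fix$space, fix$ont, eq, k_values = c(3, 5, 9))
  expect_equal(swf$chosen_k, 3L)
  # per-k values agree with individually computed ROCs
  labels <- label_pairs(fix$cohort)
  for (k in c(0, 10)) {
    sc <- pairwise_similarities(fix$cohort, fix$space, fix$ont, eq, k = k)
    expect_equal(res$auroc[res$k == k], roc_auroc(sc, labels)$auroc)
  }
})

test_that("tidiers and plots expose the result objects", {
  fix <- delta_domination_cohort()
  eq <- equal_weights(fix$space)
  sc <- pairwise_similarities(fix$cohort, fix$space, fix$ont, eq, k = 10)
  lp <- label_pairs(fix$cohort)
  r <- roc_auroc(sc, lp)
  g <- glance(r)
  expect_equal(g$auroc, r$auroc)
  expect_named(tidy(r), c("threshold", "fpr", "tpr"))
  expect_s3_class(autoplot(r), "ggplot")
  sw <- sweep_k(fix$cohort, fix$space, fix$ont, eq, k_values = c(0, 4))
  expect_equal(glance(sw)$chosen_k, sw$chosen_k)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_score_separation(sc, lp), "ggplot")
  cb <- cluster_bootstrap_auroc(sc, lp, n_boot = 50, seed = 9)
  expect_equal(cb$auroc, r$auroc)
  expect_lte(cb$boot_ci_low, cb$boot_ci_high)
  expect_lte(cb$n_boot_used, 50)
})
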