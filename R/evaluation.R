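# ROC evaluation of pairwise similarity scores as predictors of diagnosis
# co-occurrence.

#' Label report pairs as diagnosis matches or mismatches
#'
#' Forms every unordered distinct pair of reports and labels it `match` when
#' both reports carry the same diagnosis and `mismatch` otherwise. For R
#' reports with label counts R_1, R_2, ... this yields C(R, 2) pairs of which
#' sum C(R_l, 2) are matches.
#'
#' @param reports A reports tibble (see [reports()]), at least two rows.
#' @return A tibble `id_a`, `id_b`, `label` with `id_a < id_b`; a warning is
#'   raised when the cohort has a single diagnosis label (the pair set is
#'   then unusable for ROC analysis).
#' @export
label_pairs <- function(reports) {
  reports <- ontosim::reports(reports)
  if (nrow(reports) < 2) {
    abort_ontosim("Need at least two reports to form pairs.", "validation")
  }
  if (length(unique(reports$diagnosis)) < 2) {
    rlang::warn(
      "Cohort has a single diagnosis label; all pairs are matches and no ROC can be computed.",
      class = "ontosim_warning_single_class"
    )
  }
  reports <- reports[order(reports$report_id, method = "radix"), ]
  idx <- combn(nrow(reports), 2)
  tibble(
    id_a = reports$report_id[idx[1, ]],
    id_b = reports$report_id[idx[2, ]],
    label = ifelse(
      reports$diagnosis[idx[1, ]] == reports$diagnosis[idx[2, ]],
      "match", "mismatch"
    )
  )
}

# joins a score table onto a label table by unordered pair id; errors on
# incomplete coverage
align_scores <- function(scores, labels) {
  scores <- normalize_pairs(as_tibble(scores))
  labels <- normalize_pairs(as_tibble(labels))
  if (!all(c("id_a", "id_b", "score") %in% names(scores)) ||
      !all(c("id_a", "id_b", "label") %in% names(labels))) {
    abort_ontosim("Need score columns (id_a, id_b, score) and label columns (id_a, id_b, label).",
                  "format")
  }
  merged <- left_join(labels, scores, by = c("id_a", "id_b"))
  if (anyNA(merged$score)) {
    abort_ontosim(
      sprintf("%d labeled pair(s) lack similarity scores.",
              sum(is.na(merged$score))),
      "coverage"
    )
  }
  merged
}

# Mann-Whitney AUROC with midranks for ties
auroc_rank <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# threshold-sweep ROC curve; ties collapsed so the trapezoid area equals the
# rank statistic
roc_curve_points <- function(pos, neg) {
  sc <- c(pos, neg)
  lab <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  ord <- order(-sc)
  sc <- sc[ord]; lab <- lab[ord]
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)   # last index of each tie block
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1L - lab)[keep]
  tibble(
    threshold = c(Inf, sc[keep]),
    fpr = c(0, fp / length(neg)),
    tpr = c(0, tp / length(pos))
  )
}

hanley_mcneil_se <- function(a, m, n) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n))
}

#' ROC analysis of pair similarity scores
#'
#' Computes the area under the ROC curve for similarity scores predicting
#' diagnosis co-occurrence (`match` is the positive class). The AUROC uses
#' the rank (Mann-Whitney) formulation with midranks for ties; the curve is
#' obtained by a threshold sweep; the confidence interval uses the
#' Hanley-McNeil standard-error formula on the normal scale.
#'
#' @param scores A tibble `id_a`, `id_b`, `score` (e.g. from
#'   [pairwise_similarities()]).
#' @param labels A tibble `id_a`, `id_b`, `label` from [label_pairs()],
#'   covering the same pairs.
#' @param conf_level Confidence level for the AUROC interval (default 0.95).
#' @return An object of class `roc_result` with fields `auroc`, `se`,
#'   `ci_low`, `ci_high`, `curve` (tibble of `threshold`, `fpr`, `tpr`),
#'   `n_pos`, `n_neg` and the aligned `data`. Has [tidy()], [glance()] and
#'   `autoplot()` methods.
#' @export
roc_auroc <- function(scores, labels, conf_level = 0.95) {
  merged <- align_scores(scores, labels)
  pos <- merged$score[merged$label == "match"]
  neg <- merged$score[merged$label != "match"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort_ontosim(
      "ROC needs both match and mismatch pairs; the cohort is single-class.",
      "degenerate_roc"
    )
  }
  a <- auroc_rank(pos, neg)
  se <- hanley_mcneil_se(a, length(pos), length(neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      auroc = a, se = se,
      ci_low = max(0, a - z * se), ci_high = min(1, a + z * se),
      conf_level = conf_level,
      curve = roc_curve_points(pos, neg),
      n_pos = length(pos), n_neg = length(neg),
      data = merged
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUROC %.4f (%d%% CI %.4f-%.4f), %d matches vs %d mismatches\n",
    x$auroc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_pos, x$n_neg
  ))
  invisible(x)
}

# DeLong placement values: v10 over positives, v01 over negatives
delong_placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' Compare two correlated AUROCs (DeLong test)
#'
#' Tests the difference between the AUROCs of two score tables computed over
#' the *same* labeled pairs, accounting for their correlation via DeLong's
#' covariance of placement values. The p-value is two-sided.
#'
#' @param scores_a,scores_b Score tibbles (`id_a`, `id_b`, `score`) over
#'   identical pair sets.
#' @param labels A label tibble from [label_pairs()].
#' @return An object of class `roc_comparison`: list with `auroc_a`,
#'   `auroc_b`, `difference` (a - b), `se`, `z`, `p_value`, `n_pos`, `n_neg`.
#' @export
compare_auroc <- function(scores_a, scores_b, labels) {
  ma <- align_scores(scores_a, labels)
  mb <- align_scores(scores_b, labels)
  if (nrow(ma) != nrow(mb)) {
    abort_ontosim("Score tables cover different pair sets.", "contract")
  }
  # align_scores preserves the label-table row order, so rows correspond
  is_pos <- ma$label == "match"
  if (!any(is_pos) || all(is_pos)) {
    abort_ontosim("ROC comparison needs both pair classes.", "degenerate_roc")
  }
  pa <- delong_placements(ma$score[is_pos], ma$score[!is_pos])
  pb <- delong_placements(mb$score[is_pos], mb$score[!is_pos])
  m <- sum(is_pos); n <- sum(!is_pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$theta - pb$theta
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  structure(
    list(auroc_a = pa$theta, auroc_b = pb$theta, difference = diff,
         se = sqrt(max(var_diff, 0)), z = z,
         p_value = 2 * pnorm(-abs(z)), n_pos = m, n_neg = n),
    class = "roc_comparison"
  )
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<roc_comparison> AUROC %.4f vs %.4f, difference %+.4f, z = %.3f, p = %.4g\n",
    x$auroc_a, x$auroc_b, x$difference, x$z, x$p_value
  ))
  invisible(x)
}

#' Sweep the regularization exponent k
#'
#' Recomputes pairwise similarities and their AUROC for each candidate k
#' (delta = 10^-k) and picks the smallest k whose AUROC sits within a plateau
#' tolerance of the maximum, mirroring the observation that accuracy rises
#' with k and then saturates.
#'
#' @inheritParams pairwise_similarities
#' @param k_values Non-negative integer exponents to sweep (default 0:12).
#' @param plateau_tol Tolerance defining the plateau around the maximum AUROC
#'   (default 1e-3).
#' @return An object of class `k_sweep`: list with `results` (tibble `k`,
#'   `auroc`) and `chosen_k`. Has [tidy()], [glance()] and `autoplot()`
#'   methods.
#' @export
sweep_k <- function(reports, space, ont, weights, k_values = 0:12,
                    plateau_tol = 1e-3) {
  reports <- ontosim::reports(reports)
  if (length(k_values) == 0) {
    abort_ontosim("`k_values` must be non-empty.", "validation")
  }
  purrr::walk(k_values, check_k)
  labels <- suppressWarnings(label_pairs(reports))
  reports <- reports[order(reports$report_id, method = "radix"), ]
  m <- feature_matrix(reports, space, ont, weights, k = k_values[1])
  aurocs <- purrr::map_dbl(k_values, function(k) {
    m[, ".delta"] <- 10^(-k)
    sc <- cosine_pairs(m, reports$report_id)
    roc_auroc(sc, labels)$auroc
  })
  best <- max(aurocs)
  chosen <- k_values[which(aurocs >= best - plateau_tol)[1]]
  structure(
    list(results = tibble(k = as.integer(k_values), auroc = aurocs),
         chosen_k = as.integer(chosen), plateau_tol = plateau_tol),
    class = "k_sweep"
  )
}

#' @export
print.k_sweep <- function(x, ...) {
  cat(sprintf("<k_sweep> %d values of k, chosen k = %d (plateau tol %g)\n",
              nrow(x$results), x$chosen_k, x$plateau_tol))
  print(x$results)
  invisible(x)
}

#' Cluster bootstrap for the AUROC of pair scores
#'
#' Sensitivity analysis for the fact that pairs sharing a report are
#' statistically dependent, which the standard pairwise ROC treats as
#' independent. Reports (not pairs) are resampled with replacement; each
#' bootstrap cohort's pairs are scored with the original score table and the
#' AUROC distribution over replicates gives a percentile interval. This is a
#' robustness check on top of the primary analysis, not part of it.
#'
#' @param scores,labels As in [roc_auroc()].
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param conf_level Percentile interval level (default 0.95).
#' @param seed Optional seed for reproducibility.
#' @return A tibble with one row: `auroc` (observed), `boot_ci_low`,
#'   `boot_ci_high`, `n_boot_used` (replicates with both classes present).
#' @export
cluster_bootstrap_auroc <- function(scores, labels, n_boot = 200,
                                    conf_level = 0.95, seed = NULL) {
  merged <- align_scores(scores, labels)
  ids <- unique(c(merged$id_a, merged$id_b))
  key <- paste(merged$id_a, merged$id_b, sep = "\r")
  score_of <- setNames(merged$score, key)
  label_of <- setNames(merged$label, key)
  obs <- roc_auroc(merged[, c("id_a", "id_b", "score")],
                   merged[, c("id_a", "id_b", "label")])$auroc
  boots <- with_seed_if(seed, {
    purrr::map_dbl(seq_len(n_boot), function(b) {
      samp <- sample(ids, length(ids), replace = TRUE)
      idx <- combn(length(samp), 2)
      a <- samp[idx[1, ]]; bb <- samp[idx[2, ]]
      keep <- a != bb
      a <- a[keep]; bb <- bb[keep]
      kk <- paste(pmin(a, bb), pmax(a, bb), sep = "\r")
      sc <- score_of[kk]; lb <- label_of[kk]
      if (length(unique(lb)) < 2) return(NA_real_)
      auroc_rank(sc[lb == "match"], sc[lb != "match"])
    })
  })
  ok <- boots[!is.na(boots)]
  alpha <- (1 - conf_level) / 2
  tibble(
    auroc = obs,
    boot_ci_low = unname(stats::quantile(ok, alpha)),
    boot_ci_high = unname(stats::quantile(ok, 1 - alpha)),
    n_boot_used = length(ok)
  )
}
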