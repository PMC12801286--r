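test_that("weighted cross-entropy follows the class-weighted formula", {
  expect_lt(weighted_ce_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(weighted_ce_loss(0.5, 1), 1.2 * log(2))
  expect_equal(weighted_ce_loss(exp(-1), 1), 1.2)
  # unit weights reduce to plain cross-entropy
  p <- c(0.8, 0.3, 0.6); y <- c(1, 0, 1)
  expect_equal(weighted_ce_loss(p, y, 1, 1),
               mean(-log(ifelse(y == 1, p, 1 - p))))
  expect_warning(weighted_ce_loss(c(0), c(1)), "clipping")
})

test_that("AUROC equals the all-pairs Mann-Whitney count with tie half-credit", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(17)
  for (rep in 1:10) {
    n <- 12
    probs <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pairs <- expand.grid(i = which(labels == 1), j = which(labels == 0))
    brute <- mean((probs[pairs$i] > probs[pairs$j]) +
                    0.5 * (probs[pairs$i] == probs[pairs$j]))
    expect_equal(auroc(probs, labels), brute)
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  probs <- runif(60); labels <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(probs, labels), ref, tolerance = 1e-12)
})

test_that("EER threshold matches an exhaustive sweep oracle", {
  sweep_oracle <- function(probs, labels) {
    cand <- c(sort(unique(probs)), Inf)
    gaps <- vapply(cand, function(t) {
      abs(mean(probs[labels == 0] >= t) - mean(probs[labels == 1] < t))
    }, 0)
    cand[which(gaps <= min(gaps) + 1e-15)][1]
  }
  # perfectly separated: smallest candidate achieving FPR = FNR = 0
  probs <- c(0.9, 0.8, 0.3, 0.2); labels <- c(1, 1, 0, 0)
  t0 <- eer_threshold(probs, labels)
  expect_equal(as.numeric(t0), 0.8)
  expect_equal(attr(t0, "fpr"), 0)
  expect_equal(attr(t0, "fnr"), 0)
  set.seed(23)
  for (rep in 1:12) {
    n <- 15
    probs <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(as.numeric(eer_threshold(probs, labels)),
                 sweep_oracle(probs, labels))
  }
  expect_warning(t1 <- eer_threshold(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)),
                 "degenerate")
  expect_equal(as.numeric(t1), 0.4)
})

test_that("risk stratification is consistent with its threshold", {
  rs <- risk_stratify(c(0.2, 0.5, 0.7), 0.5, c("a", "b", "c"))
  expect_equal(rs$risk_class, c("low", "high", "high"))
  expect_true(all(rs$threshold == 0.5))
})

test_that("DeLong comparison: identical models, antisymmetry, jackknife variance", {
  set.seed(29)
  labels <- rbinom(40, 1, 0.5)
  pA <- runif(40) + 0.5 * labels
  same <- delong_compare(pA, pA, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  pB <- runif(40) + 0.3 * labels
  ab <- delong_compare(pA, pB, labels)
  ba <- delong_compare(pB, pA, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # jackknife oracle for the single-model AUROC variance
  set.seed(31)
  n <- 200
  labels <- rbinom(n, 1, 0.4)
  probs <- runif(n) + 0.8 * labels
  dl <- delong_compare(probs, runif(n), labels)
  theta <- vapply(seq_len(n), function(i) auroc(probs[-i], labels[-i]), 0)
  v_jack <- (n - 1) / n * sum((theta - mean(theta))^2)
  expect_equal(dl$var[1], v_jack, tolerance = 0.1)
})

test_that("DeLong p-value agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  labels <- rbinom(80, 1, 0.5)
  pA <- runif(80) + 0.6 * labels
  pB <- runif(80) + 0.2 * labels
  ours <- delong_compare(pA, pB, labels)
  ref <- pROC::roc.test(pROC::roc(labels, pA, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, pB, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("Kaplan-Meier handles censoring and degenerate inputs", {
  km <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  km2 <- km_curve(c(2, 4, 6, 8), c(1, 1, 0, 1))
  expect_equal(km2$surv[km2$time == 2], 0.75)
  expect_error(km_curve(c(-1, 2), c(1, 1)), "times")
  grouped <- km_curve(c(2, 4, 6, 8), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_true(all(c("a", "b") %in% grouped$group))
})

test_that("log-rank statistic matches a hand-tabulated oracle", {
  logrank_oracle <- function(times, events, group) {
    g <- as.integer(factor(group))
    O1 <- E1 <- V <- 0
    for (t in sort(unique(times[events == 1]))) {
      at <- times >= t
      n <- sum(at); n1 <- sum(at & g == 1)
      d <- sum(times == t & events == 1)
      d1 <- sum(times == t & events == 1 & g == 1)
      O1 <- O1 + d1
      E1 <- E1 + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
  }
  # 6-subject toy table
  times <- c(3, 5, 7, 9, 11, 13)
  events <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "a", "a", "b", "b", "b")
  ours <- logrank_test(times, events, group)
  expect_equal(ours$chisq, logrank_oracle(times, events, group),
               tolerance = 1e-12)
  expect_equal(ours$p, pchisq(ours$chisq, 1, lower.tail = FALSE))

  set.seed(41)
  for (rep in 1:5) {
    tt <- rexp(20, 0.05) + 0.5
    ee <- rbinom(20, 1, 0.8)
    gg <- rep(c("x", "y"), 10)
    expect_equal(logrank_test(tt, ee, gg)$chisq,
                 logrank_oracle(tt, ee, gg), tolerance = 1e-10)
  }
  # identical groups: duplicate every subject into both arms
  tt <- c(2, 5, 9); ee <- c(1, 0, 1)
  res <- logrank_test(c(tt, tt), c(ee, ee), rep(c("a", "b"), each = 3))
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(tt, ee, rep("a", 3)), "two groups")
})

test_that("bootstrap AUROC interval brackets the point estimate", {
  set.seed(43)
  labels <- rbinom(60, 1, 0.5)
  probs <- runif(60) + labels
  ci <- auroc_ci(probs, labels, n_boot = 300, seed = 3)
  expect_lte(ci$lower, ci$auroc)
  expect_gte(ci$upper, ci$auroc)
  ci2 <- auroc_ci(probs, labels, n_boot = 300, seed = 3)
  expect_identical(ci, ci2)
})
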