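test_that("pooled t-test matches the closed form and its summary twin", {
  out <- t_test_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, -3.674, tolerance = 1e-3)
  expect_equal(out$p_value, 0.021312, tolerance = 1e-4)

  expect_equal(t_test_groups(c(5, 6, 7), c(5, 6, 7))$p_value, 1)

  # moment-matched raw samples reproduce the summary route to 1e-12
  withr::with_seed(8, {
    a <- stats::rnorm(18); b <- stats::rnorm(51)
  })
  a <- (a - mean(a)) / stats::sd(a) * 6.0 + 9.3
  b <- (b - mean(b)) / stats::sd(b) * 9.1 + 15.9
  raw <- t_test_groups(a, b)
  summ <- t_test_summary(9.3, 6.0, 18, 15.9, 9.1, 51)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)

  expect_equal(t_test_summary(5, 0, 10, 5, 0, 10)$p_value, 1)
  expect_error(t_test_summary(4, 0, 10, 5, 0, 10), "zero pooled variance")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  out <- categorical_test(matrix(c(10, 0, 0, 10), 2), method = "fisher")
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(categorical_test(matrix(1, 2, 2), method = "fisher")$p_value, 1)

  # enumeration oracle over random tables with margins <= 30
  fisher_enum <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    pr <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n, k)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  withr::with_seed(21, {
    for (i in 1:25) {
      tab <- matrix(stats::rpois(4, 4), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(categorical_test(tab, method = "fisher")$p_value,
                   fisher_enum(tab), tolerance = 1e-9)
    }
  })
})

test_that("the auto rule picks Fisher when expected counts drop below 5", {
  small <- matrix(c(3, 1, 2, 4), 2)
  expect_match(categorical_test(small, "auto")$method, "Fisher")
  big <- matrix(c(30, 20, 25, 35), 2)
  expect_match(categorical_test(big, "auto")$method, "chi-squared")
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE),
                                "auto"), "empty margin")
})

test_that("mixed ANOVA separates uniform group shifts from interactions", {
  withr::with_seed(15, {
    n <- 12
    base <- stats::rnorm(2 * n)
    d <- expand.grid(id = sprintf("S%02d", 1:(2 * n)), region = LA_REGIONS)
    d$group <- rep(rep(c("a", "b"), each = n), times = 5)
    d$value <- stats::rnorm(nrow(d)) + base[as.integer(factor(d$id))] +
      ifelse(d$group == "b", 3, 0)  # uniform shift, no interaction
  })
  out <- mixed_anova(d, subject = "id", group = "group",
                     region = "region", value = "value")
  expect_setequal(out$effect, c("group", "region", "group:region"))
  expect_lt(out$p_value[out$effect == "group"], 0.01)
  expect_gt(out$p_value[out$effect == "group:region"], 0.05)
  expect_true(all(out$gg_epsilon[out$effect != "group"] <= 1 + 1e-9,
                  na.rm = TRUE))

  single <- d[d$id %in% c("S01", "S13"), ]
  expect_error(mixed_anova(single, "id", "group", "region", "value"),
               ">= 2 subjects")
  expect_error(mixed_anova(d[-1, ], "id", "group", "region", "value"),
               "unbalanced")
})

test_that("AUC equals brute-force concordant-pair counting for small n", {
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(cmp)
  }
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 200)$auc, 1)
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1), n_boot = 200)$auc,
               0.75)
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(6:12, 1)
      labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      scores <- round(stats::rnorm(n), 1)  # ties likely
      a <- roc_analysis(scores, labels, n_boot = 200, seed = i)$auc
      b <- pair_auc(scores, labels)
      expect_equal(a, max(b, 1 - b), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(2, {
    scores <- stats::rnorm(40)
    labels <- stats::rbinom(40, 1, 0.5)
  })
  a1 <- roc_analysis(scores, labels, n_boot = 200, seed = 1)
  a2 <- roc_analysis(exp(2 * scores) + 5, labels, n_boot = 200, seed = 1)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 with a degenerate upper CI", {
  out <- roc_analysis(c(1:10, 21:30), rep(c(0, 1), each = 10),
                      n_boot = 200, seed = 4)
  expect_equal(out$auc, 1)
  expect_equal(unname(out$ci["upper"]), 1)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  expect_equal(out$f1, 1)
  expect_error(roc_analysis(1:5, rep(1, 5), n_boot = 200), "both outcome")
  expect_error(roc_analysis(1:5, c(0, 0, 0, 1, 1), n_boot = 50), "200")
})

test_that("DeLong's test is null for identical or monotone-equivalent scores", {
  withr::with_seed(6, {
    scores <- stats::rnorm(30)
    labels <- stats::rbinom(30, 1, 0.5)
  })
  same <- delong_test(scores, scores, labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_test(scores, scores^3 + 2 * scores, labels)
  expect_equal(mono$delta_auc, 0)
  expect_equal(mono$p_value, 1)
  expect_error(delong_test(scores, scores[-1], labels), "equal length")
})

test_that("DeLong detects a real AUC gap on correlated scores", {
  withr::with_seed(17, {
    n <- 300
    labels <- rep(c(0, 1), each = n / 2)
    good <- stats::rnorm(n) + labels * 2.0
    weak <- 0.5 * good + stats::rnorm(n, sd = 1.2)
  })
  out <- delong_test(good, weak, labels)
  expect_gt(out$delta_auc, 0.05)
  expect_lt(out$p_value, 0.01)
})

test_that("clustering recovers two separated blobs and removes lone outliers", {
  withr::with_seed(9, {
    X <- rbind(matrix(stats::rnorm(20 * 36, mean = 0), ncol = 36),
               matrix(stats::rnorm(20 * 36, mean = 4), ncol = 36))
  })
  rownames(X) <- sprintf("S%03d", 1:40)
  out <- cluster_phenotypes(X, k_range = 2:5, seed = 1)
  expect_equal(out$k, 2)
  truth <- rep(1:2, each = 20)
  agree <- max(mean(out$assignments == truth),
               mean(out$assignments == 3 - truth))
  expect_equal(agree, 1)
  expect_length(out$removed, 0)
  expect_equal(sum(out$pca$var_explained), 1, tolerance = 1e-9)

  # one extreme outlier forms a sole-member cluster and is removed
  X2 <- rbind(X, outlier = matrix(60, 1, 36))
  rownames(X2) <- c(rownames(X), "S999")
  out2 <- suppressMessages(cluster_phenotypes(X2, k_range = 2:5, seed = 1))
  expect_true("S999" %in% out2$removed)
  expect_equal(out2$k, 2)

  # constant columns are dropped with a message; identical rows error
  X3 <- cbind(X, const = 1)
  expect_message(cluster_phenotypes(X3, k_range = 2:3, seed = 1),
                 "zero-variance")
  X4 <- matrix(1, 10, 4)
  expect_error(suppressMessages(cluster_phenotypes(X4, k_range = 2:3, seed = 1)),
               "degenerate")
})

test_that("clustering is deterministic under a fixed seed", {
  withr::with_seed(10, X <- matrix(stats::rnorm(30 * 8), ncol = 8))
  a <- cluster_phenotypes(X, k_range = 2:4, seed = 77)
  b <- cluster_phenotypes(X, k_range = 2:4, seed = 77)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$silhouette, b$silhouette)
})
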