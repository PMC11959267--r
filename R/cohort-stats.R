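#' Pooled-variance two-sided Student's t-test
#'
#' Group comparison of a continuous feature with the classical pooled
#' two-sample t statistic (`df = n_a + n_b - 2`). Welch's unequal-variance
#' form is available behind a flag.
#'
#' @param group_a,group_b Numeric samples (each n >= 2, finite).
#' @param welch Use Welch's correction instead of pooled variance.
#' @return A one-row data frame: `mean_a`, `mean_b`, `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
t_test_groups <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(is.finite(group_a)), all(is.finite(group_b)))
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(data.frame(mean_a = mean(group_a), mean_b = mean(group_b),
                        statistic = 0, df = length(group_a) + length(group_b) - 2,
                        p_value = 1, method = "Student t (pooled), degenerate"))
    stop("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  data.frame(mean_a = mean(group_a), mean_b = mean(group_b),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             method = if (welch) "Welch t" else "Student t (pooled)")
}

#' Pooled t-test from summary statistics
#'
#' Identical formula to [t_test_groups()] via sufficient statistics, so
#' published group means/SDs/counts can be re-tested directly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (`sd >= 0`,
#'   `n >= 2`).
#' @return A one-row data frame as in [t_test_groups()].
#' @export
t_test_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      return(data.frame(mean_a = mean_a, mean_b = mean_b, statistic = 0,
                        df = df, p_value = 1,
                        method = "Student t (pooled, summary), degenerate"))
    stop("zero pooled variance with unequal means")
  }
  tstat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  data.frame(mean_a = mean_a, mean_b = mean_b, statistic = tstat, df = df,
             p_value = 2 * stats::pt(-abs(tstat), df),
             method = "Student t (pooled, summary)")
}

#' Categorical 2x2 group comparison
#'
#' Chi-squared (with continuity correction) or Fisher's exact test on a 2x2
#' contingency table; `"auto"` follows the usual rule of using Fisher's
#' exact test whenever any expected count is below 5.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method `"auto"`, `"fisher"` or `"chi2"`.
#' @return A one-row data frame: `statistic` (chi2 only), `p_value`,
#'   `method`.
#' @export
categorical_test <- function(table, method = c("auto", "fisher", "chi2")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin in 2x2 table")
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    data.frame(statistic = NA_real_, p_value = ft$p.value,
               method = "Fisher exact")
  } else {
    ct <- stats::chisq.test(table, correct = TRUE)
    data.frame(statistic = unname(ct$statistic), p_value = ct$p.value,
               method = "chi-squared (continuity-corrected)")
  }
}

#' Two-way mixed ANOVA for regional parameters
#'
#' Between-subjects factor (group) by within-subjects factor (region) mixed
#' ANOVA, testing in particular the group-by-region interaction. Sphericity
#' is assessed (Mauchly) and Greenhouse-Geisser-corrected p-values are
#' reported alongside the uncorrected ones.
#'
#' @param data Long-format data frame.
#' @param subject,group,region,value Column names (strings) identifying the
#'   subject id, between factor, within factor and response.
#' @return Data frame with one row per effect (`group`, `region`,
#'   `group:region`): `df1`, `df2`, `F`, `p_value`, `gg_epsilon`,
#'   `p_value_gg`.
#' @export
mixed_anova <- function(data, subject = "id", group = "group",
                        region = "region", value = "value") {
  d <- data.frame(id = factor(data[[subject]]), g = factor(data[[group]]),
                  r = factor(data[[region]]), y = data[[value]])
  wide <- stats::reshape(d, idvar = c("id", "g"), timevar = "r",
                         direction = "wide")
  ymat <- as.matrix(wide[, grep("^y\\.", names(wide)), drop = FALSE])
  if (anyNA(ymat)) stop("unbalanced within-factor: missing region rows")
  if (any(table(wide$g) < 2)) stop("need >= 2 subjects per group")
  g <- droplevels(wide$g)
  mod <- stats::lm(ymat ~ g)
  idata <- data.frame(region = factor(sub("^y\\.", "", colnames(ymat))))
  aa <- car::Anova(mod, idata = idata, idesign = ~region, type = 3)
  ss <- suppressWarnings(summary(aa, multivariate = FALSE))
  ut <- ss$univariate.tests
  adj <- ss$pval.adjustments
  pick <- function(nm) {
    row <- ut[nm, ]
    gg_eps <- if (nm %in% rownames(adj)) adj[nm, "GG eps"] else NA_real_
    p_gg <- if (nm %in% rownames(adj)) adj[nm, "Pr(>F[GG])"] else row[["Pr(>F)"]]
    data.frame(effect = nm, df1 = row[["num Df"]], df2 = row[["den Df"]],
               F = row[["F value"]], p_value = row[["Pr(>F)"]],
               gg_epsilon = gg_eps, p_value_gg = p_gg)
  }
  out <- do.call(rbind, lapply(c("g", "region", "g:region"), pick))
  out$effect <- c("group", "region", "group:region")
  rownames(out) <- NULL
  out
}

#' ROC analysis of one feature against a binary outcome
#'
#' Rank-based AUC with the orientation chosen automatically so the reported
#' AUC is >= 0.5 (the chosen direction is recorded — reduced strain
#' magnitudes typically predict events). A stratified subject-level
#' percentile bootstrap gives the 95% CI, and the operating point maximizing
#' Youden's J supplies sensitivity, specificity, PPV and F1.
#'
#' @param scores Numeric feature values.
#' @param labels Binary outcome (0/1, logical, or two-level factor).
#' @param n_boot Bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return List: `auc`, `ci` (length-2), `direction`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `f1`, `n`, `n_boot`.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels)) != 2) stop("both outcome classes must be present")
  if (n_boot < 200) stop("n_boot must be >= 200")
  r <- oriented_roc(labels, scores)
  ci <- withr::with_seed(seed,
    suppressWarnings(pROC::ci.auc(r, method = "bootstrap", boot.n = n_boot,
                                  boot.stratified = TRUE)))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity",
                               "ppv"),
                       transpose = FALSE)
  best <- best[1, ]  # earliest operating point on ties
  f1 <- 2 * best$ppv * best$sensitivity / (best$ppv + best$sensitivity)
  ci <- as.numeric(ci)
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(lower = ci[1], upper = ci[3]),
       direction = r$direction, threshold = best$threshold,
       sensitivity = best$sensitivity, specificity = best$specificity,
       ppv = best$ppv, f1 = f1, n = length(scores), n_boot = n_boot)
}

# orientation rule: report the direction whose AUC is >= 0.5
oriented_roc <- function(labels, scores) {
  lt <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                  quiet = TRUE)
  if (as.numeric(pROC::auc(lt)) >= 0.5) return(lt)
  pROC::roc(labels, scores, direction = ">", levels = c(0, 1), quiet = TRUE)
}

#' DeLong's test for two paired ROC curves
#'
#' Compares the AUCs of two features measured on the same subjects using the
#' DeLong placement-value covariance and a two-sided z-test.
#'
#' @param scores_1,scores_2 Paired feature values (same subjects, same
#'   order).
#' @param labels Binary outcome.
#' @return List: `auc_1`, `auc_2`, `delta_auc`, `statistic`, `p_value`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2))
    stop("paired scores must have equal length")
  labels <- as.integer(as.factor(labels)) - 1L
  r1 <- oriented_roc(labels, scores_1)
  r2 <- oriented_roc(labels, scores_2)
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(a1, a2, tolerance = 1e-12)))
    return(list(auc_1 = a1, auc_2 = a2, delta_auc = 0,
                statistic = 0, p_value = 1))
  dt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  list(auc_1 = a1, auc_2 = a2, delta_auc = a1 - a2,
       statistic = unname(dt$statistic), p_value = dt$p.value)
}

#' Unsupervised phenotype clustering of the 36 phasic parameters
#'
#' Z-score standardizes the feature matrix, runs k-means (multiple seeded
#' restarts) over a range of cluster counts, and selects k by the maximum
#' mean silhouette width. If any cluster holds exactly one subject, that
#' subject is removed as an outlier, features re-standardized and clustering
#' repeated (iterated, with removals logged). A PCA of the standardized
#' features supplies 2-D coordinates and per-component explained variance
#' for visualization.
#'
#' @param features Numeric matrix (subjects x features), complete rows;
#'   zero-variance columns are dropped with a message.
#' @param k_range Candidate cluster counts (subset of `2..n-1`).
#' @param seed Integer seed.
#' @param nstart Random restarts per k-means run.
#' @return List: `k`, `assignments` (named by rownames), `silhouette`
#'   (data frame k vs mean width), `removed` (outlier ids), `centers`
#'   (standardized), `pca` (`coords`, `var_explained`).
#' @export
cluster_phenotypes <- function(features, k_range = 2:6, seed = 1L,
                               nstart = 10) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("feature rows must be complete")
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  if (any(k_range < 2) || any(k_range > nrow(X) - 1))
    stop("k_range must lie within [2, n - 1]")
  removed <- character(0)
  withr::with_seed(seed, {
    repeat {
      sds <- apply(X, 2, stats::sd)
      if (any(sds == 0)) {
        message("dropping ", sum(sds == 0), " zero-variance feature column(s)")
        X <- X[, sds > 0, drop = FALSE]
        if (ncol(X) == 0) stop("degenerate features: all columns constant")
      }
      Z <- scale(X)
      fits <- lapply(k_range, function(k)
        stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100))
      sil <- vapply(seq_along(k_range), function(i)
        mean(cluster::silhouette(fits[[i]]$cluster, stats::dist(Z))[, 3]),
        numeric(1))
      best <- which.max(sil)
      fit <- fits[[best]]
      sizes <- table(fit$cluster)
      lone <- names(sizes)[sizes == 1]
      if (!length(lone)) {
        pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
        ve <- pca$sdev^2 / sum(pca$sdev^2)
        return(list(k = k_range[best],
                    assignments = stats::setNames(fit$cluster, rownames(X)),
                    silhouette = data.frame(k = k_range,
                                            mean_silhouette = sil),
                    removed = removed, centers = fit$centers,
                    pca = list(coords = pca$x[, 1:2, drop = FALSE],
                               var_explained = ve)))
      }
      drop_ids <- rownames(X)[fit$cluster %in% as.integer(lone)]
      message("removing sole-member cluster outlier(s): ",
              paste(drop_ids, collapse = ", "))
      removed <- c(removed, drop_ids)
      X <- X[!rownames(X) %in% drop_ids, , drop = FALSE]
      if (any(k_range > nrow(X) - 1)) k_range <- k_range[k_range <= nrow(X) - 1]
    }
  })
}
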