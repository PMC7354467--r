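# Statistics: correlations against brute force, exact Mann-Whitney, ROC/AUC
# against pair enumeration, logistic risk models, clustering, group summary.

test_that("Pearson R matches the brute-force formula to 1e-12", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(10)
    y <- 2 * x + rnorm(10)
    res <- correlate_modes(matrix(x, ncol = 1), data.frame(d = y))
    expect_equal(res$R, pearson_bruteforce(x, y), tolerance = 1e-12)
  }
})

test_that("exact linear descriptor gives R = 1 with vanishing p", {
  x <- rnorm(20)
  res <- correlate_modes(matrix(x, ncol = 1), data.frame(d = 2 * x + 3))
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
})

test_that("independent descriptor gives small |R| at n = 1000", {
  hits <- sapply(1:20, function(i) {
    set.seed(100 + i)
    x <- rnorm(1000)
    y <- rnorm(1000)
    abs(correlate_modes(matrix(x, ncol = 1), data.frame(d = y))$R) < 0.1
  })
  expect_gte(mean(hits), 0.9)  # ~ 95% expected under the null
})

test_that("zero-variance descriptor is flagged undefined, not an error", {
  res <- correlate_modes(matrix(rnorm(10), ncol = 1), data.frame(d = rep(1, 10)))
  expect_true(res$undefined)
  expect_true(is.na(res$R))
})

test_that("Mann-Whitney U for {1,2} vs {3,4} matches the enumerated 1/3", {
  # 6 equally likely assignments of ranks; only U=0 and the symmetric U=4
  # are as extreme, so the exact two-sided p is 2/6 = 1/3
  res <- compare_groups(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_true(res$exact)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
})

test_that("identical groups give Mann-Whitney p = 1 and chi-square p = 1", {
  res <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 1, tolerance = 1e-9)
  cs <- compare_groups(matrix(c(10, 10, 10, 10), 2), kind = "chi_square")
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)
})

test_that("ROC matches pair-enumeration AUC on worked and random examples", {
  # the 4-point worked example: 3 of 4 positive-negative pairs won
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_pairs(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  # degenerate cases
  expect_equal(roc_curve(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
  # rank-sum oracle equivalence on random fixtures, with ties
  set.seed(77)
  for (rep in 1:10) {
    p <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (sum(y) %in% c(0, 30)) next
    expect_equal(roc_curve(p, y)$auc, auc_pairs(p, y), tolerance = 1e-12)
  }
  # ROC points monotone in both coordinates
  r2 <- roc_curve(runif(50), rbinom(50, 1, 0.5))
  expect_true(all(diff(r2$points$fpr) >= 0))
  expect_true(all(diff(r2$points$tpr) >= 0))
  # AUC invariant under monotone transform of the scores
  p3 <- runif(40); y3 <- rbinom(40, 1, 0.5)
  expect_equal(roc_curve(p3, y3)$auc, roc_curve(qlogis(p3 / 2 + 0.25), y3)$auc)
})

test_that("logistic risk model: separation, null labels, score equations", {
  set.seed(5)
  x <- matrix(rnorm(200), ncol = 1)
  # perfectly separated labels -> AUC 1, ridge guard engages
  y_sep <- x[, 1] > 0
  m <- fit_risk_model(x, y_sep, predictor = "modes_90")
  expect_equal(m$auc, 1)
  expect_true(m$ridge_active)
  # shuffled labels -> AUC near 0.5
  aucs <- sapply(1:20, function(i) {
    set.seed(200 + i)
    fit_risk_model(x, sample(rep(c(TRUE, FALSE), 100)), predictor = "modes_90")$auc
  })
  expect_gte(mean(aucs > 0.4 & aucs < 0.6), 0.9)
  # non-separable fit satisfies the score equations (gradient ~ 0)
  y <- plogis(x[, 1]) > runif(200)
  m2 <- fit_risk_model(x, y, predictor = "modes_90")
  expect_false(m2$ridge_active)
  expect_lt(m2$gradient_norm, 1e-6)
  # AUC equals the rank-sum statistic of the fitted probabilities
  expect_equal(m2$auc, auc_pairs(m2$probabilities, y), tolerance = 1e-12)
  expect_error(fit_risk_model(x, rep(TRUE, 200)), ">= 2 subjects")
})

test_that("k-means on the mode plane separates two blobs and is seeded", {
  set.seed(8)
  X <- rbind(cbind(rnorm(40, 0), rnorm(40, 0)),
             cbind(rnorm(40, 8), rnorm(40, 8)))
  truth <- rep(1:2, each = 40)
  cl <- cluster_scores(X, k = 2, seed = 3)
  agreement <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_gte(agreement, 0.95)
  cl2 <- cluster_scores(X, k = 2, seed = 3)
  expect_identical(cl$labels, cl2$labels)
  # auto-k picks 2 on well-separated blobs
  expect_equal(cluster_scores(X, k = "auto", seed = 3)$k, 2)
  # k = n: every point its own cluster, silhouette flagged degenerate
  small <- X[1:5, ]
  cln <- cluster_scores(small, k = 5, seed = 1)
  expect_true(cln$degenerate)
  expect_true(is.na(cln$silhouette))
  expect_error(cluster_scores(X, k = 200, seed = 1), "exceeds")
})

test_that("group summary stars groups that differ from control", {
  set.seed(12)
  scores <- cbind(c(rnorm(20, 0), rnorm(20, 1.2)), rnorm(40))
  groups <- rep(c("control", "ataa"), each = 20)
  gs <- group_mode_summary(scores, groups)
  expect_true(gs$significant[gs$group == "ataa"])
  expect_false(any(gs$significant[gs$group == "control"]))
  # identical groups: no stars
  scores2 <- cbind(rep(1:20, 2), rnorm(40))
  gs2 <- group_mode_summary(scores2, groups)
  expect_false(any(gs2$significant, na.rm = TRUE))
  # a single control subject still runs (exact small-n test, wide p)
  gs3 <- group_mode_summary(scores[c(1, 21:40), , drop = FALSE],
                            c("control", rep("ataa", 20)))
  expect_true(is.finite(gs3$p_vs_control[gs3$group == "ataa"]))
  expect_error(group_mode_summary(scores, rep("ataa", 40)), "control")
})

test_that("a tortuosity-driving mode correlates with measured tortuosity", {
  # basis with an out-of-plane bending field as mode 2: its weight adds to
  # the template bow, so subject tortuosity tracks the mode-2 weight
  template <- synth_aorta(aorta_spec(axial_resolution = 40,
                                     circumferential_resolution = 20))
  basis <- make_mode_basis(template, types = c("inflate", "bend", "bulge"))
  pop <- make_population(40, c(4, 1.5, 0.75), seed = 19, template = template,
                         mode_basis = basis, perturb = FALSE)
  X <- sample_corresponded(pop$meshes, 800, seed = 20)
  atlas <- fit_pca(X)
  tort <- vapply(pop$meshes, function(m)
    tortuosity(extract_centerline(m, n_stations = 30)), numeric(1))
  res <- correlate_modes(atlas$scores, data.frame(tortuosity = tort),
                         columns = "tortuosity", modes = 2)
  expect_gt(abs(res$R), 0.8)
  expect_lt(res$p, 0.001)
})
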