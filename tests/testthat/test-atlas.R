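# PCA atlas: oracle equivalence, variance accounting, deformation, projection.

make_cloud_array <- function(n, N, seed) {
  set.seed(seed)
  base <- matrix(rnorm(N * 3), N, 3) * 10
  X <- array(NA_real_, c(n, N, 3))
  for (i in seq_len(n)) X[i, , ] <- base + matrix(rnorm(N * 3), N, 3)
  X
}

test_that("rank-1 data put all variance in mode 1", {
  # points sliding along a fixed line segment direction
  N <- 30
  base <- cbind(seq_len(N), 0, 0)
  dirs <- matrix(rep(c(1, 2, -1), each = N), N, 3)
  X <- array(NA_real_, c(5, N, 3))
  for (i in 1:5) X[i, , ] <- base + (i - 3) * dirs
  atlas <- fit_pca(X)
  expect_equal(atlas$variance_fractions[1], 1.0, tolerance = 1e-12)
  expect_equal(length(atlas$eigenvalues), 1L)
})

test_that("SVD path matches the brute-force covariance eigendecomposition", {
  X <- make_cloud_array(10, 50, seed = 17)
  atlas <- fit_pca(X)
  flat <- t(vapply(1:10, function(i) as.vector(t(X[i, , ])), numeric(150)))
  oracle <- pca_bruteforce(flat)
  k <- length(atlas$eigenvalues)
  expect_equal(atlas$eigenvalues, oracle$values[seq_len(k)], tolerance = 1e-8)
  # eigenvectors agree up to sign
  for (j in seq_len(k))
    expect_equal(abs(sum(atlas$modes[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  # reconstruction with all modes reproduces each subject within 1e-6 mm
  for (i in c(1, 5, 10)) {
    rec <- reconstruct_subject(atlas, atlas$scores[i, ])
    expect_lt(max(abs(rec - X[i, , ])), 1e-6)
  }
})

test_that("atlas invariants hold: orthonormal modes, centred scores", {
  X <- make_cloud_array(8, 40, seed = 23)
  atlas <- fit_pca(X)
  G <- crossprod(atlas$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(atlas$eigenvalues) <= 1e-12))
  expect_equal(sum(atlas$variance_fractions), 1, tolerance = 1e-8)
  expect_lt(max(abs(colMeans(atlas$scores))), 1e-8)
})

test_that("variance fractions and retained-mode counts follow the arithmetic", {
  # inject eigenvalues (5,3,1,1) through data built along orthogonal directions
  atlas <- list(variance_fractions = c(5, 3, 1, 1) / 10, degenerate = FALSE)
  class(atlas) <- "shape_atlas"
  expect_equal(modes_for_variance(atlas, 0.90), 3L)
  expect_equal(modes_for_variance(atlas, 1.0), 4L)
  atlas2 <- list(variance_fractions = c(0.95, 0.05), degenerate = FALSE)
  class(atlas2) <- "shape_atlas"
  expect_equal(modes_for_variance(atlas2, 0.90), 1L)
  expect_error(modes_for_variance(atlas2, 0), "in \\(0, 1\\]")
})

test_that("a population of identical clouds is flagged degenerate, not a crash", {
  set.seed(3)
  base <- matrix(rnorm(60), 20, 3)
  X <- array(NA_real_, c(4, 20, 3))
  for (i in 1:4) X[i, , ] <- base
  atlas <- fit_pca(X)
  expect_true(atlas$degenerate)
  expect_error(modes_for_variance(atlas), "degenerate")
})

test_that("template deformation is linear and bounded by the SD warning", {
  X <- make_cloud_array(6, 25, seed = 31)
  atlas <- fit_pca(X)
  d0 <- deform_template(atlas, 1, 0)
  expect_equal(d0$points, atlas$template, tolerance = 1e-12)
  dp <- deform_template(atlas, 1, 2)
  dm <- deform_template(atlas, 1, -2)
  expect_equal((dp$points + dm$points) / 2, atlas$template, tolerance = 1e-9)
  expect_warning(deform_template(atlas, 1, 2.5), "extrapolating")
  expect_error(deform_template(atlas, 99, 1), "mode_k")
})

test_that("a size-mode atlas inflates the mean radius at +2 SD", {
  pop <- make_population(20, c(4, 2, 1), seed = 51, perturb = FALSE)
  N <- nrow(pop$meshes[[1]]$vertices)
  X <- array(NA_real_, c(20, N, 3))
  for (i in 1:20) X[i, , ] <- pop$meshes[[i]]$vertices
  atlas <- fit_pca(X)
  ctr <- colMeans(atlas$template)
  mean_r <- function(p) mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
  expect_gt(mean_r(deform_template(atlas, 1, 2)$points), mean_r(atlas$template))
})

test_that("projection round-trips training subjects and synthetic offsets", {
  X <- make_cloud_array(9, 30, seed = 41)
  atlas <- fit_pca(X)
  # projecting the mean shape gives zero scores
  expect_lt(max(abs(project_subject(atlas, atlas$template))), 1e-9)
  # training subject reproduces its stored score row
  sc <- project_subject(atlas, X[4, , ])
  expect_equal(sc, unname(atlas$scores[4, ]), tolerance = 1e-6)
  # template + 1 SD along mode 2 projects to (0, sqrt(lambda2), 0, ...)
  shifted <- atlas$template +
    matrix(sqrt(atlas$eigenvalues[2]) * atlas$modes[, 2], ncol = 3, byrow = TRUE)
  sc2 <- project_subject(atlas, shifted)
  expected <- rep(0, length(sc2))
  expected[2] <- sqrt(atlas$eigenvalues[2])
  expect_equal(sc2, expected, tolerance = 1e-8)
  expect_error(project_subject(atlas, atlas$template[1:10, ]), "points")
})

test_that("the atlas text bundle round-trips", {
  X <- make_cloud_array(6, 20, seed = 61)
  atlas <- fit_pca(X)
  dir <- tempfile()
  save_atlas(atlas, dir)
  back <- load_atlas(dir)
  expect_equal(back$eigenvalues, atlas$eigenvalues, tolerance = 1e-10)
  expect_equal(back$scores, atlas$scores, tolerance = 1e-10)
  expect_equal(back$template, atlas$template, tolerance = 1e-10)
  expect_equal(back$n_modes_retained_90, atlas$n_modes_retained_90)
})
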