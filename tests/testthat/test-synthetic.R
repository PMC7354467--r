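# Generator contracts: centerline closed forms, tube construction, population
# ground truth, phase pairs, covariate links, determinism.

test_that("centerline hits the requested arc length and closed-form tortuosity", {
  cl <- make_centerline(100, 0, 50, arc_angle_deg = 0)
  expect_equal(tail(cl$arclen, 1), 100, tolerance = 1e-9)
  expect_equal(tortuosity(cl), 0)
  semi <- make_centerline(120, 0, 200, arc_angle_deg = 180)
  expect_equal(tail(semi$arclen, 1), 120, tolerance = 1e-9)
  expect_equal(tortuosity(semi), pi / 2 - 1, tolerance = 2e-3)
  # perturbed curves still meet the 1% arc-length contract
  wig <- make_centerline(100, 5, 80, seed = 3, arc_angle_deg = 100)
  expect_lt(abs(tail(wig$arclen, 1) - 100) / 100, 0.01)
})

test_that("centerline generation is deterministic given (spec, seed)", {
  a <- make_centerline(100, 4, 60, seed = 42)
  b <- make_centerline(100, 4, 60, seed = 42)
  expect_identical(a$points, b$points)
  c3 <- make_centerline(100, 4, 60, seed = 43)
  expect_false(identical(a$points, c3$points))
})

test_that("tube construction: vertex count, diameter, preconditions", {
  cl <- make_centerline(80, 0, 20, arc_angle_deg = 0)
  tube <- make_tube(cl, 12, 16)
  expect_equal(nrow(tube$vertices), 20 * 16)
  cle <- extract_centerline(tube)
  expect_equal(station_diameter(tube, cle, 0.5), 24, tolerance = 24 * 0.01)
  expect_error(make_tube(cl, 12, 7), ">= 8")
  expect_error(make_tube(cl, -1, 16), "positive")
  # radius above the local radius of curvature -> self-intersection error
  bent <- make_centerline(100, 0, 40, arc_angle_deg = 170)  # R ~ 33.7 mm
  expect_error(make_tube(bent, 35, 16), "self-intersect")
})

test_that("a Gaussian bump profile puts the max diameter at its center", {
  cl <- make_centerline(100, 0, 41, arc_angle_deg = 0)
  prof <- function(s) 12 + 5 * exp(-(s - 0.5)^2 / (2 * 0.1^2))
  tube <- make_tube(cl, prof, 24)
  cle <- extract_centerline(tube)
  stations <- seq(0.2, 0.8, by = 0.025)
  d <- vapply(stations, function(s) station_diameter(tube, cle, s), numeric(1))
  expect_equal(stations[which.max(d)], 0.5, tolerance = 0.026)
})

test_that("population ground truth: weight SDs, orthogonality, determinism", {
  pop <- make_population(80, c(4, 2, 1), seed = 21, perturb = FALSE)
  w <- pop$ground_truth$weights
  expect_equal(unname(apply(w, 2, sd)), c(4, 2, 1), tolerance = 1e-9)
  # basis orthogonality (flattened)
  flat <- vapply(pop$ground_truth$basis, function(f) as.vector(t(f)),
                 numeric(3 * nrow(pop$meshes[[1]]$vertices)))
  G <- crossprod(flat)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6 * max(diag(G)))
  # determinism
  pop2 <- make_population(80, c(4, 2, 1), seed = 21, perturb = FALSE)
  expect_identical(pop2$meshes[[5]]$vertices, pop$meshes[[5]]$vertices)
  # a non-orthogonal basis errors with the dot products
  basis <- pop$ground_truth$basis
  basis[[2]] <- basis[[1]] + 0.5 * basis[[2]]
  expect_error(make_population(5, c(4, 2, 1), seed = 1,
                               template = pop$ground_truth$template,
                               mode_basis = basis), "not orthogonal")
  # non-decreasing SDs rejected
  expect_error(make_population(5, c(2, 4, 1), seed = 1), "decreasing")
})

test_that("degenerate populations behave: n = 1 and all-zero SDs", {
  pop1 <- make_population(1, c(4, 2, 1), seed = 2)
  expect_length(pop1$meshes, 1L)
  pop0 <- make_population(4, c(0, 0, 0), seed = 2, perturb = FALSE)
  v1 <- pop0$meshes[[1]]$vertices
  for (m in pop0$meshes[-1]) expect_equal(m$vertices, v1)
})

test_that("rigid perturbations stay within the configured bounds", {
  pop <- make_population(25, c(4, 2, 1), seed = 9,
                         max_rotation = 30, max_translation = 50)
  for (tf in pop$ground_truth$transforms) {
    expect_lte(rotation_angle(tf), 30 + 1e-9)
    expect_lte(max(abs(tf$translation)), 50 + 1e-9)
  }
})

test_that("covariates: logistic link, prevalence, determinism, limits", {
  pop <- make_population(200, c(4, 2, 1), seed = 31, perturb = FALSE)
  # beta = 0: prevalence within the binomial 95% interval of sigmoid(b0)
  cov0 <- make_covariates(pop, logistic_beta = c(-1, 0, 0, 0), seed = 7,
                          measure = FALSE)
  p0 <- plogis(-1)
  expect_lt(abs(mean(cov0$surgery) - p0), 1.96 * sqrt(p0 * (1 - p0) / 200))
  # strongly separating beta: labels deterministic in the sign of beta . w
  covs <- make_covariates(pop, logistic_beta = c(0, 1000, 0, 0), seed = 7,
                          measure = FALSE)
  z1 <- pop$ground_truth$weights[, 1]
  expect_equal(unname(covs$surgery), unname(z1 > 0))
  # same seed -> identical labels
  cov_a <- make_covariates(pop, seed = 3, measure = FALSE)
  cov_b <- make_covariates(pop, seed = 3, measure = FALSE)
  expect_identical(cov_a$surgery, cov_b$surgery)
  expect_identical(cov_a$valve, cov_b$valve)
})

test_that("measured covariate descriptors come from the meshes", {
  pop <- make_population(5, c(4, 2, 1), seed = 41)
  covs <- make_covariates(pop, seed = 1)
  # diameters positive and within plausible tube range; vary across subjects
  expect_true(all(covs$diameter_midaa > 20 & covs$diameter_midaa < 80))
  expect_gt(sd(covs$diameter_midaa), 0)
  expect_true(all(covs$tortuosity > 0))
})

test_that("phase pairs carry exact ground-truth strain", {
  mesh <- synth_aorta(aorta_spec(axial_resolution = 30,
                                 circumferential_resolution = 16))
  pair <- make_phase_pair(mesh, function(s) 0.1 * s)
  expect_equal(pair$true_strain, 0.1 * pair$station, tolerance = 1e-12)
  expect_error(make_phase_pair(mesh, function(s) s - 0.5), ">= 0")
})

test_that("simulate_cohort merges controls with smaller size mode", {
  sim <- simulate_cohort(n_ataa = 12, n_control = 6, seed = 5, measure = FALSE,
                         perturb = FALSE)
  expect_equal(sum(sim$cohort$group == "control"), 6L)
  expect_false(any(sim$cohort$surgery[sim$cohort$group == "control"]))
  w <- sim$ground_truth$weights
  ctrl <- grepl("^C", rownames(w))
  expect_lt(mean(w[ctrl, 1]), mean(w[!ctrl, 1]))
})

test_that("a written synthetic cohort can be read back", {
  sim <- simulate_cohort(n_ataa = 4, seed = 2, measure = FALSE, perturb = FALSE,
                         spec = aorta_spec(axial_resolution = 12,
                                           circumferential_resolution = 10))
  dir <- tempfile()
  write_synthetic_cohort(sim, dir)
  tab <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 4L)
  m <- read_mesh(file.path(dir, tab$mesh_path[1]))
  expect_equal(nrow(m$vertices), 120)
  gt <- read.csv(file.path(dir, "ground_truth_weights.csv"))
  expect_equal(gt$subject_id, tab$subject_id)
})
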