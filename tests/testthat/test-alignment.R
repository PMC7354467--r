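# ICP registration, reference selection, correspondence, template build.

test_that("ICP on identical clouds returns the identity with zero RMSD", {
  pc <- resample_surface(synth_aorta(), 600, seed = 2)
  fit <- icp_rigid(pc, pc)
  expect_lt(fit$rmsd, 1e-10)
  expect_lt(rotation_angle(fit$transform), 1e-6)
  expect_lt(max(abs(fit$transform$translation)), 1e-8)
})

test_that("ICP recovers known rigid transforms to 0.1 deg / 0.01 mm", {
  pc <- resample_surface(synth_aorta(), 800, seed = 3)
  for (i in 1:5) {
    tf <- random_rigid(30, 50, seed = 100 + i)
    moved <- apply_rigid(tf, pc)
    fit <- icp_rigid(pc, moved)
    expect_lt(rotation_angle(t(tf$rotation) %*% fit$transform$rotation), 0.1)
    expect_lt(sqrt(sum((fit$transform$translation - tf$translation)^2)), 0.01)
    expect_true(all(diff(fit$history) <= 1e-9))  # RMSD non-increasing
  }
})

test_that("degenerate clouds are rejected", {
  pc <- resample_surface(synth_aorta(), 500, seed = 1)
  expect_error(icp_rigid(matrix(rnorm(6), 2, 3), pc), ">= 3")
  line <- cbind(1:10, 0, 0)
  expect_error(icp_rigid(line, pc), "collinear")
})

test_that("initial reference is the subject nearest the mean diameter", {
  df <- base_cohort_df(3)
  df$diameter_midaa <- c(40, 44, 48)   # mean 44 -> exact member
  expect_equal(select_initial_reference(as_cohort_table(df)), "P02")
  df$diameter_midaa <- c(40, 45, 49)   # mean 44.67 -> 45
  expect_equal(select_initial_reference(as_cohort_table(df)), "P02")
  df2 <- base_cohort_df(2)
  df2$diameter_midaa <- c(45, 43)      # tie around 44 -> lexicographic first
  expect_equal(select_initial_reference(as_cohort_table(df2)), "P01")
  df2$diameter_midaa[1] <- NA
  expect_error(select_initial_reference(as_cohort_table(df2)), "P01")
})

test_that("correspondence is identity on self and tracks a radial offset", {
  cyl <- make_cylinder(radius = 10, length = 60, n_axial = 20, n_circ = 24)
  pc <- resample_surface(cyl, 800, seed = 4)
  expect_equal(correspond(pc$points, pc$points), pc$points)
  # subject = template under a permutation -> displacement ~ 0
  perm <- sample(nrow(pc$points))
  expect_equal(correspond(pc$points, pc$points[perm, ]), pc$points)
  # uniform radial offset of 1 mm on the cylinder: correspondence distances ~ 1
  out <- pc$points
  rad <- out[, 2:3] / sqrt(rowSums(out[, 2:3]^2))
  out[, 2:3] <- out[, 2:3] + rad
  d <- sqrt(rowSums((correspond(pc$points, out) - pc$points)^2))
  expect_equal(median(d), 1, tolerance = 0.25)
})

test_that("template build recovers the common shape from rigid copies", {
  pc <- resample_surface(synth_aorta(), 700, seed = 5)
  clouds <- lapply(1:8, function(i)
    apply_rigid(random_rigid(30, 50, seed = 300 + i), pc))
  tb <- build_template(clouds)
  expect_true(tb$converged)
  # gauge-fix the template onto the original cloud and compare
  g <- aortashape:::kabsch(tb$template, pc$points)
  back <- apply_rigid(g, tb$template)
  expect_lt(sqrt(mean(rowSums((back - pc$points)^2))), 0.01)
})

test_that("max_rounds = 1 returns an unconverged template with the flag set", {
  pop <- make_population(5, c(4, 2, 1), seed = 6)
  clouds <- lapply(pop$meshes, resample_surface, n_points = 400, seed = 2)
  tb <- build_template(clouds, max_rounds = 1)
  expect_false(tb$converged)
  expect_equal(tb$iteration_count, 1L)
})

test_that("two clouds build a midpoint template with a small-n message", {
  pc <- resample_surface(synth_aorta(), 400, seed = 7)
  clouds <- list(pc, apply_rigid(random_rigid(10, 10, seed = 1), pc))
  expect_message(tb <- build_template(clouds), "2 subjects")
  expect_equal(nrow(tb$template), 400)
})

test_that("mismatched point counts across clouds are rejected", {
  m <- synth_aorta()
  clouds <- list(resample_surface(m, 400, seed = 1),
                 resample_surface(m, 500, seed = 1),
                 resample_surface(m, 400, seed = 2))
  expect_error(build_template(clouds), "mismatched point counts")
})

test_that("template build is equivariant under a common rigid transform", {
  pop <- make_population(6, c(4, 2, 1), seed = 8, perturb = FALSE)
  clouds <- lapply(pop$meshes, resample_surface, n_points = 500, seed = 3)
  tb1 <- build_template(clouds, max_rounds = 3)
  tf <- random_rigid(20, 30, seed = 12)
  tb2 <- build_template(lapply(clouds, function(c) apply_rigid(tf, c)),
                        max_rounds = 3)
  g <- aortashape:::kabsch(tb2$template, tb1$template)
  aligned <- apply_rigid(g, tb2$template)
  expect_lt(sqrt(mean(rowSums((aligned - tb1$template)^2))), 0.05)
})
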