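# Strain pipeline: analytic concentric-sphere oracle, generator phase pairs,
# centerline extraction, rigid invariance.

test_that("concentric spheres 10 -> 11 mm give strain 0.100 within 1e-3 relative", {
  dia <- make_uv_sphere(r = 10, n_lat = 200, n_lon = 400)
  sys <- make_uv_sphere(r = 11, n_lat = 200, n_lon = 400)
  pc <- resample_surface(dia, 300, seed = 6)
  disp <- displacement_field(pc, sys, cutoff = 30)
  expect_equal(disp$n_fallback, 0L)
  sf <- strain_field(disp, c(0, 0, 0))
  expect_lt(max(abs(sf$strain - 0.1)) / 0.1, 1e-3)
})

test_that("identical phases give zero displacement and zero strain", {
  mesh <- synth_aorta(aorta_spec(axial_resolution = 30,
                                 circumferential_resolution = 16))
  pc <- resample_surface(mesh, 400, seed = 3)
  disp <- displacement_field(pc, mesh, centerline = mesh$centerline)
  expect_lt(max(disp$displacement), 1e-9)
  sf <- strain_field(disp, mesh$centerline)
  expect_lt(max(abs(sf$strain), na.rm = TRUE), 1e-9)
})

test_that("generator phase pair recovers a Gaussian strain peak of 0.15", {
  spec <- aorta_spec(axial_resolution = 60, circumferential_resolution = 32)
  mesh <- synth_aorta(spec)
  profile <- function(s) 0.15 * exp(-(s - 0.5)^2 / (2 * 0.1^2))
  pair <- make_phase_pair(mesh, profile)
  # construction: true strain max is 0.15 at mid-tube
  expect_equal(max(pair$true_strain), 0.15, tolerance = 0.01)
  expect_equal(pair$station[which.max(pair$true_strain)], 0.5, tolerance = 0.02)

  pc <- resample_surface(pair$diastole, 2000, seed = 9)
  disp <- displacement_field(pc, pair$systole, centerline = mesh$centerline)
  cl <- extract_centerline(pair$diastole)
  sf <- strain_field(disp, cl)
  peak <- strain_at_station(sf, c(0.35, 0.65))
  expect_lt(abs(peak$peak - 0.15), 0.0075)
  expect_lt(abs(peak$peak_station - 0.5), 0.05)
  # displacement equals true strain x local radius within a few percent
  loc <- aortashape:::local_radius(pc$points, mesh$centerline)
  expected_disp <- profile(loc$station) * loc$radius
  ok <- expected_disp > 0.5
  expect_lt(median(abs(disp$displacement[ok] - expected_disp[ok]) /
                     expected_disp[ok]), 0.03)
})

test_that("uniform phase pair: cylinder radius 10 with strain 0.1 reaches 11", {
  cyl <- make_cylinder(radius = 10, length = 60, n_axial = 30, n_circ = 32)
  pair <- make_phase_pair(cyl, 0.1)
  r_sys <- aortashape:::local_radius(pair$systole$vertices, cyl$centerline)$radius
  expect_equal(unname(range(r_sys)), c(11, 11), tolerance = 1e-4)
  # zero profile leaves the mesh untouched
  pair0 <- make_phase_pair(cyl, 0)
  expect_equal(pair0$systole$vertices, cyl$vertices)
})

test_that("strain summary windows behave and reject bad input", {
  sf <- strain_field(rep(1, 5), centerline(cbind(0:10, 0, 0)),
                     points = cbind(seq(1, 9, 2), 5, 0))
  out <- strain_at_station(sf, c(0, 1))
  expect_equal(out$mean, out$peak, tolerance = 1e-5)
  expect_error(strain_at_station(sf, c(0.9, 0.8)), "lo < hi|must be")
  expect_error(strain_at_station(sf, c(0.98, 0.99)), "no valid strain points")
})

test_that("points with sub-floor baseline radius are flagged invalid", {
  pts <- rbind(c(0, 0.05, 0), c(0, 5, 0))
  sf <- strain_field(c(1, 1), centerline(cbind(-5:5, 0, 0)), points = pts)
  expect_false(sf$valid[1])
  expect_true(sf$valid[2])
  expect_true(is.na(sf$strain[1]))
})

test_that("strain is invariant under a common rigid transform of both phases", {
  spec <- aorta_spec(axial_resolution = 40, circumferential_resolution = 24)
  mesh <- synth_aorta(spec)
  pair <- make_phase_pair(mesh, function(s) 0.08 + 0.04 * s)
  pc <- resample_surface(pair$diastole, 800, seed = 13)
  cl <- extract_centerline(pair$diastole)
  sf1 <- strain_field(displacement_field(pc, pair$systole, centerline = cl), cl)

  tf <- random_rigid(25, 40, seed = 21)
  pc2 <- apply_rigid(tf, pc)
  sys2 <- apply_rigid(tf, pair$systole)
  cl2 <- centerline(apply_rigid(tf, cl$points))
  sf2 <- strain_field(displacement_field(pc2, sys2, centerline = cl2), cl2)
  expect_equal(sf2$strain, sf1$strain, tolerance = 1e-6)
})

test_that("centerline extraction is accurate and rejects bad topology", {
  # straight cylinder: collinear with the axis
  cyl <- make_cylinder(radius = 10, length = 80, n_axial = 30, n_circ = 24)
  cl <- extract_centerline(cyl)
  off_axis <- sqrt(rowSums(cl$points[, 2:3, drop = FALSE]^2))
  expect_lt(max(off_axis), 0.1 * 10)  # < 1% of radius would be 0.1 mm; allow 1 mm
  # curved constant-radius generator tube: Hausdorff within 2% of radius
  hausdorff <- function(mesh) {
    cl_est <- extract_centerline(mesh, n_stations = 60)
    a <- aortashape:::densify_centerline(mesh$centerline, 500)$points
    b <- aortashape:::densify_centerline(cl_est, 500)$points
    max(max(aortashape:::nn1(a, b)$dist), max(aortashape:::nn1(b, a)$dist))
  }
  bent <- make_tube(make_centerline(100, 0, 60, arc_angle_deg = 100,
                                    nonplanarity = 6), 15, 32)
  expect_lt(hausdorff(bent), 0.02 * 15)
  # steep radius features (sinus waist-bulge) distort the harmonic
  # coordinate locally; accuracy degrades but stays well under a millimetre
  mesh <- synth_aorta(aorta_spec(axial_resolution = 60,
                                 circumferential_resolution = 32))
  expect_lt(hausdorff(mesh), 1)
  # sphere: no boundary -> topology error
  expect_error(extract_centerline(make_uv_sphere(r = 5, n_lat = 12, n_lon = 16)),
               "closed surface|boundary")
})
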