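test_that("phantom construction is deterministic and well-formed", {
  pp <- phantom_params(mesh_resolution = 700, seed = 42)
  a <- generate_phantom(pp)
  b <- generate_phantom(pp)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  # closed genus-0 surface
  expect_equal(euler_characteristic(a$mesh), 2L)
  expect_gt(mesh_volume(a$mesh), 0)
  # RS above DSN; landmarks are exact vertices
  expect_gt(unclass(a$landmarks)["RS", 3], unclass(a$landmarks)["DSN", 3])
  for (nm in c("RS", "DSN", "DDR")) {
    d <- nn_dist(matrix(unclass(a$landmarks)[nm, ], 1, 3), a$mesh$vertices)
    expect_lt(d, 1e-12)
  }
  expect_error(phantom_params(mesh_resolution = 100), "mesh_resolution")
})

test_that("degenerate parameters give a plain tapered cylinder", {
  pp <- phantom_params(flare_scale = 1, styloid_height = 0, notch_depth = 0,
                       mesh_resolution = 900, seed = 1)
  ph <- generate_phantom(pp)
  r <- sqrt(rowSums(ph$mesh$vertices[, 1:2]^2))
  expect_lt(max(r), pp$shaft_radius * 1.2 * 1.02) # superellipse a = 1.15
})

test_that("a = 0 pairs are exact rigidly-moved mirrors", {
  pp <- phantom_params(mesh_resolution = 700, seed = 3)
  pr <- generate_pair(pp, asymmetry_mm = 0, seed = 9)
  expect_equal(pr$ground_truth$mean_mm, 0)
  # undo the poses: right must equal the mirrored left exactly
  l0 <- apply_transform(invert_transform(pr$poses$left), pr$left$mesh)
  r0 <- apply_transform(invert_transform(pr$poses$right), pr$right$mesh)
  lm <- mirror_x(l0)$mesh
  expect_equal(r0$vertices, lm$vertices, tolerance = 1e-9)
})

test_that("injected asymmetry has the requested mean magnitude and smoothness", {
  pp <- phantom_params(mesh_resolution = 700, seed = 3)
  pr <- generate_pair(pp, asymmetry_mm = 0.6, seed = 13)
  expect_lt(abs(pr$ground_truth$mean_mm - 0.6) / 0.6, 0.05)
  # analytic RBF Lipschitz bound on the scalar amplitude:
  # |grad k| peaks at sqrt(2/e)/sigma for k = exp(-d^2/sigma^2)
  r0 <- apply_transform(invert_transform(pr$poses$right), pr$right$mesh)
  verts <- r0$vertices - 0 # displaced vertices (pose removed)
  amp <- pr$ground_truth$magnitude
  sig <- pp$asymmetry_smoothness
  # empirical gradient between nearby vertices vs analytic bound
  e <- mesh_edges(r0)
  dv <- sqrt(rowSums((verts[e[, 1], ] - verts[e[, 2], ])^2))
  da <- abs(amp[e[, 1]] - amp[e[, 2]])
  # bound: sum|w_i| * sqrt(2/e) / sigma; mean|amp| = 0.6 over ~unit-mass
  # kernel mixtures keeps sum|w| within a small factor of the amplitude scale
  emp <- max(da / pmax(dv, 1e-9))
  expect_lt(emp, 10 * 0.6 / sig)
})

test_that("cohort generation follows the 4 x n design with ground truth", {
  pp <- phantom_params(mesh_resolution = 600, seed = 5, individual_sd = 0.5)
  co <- generate_cohort(n_per_group = 2, params = pp, seed = 77)
  expect_equal(nrow(co$metadata), 8)
  expect_equal(as.integer(table(co$metadata$group)), rep(2L, 4))
  expect_true(all(co$metadata$sex %in% c("M", "F")))
  expect_true(all(co$metadata$true_asymmetry_mm >= 0.3 - 0.05 &
                    co$metadata$true_asymmetry_mm <= 0.8 + 0.05))
  # determinism
  co2 <- generate_cohort(n_per_group = 2, params = pp, seed = 77)
  expect_identical(co$subjects[[1]]$left$mesh$vertices,
                   co2$subjects[[1]]$left$mesh$vertices)
  expect_identical(co$metadata$true_asymmetry_mm, co2$metadata$true_asymmetry_mm)
})

test_that("cohort directories round-trip", {
  pp <- phantom_params(mesh_resolution = 600, seed = 5)
  co <- generate_cohort(n_per_group = 1, params = pp, seed = 78)
  dir <- file.path(tempdir(), "cohort_roundtrip")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$metadata), 4)
  id <- co$metadata$subject[1]
  expect_equal(back$subjects[[id]]$left$mesh$vertices,
               co$subjects[[id]]$left$mesh$vertices, tolerance = 1e-6)
  expect_equal(back$subjects[[id]]$ground_truth$mean_mm,
               co$subjects[[id]]$ground_truth$mean_mm, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
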