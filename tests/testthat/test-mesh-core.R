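test_that("mesh constructor enforces the structural invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(surface_mesh(v, rbind(c(1, 2, 3))), "surface_mesh")
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "repeated vertex")
  expect_error(surface_mesh(rbind(v, c(2, 2, 2)), rbind(c(1, 2, 3))), "isolated")
  expect_error(surface_mesh(v, matrix(integer(0), 0, 3)), "zero faces")
})

test_that("mesh I/O round-trips exactly across all three formats", {
  tet <- fixture_tetrahedron()
  # single-triangle round trip through each writer/reader
  tri <- surface_mesh(rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 3.25, 1)),
                      rbind(c(1, 2, 3)))
  for (fmt in c("vtk", "ply", "stl")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_mesh(tri, p)
    back <- read_mesh(p)
    expect_equal(back$vertices, tri$vertices, tolerance = 1e-6)
    expect_equal(nrow(back$faces), 1L)
  }
  # tetrahedron: 4 vertices, 4 faces
  p <- tempfile(fileext = ".vtk")
  write_mesh(tet, p)
  back <- read_mesh(p)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$faces), 4L)
  # phantom through all three formats: max vertex discrepancy < 1e-5 mm
  ph <- fixture_phantom()$mesh
  for (fmt in c("vtk", "ply", "stl")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_mesh(ph, p)
    back <- read_mesh(p)
    expect_equal(nrow(back$vertices), nrow(ph$vertices))
    # stl reorders vertices on weld; compare via nearest neighbour
    d <- nn_dist(back$vertices, ph$vertices)
    expect_lt(max(d), 1e-5)
  }
  # binary STL path
  p <- tempfile(fileext = ".stl")
  write_mesh(ph, p, binary = TRUE)
  back <- read_mesh(p)
  expect_lt(max(nn_dist(back$vertices, ph$vertices)), 1e-4) # float32 storage
  expect_error(read_mesh(tempfile(fileext = ".vtk")), "no such file")
})

test_that("VTK files carry point scalars for surface colouring", {
  ph <- fixture_phantom()$mesh
  d <- ph$vertices[, 3] / 10
  p <- tempfile(fileext = ".vtk")
  write_mesh(ph, p, point_scalars = list(signed_distance_mm = d))
  back <- read_mesh(p)
  sc <- attr(back, "point_scalars")
  expect_named(sc, "signed_distance_mm")
  expect_equal(sc$signed_distance_mm, d, tolerance = 1e-6)
})

test_that("mirroring negates x, preserves volume and is an involution", {
  ph <- fixture_phantom()
  m1 <- mirror_x(ph$mesh, ph$landmarks)
  expect_equal(m1$mesh$vertices[, 1], -ph$mesh$vertices[, 1])
  expect_equal(m1$mesh$vertices[, 2:3], ph$mesh$vertices[, 2:3])
  expect_equal(unclass(m1$landmarks)["RS", 1], -unclass(ph$landmarks)["RS", 1])
  # winding fixed: signed volume unchanged
  expect_equal(mesh_volume(m1$mesh), mesh_volume(ph$mesh), tolerance = 1e-12)
  m2 <- mirror_x(m1$mesh, m1$landmarks)
  expect_identical(m2$mesh$vertices, ph$mesh$vertices)
  expect_identical(m2$mesh$faces, ph$mesh$faces)
})

test_that("principal-axis alignment puts the articular end toward +z", {
  ph <- fixture_phantom()
  # aligning an already-aligned mesh again gives the identity rotation
  al0 <- principal_axis_align(ph$mesh, ph$landmarks)
  al00 <- principal_axis_align(al0$mesh, al0$landmarks)
  ang <- acos(min(1, (sum(diag(al00$transform$rotation)) - 1) / 2))
  expect_lt(ang, 1e-6)
  set.seed(7)
  for (i in 1:5) {
    tr <- random_rigid()
    m <- apply_transform(tr, ph$mesh)
    lm <- apply_transform(tr, ph$landmarks)
    al <- principal_axis_align(m, lm)
    ev <- eigen(stats::cov(al$mesh$vertices), symmetric = TRUE)
    expect_gt(abs(ev$vectors[3, 1]), 0.9999)
    # RS (articular end) above the centroid
    expect_gt(unclass(al$landmarks)["RS", 3], mean(al$mesh$vertices[, 3]))
  }
  # rigidity: pairwise distances preserved
  d0 <- as.numeric(stats::dist(ph$mesh$vertices[1:50, ]))
  d1 <- as.numeric(stats::dist(al0$mesh$vertices[1:50, ]))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("shift_lowest_to_origin is exact and idempotent", {
  ph <- fixture_phantom()
  s1 <- shift_lowest_to_origin(ph$mesh, ph$landmarks)
  i <- which.min(s1$mesh$vertices[, 3])
  expect_equal(as.numeric(s1$mesh$vertices[i, ]), c(0, 0, 0), tolerance = 1e-12)
  s2 <- shift_lowest_to_origin(s1$mesh, s1$landmarks)
  expect_equal(s2$mesh$vertices, s1$mesh$vertices, tolerance = 1e-12)
  # landmark-vertex offsets preserved
  off1 <- unclass(s1$landmarks)["RS", ] - s1$mesh$vertices[1, ]
  off0 <- unclass(ph$landmarks)["RS", ] - ph$mesh$vertices[1, ]
  expect_equal(off1, off0, tolerance = 1e-12)
})

test_that("plane crops clip exactly and match the half-space predicate", {
  ph <- fixture_phantom()$mesh
  zmax <- max(ph$vertices[, 3])
  cr <- crop_by_plane(ph, c(0, 0, zmax - 20), c(0, 0, 1), keep = "above")
  expect_gte(min(cr$vertices[, 3]), zmax - 20 - 1e-9)
  cr2 <- crop_by_plane(ph, c(0, 0, 50), c(0, 0, 1), keep = "below")
  expect_lte(max(cr2$vertices[, 3]), 50 + 1e-9)
  # no-op when the plane clears the mesh
  cr3 <- crop_by_plane(ph, c(0, 0, zmax + 10), c(0, 0, 1), keep = "below")
  expect_equal(nrow(cr3$vertices), nrow(ph$vertices))
  # retained original vertices equal brute-force filter (1e-6 slack for
  # floating-point cancellation in the blocked distance computation)
  keep_oracle <- which(ph$vertices[, 3] >= zmax - 20)
  orig_kept <- cr$vertices[nn_dist(cr$vertices, ph$vertices[keep_oracle, , drop = FALSE]) < 1e-6, ]
  expect_gte(nrow(orig_kept), length(keep_oracle))
  expect_error(crop_by_plane(ph, c(0, 0, zmax + 1), c(0, 0, 1), keep = "above"),
               "whole mesh")
})

test_that("clipped sphere cap area matches the closed form", {
  sp <- icosphere(10, 4)
  h <- 4 # cap height above z = 6
  cap <- crop_by_plane(sp, c(0, 0, 10 - h), c(0, 0, 1), keep = "above")
  expect_lt(abs(mesh_area(cap) - 2 * pi * 10 * h) / (2 * pi * 10 * h), 0.02)
})

test_that("Kabsch alignment recovers known transforms and rejects reflections", {
  set.seed(11)
  pts <- matrix(stats::rnorm(30), 10, 3)
  # identity
  id <- rigid_align_landmarks(pts, pts)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
  # compose-and-compare
  for (i in 1:10) {
    tr <- random_rigid()
    rec <- rigid_align_landmarks(pts, apply_transform(tr, pts))
    expect_equal(rec$rotation, tr$rotation, tolerance = 1e-9)
    expect_equal(rec$translation, tr$translation, tolerance = 1e-9)
  }
  # mirrored target still yields a proper rotation
  mpts <- pts
  mpts[, 1] <- -mpts[, 1]
  rec <- rigid_align_landmarks(pts, mpts)
  expect_gt(det(rec$rotation), 0.999)
  expect_error(rigid_align_landmarks(cbind(1:5, 0, 0), cbind(2:6, 0, 0)),
               "collinear")
})

test_that("Kabsch residual beats 1000 random proper rigid transforms", {
  set.seed(13)
  src <- matrix(stats::rnorm(24), 8, 3)
  tgt <- apply_transform(random_rigid(), src) + matrix(stats::rnorm(24, sd = 0.1), 8, 3)
  best <- rigid_align_landmarks(src, tgt)
  res <- function(tr) sum((apply_transform(tr, src) - tgt)^2)
  r0 <- res(best)
  rs <- replicate(1000, res(random_rigid()))
  expect_true(all(r0 <= rs + 1e-12))
})

test_that("rigid transform group laws hold", {
  set.seed(17)
  a <- random_rigid()
  b <- random_rigid()
  x <- matrix(stats::rnorm(15), 5, 3)
  expect_equal(apply_transform(compose_transforms(a, b), x),
               apply_transform(b, apply_transform(a, x)), tolerance = 1e-12)
  expect_equal(apply_transform(compose_transforms(a, invert_transform(a)), x),
               x, tolerance = 1e-9)
})

test_that("articular isolation equals the brute-force DSN-plane filter", {
  ph <- fixture_phantom()
  al <- principal_axis_align(ph$mesh, ph$landmarks)
  m <- al$mesh
  lm <- al$landmarks
  art <- isolate_articular_surface(m, lm)
  zdsn <- unclass(lm)["DSN", 3]
  expect_true(all(art$vertices[, 3] >= zdsn - 1e-9))
  # predicate-scan oracle: every retained vertex is an original passing vertex
  mask <- articular_mask(m, lm)
  expect_identical(mask, m$vertices[, 3] >= zdsn - 1e-9)
  expect_lte(nrow(art$vertices), sum(mask))
  # DSN at the minimum z returns the whole mesh
  lm2 <- landmark_set(rbind(RS = unclass(lm)["RS", ],
                            DSN = c(0, 0, min(m$vertices[, 3]) - 1e-6)))
  expect_equal(nrow(isolate_articular_surface(m, lm2)$vertices),
               nrow(m$vertices))
  lm3 <- landmark_set(rbind(RS = unclass(lm)["RS", ],
                            DSN = c(0, 0, max(m$vertices[, 3]) + 1)))
  expect_error(isolate_articular_surface(m, lm3), "empty articular")
})

test_that("decimation hits the vertex budget and preserves geometry", {
  ph <- generate_phantom(phantom_params(mesh_resolution = 4000, seed = 9))$mesh
  dec <- decimate(ph, 1000)
  expect_lte(abs(nrow(dec$vertices) - 1000) / 1000, 0.02)
  expect_lt(hausdorff_surface_distance(dec, ph), 2 * mean_edge_length(ph))
  # no-op at or above current count
  expect_identical(decimate(ph, nrow(ph$vertices)), ph)
  expect_warning(dec2 <- decimate(ph, nrow(ph$vertices) + 50), "unchanged")
  # decimated sphere stays within 0.5 mm radial error
  sp <- icosphere(10, 4)
  spd <- decimate(sp, 1200)
  expect_lt(max(abs(sqrt(rowSums(spd$vertices^2)) - 10)), 0.5)
})

test_that("landmark validation flags missing names and outliers", {
  ph <- fixture_phantom()
  expect_silent(validate_landmarks(ph$landmarks, ph$mesh, require_ddr = TRUE))
  lm <- landmark_set(rbind(RS = c(0, 0, 0)))
  expect_error(validate_landmarks(lm, ph$mesh), "DSN")
  far <- landmark_set(rbind(RS = c(500, 0, 0), DSN = c(0, 0, 0)))
  expect_error(validate_landmarks(far, ph$mesh), "bounding box")
})

test_that("landmark files round-trip through CSV and JSON", {
  lm <- fixture_phantom()$landmarks
  for (ext in c(".csv", ".json")) {
    p <- tempfile(fileext = ext)
    write_landmarks(lm, p)
    back <- read_landmarks(p)
    expect_equal(unclass(back), unclass(lm), tolerance = 1e-9)
  }
})
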