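test_that("atlas of identical targets keeps momenta near zero", {
  small <- decimate(fixture_phantom()$mesh, 150)
  at <- deterministic_atlas(small, list(small, small),
                            deformation_params(max_iterations = 5,
                                               control_spacing = 8))
  expect_length(at$momenta, 2)
  for (m in at$momenta) expect_lt(max(abs(m)), 1e-8)
  expect_equal(at$template$vertices, small$vertices)
})

test_that("atlas momenta have the contracted shape with a frozen template", {
  small <- decimate(fixture_phantom()$mesh, 120)
  t1 <- small; t1$vertices <- sweep(t1$vertices, 2, c(0.3, 0, 0), "+")
  t2 <- small; t2$vertices <- sweep(t2$vertices, 2, c(-0.2, 0.1, 0), "+")
  t3 <- small; t3$vertices <- sweep(t3$vertices, 2, c(0, 0.25, 0), "+")
  p <- deformation_params(max_iterations = 10, control_spacing = 9)
  at <- deterministic_atlas(small, list(t1, t2, t3), p)
  K <- nrow(at$control_points)
  expect_length(at$momenta, 3)
  for (m in at$momenta) expect_identical(dim(m), c(K, 3L))
  expect_length(at$registrations, 3)
})

test_that("free template stays at the midpoint of symmetric targets", {
  sp <- icosphere(1.5, 1)
  delta <- 0.4
  up <- sp; up$vertices <- sweep(up$vertices, 2, c(delta, 0, 0), "+")
  dn <- sp; dn$vertices <- sweep(dn$vertices, 2, c(-delta, 0, 0), "+")
  p <- deformation_params(max_iterations = 40, freeze_template = FALSE)
  at <- deterministic_atlas(sp, list(up, dn), p)
  drift <- sqrt(rowSums((at$template$vertices - sp$vertices)^2))
  expect_lt(mean(drift), 0.1 * delta)
})

test_that("build_mean_shape averages vertices elementwise", {
  small <- decimate(fixture_phantom()$mesh, 120)
  m1 <- small; m1$vertices <- m1$vertices + 1
  m2 <- small; m2$vertices <- m2$vertices - 1
  mean_m <- build_mean_shape(list(m1, m2))
  expect_equal(mean_m$vertices, small$vertices, tolerance = 1e-12)
  # identical inputs: identity
  expect_equal(build_mean_shape(list(small, small))$vertices, small$vertices)
  # brute-force elementwise oracle on 10 perturbed copies
  set.seed(41)
  copies <- lapply(1:10, function(i) {
    m <- small
    m$vertices <- m$vertices + matrix(stats::rnorm(length(m$vertices), sd = 0.3),
                                      ncol = 3)
    m
  })
  oracle <- Reduce(`+`, lapply(copies, `[[`, "vertices")) / 10
  expect_equal(build_mean_shape(copies)$vertices, oracle, tolerance = 1e-12)
  bad <- decimate(small, 80)
  expect_error(build_mean_shape(list(small, bad)), "correspondence")
})

test_that("mean_landmarks averages per name and checks presence", {
  a <- landmark_set(rbind(RS = c(1, 0, 40), DSN = c(0, 2, 37)))
  b <- landmark_set(rbind(RS = c(3, 0, 42), DSN = c(0, 4, 39)))
  m <- mean_landmarks(list(a, b))
  expect_equal(unname(unclass(m)["DSN", 3]), 38)
  expect_equal(unname(unclass(m)["RS", ]), c(2, 0, 41))
  expect_equal(unclass(mean_landmarks(list(a, a))), unclass(a))
  # elementwise oracle over many sets
  set.seed(43)
  sets <- lapply(1:40, function(i) {
    landmark_set(rbind(RS = stats::rnorm(3), DSN = stats::rnorm(3),
                       DDR = stats::rnorm(3)))
  })
  oracle <- Reduce(`+`, lapply(sets, unclass)) / 40
  expect_equal(unclass(mean_landmarks(sets)), oracle, tolerance = 1e-12)
  cc <- landmark_set(rbind(RS = c(0, 0, 0)))
  expect_error(mean_landmarks(list(a, cc)), "missing")
})

test_that("deformation states round-trip through the plain-text format", {
  set.seed(47)
  st <- deformation_state(matrix(stats::rnorm(12), 4, 3),
                          matrix(stats::rnorm(12), 4, 3),
                          deformation_params(control_spacing = 5))
  pre <- file.path(tempdir(), "state_roundtrip")
  write_deformation_state(st, pre)
  back <- read_deformation_state(pre)
  expect_equal(back$control_points, st$control_points, tolerance = 1e-12)
  expect_equal(back$momenta, st$momenta, tolerance = 1e-12)
  expect_equal(back$params$deformation_kernel_width,
               st$params$deformation_kernel_width)
  expect_equal(back$params$control_spacing, 5)
})
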