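test_that("gaussian kernel has the documented convention and is PSD", {
  expect_equal(gaussian_kernel(matrix(0, 1, 3), matrix(0, 1, 3), 2)[1, 1], 1)
  x <- matrix(c(0, 0, 0), 1, 3)
  y <- matrix(c(3, 0, 0), 1, 3)
  expect_equal(gaussian_kernel(x, y, 3)[1, 1], exp(-1))
  set.seed(3)
  p <- matrix(stats::rnorm(150), 50, 3)
  G <- gaussian_kernel(p, p, 1.5)
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(gaussian_kernel(x, y, 0), "positive")
})

test_that("control grids cover the shape at the requested spacing", {
  cube <- surface_mesh(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                       rbind(c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
                             c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7),
                             c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8)))
  g <- make_control_grid(cube, 2)
  expect_gte(nrow(g), 8)
  ph <- fixture_phantom()$mesh
  g1 <- make_control_grid(ph, 4)
  # every vertex within sqrt(3) * spacing of a control point
  expect_lt(max(nn_dist(ph$vertices, g1)), sqrt(3) * 4)
  g2 <- make_control_grid(ph, 2)
  expect_gt(nrow(g2), 2 * nrow(g1))
})

test_that("geodesic shooting conserves the Hamiltonian and fixed points", {
  set.seed(5)
  C <- matrix(stats::rnorm(15), 5, 3) * 3
  A <- matrix(stats::rnorm(15), 5, 3) * 0.5
  p10 <- deformation_params(n_time_points = 10)
  st <- deformation_state(C, A, p10)
  H0 <- kinetic_energy(st)
  tr <- shoot(st)
  HT <- kinetic_energy(deformation_state(tr$states[[10]]$C, tr$states[[10]]$A, p10))
  expect_lt(abs(HT - H0) / H0, 0.01)
  p1k <- deformation_params(n_time_points = 1000)
  trf <- shoot(deformation_state(C, A, p1k))
  HTf <- kinetic_energy(deformation_state(trf$states[[1000]]$C, trf$states[[1000]]$A, p10))
  expect_lt(abs(HTf - H0) / H0, 1e-4)
  # zero momenta: nothing moves
  tr0 <- shoot(deformation_state(C, matrix(0, 5, 3), p10), points = C + 1)
  expect_equal(tr0$states[[10]]$C, C)
  expect_equal(tr0$states[[10]]$X, C + 1)
  # single control point: K(c, c) = 1, momentum constant, c moves by alpha
  st1 <- deformation_state(matrix(0, 1, 3), matrix(c(0.7, -0.2, 0.1), 1, 3), p10)
  tr1 <- shoot(st1)
  expect_equal(as.numeric(tr1$states[[10]]$C), c(0.7, -0.2, 0.1), tolerance = 1e-12)
})

test_that("RK2 endpoints agree with a 1000-step integration to 1e-4 mm", {
  set.seed(6)
  C <- matrix(stats::rnorm(6), 2, 3) * 2
  A <- matrix(stats::rnorm(6), 2, 3) * 0.3  # sub-mm motions, the pipeline's regime
  X <- matrix(stats::rnorm(12), 4, 3) * 2
  tr10 <- shoot(deformation_state(C, A, deformation_params(n_time_points = 10)),
                points = X)
  tr1k <- shoot(deformation_state(C, A, deformation_params(n_time_points = 1000)),
                points = X)
  expect_lt(max(abs(tr10$states[[10]]$C - tr1k$states[[1000]]$C)), 1e-4)
  expect_lt(max(abs(tr10$states[[10]]$X - tr1k$states[[1000]]$X)), 1e-4)
})

test_that("flowed points far from all control points barely move", {
  C <- matrix(0, 1, 3)
  A <- matrix(c(1, 0, 0), 1, 3)
  far <- matrix(c(0, 0, 30), 1, 3) # 15 sigma away
  tr <- shoot(deformation_state(C, A, deformation_params()))
  out <- flow_points(far, tr)
  expect_lt(sqrt(sum((out - far)^2)), 1e-3)
})

test_that("adjoint gradients match central finite differences", {
  set.seed(8)
  K <- 4
  C <- matrix(stats::rnorm(3 * K), K, 3) * 2
  A <- matrix(stats::rnorm(3 * K), K, 3) * 0.3
  X <- matrix(stats::rnorm(9), 3, 3) * 2
  p <- deformation_params(n_time_points = 6)
  W <- matrix(stats::rnorm(9), 3, 3)
  loss <- function(avec) {
    t_ <- shoot(deformation_state(C, matrix(avec, K, 3), p), points = X)
    sum(t_$states[[6]]$X * W)
  }
  tr <- shoot(deformation_state(C, A, p), points = X)
  back <- radsym:::backpropagate_flow(tr, matrix(0, K, 3), matrix(0, K, 3), W)
  g_fd <- numeric(3 * K)
  av <- as.vector(A)
  for (i in seq_along(av)) {
    hi <- av; hi[i] <- hi[i] + 1e-6
    lo <- av; lo[i] <- lo[i] - 1e-6
    g_fd[i] <- (loss(hi) - loss(lo)) / 2e-6
  }
  expect_lt(max(abs(as.vector(back$A) - g_fd)) / max(abs(g_fd)), 1e-4)
})

test_that("varifold distance is an unoriented squared pseudo-metric", {
  ph <- fixture_phantom()$mesh
  small <- decimate(ph, 150)
  expect_equal(varifold_distance_sq(small, small, 4), 0, tolerance = 1e-10)
  other <- small
  other$vertices <- sweep(other$vertices, 2, c(1, 0.5, 0))
  d1 <- varifold_distance_sq(small, other, 4)
  expect_gt(d1, 0)
  expect_equal(d1, varifold_distance_sq(other, small, 4))
  # orientation flip of every face leaves the value unchanged
  flipped <- other
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_equal(varifold_distance_sq(small, flipped, 4), d1, tolerance = 1e-10)
  # face re-indexing invariance
  perm <- sample(nrow(other$faces))
  reord <- other
  reord$faces <- reord$faces[perm, ]
  expect_equal(varifold_distance_sq(small, reord, 4), d1, tolerance = 1e-10)
})

test_that("varifold distance of two single triangles matches the hand sum", {
  A <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  B <- surface_mesh(rbind(c(0, 0, 1), c(1, 0, 1.2), c(0, 1, 1.1)), rbind(c(1, 2, 3)))
  s <- 2
  hand_inner <- function(va, vb) {
    fa <- colMeans(va)
    fb <- colMeans(vb)
    na <- 0.5 * pracma_cross(va[2, ] - va[1, ], va[3, ] - va[1, ])
    nb <- 0.5 * pracma_cross(vb[2, ] - vb[1, ], vb[3, ] - vb[1, ])
    exp(-sum((fa - fb)^2) / s^2) * sum(na * nb)^2 /
      (sqrt(sum(na^2)) * sqrt(sum(nb^2)))
  }
  pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  expected <- hand_inner(A$vertices, A$vertices) +
    hand_inner(B$vertices, B$vertices) - 2 * hand_inner(A$vertices, B$vertices)
  expect_equal(varifold_distance_sq(A, B, s), expected, tolerance = 1e-12)
})

test_that("registering a mesh onto itself keeps momenta at zero", {
  small <- decimate(fixture_phantom()$mesh, 150)
  reg <- register(small, small, deformation_params(max_iterations = 5,
                                                   control_spacing = 8))
  expect_lt(reg$final_regularity, 1e-6)
  expect_lt(max(abs(reg$deformed_source$vertices - small$vertices)), 1e-6)
})

test_that("registration cost decreases monotonically and satisfies the cost identity", {
  sp <- icosphere(1.5, 2)
  tg <- sp
  tg$vertices <- sweep(tg$vertices, 2, c(0.7, 0, 0), "+")
  p <- deformation_params(max_iterations = 30)
  reg <- register(sp, tg, p)
  expect_true(all(diff(reg$cost_trace) <= 1e-9))
  expect_lte(reg$final_cost, reg$cost_trace[1])
  expect_equal(reg$final_cost,
               reg$final_attachment / (2 * p$noise_std^2) + reg$final_regularity,
               tolerance = 1e-8)
})

test_that("registration recovers a 1 mm translation of a sphere", {
  sp <- icosphere(1.5, 2)
  tg <- sp
  tg$vertices <- sweep(tg$vertices, 2, c(1, 0, 0), "+")
  reg <- register(sp, tg, deformation_params(max_iterations = 300,
                                             convergence_tol = 1e-6))
  err <- sqrt(rowSums((reg$deformed_source$vertices - tg$vertices)^2))
  expect_lt(mean(err), 0.1)
})

test_that("registration is equivariant under a common rigid motion", {
  sp <- icosphere(1.5, 1)
  tg <- sp
  tg$vertices <- sweep(tg$vertices, 2, c(0.6, 0, 0), "+")
  p <- deformation_params(max_iterations = 60)
  r1 <- register(sp, tg, p)
  set.seed(21)
  tr <- random_rigid()
  r2 <- register(apply_transform(tr, sp), apply_transform(tr, tg), p,
                 control_points = apply_transform(tr, make_control_grid(sp, 2)))
  expect_lt(abs(r1$final_attachment - r2$final_attachment) /
              max(r1$final_attachment, 1e-12), 1e-3)
})

test_that("parameter recovery: flowing known momenta is undone by registration", {
  small <- decimate(fixture_phantom()$mesh, 200)
  ctrl <- make_control_grid(small, 8)
  set.seed(31)
  p <- deformation_params(max_iterations = 150, control_spacing = 8)
  # smooth ground-truth momenta: low amplitude so the deformation is mild
  Astar <- matrix(stats::rnorm(nrow(ctrl) * 3, sd = 0.15), ncol = 3)
  trj <- shoot(deformation_state(ctrl, Astar, p), points = small$vertices)
  target <- surface_mesh(trj$states[[p$n_time_points]]$X, small$faces,
                         validate = FALSE)
  reg <- register(small, target, p, control_points = ctrl)
  err <- sqrt(rowSums((reg$deformed_source$vertices - target$vertices)^2))
  expect_lt(mean(err), 0.2)
})
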