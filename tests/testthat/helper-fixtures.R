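# shared fixtures, built once per test run

# canonical small phantom (deterministic)
fixture_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_params(mesh_resolution = 700, seed = 42))
    }
    cache
  }
})

# a single closed triangle-pair tetrahedron surface
fixture_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  surface_mesh(v, f)
}

# brute-force nearest-neighbour distance (oracle, independent of nn_dist)
oracle_nn <- function(x, y) {
  apply(x, 1, function(p) sqrt(min(colSums((t(y) - p)^2))))
}

# random proper rigid transform
random_rigid <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rodrigues_rotation(ax, stats::runif(1, -pi, pi)),
                  stats::rnorm(3, sd = 5))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
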