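test_that("signed distances have the right magnitudes and signs", {
  ph <- compute_vertex_normals(decimate(fixture_phantom()$mesh, 200))
  # identity: all zeros
  f0 <- signed_distance(ph, ph)
  expect_equal(f0$distance, rep(0, nrow(ph$vertices)))
  # pure outward offset along normals: +0.5 everywhere
  out <- ph$vertices + 0.5 * ph$normals
  f1 <- signed_distance(ph, out)
  expect_equal(f1$distance, rep(0.5, nrow(ph$vertices)), tolerance = 1e-9)
  # random smooth displacement: magnitudes equal pairwise distances,
  # signs equal dot-product signs (per-vertex oracle)
  set.seed(51)
  disp <- matrix(stats::rnorm(length(ph$vertices), sd = 0.3), ncol = 3)
  f2 <- signed_distance(ph, ph$vertices + disp)
  expect_equal(abs(f2$distance), sqrt(rowSums(disp^2)), tolerance = 1e-9)
  sgn_oracle <- sign(rowSums(disp * ph$normals))
  nz <- sgn_oracle != 0
  expect_equal(sign(f2$distance)[nz], sgn_oracle[nz])
  expect_error(signed_distance(ph, ph$vertices[-1, ]), "correspondence")
})

test_that("subject summaries follow the absolute-value convention", {
  ph <- compute_vertex_normals(decimate(fixture_phantom()$mesh, 120))
  n <- nrow(ph$vertices)
  fld <- structure(list(distance = rep(0.5, n), mask = rep(TRUE, n), source = ph),
                   class = "correspondence_field")
  s <- summarize_subject(fld, "whole")
  expect_equal(unname(s[c("mean", "sd")]), c(0.5, 0))
  mixed <- fld
  mixed$distance <- rep(c(1, -1), length.out = n)
  s2 <- summarize_subject(mixed, "whole")
  expect_equal(unname(s2["mean"]), 1)
  expect_equal(unname(s2["sd"]), 0)
  # arithmetic oracle on a random field
  set.seed(53)
  fld$distance <- stats::rnorm(n)
  s3 <- summarize_subject(fld, "whole")
  expect_equal(unname(s3["mean"]), mean(abs(fld$distance)))
  expect_equal(unname(s3["median"]), stats::median(abs(fld$distance)))
  fld$mask <- rep(FALSE, n)
  expect_error(summarize_subject(fld, "articular"), "empty")
})

test_that("group aggregation reproduces the published cohort summaries", {
  ref <- reference_distance_tables()
  pw <- ref$pairwise[ref$pairwise$region == "whole", ]
  expect_equal(nrow(pw), 40)
  g <- summarize_group(pw$mean_mm, pw$group)
  expect_equal(round(g$mean_mm[g$group == "all"], 2), 0.53)
  expect_equal(round(g$mean_mm[g$group == "M_over40"], 2), 0.57)
  expect_equal(round(g$mean_mm[g$group == "F_under40"], 2), 0.45)
  art <- ref$pairwise[ref$pairwise$region == "articular", ]
  ga <- summarize_group(art$mean_mm, art$group)
  expect_equal(round(ga$mean_mm[ga$group == "F_under40"], 2), 0.40)
  expect_error(summarize_group(pw$mean_mm[1:5], pw$group[1:5][c(1:4, NA)]))
})

test_that("momenta standardization z-scores every feature column", {
  # two subjects with opposite momenta: rows are +-1 patterns
  v <- matrix(c(1, -2, 0.5, 0, 3, -1), 2, 3)
  X <- standardize_momenta(list(v, -v))
  expect_equal(colMeans(X), rep(0, 6), tolerance = 1e-10)
  # opposite momenta give an antisymmetric sign pattern with unit column SD
  expect_equal(X[1, ], -X[2, ], tolerance = 1e-10)
  nz <- apply(X, 2, stats::sd) > 0
  expect_equal(apply(X[, nz, drop = FALSE], 2, stats::sd),
               rep(1, sum(nz)), tolerance = 1e-10)
  # columnwise oracle on random momenta
  set.seed(57)
  ms <- lapply(1:8, function(i) matrix(stats::rnorm(12), 4, 3))
  Xs <- standardize_momenta(ms)
  raw <- t(vapply(ms, as.vector, numeric(12)))
  oracle <- scale(raw)
  expect_equal(unclass(Xs), unclass(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.vector(colMeans(Xs)), rep(0, 12), tolerance = 1e-10)
  expect_error(standardize_momenta(ms[1]), "two subjects")
  expect_error(standardize_momenta(list(ms[[1]], matrix(0, 3, 3))), "shapes")
})

test_that("kernel PCA reduces to the linear ordering in the small-gamma limit", {
  # data on a 1-D line: PC1 score order equals the line order
  t <- seq(-2, 2, length.out = 12)
  X <- cbind(t, 2 * t, -t)
  kp <- kpca_rbf(X, gamma = 1e-4, n_components = 2)
  # sign of a principal component is arbitrary: accept either orientation
  expect_equal(abs(stats::cor(kp$scores[, 1], t, method = "spearman")), 1)
  # scores centred; eigenvalues sorted; rank <= n - 1
  expect_lt(max(abs(colMeans(kp$scores))), 1e-8)
  expect_true(all(diff(kp$eigenvalues) <= 1e-8))
  expect_lte(sum(kp$eigenvalues > 1e-8 * max(kp$eigenvalues)), nrow(X) - 1)
  # duplicated subjects get identical score rows
  Xd <- rbind(X, X[3, ])
  kpd <- kpca_rbf(Xd, gamma = 0.05)
  expect_equal(kpd$scores[13, ], kpd$scores[3, ], tolerance = 1e-8)
  expect_error(kpca_rbf(X[1:2, ]), "at least 3")
  expect_error(kpca_rbf(rbind(X, NA)), "finite")
})

test_that("group test cascade reports Shapiro, Kruskal-Wallis and Welch", {
  set.seed(61)
  g <- rep(c("A", "B", "C", "D"), each = 10)
  s <- stats::rnorm(40)
  rep_ <- group_tests(s, g)
  comp <- rep_$components$PC1
  expect_true(comp$shapiro_p >= 0 && comp$shapiro_p <= 1)
  expect_true(comp$kruskal_p >= 0 && comp$kruskal_p <= 1)
  expect_equal(nrow(comp$welch), 6)
  # degenerate equality: identical groups give p = 1
  s2 <- c(rep(1:10 / 10, 2), stats::rnorm(20))
  rep2 <- group_tests(s2, g)
  ab <- rep2$components$PC1$welch
  expect_equal(ab$p[ab$group1 == "A" & ab$group2 == "B"], 1)
  expect_error(group_tests(stats::rnorm(8), rep(c("A", "B"), c(2, 6))),
               "at least 3")
})

test_that("Welch p-values agree with a permutation oracle", {
  set.seed(63)
  a <- stats::rnorm(10, 0, 1)
  b <- stats::rnorm(10, 0.8, 1.3)
  p_welch <- stats::t.test(a, b, var.equal = FALSE)$p.value
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_welch - p_perm), 0.02)
})

test_that("Kruskal-Wallis on kPCA scores is calibrated under the null", {
  set.seed(65)
  n_rep <- 1000
  rej <- logical(n_rep)
  g <- rep(c("A", "B", "C", "D"), each = 10)
  for (r in seq_len(n_rep)) {
    ms <- lapply(1:40, function(i) matrix(stats::rnorm(30), 10, 3))
    X <- standardize_momenta(ms)
    kp <- kpca_rbf(X, n_components = 1)
    rej[r] <- stats::kruskal.test(kp$scores[, 1], factor(g))$p.value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("distance reports write tables, boxplot data and coloured meshes", {
  ph <- compute_vertex_normals(decimate(fixture_phantom()$mesh, 120))
  n <- nrow(ph$vertices)
  set.seed(67)
  mk_field <- function() {
    structure(list(distance = stats::rnorm(n, sd = 0.4),
                   mask = ph$vertices[, 3] > stats::median(ph$vertices[, 3]),
                   source = ph),
              class = "correspondence_field")
  }
  fields <- list(s1 = mk_field(), s2 = mk_field(), s3 = mk_field(), s4 = mk_field())
  out <- file.path(tempdir(), "report_test")
  res <- render_distance_report(fields, c("A", "A", "B", "B"), out,
                                figure = FALSE)
  expect_true(file.exists(file.path(out, "distance_summary.csv")))
  expect_true(file.exists(file.path(out, "boxplot_stats.csv")))
  df <- utils::read.csv(file.path(out, "distance_summary.csv"))
  # 4 subject rows + 2 group rows + 1 cohort row
  expect_equal(nrow(df), 7)
  expect_true(all(c("subject", "group", "mean_mm", "sd_mm") %in% names(df)))
  # exported VTK carries the signed_distance_mm scalar
  vtk <- file.path(out, "meshes", "s1_distance.vtk")
  expect_true(file.exists(vtk))
  sc <- attr(read_mesh(vtk), "point_scalars")
  expect_equal(sc$signed_distance_mm, fields$s1$distance, tolerance = 1e-6)
  # constant field: zero IQR in the boxplot stats
  cf <- fields
  cf$s1$distance <- rep(0.3, n)
  res2 <- render_distance_report(cf["s1"], "A", file.path(tempdir(), "report2"),
                                 write_meshes = FALSE, figure = FALSE)
  expect_equal(res2$boxplot$q1, res2$boxplot$q3)
})
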