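test_that("G-matrix pairs reduce to class variances for one trait and drop incomplete families", {
  g <- toy_genotypes(list(mk = c("CO", "CO", "CO", "MT", "MT", "MT", "MT")))
  ph <- toy_phenotypes(list(a = c(1, 2, 4, 1, 3, 5, 7),
                            b = c(2, 2, 3, 9, 8, 6, NA)),
                       family_ids = g$family_id)
  pair <- estimate_g_pair(g, ph, "mk", c("a", "b"))
  # family 7 lacks trait b: complete-case n is 3 CO / 3 MT
  expect_equal(pair$V_CO, 2)
  expect_equal(pair$V_MT, 2)
  expect_equal(pair$G_MT[1, 1], var(c(1, 3, 5)))

  single <- estimate_g_pair(g, ph, "mk", "a")
  expect_equal(dim(single$G_CO), c(1, 1))
  expect_equal(single$G_CO[1, 1], var(c(1, 2, 4)))
  expect_equal(single$G_MT[1, 1], var(c(1, 3, 5, 7)))

  expect_error(estimate_g_pair(g, ph, "mk", c("a", "b"), min_class = 4),
               "fewer than 4")
})

test_that("G estimates from the two classes converge under a shared distribution", {
  withr::local_seed(30)
  n <- 4000
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  Y <- rmvn(n, c(0, 0), sigma)
  g <- toy_genotypes(list(mk = rep(c("CO", "MT"), n / 2)))
  ph <- toy_phenotypes(list(t1 = Y[, 1], t2 = Y[, 2]), family_ids = g$family_id)
  pair <- estimate_g_pair(g, ph, "mk", c("t1", "t2"))
  expect_lt(max(abs(pair$G_CO - pair$G_MT)), 0.25)
  expect_lt(max(abs(pair$G_CO - sigma)), 0.25)
})

test_that("trace-form Box's M: zero at equality, hand value, scale invariance", {
  p1 <- g_matrix_pair(diag(c(1, 2)), diag(c(1, 2)), 10, 10)
  expect_equal(boxs_m(p1), 0)

  # traces 1 and 3 with 10 df each: pooled 2, M = 20 ln2 - 10 ln3
  p2 <- g_matrix_pair(diag(c(0.5, 0.5)), diag(c(1.5, 1.5)), 10, 10)
  expect_equal(boxs_m(p2), 20 * log(2) - 10 * log(3), tolerance = 1e-12)
  expect_equal(boxs_m(p2), 2.87682, tolerance = 1e-5)

  p3 <- g_matrix_pair(7 * diag(c(0.5, 0.5)), 7 * diag(c(1.5, 1.5)), 10, 10)
  expect_equal(boxs_m(p3), boxs_m(p2), tolerance = 1e-12)
  expect_gt(boxs_m(p2), 0)

  expect_error(boxs_m(g_matrix_pair(diag(c(0, 0)), diag(2), 5, 5)),
               "non-positive trace")
})

test_that("determinant-form Box's M matches its classical formula", {
  A <- matrix(c(2, 0.5, 0.5, 1), 2); B <- diag(c(1, 3))
  p <- g_matrix_pair(A, B, 12, 8)
  pooled <- (12 * A + 8 * B) / 20
  expect_equal(boxs_m(p, form = "determinant"),
               20 * log(det(pooled)) - 12 * log(det(A)) - 8 * log(det(B)),
               tolerance = 1e-12)
  expect_equal(boxs_m(g_matrix_pair(A, A, 5, 5), form = "determinant"), 0,
               tolerance = 1e-12)
})

test_that("Gmax angle: exact geometry, reflection rule, sign invariance", {
  expect_equal(gmax_angle(g_matrix_pair(diag(c(2, 1)), diag(c(2, 1)), 5, 5)), 0)
  # leading axes e1 vs e2
  expect_equal(gmax_angle(g_matrix_pair(diag(c(2, 1)), diag(c(1, 2)), 5, 5)),
               pi / 2)
  # anti-parallel eigenvectors reflect to zero
  R <- rot2(pi)
  expect_equal(gmax_angle(g_matrix_pair(diag(c(2, 1)),
                                        R %*% diag(c(2, 1)) %*% t(R), 5, 5)),
               0, tolerance = 1e-8)
  # (1,0) vs (1,1)/sqrt(2)
  R45 <- rot2(pi / 4)
  pair45 <- g_matrix_pair(diag(c(2, 1)), R45 %*% diag(c(2, 1)) %*% t(R45), 5, 5)
  expect_equal(gmax_angle(pair45), pi / 4, tolerance = 1e-8)
  expect_error(gmax_angle(g_matrix_pair(matrix(0, 2, 2), diag(2), 5, 5)), "zero")
})

test_that("Krzanowski index: exact subspace overlaps and rotation invariance", {
  e <- function(i, p = 4) { v <- rep(0, p); v[i] <- 1; v }
  G_from <- function(vecs, vals) {
    A <- do.call(cbind, vecs)
    A %*% diag(vals, length(vecs)) %*% t(A)
  }
  # identical subspaces -> k
  G1 <- G_from(list(e(1), e(2)), c(3, 2)) + 0.01 * diag(4)
  expect_equal(krzanowski_index(g_matrix_pair(G1, G1, 9, 9), k = 2), 2,
               tolerance = 1e-8)
  # orthogonal subspaces -> 0
  G2 <- G_from(list(e(3), e(4)), c(3, 2)) + 0.01 * diag(4)
  expect_equal(krzanowski_index(g_matrix_pair(G1, G2, 9, 9), k = 2), 0,
               tolerance = 1e-8)
  # one shared axis -> 1
  G3 <- G_from(list(e(1), e(3)), c(3, 2)) + 0.01 * diag(4)
  expect_equal(krzanowski_index(g_matrix_pair(G1, G3, 9, 9), k = 2), 1,
               tolerance = 1e-8)
  # rotating B's basis within its own subspace changes nothing
  theta <- 0.7
  Grot <- G_from(list(cos(theta) * e(1) + sin(theta) * e(2),
                      -sin(theta) * e(1) + cos(theta) * e(2)), c(3, 2)) +
    0.01 * diag(4)
  expect_equal(krzanowski_index(g_matrix_pair(G1, Grot, 9, 9), k = 2), 2,
               tolerance = 1e-6)
  expect_error(krzanowski_index(g_matrix_pair(G1, G2, 9, 9), k = 3), "floor")
})

test_that("Krzanowski index equals the projection-matrix oracle on random matrices", {
  withr::local_seed(31)
  for (i in 1:25) {
    W1 <- matrix(rnorm(36), 6); W2 <- matrix(rnorm(36), 6)
    G1 <- crossprod(W1) / 6; G2 <- crossprod(W2) / 6
    k <- sample(1:3, 1)
    expect_equal(krzanowski_index(g_matrix_pair(G1, G2, 9, 9), k = k),
                 krz_oracle(G1, G2, k), tolerance = 1e-8)
  }
})

test_that("covariance scan engine agrees with the R statistics and rejects bad input", {
  withr::local_seed(32)
  g <- random_genotypes(70, 15, miss = 0)
  Y <- rmvn(70, rep(0, 4), diag(4) + 0.3)
  ph <- toy_phenotypes(list(t1 = Y[, 1], t2 = Y[, 2], t3 = Y[, 3], t4 = Y[, 4]),
                       family_ids = g$family_id)
  traits <- c("t1", "t2", "t3", "t4")
  for (method in c("boxm", "gmax_angle", "krzanowski")) {
    sc <- scan_covariance(g, ph, traits, method = method, n_perm = 30, seed = 2)
    for (mk in sample(sc$marker, 4)) {
      pair <- estimate_g_pair(g, ph, mk, traits)
      expected <- switch(method, boxm = boxs_m(pair),
                         gmax_angle = gmax_angle(pair),
                         krzanowski = krzanowski_index(pair, k = 2))
      expect_equal(sc$statistic[sc$marker == mk], expected, tolerance = 1e-10)
    }
    if (method == "gmax_angle")
      expect_true(all(sc$statistic >= 0 & sc$statistic <= pi / 2 + 1e-12))
    if (method == "krzanowski")
      expect_true(all(sc$statistic >= -1e-12 & sc$statistic <= 2 + 1e-12))
  }
  expect_error(scan_covariance(g, ph, c("t1", "t2"), method = "krzanowski",
                               n_perm = 10),
               "disabled for two-trait")
  expect_error(scan_covariance(g, ph, "t1", n_perm = 10), "at least 2 traits")
})

test_that("size and rotation perturbations are picked up by the matching method (fixed seed)", {
  withr::local_seed(33)
  n <- 170
  g <- random_genotypes(n, 30, miss = 0)
  cls <- g$mk001
  base <- diag(c(3, 0.5))
  rot <- rot2(pi / 3) %*% base %*% t(rot2(pi / 3))
  # size-only: same orientation, doubled total variance in MT
  Ys <- matrix(NA_real_, n, 2)
  Ys[cls == "CO", ] <- rmvn(sum(cls == "CO"), c(0, 0), base)
  Ys[cls == "MT", ] <- rmvn(sum(cls == "MT"), c(0, 0), 2.5 * base)
  ph_s <- toy_phenotypes(list(t1 = Ys[, 1], t2 = Ys[, 2]), family_ids = g$family_id)
  sc_box <- scan_covariance(g, ph_s, c("t1", "t2"), method = "boxm",
                            n_perm = 200, seed = 4)
  sc_ang <- scan_covariance(g, ph_s, c("t1", "t2"), method = "gmax_angle",
                            n_perm = 200, seed = 4)
  expect_lte(sc_box$perm_p[sc_box$marker == "mk001"], 0.05)
  expect_gt(sc_ang$perm_p[sc_ang$marker == "mk001"], 0.05)

  # rotation-only: equal trace, rotated orientation in MT
  Yr <- matrix(NA_real_, n, 2)
  Yr[cls == "CO", ] <- rmvn(sum(cls == "CO"), c(0, 0), base)
  Yr[cls == "MT", ] <- rmvn(sum(cls == "MT"), c(0, 0), rot)
  ph_r <- toy_phenotypes(list(t1 = Yr[, 1], t2 = Yr[, 2]), family_ids = g$family_id)
  sc_box2 <- scan_covariance(g, ph_r, c("t1", "t2"), method = "boxm",
                             n_perm = 200, seed = 4)
  sc_ang2 <- scan_covariance(g, ph_r, c("t1", "t2"), method = "gmax_angle",
                             n_perm = 200, seed = 4)
  expect_lte(sc_ang2$perm_p[sc_ang2$marker == "mk001"], 0.05)
  expect_gt(sc_box2$perm_p[sc_box2$marker == "mk001"], 0.05)
})

test_that("confidence ellipses trace the requested chi-square contour", {
  sigma <- matrix(c(2, 0.6, 0.6, 1), 2)
  ell <- confidence_ellipse(sigma, centre = c(1, -1), level = 0.95)
  # every boundary point has Mahalanobis distance^2 = qchisq(0.95, 2)
  d2 <- apply(as.matrix(ell) - rep(c(1, -1), each = nrow(ell)), 1,
              function(v) t(v) %*% solve(sigma) %*% v)
  expect_equal(unname(d2), rep(qchisq(0.95, 2), nrow(ell)), tolerance = 1e-8)
})

test_that("scan plots build without error", {
  withr::local_seed(34)
  map <- sim_genetic_map(n_markers = 20)
  g <- sim_ril_genotypes(map, n_families = 60, seed = 3)
  ph <- toy_phenotypes(list(tr = rnorm(60)), family_ids = g$family_id)
  sc <- scan_variance(g, ph, "tr", map = map, n_perm = 20, seed = 1)
  expect_s3_class(autoplot(sc), "ggplot")
  ph2 <- toy_phenotypes(list(a = rnorm(60), b = rnorm(60)), family_ids = g$family_id)
  expect_s3_class(plot_g_ellipses(g, ph2, sc$marker[1], c("a", "b")), "ggplot")
})
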