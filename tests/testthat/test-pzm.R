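test_that("disk mapping normalises and assigns polar coordinates correctly", {
  u <- matrix(5, 32, 32)
  d <- map_to_disk(u)
  expect_true(all(d$values == 1))
  expect_true(all(d$rho >= 0 & d$rho <= 1))

  # centred delta on an odd-sized grid sits at rho = 0
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  dd <- map_to_disk(img)
  expect_equal(min(dd$rho), 0)
  expect_equal(dd$values[which.min(dd$rho)], 1)

  # off-centre mapping changes in-disk mass by a directly recomputable amount
  set.seed(1)
  img <- matrix(runif(64^2), 64)
  m1 <- map_to_disk(img, disk_mapping(radius = 20))
  m2 <- map_to_disk(img, disk_mapping(center = c(25, 40), radius = 20))
  mass <- function(center) {
    r <- sqrt(outer((1:64 - center[1])^2, (1:64 - center[2])^2, "+"))
    sum(img[r <= 20])
  }
  expect_equal(sum(m1$values) * max(img[m1$idx]), mass(c(32.5, 32.5)),
               tolerance = 1e-9)
  expect_equal(sum(m2$values) * max(img[m2$idx]), mass(c(25, 40)),
               tolerance = 1e-9)

  expect_error(map_to_disk(img, disk_mapping(center = c(5, 5), radius = 20)),
               "bounds")
})

test_that("radial polynomials match the factorial-sum oracle and known forms", {
  rho <- seq(0, 1, length.out = 41)
  expect_equal(pzm_radial(0, 0, rho), rep(1, 41))
  # single-term cases: R_nn = rho^n up to the maximum order used
  for (n in c(1, 5, 17)) expect_equal(pzm_radial(n, n, rho), rho^n,
                                      tolerance = 1e-10)
  # the factorial sum itself gives R_11 = rho (single term, coefficient 1)
  expect_equal(pz_radial_direct(1, 1, rho), rho, tolerance = 1e-12)
  expect_equal(pzm_radial(1, 0, rho), 3 * rho - 2, tolerance = 1e-12)
  for (n in 0:8) for (m in 0:n) {
    expect_equal(pzm_radial(n, m, rho), pz_radial_direct(n, m, rho),
                 tolerance = 1e-8)
  }
  expect_error(pzm_radial(2, 3, rho), "exceed")
  expect_error(pzm_radial(2, 1, c(-0.5, 2)), "\\[0, 1\\]")
})

test_that("radial polynomials are orthogonal with weight rho on [0, 1]", {
  pairs <- list(c(3, 1, 0), c(6, 2, 1), c(17, 15, 0), c(17, 16, 3))
  for (p in pairs) {
    v <- stats::integrate(function(r) pzm_radial(p[1], p[3], r) *
                            pzm_radial(p[2], p[3], r) * r,
                          0, 1, rel.tol = 1e-12)$value
    expect_lt(abs(v), 1e-8)
  }
  nrm <- stats::integrate(function(r) pzm_radial(17, 0, r)^2 * r, 0, 1,
                          rel.tol = 1e-12)$value
  expect_equal(nrm, 1 / 36, tolerance = 1e-10)
})

test_that("A(0,0) of the uniform unit disk is 1 up to discretisation", {
  d <- map_to_disk(matrix(1, 256, 256))
  pz <- compute_pzm(d, n_max = 0)
  expect_equal(unname(pz$magnitudes["pzm_n00_m00"]), 1, tolerance = 1e-3)
})

test_that("moment magnitudes are rotation invariants", {
  set.seed(7)
  for (i in 1:10) {
    img <- matrix(runif(64^2), 64)
    base <- compute_pzm(map_to_disk(img), n_max = 8)$magnitudes
    rot <- img
    for (k in 1:3) {
      rot <- t(rot)[ncol(rot):1, ]
      m <- compute_pzm(map_to_disk(rot), n_max = 8)$magnitudes
      expect_lt(max(abs(m - base) / (abs(base) + 1e-12)), 0.01)
    }
  }
})

test_that("fast moments equal brute-force numerical integration", {
  set.seed(11)
  for (i in 1:3) {
    img <- matrix(runif(64^2), 64)
    fast <- compute_pzm(map_to_disk(img), n_max = 6)
    slow <- brute_pzm(img, 6)
    rel <- Mod(fast$moments - slow) / (Mod(slow) + 1e-12)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("feature counting and ordering follow the (n, m) triangle", {
  expect_equal(pzm_feature_count(17), 171L)
  expect_equal(pzm_feature_count(6), 28L)
  tab <- colonyscatter:::pzm_index_table(3)
  expect_equal(tab$n, c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3))
  expect_equal(tab$m, c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3))
  set.seed(2)
  v <- extract_features(matrix(runif(32^2), 32), n_max = 17)
  expect_length(v, 171)
  expect_true(all(is.finite(v)))
})

test_that("Fisher scores reproduce hand computations and handle degeneracy", {
  g <- matrix(c(1, 2, 3), ncol = 1)
  b <- matrix(c(4, 5, 6), ncol = 1)
  fr <- fisher_scores(g, b, k = 1)
  expect_equal(fr$scores, 4.5, tolerance = 1e-9)

  # identical class means: zero score
  fr0 <- fisher_scores(matrix(c(1, 2), ncol = 1), matrix(c(2, 1), ncol = 1))
  expect_equal(fr0$scores, 0)

  # zero variances are regularised, not infinite, and dominate the ranking
  g2 <- cbind(c(0, 0), c(1, 2))
  b2 <- cbind(c(1, 1), c(1.5, 2.5))
  fr2 <- fisher_scores(g2, b2, k = 2)
  expect_true(is.finite(fr2$scores[1]))
  expect_gt(fr2$scores[1], 1e11)
  expect_equal(fr2$ranking[1], 1L)

  expect_error(fisher_scores(matrix(1:4, 2), matrix(1:6, 2, 3)), "mismatch")
  expect_error(fisher_scores(matrix(1, 1, 1), b), "two samples")
})

test_that("Fisher scores are shift invariant and scale-stable in ranking", {
  set.seed(3)
  G <- matrix(rnorm(40), 10)
  B <- matrix(rnorm(40, 1), 10)
  f1 <- fisher_scores(G, B)
  f2 <- fisher_scores(G + 5, B + 5)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-9)
  f3 <- fisher_scores(G * 3, B * 3)
  expect_equal(f1$ranking, f3$ranking)
})

test_that("feature selection keeps exactly k features in score order", {
  set.seed(4)
  G <- matrix(rnorm(100), 10); B <- matrix(rnorm(100, 0.5), 10)
  colnames(G) <- colnames(B) <- sprintf("f%02d", 1:10)
  fr <- fisher_scores(G, B, k = 10)
  all_sel <- select_features(fr, rbind(G, B), k = 10)
  expect_equal(ncol(all_sel), 10)
  expect_equal(colnames(all_sel), sprintf("f%02d", fr$ranking))
  one <- select_features(fr, rbind(G, B), k = 1)
  expect_equal(colnames(one), sprintf("f%02d", which.max(fr$scores)))
  expect_error(select_features(fr, rbind(G, B), k = 11), "\\[1, 10\\]")
  # scores along the ranking are non-increasing
  expect_true(all(diff(fr$scores[fr$ranking]) <= 1e-12))
})
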