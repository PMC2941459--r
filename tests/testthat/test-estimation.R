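test_that("sample covariance handles degenerate and tiny inputs", {
  # two markers, two individuals: direct two-point covariance
  C <- sample_cov(matrix(c(0, 2, 2, 0), 2, byrow = TRUE))$C
  expect_equal(unname(C), matrix(c(2, -2, -2, 2), 2))

  # all genotypes equal: no polymorphic marker, zero covariance
  expect_message(C0 <- sample_cov(matrix(1, 5, 3)), "monomorphic")
  expect_equal(unname(C0$C), matrix(0, 3, 3))
  expect_equal(C0$n_markers, 0L)

  G <- matrix(c(0, 1, 2, NA, NA, NA), 3, 2)
  expect_error(sample_cov(G), "all genotypes missing")
  expect_error(sample_cov(matrix(0:2, 1, 3)), "two markers")
})

test_that("pairwise-complete covariance matches the dense path and drops monomorphics", {
  set.seed(6001)
  G <- matrix(rbinom(400 * 6, 2, 0.4), 400, 6)
  poly <- apply(G, 1, function(x) diff(range(x)) > 0)
  G <- rbind(G[poly, ][1:200, ], matrix(2L, 3, 6))   # 3 monomorphic rows
  expect_message(sc <- sample_cov(G), "dropping 3")
  expect_equal(sc$n_markers, 200L)
  expect_equal(sc$C, stats::cov(G[1:200, ]))
  # sprinkle missingness: still symmetric, close to the complete version
  Gm <- G[1:200, ]
  Gm[sample(length(Gm), 50)] <- NA
  scm <- suppressMessages(sample_cov(Gm))
  expect_equal(scm$C, t(scm$C))
  expect_lt(max(abs(scm$C - sc$C)), 0.2)
})

test_that("marker adjustment yields the Eigenstrat-centred covariance", {
  set.seed(6002)
  G <- matrix(rbinom(800 * 8, 2, 0.5), 800, 8)
  G <- G[apply(G, 1, function(x) diff(range(x)) > 0), ][1:500, ]
  sc <- sample_cov(G, marker_adjust = TRUE)
  Gc <- G - rowMeans(G)
  expect_equal(sc$C, stats::cov(Gc))
  expect_equal(sc$centering, "individual+marker")
})

test_that("off-diagonal covariance vanishes without frequency variation", {
  # with the marker frequency fixed, individuals are fully independent
  # and only the binomial sampling variance remains
  set.seed(6003)
  f <- draw_freqs_bn(20000, 0, K = 1, p_range = c(0.5, 0.5))$f
  G <- genotypes_from_freqs(f, pop_layout(12))
  C <- suppressMessages(sample_cov(G))$C
  off <- C[upper.tri(C)]
  expect_lt(abs(mean(off)), 3 * stats::sd(off) / sqrt(length(off)))
})

test_that("block averaging recovers an exact block matrix and ignores ordering", {
  u <- unbalanced3()
  C <- build_full_cov(u$params, u$layout)
  labels <- rep(u$layout$labels, u$layout$sizes)
  est <- estimate_params(C, labels)
  expect_equal(est$params$sigma2, stats::setNames(rep(1, 3), u$layout$labels))
  expect_equal(unname(est$params$c), rep(0.8, 3))
  expect_equal(est$params$d[1, 2], 0.1)
  expect_equal(unname(est$se$sigma2), rep(0, 3))   # constant cells

  perm <- sample(length(labels))
  estp <- estimate_params(C[perm, perm], labels[perm])
  ord <- u$layout$labels
  expect_equal(estp$params$sigma2[ord], est$params$sigma2[ord])
  expect_equal(estp$params$d[ord, ord], est$params$d[ord, ord])

  # singleton population: within-covariance flagged undefined, not silent
  expect_warning(est1 <- estimate_params(C[1:6, 1:6],
                                         c("A", rep("B", 5))), "singleton")
  expect_true(is.na(est1$params$c["A"]))
  expect_equal(attr(est1, "singletons"), "A")
  expect_error(representative_points(est1), "singleton")
})

test_that("correlations reproduce the printed four-population summary cells", {
  # printed estimates for the four-population simulation: variance 0.565
  # with within-covariance 0.128 gives correlation 0.227; variance 0.750
  # with 0.500 gives 0.667
  d <- matrix(0.113, 4, 4)
  est <- cov_params(c(0.565, 0.562, 0.750, 0.747),
                    c(0.128, 0.127, 0.500, 0.493), d)
  rho <- param_correlations(est)
  expect_equal(round(rho[1, 1], 3), 0.227)
  expect_equal(round(rho[3, 3], 3), 0.667)

  # diagonal covariance: all off-diagonal correlations zero
  rho0 <- param_correlations(cov_params(c(1, 2), c(0, 0),
                                        matrix(0, 2, 2)))
  expect_equal(rho0[1, 2], 0)
  expect_error(param_correlations(cov_params(c(0, 1), c(0, 0))), "positive")
})

test_that("four-population drift ordering shows up in the estimates", {
  # two weakly drifted populations (F = 0.01) and two strongly drifted
  # ones (F = 0.43), twenty individuals each: within-population
  # covariances order by drift and exceed the cross-population ones
  set.seed(6004)
  Fst <- c(0.01, 0.01, 0.43, 0.43)
  lay <- pop_layout(rep(20, 4))
  f <- draw_freqs_bn(20000, Fst)$f
  G <- genotypes_from_freqs(f, lay)
  est <- suppressMessages(
    estimate_params(sample_cov(G), rep(lay$labels, lay$sizes)))
  cw <- est$params$c
  expect_gt(min(cw[3:4]), max(cw[1:2]))
  cross <- est$params$d[upper.tri(est$params$d)]
  expect_lt(max(cross), min(cw))
})

test_that("representative points equal the theory pipeline on exact input", {
  u <- unbalanced3()
  C <- build_full_cov(u$params, u$layout)
  est <- estimate_params(C, rep(u$layout$labels, u$layout$sizes))
  rp <- representative_points(est)
  sol <- solve_reduced(build_reduced(mean_adjust(u$params, u$layout)$params,
                                     u$layout))
  a <- nontrivial_axes(sol)
  expect_equal(unname(rp[, 1:2]), unname(a[, 1:2]), tolerance = 1e-8)
})

test_that("sample PCA has no dominant axis without structure", {
  set.seed(6005)
  f <- draw_freqs_bn(20000, 0, K = 1)$f
  G <- genotypes_from_freqs(f, pop_layout(100))
  pca <- suppressMessages(sample_pca(G, m = 2))
  expect_lt(pca$values[1] / mean(pca$values), 1.5)
})

test_that("two populations cluster on exactly one sample axis", {
  set.seed(6006)
  lay <- pop_layout(c(40, 60))
  f <- draw_freqs_bn(20000, c(0.02, 0.02))$f
  G <- genotypes_from_freqs(f, lay)
  pca <- suppressMessages(sample_pca(G, m = 2))
  pop <- rep(1:2, lay$sizes)
  sep <- function(v) {
    m <- tapply(v, pop, mean)
    se <- sqrt(sum(tapply(v, pop, stats::var) / lay$sizes))
    abs(diff(m)) / se
  }
  expect_gt(sep(pca$vectors[, 1]), 10)   # axis 1 separates the populations
  expect_lt(sep(pca$vectors[, 2]), 3)    # axis 2 shows no separation
  expect_error(sample_pca(G, m = 200), "individuals")
})

test_that("sample PCA respects duplication symmetry", {
  set.seed(6007)
  lay <- pop_layout(c(15, 15))
  f <- draw_freqs_bn(5000, c(0.05, 0.05))$f
  G <- genotypes_from_freqs(f, lay)
  G2 <- cbind(G, G)
  pca <- suppressMessages(sample_pca(G2, m = 1))
  v <- pca$vectors[, 1]
  expect_lt(max(abs(v[1:30] - v[31:60])), 1e-8)
})
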