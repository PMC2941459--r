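test_that("build_reduced produces a zero-row-sum matrix similar to its symmetrization", {
  # one population: the adjusted large eigenvalue is exactly zero
  lay1 <- pop_layout(10)
  adj1 <- mean_adjust(cov_params(1, 0.8), lay1)$params
  sys1 <- build_reduced(adj1, lay1)
  expect_equal(unname(sys1$R), matrix(0, 1, 1), tolerance = 1e-12)

  u <- unbalanced3()
  adj <- mean_adjust(u$params, u$layout)$params
  sys <- build_reduced(adj, u$layout)
  expect_lt(max(abs(rowSums(sys$R))), 1e-10)
  expect_equal(sort(eigen(sys$R)$values), sort(eigen(sys$B)$values),
               tolerance = 1e-9)
  # raw parameters are rejected with guidance
  expect_error(build_reduced(u$params, u$layout), "mean_adjust")
})

test_that("reduced eigenvalues plus small eigenvalues equal the dense spectrum", {
  set.seed(5001)
  for (i in 1:30) {
    K <- sample(1:6, 1)
    params <- random_params(K)
    layout <- random_layout(K, 150)
    full <- full_spectrum(params, layout)
    red <- reduced_spectrum(params, layout)
    expect_equal(red, full, tolerance = 1e-8)
  }
})

test_that("dense top eigenvectors are piecewise constant at the reduced coefficients", {
  set.seed(5002)
  params <- random_params(3)
  layout <- pop_layout(c(7, 13, 21))
  adj <- mean_adjust(params, layout)$params
  sol <- solve_reduced(build_reduced(adj, layout))
  es <- eigen(build_full_cov(adj, layout), symmetric = TRUE)
  pop <- rep(1:3, layout$sizes)
  for (j in which(seq_len(3) != sol$trivial_index)) {
    v <- es$vectors[, j]
    a <- sol$coef[, j]
    if (sum(v * a[pop]) < 0) v <- -v
    expect_lt(max(abs(v - a[pop])), 1e-6)
  }
})

test_that("the solution carries one trivial axis and normalized, orthogonal non-trivial axes", {
  set.seed(5003)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    layout <- random_layout(K, 200)
    sol <- solve_reduced(build_reduced(
      mean_adjust(random_params(K), layout)$params, layout))
    ns <- layout$sizes
    scale <- max(abs(sol$values))
    expect_equal(sum(abs(sol$values) < 1e-9 * scale), 1)
    expect_false(is.na(sol$trivial_index))
    # trivial axis: constant coefficients
    expect_lt(diff(range(sol$coef[, sol$trivial_index])), 1e-8)
    nt <- setdiff(seq_len(K), sol$trivial_index)
    for (j in nt) {
      expect_lt(abs(sum(ns * sol$coef[, j])), 1e-8)        # zero weighted sum
      expect_equal(sum(ns * sol$coef[, j]^2), 1)           # weighted norm 1
      # dominant coefficient is positive (sign convention)
      expect_gt(sol$coef[which.max(abs(sol$coef[, j])), j], 0)
    }
    G <- t(sol$coef) %*% diag(ns) %*% sol$coef
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)           # weighted orthogonality
  }
})

test_that("two-population closed form is forced by the constraints", {
  lay <- pop_layout(c(5, 10))
  set.seed(5004)
  params <- random_params(2)
  adj <- mean_adjust(params, lay)$params
  cf <- two_pop_closed_form(lay, adj)
  expect_equal(unname(cf$coef), c(0.3651484, -0.1825742), tolerance = 1e-6)

  # equal sizes: symmetric coefficients 1/sqrt(n)
  laye <- pop_layout(c(8, 8))
  adje <- mean_adjust(params, laye)$params
  cfe <- two_pop_closed_form(laye, adje)
  expect_equal(abs(unname(cfe$coef)), rep(1 / 4, 2))

  # eigenvalue and axis agree with the reduced solver and the dense oracle
  sol <- solve_reduced(build_reduced(adj, lay))
  j <- setdiff(1:2, sol$trivial_index)
  expect_equal(cf$value, sol$values[j], tolerance = 1e-10)
  expect_equal(unname(cf$coef), unname(sol$coef[, j]), tolerance = 1e-10)
  full <- eigen(build_full_cov(adj, lay), symmetric = TRUE,
                only.values = TRUE)$values
  expect_equal(cf$value, full[1], tolerance = 1e-8)
  expect_error(two_pop_closed_form(pop_layout(c(2, 2, 2)), adj), "two popul")
})

test_that("unbalanced sizes put small populations far from the center", {
  u <- unbalanced3()
  sol <- solve_reduced(build_reduced(mean_adjust(u$params, u$layout)$params,
                                     u$layout))
  a <- nontrivial_axes(sol)
  dist <- sqrt(rowSums(a^2))
  # identical covariance parameters: the pattern reflects sizes alone
  expect_gt(dist["P1"], dist["P2"])
  expect_gt(dist["P2"], dist["P3"])
})

test_that("a close triple collapses on the leading axes and splits on later ones", {
  f <- five_pop()
  sol <- solve_reduced(build_reduced(mean_adjust(f$params, f$layout)$params,
                                     f$layout))
  a <- nontrivial_axes(sol)
  triple <- 1:3
  spread12 <- max(dist(a[triple, 1:2]))
  spread34 <- max(dist(a[triple, 3:4]))
  expect_lt(spread12, 0.2 * spread34)   # P1-P3 indistinguishable on axes 1-2
  # P4 and P5 are contrasted on axis 2 (opposite signs, large separation)
  expect_lt(a[4, 2] * a[5, 2], 0)
  expect_gt(abs(a[4, 2] - a[5, 2]), max(abs(a[triple, 2])))
})

test_that("asymptotic solver matches the symmetric closed form", {
  # exchangeable populations: every non-trivial unit eigenvalue is
  # (c_tilde - d_tilde)/K = (c - d)/K
  K <- 4
  params <- cov_params(rep(1, K), rep(0.6, K), matrix(0.2, K, K))
  asy <- asymptotic_solve(params, rep(1 / K, K))
  nt <- setdiff(seq_len(K), asy$trivial_index)
  expect_equal(asy$unit_values[nt], rep((0.6 - 0.2) / K, K - 1),
               tolerance = 1e-10)
})

test_that("finite-size coefficients converge to the asymptotic pattern", {
  set.seed(5005)
  params <- random_params(4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  asy <- asymptotic_solve(params, w)
  a_inf <- asy$coef
  for (n in c(100, 10000)) {
    layout <- pop_layout(round(n * w))
    sol <- solve_reduced(build_reduced(mean_adjust(params, layout)$params,
                                       layout))
    # rescale: finite solver normalizes sum n_s a^2 = 1, asymptotic sum w_s a^2 = 1
    a_n <- sol$coef * sqrt(layout$n)
    nt <- setdiff(1:4, sol$trivial_index)
    nt_inf <- setdiff(1:4, asy$trivial_index)
    d <- max(abs(a_n[, nt] - a_inf[, nt_inf]))
    if (n == 10000) expect_lt(d, 1e-3) else dist_small_n <- d
  }
  expect_gt(dist_small_n, 0)   # convergence is from a visibly different start
})

test_that("asymptotic coefficients ignore the variances", {
  set.seed(5006)
  params <- random_params(3)
  w <- c(0.2, 0.3, 0.5)
  base <- asymptotic_solve(params, w)
  bumped <- params
  bumped$sigma2 <- params$sigma2 + 0.5
  pert <- asymptotic_solve(bumped, w)
  expect_equal(pert$coef, base$coef, tolerance = 1e-10)
  expect_equal(pert$unit_values, base$unit_values, tolerance = 1e-10)
})

test_that("non-trivial eigenvalues grow linearly with n at fixed proportions", {
  lam <- function(params, n, w) {
    layout <- pop_layout(round(n * w))
    sol <- solve_reduced(build_reduced(mean_adjust(params, layout)$params,
                                       layout))
    sort(sol$values[setdiff(seq_along(w), sol$trivial_index)])
  }
  # well-separated populations: linear growth visible already at n = 100 K
  w <- c(0.25, 0.35, 0.4)
  params <- cov_params(rep(1, 3), rep(0.6, 3), matrix(0.2, 3, 3))
  expect_equal(lam(params, 600, w) / lam(params, 300, w), rep(2, 2),
               tolerance = 0.02)
  # arbitrary parameters: the O(1) offset fades at larger n
  set.seed(5007)
  rnd <- random_params(3)
  expect_equal(lam(rnd, 10000, w) / lam(rnd, 5000, w), rep(2, 2),
               tolerance = 0.02)
})

test_that("critical size has the exchangeable closed form and diverges as d approaches c", {
  params <- cov_params(rep(1, 3), rep(0.8, 3), matrix(0.1, 3, 3))
  expect_equal(critical_size(params), 3 * 0.2 / 0.7, tolerance = 1e-12)

  closer <- cov_params(rep(1, 3), rep(0.8, 3), matrix(0.79, 3, 3))
  expect_gt(critical_size(closer), critical_size(params))
  degenerate <- cov_params(rep(1, 3), rep(0.8, 3), matrix(0.8, 3, 3))
  expect_error(critical_size(degenerate), "indistinguishable")

  two <- cov_params(rep(1, 2), rep(0.8, 2), matrix(0.1, 2, 2))
  expect_true(isTRUE(attr(critical_size(two), "size_determined")))

  # non-exchangeable: the neglected-term ratio shrinks with n
  set.seed(5008)
  gen <- random_params(3)
  r1 <- critical_size(gen, n = 100)
  r2 <- critical_size(gen, n = 10000)
  expect_gt(r1, r2)
})

test_that("representative distances follow the closed forms", {
  lay <- pop_layout(c(5, 10))
  set.seed(5009)
  adj <- mean_adjust(random_params(2), lay)$params
  sol <- solve_reduced(build_reduced(adj, lay))
  j <- setdiff(1:2, sol$trivial_index)
  expect_equal(representative_distance(sol, j, c("P1", "P2")),
               sqrt(10 / (5 * 15)) + sqrt(5 / (10 * 15)), tolerance = 1e-10)
  expect_error(representative_distance(sol, sol$trivial_index, c(1, 2)),
               "trivial")

  # populations with identical parameter rows are at distance zero
  K <- 3
  d <- matrix(0.1, K, K); d[1, 2] <- d[2, 1] <- 0.1
  params <- cov_params(rep(1, K), c(0.5, 0.5, 0.8), d)
  layq <- pop_layout(c(10, 10, 30))
  solq <- solve_reduced(build_reduced(mean_adjust(params, layq)$params, layq))
  # P1 and P2 are exchangeable; on axes contrasting them with P3 they coincide
  nt <- setdiff(1:3, solq$trivial_index)
  dmin <- min(vapply(nt, function(j)
    representative_distance(solq, j, c("P1", "P2")), 0))
  expect_lt(dmin, 1e-8)
})
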