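# shared fixtures and oracles, all built in code

# random valid raw parameters via a random allele-frequency model:
# psi = scaled A A' guarantees PSD and the frequency-variance bound,
# so the implied full genotype covariance is PSD by construction
random_params <- function(K) {
  mu <- runif(K, 0.2, 0.8)
  A <- matrix(rnorm(K * K), K)
  psi <- crossprod(A)
  cap <- 0.9 * min(mu * (1 - mu))
  psi <- psi * (cap / max(diag(psi))) * runif(1, 0.1, 1)
  freq_to_cov(afreq_model(mu, psi))
}

random_layout <- function(K, n_max = 300) {
  sizes <- sample(2:max(2, n_max %/% K), K, replace = TRUE)
  pop_layout(sizes)
}

# parameters of the unbalanced three-population example
# (sizes 5/10/100, variance 1, within-covariance 0.8, between 0.1)
unbalanced3 <- function() {
  list(layout = pop_layout(c(5, 10, 100)),
       params = cov_params(rep(1, 3), rep(0.8, 3), matrix(0.1, 3, 3)))
}

# five populations: a close triple (P1-P3) and two distant ones (P4, P5)
five_pop <- function() {
  d <- matrix(0, 5, 5)
  d[1, 2:5] <- c(0.7, 0.7, 0.10, 0.11)
  d[2, 3:5] <- c(0.7, 0.13, 0.14)
  d[3, 4:5] <- c(0.14, 0.09)
  d[4, 5] <- 0.17
  d <- d + t(d)
  list(layout = pop_layout(c(100, 110, 120, 130, 140)),
       params = cov_params(rep(1, 5), c(0.8, 0.73, 0.75, 0.9, 0.91), d))
}

# dense-oracle spectrum: eigenvalues of the explicitly built adjusted matrix
full_spectrum <- function(params, layout) {
  adj <- mean_adjust(params, layout)$params
  eigen(build_full_cov(adj, layout), symmetric = TRUE, only.values = TRUE)$values
}

# reduced-route spectrum: reduced eigenvalues plus the small eigenvalues
reduced_spectrum <- function(params, layout) {
  adj <- mean_adjust(params, layout)$params
  sol <- solve_reduced(build_reduced(adj, layout))
  small <- small_eigenvalues(params, layout)
  sort(c(sol$values, rep(small$value, small$multiplicity)), decreasing = TRUE)
}

# textbook Cochran-Armitage trend chi-square from a 2 x 3 count table
# (rows: cases, controls; columns: genotypes 0, 1, 2), scores s = (0, 1, 2)
catt_from_table <- function(cases, controls) {
  s <- c(0, 1, 2)
  n <- cases + controls
  N <- sum(n)
  R <- sum(cases)
  A <- sum(s * cases)                    # sum of scores over cases
  B <- sum(s * n)                        # sum of scores overall
  C2 <- sum(s^2 * n)
  N * (A - B * R / N)^2 / ((C2 - B^2 / N) * R * (N - R) / N)
}

# expand a 2 x 3 genotype count table into (g, y) vectors
expand_table <- function(cases, controls) {
  g <- c(rep(0:2, cases), rep(0:2, controls))
  y <- c(rep(1, sum(cases)), rep(0, sum(controls)))
  list(g = g, y = y)
}
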