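#' Allele-frequency model for K populations
#'
#' The populations are characterised by the mean \eqn{\mu_s} and the K x K
#' variance-covariance matrix \eqn{\psi} of the random vector of allele
#' frequencies \eqn{(f_1, \dots, f_K)} at a randomly chosen marker.
#'
#' @param mu Numeric vector of mean allele frequencies, one per population,
#'   each in \[0, 1\].
#' @param psi K x K symmetric positive semidefinite matrix of allele-frequency
#'   variances/covariances; each diagonal entry must satisfy
#'   \eqn{\psi_{ss} \le \mu_s (1 - \mu_s)} (a frequency supported on \[0, 1\]
#'   cannot have larger variance given its mean).
#' @param labels Optional population labels.
#' @return An object of class `afreq_model`.
#' @seealso [freq_to_cov()], [bn_freq_model()]
#' @export
afreq_model <- function(mu, psi, labels = NULL) {
  K <- length(mu)
  psi <- as.matrix(psi)
  if (any(mu < 0 | mu > 1)) stop("allele-frequency means must lie in [0, 1]")
  if (!all(dim(psi) == K)) stop("'psi' must be K x K")
  if (max(abs(psi - t(psi))) > 1e-8) stop("'psi' must be symmetric")
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1)) stop("'psi' must be positive semidefinite")
  if (any(diag(psi) > mu * (1 - mu) + 1e-12))
    stop("psi_ss exceeds mu_s (1 - mu_s): not a valid frequency variance")
  if (is.null(labels)) labels <- paste0("P", seq_len(K))
  structure(list(mu = mu, psi = psi, labels = as.character(labels)),
            class = "afreq_model")
}

#' Allele-frequency moments implied by the Balding-Nichols model
#'
#' Under the Balding-Nichols model, the allele frequency of population `s` is
#' drawn as \eqn{f_s \sim Beta(p (1-F_s)/F_s, (1-p)(1-F_s)/F_s)} around an
#' ancestral frequency `p`, giving \eqn{E[f_s | p] = p} and
#' \eqn{Var(f_s | p) = F_s p (1-p)}, with populations conditionally
#' independent given `p`. With `p` itself uniform on `(p_lo, p_hi)`, the
#' marginal moments are
#' \eqn{\mu_s = E[p]}, \eqn{\psi_{ss} = F_s E[p(1-p)] + Var(p)} and
#' \eqn{\psi_{st} = Var(p)} for \eqn{s \ne t}.
#'
#' @param Fst Numeric vector of differentiation parameters, one per
#'   population, each in \[0, 1).
#' @param p_range Support of the uniform ancestral frequency (default
#'   `c(0.1, 0.9)`).
#' @param labels Optional population labels.
#' @return An `afreq_model` with the implied moments.
#' @export
bn_freq_model <- function(Fst, p_range = c(0.1, 0.9), labels = NULL) {
  if (any(Fst < 0 | Fst >= 1)) stop("'Fst' must lie in [0, 1)")
  mp <- mean(p_range)
  vp <- diff(p_range)^2 / 12
  ep1p <- mp * (1 - mp) - vp          # E[p(1-p)] = E[p] - E[p^2]
  K <- length(Fst)
  psi <- matrix(vp, K, K)
  diag(psi) <- Fst * ep1p + vp
  afreq_model(rep(mp, K), psi, labels = labels)
}

#' Genotype variance-covariance parameters
#'
#' Container for the parameter triple of the structured genotype covariance:
#' `sigma2` (\eqn{\sigma_s^2}, variance of an individual's allele count),
#' `c` (\eqn{c_s}, covariance of two distinct individuals from the same
#' population) and `d` (\eqn{d_{st}}, covariance of individuals from
#' different populations). The `d` matrix stores \eqn{c_s} on its diagonal,
#' the convention used throughout the reduced eigen-equation; the `c` element
#' exposes it separately.
#'
#' @param sigma2 Numeric vector of per-population variances.
#' @param c Numeric vector of within-population covariances.
#' @param d K x K symmetric matrix of between-population covariances; its
#'   diagonal is ignored and overwritten with `c`.
#' @param adjusted Logical flag: `FALSE` for raw parameters, `TRUE` for
#'   parameters of the per-marker mean-adjusted genotype vector.
#' @param labels Optional population labels.
#' @return An object of class `cov_params`.
#' @export
cov_params <- function(sigma2, c, d = matrix(0, length(sigma2), length(sigma2)),
                       adjusted = FALSE, labels = NULL) {
  K <- length(sigma2)
  if (length(c) != K) stop("'sigma2' and 'c' lengths differ")
  d <- as.matrix(d)
  if (!all(dim(d) == K)) stop("'d' must be K x K")
  if (max(abs(d - t(d))) > 1e-8) stop("'d' must be symmetric")
  diag(d) <- c
  if (!adjusted && any(sigma2 - c < -1e-9))
    stop("raw parameters require sigma2_s >= c_s")
  if (is.null(labels)) labels <- paste0("P", seq_len(K))
  dimnames(d) <- list(labels, labels)
  structure(list(sigma2 = stats::setNames(sigma2, labels),
                 c = stats::setNames(c, labels),
                 d = d, adjusted = adjusted, labels = as.character(labels)),
            class = "cov_params")
}

#' @export
print.cov_params <- function(x, digits = 4, ...) {
  cat(if (x$adjusted) "Mean-adjusted" else "Raw",
      "genotype variance-covariance parameters (K =", length(x$sigma2), ")\n")
  tab <- rbind(sigma2 = x$sigma2, c = x$c)
  print(round(tab, digits))
  cat("d (between-population covariances, diagonal = c):\n")
  print(round(x$d, digits))
  invisible(x)
}

#' Genotype covariance parameters implied by an allele-frequency model
#'
#' For a diploid genotype \eqn{X | f \sim Binomial(2, f_s)} with individuals
#' conditionally independent given the frequency vector, the law of total
#' (co)variance gives
#' \deqn{\sigma_s^2 = 2\mu_s(1-\mu_s) + 2\psi_{ss}, \quad
#'       c_s = 4\psi_{ss}, \quad d_{st} = 4\psi_{st}.}
#'
#' @param model An [afreq_model()].
#' @return Raw [cov_params()].
#' @examples
#' freq_to_cov(afreq_model(0.5, matrix(0, 1, 1)))   # sigma2 = 0.5, c = 0
#' @export
freq_to_cov <- function(model) {
  if (!inherits(model, "afreq_model")) stop("'model' must be an afreq_model")
  mu <- model$mu
  psi <- model$psi
  cov_params(sigma2 = 2 * mu * (1 - mu) + 2 * diag(psi),
             c = 4 * diag(psi), d = 4 * psi,
             adjusted = FALSE, labels = model$labels)
}

#' Per-marker mean adjustment of the covariance parameters
#'
#' Centering every marker across individuals (subtracting the grand
#' individual mean) removes the single large co-variation eigenvalue that
#' reflects the overall correlation of all individuals rather than
#' structure. The adjusted parameters are
#' \deqn{\tilde\sigma_s^2 = \sigma_s^2 - 2 r_s + g,\quad
#'       \tilde c_s = c_s - 2 r_s + g,\quad
#'       \tilde d_{st} = d_{st} - r_s - r_t + g,}
#' with \eqn{r_s = (\sigma_s^2 + (n_s-1) c_s + \sum_{t \ne s} n_t d_{st})/n}
#' (covariance of an individual in `s` with the grand mean) and
#' \eqn{g = (\sum_t n_t \sigma_t^2 + \sum_t n_t (n_t-1) c_t +
#' \sum_{t \ne u} n_t n_u d_{tu})/n^2} (variance of the grand mean).
#' The within-population spread is untouched:
#' \eqn{\tilde\sigma_s^2 - \tilde c_s = \sigma_s^2 - c_s} exactly, and the
#' adjusted parameters satisfy the zero-sum identity
#' \eqn{(\tilde\sigma_t^2-\tilde c_t) + n_t \tilde c_t +
#' \sum_{s\ne t} n_s \tilde d_{st} = 0} for every `t`, which forces zero row
#' sums of the reduced matrix.
#'
#' @param params Raw [cov_params()].
#' @param layout A [pop_layout()] with matching K.
#' @return A list with elements `params` (adjusted [cov_params()]), `r`
#'   (per-population covariance with the grand mean) and `g` (variance of the
#'   grand mean).
#' @examples
#' adj <- mean_adjust(cov_params(1, 0.8), pop_layout(10))
#' adj$params$sigma2 + 9 * adj$params$c   # adjusted large eigenvalue: 0
#' @export
mean_adjust <- function(params, layout) {
  stopifnot(inherits(params, "cov_params"), inherits(layout, "pop_layout"))
  if (params$adjusted) stop("'params' are already mean-adjusted")
  K <- length(params$sigma2)
  if (K != layout$K) stop("K mismatch between 'params' and 'layout'")
  n <- layout$n
  ns <- layout$sizes
  excess <- params$sigma2 - params$c           # sigma_s^2 - c_s
  r <- (excess + drop(params$d %*% ns)) / n
  g <- (sum(ns * excess) + drop(ns %*% params$d %*% ns)) / n^2
  dt <- params$d - outer(r, r, `+`) + g
  adj <- cov_params(sigma2 = params$sigma2 - 2 * r + g,
                    c = params$c - 2 * r + g,
                    d = dt, adjusted = TRUE, labels = params$labels)
  list(params = adj, r = stats::setNames(r, params$labels), g = g)
}

#' Explicit n x n block covariance matrix
#'
#' Builds the full variance-covariance matrix of the genotype vector: for
#' population `s` the diagonal block is
#' \eqn{(\sigma_s^2 - c_s) I + c_s J} and the off-diagonal block between
#' `s` and `t` is \eqn{d_{st} J} (J the all-ones matrix). This dense
#' constructor is the brute-force oracle for the reduced solver and is
#' capped in size: use [solve_reduced()] for anything large.
#'
#' @param params [cov_params()] (raw or adjusted).
#' @param layout A [pop_layout()].
#' @param max_n Size cap (default 2000); exceeding it is an error.
#' @return A symmetric `n x n` matrix.
#' @export
build_full_cov <- function(params, layout, max_n = 2000) {
  stopifnot(inherits(params, "cov_params"), inherits(layout, "pop_layout"))
  if (length(params$sigma2) != layout$K) stop("K mismatch")
  if (layout$n > max_n)
    stop("n = ", layout$n, " exceeds the dense-oracle cap (", max_n,
         "); use the reduced solver")
  pop <- rep(seq_len(layout$K), layout$sizes)
  V <- params$d[pop, pop, drop = FALSE]
  diag(V) <- params$sigma2[pop]
  dimnames(V) <- NULL
  V
}

#' Small (within-population) eigenvalues
#'
#' The within-population contrasts contribute the eigenvalue
#' \eqn{\sigma_s^2 - c_s} with multiplicity \eqn{n_s - 1} for each
#' population; these are unchanged by the mean adjustment.
#'
#' @param params [cov_params()] (raw or adjusted; the difference is
#'   invariant).
#' @param layout A [pop_layout()].
#' @return A data frame with columns `population`, `value`, `multiplicity`.
#' @export
small_eigenvalues <- function(params, layout) {
  stopifnot(inherits(params, "cov_params"), inherits(layout, "pop_layout"))
  data.frame(population = params$labels,
             value = unname(params$sigma2 - params$c),
             multiplicity = layout$sizes - 1L,
             row.names = NULL)
}
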