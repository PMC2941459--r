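#' Reduced K x K eigen-system
#'
#' The large (between-population) eigenpairs of the mean-adjusted n x n
#' genotype covariance have eigenvectors that are piecewise constant within
#' populations, with one coefficient \eqn{a_s} per population. Substituting
#' that form reduces the eigenproblem to the K x K equation
#' \eqn{R a = \lambda a} with
#' \deqn{R_{ss} = n_s \tilde c_s + (\tilde\sigma_s^2 - \tilde c_s), \qquad
#'       R_{st} = n_t \tilde d_{st} \ (s \ne t).}
#' The zero-sum identity of the adjusted parameters makes every row of `R`
#' sum to zero. `R` is not symmetric; the similarity transform
#' \eqn{B = S R S^{-1}} with \eqn{S = diag(\sqrt{n_s})} yields the symmetric
#' \eqn{B_{st} = \sqrt{n_s n_t}\, \tilde d_{st} +
#' \delta_{st}(\tilde\sigma_s^2 - \tilde c_s)} used by the solver.
#'
#' @param adj Mean-adjusted [cov_params()] (as returned in
#'   `mean_adjust(...)$params`).
#' @param layout A [pop_layout()].
#' @return An object of class `reduced_system`: list with `R`, `B`, `layout`,
#'   `params`.
#' @export
build_reduced <- function(adj, layout) {
  stopifnot(inherits(adj, "cov_params"), inherits(layout, "pop_layout"))
  if (!adj$adjusted)
    stop("parameters are raw; apply mean_adjust() before build_reduced()")
  if (length(adj$sigma2) != layout$K) stop("K mismatch")
  sys <- reduced_system_core(adj$d, adj$sigma2 - adj$c, layout$sizes)
  structure(c(sys, list(layout = layout, params = adj)),
            class = "reduced_system")
}

# core constructor on plain numerics; sizes may be non-integer weights
# (used by the asymptotic solver with w_s in place of n_s)
reduced_system_core <- function(dtil, excess, sizes) {
  R <- sweep(dtil, 2, sizes, `*`)
  diag(R) <- diag(R) + excess
  sq <- sqrt(sizes)
  B <- dtil * outer(sq, sq)
  diag(B) <- diag(B) + excess
  list(R = R, B = (B + t(B)) / 2)
}

#' Solve the reduced eigen-equation for the axes of variation
#'
#' Solves the symmetric form \eqn{B b = \lambda b}, maps back to
#' per-population coefficients \eqn{a_s = b_s / \sqrt{n_s}} (so that
#' \eqn{\sum_s n_s a_s^2 = 1}), orders eigenvalues in decreasing order, and
#' identifies the trivial solution \eqn{\lambda = 0} with constant
#' coefficients that every adjusted system possesses. All non-trivial axes
#' satisfy the zero-sum constraint \eqn{\sum_s n_s a_s = 0}. The sign of each
#' axis is fixed so that its coefficient of largest magnitude is positive;
#' ties between equal eigenvalues are broken by the ascending population
#' index of the dominant coefficient.
#'
#' @param system A `reduced_system` from [build_reduced()].
#' @param zero_tol Relative tolerance for detecting the zero eigenvalue
#'   (default `1e-9` times the largest absolute eigenvalue).
#' @return An object of class `reduced_eigen`: list with `values` (K
#'   eigenvalues, decreasing), `coef` (K x K matrix, rows = populations,
#'   columns = axes), `trivial_index`, `layout`.
#' @export
solve_reduced <- function(system, zero_tol = 1e-9) {
  stopifnot(inherits(system, "reduced_system"))
  sol <- solve_reduced_core(system$B, system$layout$sizes, zero_tol)
  sol$layout <- system$layout
  dimnames(sol$coef) <- list(system$layout$labels,
                             paste0("axis", seq_len(ncol(sol$coef))))
  sol
}

solve_reduced_core <- function(B, sizes, zero_tol = 1e-9) {
  K <- nrow(B)
  es <- eigen(B, symmetric = TRUE)
  vals <- es$values                       # decreasing
  a <- es$vectors / sqrt(sizes)           # rows scaled: a_s = b_s / sqrt(n_s)
  # sign convention: dominant coefficient positive; on magnitude ties the
  # lowest population index decides, so mirrored solutions are reproducible
  for (j in seq_len(K)) {
    i <- which(abs(a[, j]) >= (1 - 1e-8) * max(abs(a[, j])))[1]
    if (a[i, j] < 0) a[, j] <- -a[, j]
  }
  # tie-break within numerically equal eigenvalues
  if (K > 1) {
    scale <- max(abs(vals), 1e-300)
    grp <- cumsum(c(1, diff(vals) < -1e-9 * scale))
    dom <- apply(abs(a), 2, which.max)
    ord <- order(grp, dom)
    vals <- vals[ord]
    a <- a[, ord, drop = FALSE]
  }
  # relative to the largest eigenvalue, floored at 1 so that a system whose
  # only eigenvalue is the trivial zero (K = 1) is still recognised
  scale <- max(abs(vals), 1)
  zero <- which(abs(vals) < zero_tol * scale)
  trivial <- NA_integer_
  if (length(zero) == 1) {
    trivial <- zero
  } else if (length(zero) > 1) {
    # among (near-)zero eigenvalues, the trivial one has constant coefficients
    flat <- vapply(zero, function(j)
      diff(range(a[, j])) / max(abs(a[, j])), 0)
    trivial <- zero[which.min(flat)]
  }
  structure(list(values = vals, coef = a, trivial_index = trivial),
            class = "reduced_eigen")
}

#' @export
print.reduced_eigen <- function(x, digits = 4, ...) {
  cat("Axes of variation (reduced eigen-solution)\n")
  cat("Eigenvalues:", paste(signif(x$values, digits), collapse = ", "), "\n")
  if (!is.na(x$trivial_index))
    cat("Trivial (zero, constant) solution: axis", x$trivial_index, "\n")
  print(round(x$coef, digits))
  invisible(x)
}

#' Non-trivial axes of a reduced eigen-solution
#'
#' @param sol A `reduced_eigen` object.
#' @return The coefficient matrix without the trivial column, columns
#'   renumbered `axis1 ... axis(K-1)` in decreasing eigenvalue order, with the
#'   eigenvalues attached as attribute `"values"`.
#' @export
nontrivial_axes <- function(sol) {
  stopifnot(inherits(sol, "reduced_eigen"))
  keep <- setdiff(seq_along(sol$values), sol$trivial_index)
  a <- sol$coef[, keep, drop = FALSE]
  colnames(a) <- paste0("axis", seq_len(ncol(a)))
  attr(a, "values") <- sol$values[keep]
  a
}

#' Two-population closed form
#'
#' With K = 2 the single non-trivial axis is fully determined by the
#' constraints \eqn{n_1 a_1 + n_2 a_2 = 0} and \eqn{n_1 a_1^2 + n_2 a_2^2 = 1}:
#' \eqn{a = (\sqrt{n_2 / (n_1 n)}, -\sqrt{n_1 / (n_2 n)})} up to sign. It
#' depends only on the sample-size ratio, not on the covariance parameters.
#' The corresponding large eigenvalue is \eqn{-n \tilde d_{12}}.
#'
#' @param layout A two-population [pop_layout()].
#' @param adj Mean-adjusted [cov_params()] (needed only for the eigenvalue).
#' @return List with `value` (the non-trivial eigenvalue) and `coef`
#'   (length-2 coefficient vector, sign-fixed as in [solve_reduced()]).
#' @export
two_pop_closed_form <- function(layout, adj) {
  stopifnot(inherits(layout, "pop_layout"))
  if (layout$K != 2) stop("closed form requires exactly two populations")
  if (!adj$adjusted) stop("parameters must be mean-adjusted")
  n1 <- layout$sizes[1]; n2 <- layout$sizes[2]; n <- layout$n
  a <- c(sqrt(n2 / (n1 * n)), -sqrt(n1 / (n2 * n)))
  if (a[which.max(abs(a))] < 0) a <- -a
  list(value = -n * adj$d[1, 2], coef = stats::setNames(a, layout$labels))
}

#' Asymptotic (large-n) form of the reduced eigen-equation
#'
#' As all sample sizes grow with fixed proportions \eqn{w_s}, the large
#' eigenvalues grow linearly in n while the coefficient pattern converges.
#' The limit solves \eqn{A a = \Lambda a} with \eqn{A_{st} = w_t \tilde
#' d_{st}} (\eqn{\tilde d_{ss} \equiv \tilde c_s}), where the adjusted
#' covariances are computed in the n-to-infinity limit: \eqn{r_s = \sum_t
#' w_t d_{st}} and \eqn{g = \sum_{t,u} w_t w_u d_{tu}}, dropping the O(1/n)
#' diagonal corrections. The limiting coefficients do not depend on the
#' variances \eqn{\sigma_s^2} at all; the per-population term neglected at a
#' finite size n is \eqn{\epsilon_s = (\sigma_s^2 - c_s)/n}.
#'
#' @param params Raw [cov_params()].
#' @param proportions Per-population weights summing to 1.
#' @param n Optional finite sample size at which to report the neglected
#'   terms.
#' @return List with `A`, `unit_values` (eigenvalues of A; the full-matrix
#'   large eigenvalues behave as `n * unit_values`), `coef` (K x K, rows =
#'   populations, normalised to \eqn{\sum_s w_s a_s^2 = 1}), `trivial_index`
#'   and `neglected` (\eqn{\epsilon_s}, or NULL).
#' @export
asymptotic_solve <- function(params, proportions, n = NULL) {
  stopifnot(inherits(params, "cov_params"))
  if (params$adjusted) stop("'params' must be raw; the limit adjusts internally")
  w <- proportions
  if (abs(sum(w) - 1) > 1e-8) stop("'proportions' must sum to 1")
  if (length(w) != length(params$sigma2)) stop("K mismatch")
  r <- drop(params$d %*% w)
  g <- drop(w %*% params$d %*% w)
  dt <- params$d - outer(r, r, `+`) + g
  A <- sweep(dt, 2, w, `*`)
  sq <- sqrt(w)
  B <- dt * outer(sq, sq)
  sol <- solve_reduced_core((B + t(B)) / 2, w)
  dimnames(sol$coef) <- list(params$labels,
                             paste0("axis", seq_len(ncol(sol$coef))))
  list(A = A, unit_values = sol$values, coef = sol$coef,
       trivial_index = sol$trivial_index,
       neglected = if (!is.null(n)) (params$sigma2 - params$c) / n)
}

#' Critical sample size for the asymptotic pattern
#'
#' In the exchangeable case (equal \eqn{\sigma^2}, equal c, equal d across
#' all population pairs) the neglected within-population term is comparable
#' to the smallest non-trivial eigenvalue of the asymptotic equation at the
#' critical size
#' \deqn{n^* = K (\sigma^2 - c) / (c - d),}
#' which diverges as the populations become indistinguishable (d close to
#' c). For non-exchangeable parameters no single closed form exists; given a
#' concrete `n` the function instead returns the ratio of the largest
#' neglected term to the smallest non-trivial asymptotic eigenvalue times n
#' (a ratio well below 1 indicates the pattern is essentially asymptotic).
#' With two populations the non-trivial axis is determined by the sample
#' sizes alone, so the notion of a critical size does not apply and the
#' result carries attribute `size_determined = TRUE`.
#'
#' @param params Raw [cov_params()].
#' @param proportions Population proportions (only used in the
#'   non-exchangeable case; default equal).
#' @param n Finite sample size for the general-case ratio.
#' @return The critical size `n*` (exchangeable case) or the neglected-term
#'   ratio at `n` (general case).
#' @export
critical_size <- function(params, proportions = NULL, n = NULL) {
  stopifnot(inherits(params, "cov_params"))
  if (params$adjusted) stop("'params' must be raw")
  K <- length(params$sigma2)
  off <- params$d[upper.tri(params$d)]
  sym <- K >= 2 &&
    diff(range(params$sigma2)) < 1e-12 &&
    diff(range(params$c)) < 1e-12 &&
    (length(off) == 0 || diff(range(off)) < 1e-12)
  if (sym) {
    cc <- params$c[[1]]; dd <- if (length(off)) off[1] else 0
    if (cc <= dd)
      stop("c <= d: populations are indistinguishable, no finite critical size")
    out <- K * (params$sigma2[[1]] - cc) / (cc - dd)
  } else {
    if (is.null(n))
      stop("non-exchangeable parameters: supply 'n' for the neglected-term ratio")
    if (is.null(proportions)) proportions <- rep(1 / K, K)
    sol <- asymptotic_solve(params, proportions, n = n)
    lam <- sol$unit_values[setdiff(seq_len(K), sol$trivial_index)]
    out <- max(sol$neglected) / (n * min(abs(lam)))
  }
  if (K == 2) attr(out, "size_determined") <- TRUE
  out
}

#' Distance between two populations on one axis
#'
#' The separation \eqn{|a_s - a_t|} of two representative points on a
#' non-trivial axis; the quantity whose n-dependence traces the approach to
#' the asymptotic pattern.
#'
#' @param sol A `reduced_eigen` object.
#' @param axis Axis index (column of `sol$coef`); requesting the trivial
#'   axis is an error.
#' @param pair Two population labels or indices.
#' @return The absolute coefficient difference.
#' @export
representative_distance <- function(sol, axis, pair) {
  stopifnot(inherits(sol, "reduced_eigen"))
  if (!is.na(sol$trivial_index) && axis == sol$trivial_index)
    stop("axis ", axis, " is the trivial (constant) solution")
  if (is.character(pair)) pair <- match(pair, rownames(sol$coef))
  if (anyNA(pair) || length(pair) != 2) stop("'pair' must name two populations")
  abs(sol$coef[pair[1], axis] - sol$coef[pair[2], axis])
}
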