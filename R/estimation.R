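#' Sample variance-covariance matrix of individuals across markers
#'
#' Treats each marker as one observation of the n-dimensional genotype
#' vector and computes the n x n covariance across markers, centering each
#' individual at its own across-marker mean. Missing genotypes are handled
#' pairwise-complete. Markers monomorphic across the whole sample carry no
#' information about covariance and are dropped with a message.
#'
#' With `marker_adjust = TRUE` every marker row is first centered across
#' individuals (the per-marker mean adjustment); the eigenvectors of the
#' resulting matrix are the Eigenstrat-style sample eigenvectors.
#'
#' @param G Marker x individual genotype matrix (allele counts 0/1/2, NA for
#'   missing).
#' @param marker_adjust Center each marker across individuals first
#'   (default `FALSE`).
#' @return Object of class `sample_cov`: list with `C` (n x n), `centering`,
#'   `n_markers` (markers used), `n_dropped` (monomorphic markers dropped).
#' @export
sample_cov <- function(G, marker_adjust = FALSE) {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop("at least two markers are required")
  all_miss <- colSums(!is.na(G)) == 0
  if (any(all_miss))
    stop("individual(s) with all genotypes missing: ",
         paste(which(all_miss), collapse = ", "))
  rng <- apply(G, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) diff(range(x)) else 0
  })
  mono <- rng == 0
  n_dropped <- sum(mono)
  n <- ncol(G)
  if (n_dropped == nrow(G)) {
    # no polymorphic marker carries covariance information
    message("all ", n_dropped, " markers are monomorphic; covariance is zero")
    return(structure(list(C = matrix(0, n, n,
                                     dimnames = list(colnames(G), colnames(G))),
                          centering = if (marker_adjust)
                            "individual+marker" else "individual",
                          n_markers = 0L, n_dropped = n_dropped),
                     class = "sample_cov"))
  }
  if (n_dropped) {
    message("dropping ", n_dropped, " monomorphic marker(s)")
    G <- G[!mono, , drop = FALSE]
    if (nrow(G) < 2) stop("fewer than two polymorphic markers remain")
  }
  if (marker_adjust) G <- G - rowMeans(G, na.rm = TRUE)
  if (anyNA(G)) {
    C <- stats::cov(G, use = "pairwise.complete.obs")
  } else {
    # complete data: centered cross-product (much faster than pairwise cov)
    Gc <- sweep(G, 2, colMeans(G))
    C <- crossprod(Gc) / (nrow(G) - 1)
    dimnames(C) <- if (!is.null(colnames(G))) list(colnames(G), colnames(G))
  }
  structure(list(C = C,
                 centering = if (marker_adjust) "individual+marker" else "individual",
                 n_markers = nrow(G), n_dropped = n_dropped),
            class = "sample_cov")
}

#' Estimate variance-covariance parameters by block averaging
#'
#' With known population memberships each parameter is estimated by the
#' average of the corresponding cells of the sample covariance matrix:
#' diagonal cells within a population for \eqn{\hat\sigma_s^2}, off-diagonal
#' within-population cells for \eqn{\hat c_s}, and cross-population cells
#' for \eqn{\hat d_{st}}. A standard error is attached to each entry as the
#' standard deviation of the averaged cells divided by the square root of
#' their count; the cells share markers and are therefore correlated, so
#' these SEs are an approximation (typically an underestimate).
#'
#' @param C A [sample_cov()] object (or bare n x n matrix).
#' @param labels Population membership, one entry per individual.
#' @return Object of class `param_estimates`: a raw [cov_params()] plus
#'   `se` (list with `sigma2`, `c`, `d`) and `cells` (cell counts).
#'   Populations with a single member have `c` recorded as NA and are listed
#'   in attribute `"singletons"` (with a warning).
#' @export
estimate_params <- function(C, labels) {
  if (inherits(C, "sample_cov")) C <- C$C
  C <- as.matrix(C)
  labels <- as.character(labels)
  if (length(labels) != nrow(C)) stop("one label per individual is required")
  layout <- layout_from_labels(labels)
  idx <- pop_index(labels, layout)
  K <- layout$K
  blk <- function(cells) {
    c(mean = mean(cells),
      se = if (length(cells) > 1) stats::sd(cells) / sqrt(length(cells)) else 0,
      count = length(cells))
  }
  sigma2 <- cvec <- s_se <- c_se <- numeric(K)
  d <- d_se <- cnt_d <- matrix(0, K, K)
  singles <- character(0)
  for (s in seq_len(K)) {
    di <- blk(diag(C)[idx[[s]]])
    sigma2[s] <- di["mean"]; s_se[s] <- di["se"]
    Cs <- C[idx[[s]], idx[[s]], drop = FALSE]
    off <- Cs[upper.tri(Cs)]
    if (length(off) == 0) {
      cvec[s] <- NA_real_; c_se[s] <- NA_real_
      singles <- c(singles, layout$labels[s])
    } else {
      wi <- blk(off)
      cvec[s] <- wi["mean"]; c_se[s] <- wi["se"]
    }
    for (t in seq_len(K)) {
      if (t <= s) next
      cr <- blk(as.vector(C[idx[[s]], idx[[t]], drop = FALSE]))
      d[s, t] <- d[t, s] <- cr["mean"]
      d_se[s, t] <- d_se[t, s] <- cr["se"]
      cnt_d[s, t] <- cnt_d[t, s] <- cr["count"]
    }
  }
  if (length(singles))
    warning("singleton population(s) with undefined within-covariance c: ",
            paste(singles, collapse = ", "))
  est <- cov_params(sigma2, ifelse(is.na(cvec), 0, cvec), d,
                    adjusted = FALSE, labels = layout$labels)
  est$c[is.na(cvec)] <- NA_real_
  diag(est$d)[is.na(cvec)] <- NA_real_
  out <- structure(
    list(params = est, layout = layout,
         se = list(sigma2 = stats::setNames(s_se, layout$labels),
                   c = stats::setNames(c_se, layout$labels),
                   d = d_se),
         cells = cnt_d),
    class = "param_estimates")
  attr(out, "singletons") <- singles
  out
}

#' @export
print.param_estimates <- function(x, digits = 4, ...) {
  cat("Estimated variance-covariance parameters (block averages)\n")
  tab <- rbind(sigma2 = x$params$sigma2, se = x$se$sigma2,
               c = x$params$c, c_se = x$se$c)
  print(round(tab, digits))
  cat("d (between-population; diagonal = c):\n")
  print(round(x$params$d, digits))
  invisible(x)
}

#' Correlation form of the parameter estimates
#'
#' \eqn{\rho_{st} = \hat d_{st} / \sqrt{\hat\sigma_s^2 \hat\sigma_t^2}} with
#' \eqn{\hat d_{ss} \equiv \hat c_s}; a sample-size-free summary of
#' population proximity (large within-population diagonal entries mean
#' strongly drifted populations; off-diagonal entries measure shared
#' ancestry of pairs).
#'
#' @param est A [estimate_params()] result or a raw [cov_params()].
#' @return K x K correlation matrix.
#' @export
param_correlations <- function(est) {
  p <- if (inherits(est, "param_estimates")) est$params else est
  stopifnot(inherits(p, "cov_params"))
  if (any(!is.finite(p$sigma2)) || any(p$sigma2 <= 0))
    stop("correlations require strictly positive variance estimates")
  sc <- sqrt(p$sigma2)
  p$d / outer(sc, sc)
}

#' Representative points from estimated parameters
#'
#' Runs the full theoretical pipeline on estimated parameters:
#' [mean_adjust()], [build_reduced()], [solve_reduced()], and returns the
#' non-trivial axes. On marker-rich data the points lie at the centroids of
#' the corresponding sample-eigenvector clusters (up to sign and the
#' ordering of nearly tied axes).
#'
#' @param est A [estimate_params()] result.
#' @param layout Optional [pop_layout()]; defaults to the layout the
#'   estimates were computed under.
#' @return Non-trivial axis matrix as in [nontrivial_axes()], with the full
#'   `reduced_eigen` solution attached as attribute `"solution"`.
#' @export
representative_points <- function(est, layout = NULL) {
  stopifnot(inherits(est, "param_estimates"))
  if (is.null(layout)) layout <- est$layout
  if (anyNA(est$params$c))
    stop("within-population covariance undefined for singleton population(s)")
  adj <- mean_adjust(est$params, layout)$params
  sol <- solve_reduced(build_reduced(adj, layout))
  a <- nontrivial_axes(sol)
  attr(a, "solution") <- sol
  a
}

#' Sample principal components of a genotype matrix
#'
#' Eigendecomposition of the marker-adjusted sample covariance
#' ([sample_cov()] with `marker_adjust = TRUE`): the Eigenstrat sample
#' eigenvectors. Vectors are unit-norm over individuals, sorted by
#' decreasing eigenvalue, and sign-fixed so the entry of largest magnitude
#' is positive.
#'
#' @param G Marker x individual genotype matrix.
#' @param m Number of axes to return (at most n).
#' @return List with `vectors` (n x m), `values` (all n eigenvalues,
#'   decreasing) and `n_markers`.
#' @export
sample_pca <- function(G, m = 2) {
  n <- ncol(G)
  if (m > n) stop("cannot extract ", m, " axes from ", n, " individuals")
  sc <- sample_cov(G, marker_adjust = TRUE)
  es <- eigen(sc$C, symmetric = TRUE)
  V <- es$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which(abs(V[, j]) >= (1 - 1e-8) * max(abs(V[, j])))[1]
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(m))
  list(vectors = V, values = es$values, n_markers = sc$n_markers)
}
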