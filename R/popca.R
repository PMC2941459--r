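#' Fit the population-level PCA model to a genotype matrix
#'
#' Estimates the variance-covariance parameters (\eqn{\sigma_s^2, c_s,
#' d_{st}}) of the structured genotype covariance by block-averaging the
#' sample covariance of individuals across markers, mean-adjusts them, and
#' solves the reduced K x K eigen-equation for the axes of variation. The
#' result bundles the parameter estimates (with approximate standard
#' errors), their correlation form, the representative points of the
#' populations on each non-trivial axis, and optionally the Eigenstrat
#' sample eigenvectors for comparison.
#'
#' @param G Marker x individual genotype matrix (0/1/2 allele counts, NA
#'   missing), or a `geno_data` object from [read_geno()].
#' @param labels Population membership per individual (taken from the
#'   `geno_data` object if omitted there).
#' @param sample_pcs Number of sample eigenvectors to compute alongside the
#'   theoretical axes (0 to skip; default `K - 1`).
#' @return Object of class `popca` with components `layout`, `estimates`
#'   ([estimate_params()] result), `correlations`, `adjusted` (mean-adjusted
#'   parameters), `solution` (full `reduced_eigen`), `axes` (non-trivial
#'   representative points), `sample_pca` (or NULL), `n_markers` and `call`.
#' @examples
#' set.seed(1)
#' lay <- pop_layout(c(30, 30))
#' f <- draw_freqs_bn(2000, c(0.05, 0.05))$f
#' fit <- popca(genotypes_from_freqs(f, lay), rep(c("P1", "P2"), each = 30))
#' coef(fit)
#' @export
popca <- function(G, labels = NULL, sample_pcs = NULL) {
  cl <- match.call()
  if (inherits(G, "geno_data")) {
    if (is.null(labels)) labels <- G$labels
    G <- G$G
  }
  if (is.null(labels)) stop("population labels are required")
  G <- as.matrix(G)
  if (length(labels) != ncol(G)) stop("one label per individual is required")
  layout <- layout_from_labels(labels)
  sc <- sample_cov(G)
  est <- estimate_params(sc, labels)
  adj <- mean_adjust(est$params, layout)$params
  sol <- solve_reduced(build_reduced(adj, layout))
  axes <- nontrivial_axes(sol)
  if (is.null(sample_pcs)) sample_pcs <- layout$K - 1L
  spc <- if (sample_pcs > 0) sample_pca(G, m = sample_pcs)
  structure(list(layout = layout, estimates = est,
                 correlations = param_correlations(est),
                 adjusted = adj, solution = sol, axes = axes,
                 sample_pca = spc, labels = as.character(labels),
                 n_markers = sc$n_markers, call = cl),
            class = "popca")
}

#' @export
print.popca <- function(x, digits = 4, ...) {
  cat("Population-level PCA fit\n")
  cat("  populations:", x$layout$K, " individuals:", x$layout$n,
      " markers:", x$n_markers, "\n")
  cat("  non-trivial eigenvalues:",
      paste(signif(attr(x$axes, "values"), digits), collapse = ", "), "\n")
  cat("Representative points (axes of variation):\n")
  a <- x$axes; attributes(a)[c("values", "solution")] <- NULL
  print(round(a, digits))
  invisible(x)
}

#' @export
summary.popca <- function(object, ...) {
  structure(list(fit = object), class = "summary.popca")
}

#' @export
print.summary.popca <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nParameter estimates (block averages, SE in parentheses):\n")
  e <- f$estimates
  tab <- sprintf("%.*f (%.*f)", digits, e$params$sigma2, digits, e$se$sigma2)
  cat("  sigma2:", paste(tab, collapse = "  "), "\n")
  tab <- sprintf("%.*f (%.*f)", digits, e$params$c, digits, e$se$c)
  cat("  c:     ", paste(tab, collapse = "  "), "\n")
  cat("Correlations (diagonal = within-population):\n")
  print(round(f$correlations, digits))
  cat("Small within-population eigenvalue sigma2 - c:\n")
  print(round(e$params$sigma2 - e$params$c, digits))
  invisible(x)
}

#' @export
coef.popca <- function(object, ...) {
  p <- object$estimates$params
  list(sigma2 = p$sigma2, c = p$c, d = p$d)
}

#' popu-Eigenstrat residuals of the fitted data or new data
#'
#' Returns the genotype matrix with per-marker population means removed --
#' the stratification-corrected genotypes used by the popu-Eigenstrat
#' association test.
#'
#' @param object A [popca()] fit.
#' @param G Genotype matrix to residualise (the individuals must match the
#'   fitted labels).
#' @param ... Unused.
#' @return Residual matrix.
#' @export
residuals.popca <- function(object, G, ...) {
  popu_residual(G, object$labels)
}

#' Representative-axis coordinates for (new) labelled individuals
#'
#' Every individual inherits the representative point of its population on
#' each non-trivial axis; useful for overlaying the theoretical pattern on
#' a sample-eigenvector scatter plot.
#'
#' @param object A [popca()] fit.
#' @param newdata Optional vector of population labels (defaults to the
#'   fitted individuals).
#' @param ... Unused.
#' @return Matrix with one row per individual and one column per
#'   non-trivial axis.
#' @export
predict.popca <- function(object, newdata = NULL, ...) {
  labels <- if (is.null(newdata)) object$labels else as.character(newdata)
  i <- match(labels, object$layout$labels)
  if (anyNA(i)) stop("unknown population label(s): ",
                     paste(unique(labels[is.na(i)]), collapse = ", "))
  a <- object$axes; attributes(a)[c("values", "solution")] <- NULL
  a[i, , drop = FALSE]
}

#' Scatter plot of sample eigenvectors with representative points
#'
#' Plots two sample-PC axes with individuals coloured by population and
#' overlays the representative points computed from the estimated
#' parameters (scaled to the unit-norm convention of sample eigenvectors).
#'
#' @param x A [popca()] fit (with `sample_pcs >= max(axes)`).
#' @param axes Which two axes to display (default `c(1, 2)`).
#' @param ... Passed to [plot()].
#' @export
plot.popca <- function(x, axes = c(1, 2), ...) {
  if (is.null(x$sample_pca) || ncol(x$sample_pca$vectors) < max(axes))
    stop("fit does not carry enough sample PCs; refit with sample_pcs >= ",
         max(axes))
  V <- x$sample_pca$vectors[, axes, drop = FALSE]
  pops <- factor(x$labels, levels = x$layout$labels)
  plot(V[, 1], V[, 2], col = as.integer(pops), pch = 1,
       xlab = paste0("sample PC", axes[1]), ylab = paste0("sample PC", axes[2]),
       ...)
  # representative a_s carry weighted norm sum n_s a_s^2 = 1, matching the
  # unit-norm sample eigenvectors' population-block scale directly
  pts <- x$axes[, axes, drop = FALSE]
  graphics::points(pts[, 1], pts[, 2], col = seq_len(x$layout$K),
                   pch = 8, cex = 2, lwd = 2)
  graphics::legend("topright", legend = x$layout$labels,
                   col = seq_len(x$layout$K), pch = 1, bty = "n")
  invisible(x)
}
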