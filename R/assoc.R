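#' popu-Eigenstrat residuals: subtract population means
#'
#' Regressing the K representative PCs (plus the constant) out of a marker
#' row is algebraically identical to projecting onto the orthogonal
#' complement of the span of the population indicator vectors, i.e. to
#' subtracting from each genotype the mean allele count of the individual's
#' population at that marker. This function applies that correction
#' directly; no covariance parameters are needed.
#'
#' @param G Marker x individual genotype matrix (NA allowed; missing entries
#'   are excluded from the population means and stay NA in the output).
#' @param labels Population membership per individual.
#' @return Residual matrix of the same shape; per-marker per-population
#'   residual means are zero.
#' @export
popu_residual <- function(G, labels) {
  G <- as.matrix(G)
  labels <- as.character(labels)
  if (length(labels) != ncol(G)) stop("one label per individual is required")
  layout <- layout_from_labels(labels)
  idx <- pop_index(labels, layout)
  R <- G
  for (s in seq_len(layout$K)) {
    i <- idx[[s]]
    sub <- G[, i, drop = FALSE]
    if (any(rowSums(!is.na(sub)) == 0))
      stop("population ", layout$labels[s],
           " has no observed genotypes at some marker(s)")
    R[, i] <- sub - rowMeans(sub, na.rm = TRUE)
  }
  R
}

#' Residualise markers on sample principal components
#'
#' Removes from each marker row its projection on the constant vector and
#' on each of the supplied orthonormal eigenvectors; the Eigenstrat
#' correction of the genotype.
#'
#' @param G Marker x individual genotype matrix (no missing entries).
#' @param pcs n x L matrix of orthonormal sample eigenvectors (columns).
#' @return Residual matrix; each row is orthogonal to every PC and to the
#'   constant vector.
#' @export
pc_residual <- function(G, pcs) {
  G <- as.matrix(G)
  pcs <- as.matrix(pcs)
  if (nrow(pcs) != ncol(G)) stop("'pcs' rows must match the number of individuals")
  if (anyNA(G)) stop("pc_residual() requires complete genotypes")
  gram <- crossprod(pcs)
  if (max(abs(gram - diag(ncol(pcs)))) > 1e-6)
    stop("'pcs' are not orthonormal (Gram deviation > 1e-6)")
  # remove the constant direction first, then the span of the centred PCs
  Gc <- G - rowMeans(G)
  P <- sweep(pcs, 2, colMeans(pcs))
  qrP <- qr(P)
  if (qrP$rank > 0) {
    Q <- qr.Q(qrP)[, seq_len(qrP$rank), drop = FALSE]
    Gc <- Gc - (Gc %*% Q) %*% t(Q)
  }
  Gc
}

# vectorised trend scan: chi-square = scale * r^2 per marker row
# (scale = N for the plain statistic, N - df_loss for the generalised one)
trend_scan <- function(G, y, df_loss = 0) {
  G <- as.matrix(G)
  N <- length(y)
  if (ncol(G) != N) stop("genotype/phenotype dimension mismatch")
  yc <- y - mean(y)
  sy <- sum(yc^2)
  if (sy == 0) stop("phenotype requires at least one case and one control")
  Gc <- G - rowMeans(G, na.rm = TRUE)
  Gc[is.na(Gc)] <- 0                       # missing: zero contribution
  num <- drop(Gc %*% yc)
  sg <- rowSums(Gc^2)
  testable <- sg > 0
  chi <- rep(NA_real_, nrow(G))
  chi[testable] <- (N - df_loss) * num[testable]^2 / (sg[testable] * sy)
  data.frame(chi2 = chi,
             p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
             direction = ifelse(testable, sign(num), NA_real_),
             testable = testable)
}

#' Armitage trend test
#'
#' The trend chi-square for a 0/1/2-coded genotype against case-control
#' status: \eqn{\chi^2 = N r^2} with `r` the sample correlation between
#' genotype and phenotype, referred to a 1-df chi-square. Identical to the
#' Cochran-Armitage trend statistic with scores (0, 1, 2).
#'
#' @param g Genotype vector (one marker) or marker x individual matrix.
#' @param y Binary phenotype (1 = case, 0 = control).
#' @return Data frame with one row per marker: `chi2`, `p`, `direction`
#'   (sign of the genotype-phenotype correlation) and `testable` (FALSE for
#'   constant genotypes, which are excluded from any rejection-rate
#'   denominator).
#' @examples
#' armitage_trend(c(2, 2, 0, 0), c(1, 1, 0, 0))   # chi2 = 4
#' @export
armitage_trend <- function(g, y) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("at least one case and one control are required")
  trend_scan(g, y, df_loss = 0)
}

#' Generalised Armitage trend test on residualised data
#'
#' The trend statistic applied after stratification correction:
#' \eqn{\chi^2 = (N - df_{loss}) r^2} where `r` correlates the residualised
#' genotype with the phenotype (itself residualised or not, as supplied by
#' the caller). `df_loss` defaults to 0, i.e. the plain \eqn{N r^2}.
#'
#' @param g_res Residualised genotype vector or matrix (markers x
#'   individuals).
#' @param y_res Phenotype vector (raw 0/1 or residualised).
#' @param df_loss Degrees of freedom charged for the removed components.
#' @return As [armitage_trend()].
#' @export
generalized_armitage <- function(g_res, y_res, df_loss = 0) {
  if (is.null(dim(g_res))) g_res <- matrix(g_res, nrow = 1)
  N <- length(y_res)
  yc <- y_res - mean(y_res)
  sy <- sum(yc^2)
  if (sy == 0) stop("phenotype has zero variance")
  Gc <- g_res - rowMeans(g_res, na.rm = TRUE)
  Gc[is.na(Gc)] <- 0
  num <- drop(Gc %*% yc)
  sg <- rowSums(Gc^2)
  testable <- sg > 1e-12
  chi <- rep(NA_real_, nrow(g_res))
  chi[testable] <- (N - df_loss) * num[testable]^2 / (sg[testable] * sy)
  data.frame(chi2 = chi,
             p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
             direction = ifelse(testable, sign(num), NA_real_),
             testable = testable)
}

#' Covariate-adjusted trend test
#'
#' One-degree-of-freedom likelihood-ratio test of the genotype trend term
#' in a logistic regression of case-control status on genotype plus K - 1
#' population indicators.
#'
#' @param g Genotype vector or marker x individual matrix.
#' @param y Binary phenotype.
#' @param labels Population membership per individual.
#' @return As [armitage_trend()]; `direction` is the sign of the genotype
#'   coefficient. Markers with separation or no within-stratum variation are
#'   flagged untestable.
#' @export
covariate_trend <- function(g, y, labels) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("at least one case and one control are required")
  labels <- as.character(labels)
  N <- length(y)
  X0 <- if (length(unique(labels)) > 1)
    stats::model.matrix(~ factor(labels)) else matrix(1, N, 1)
  dev0 <- stats::glm.fit(X0, y, family = stats::binomial())$deviance
  M <- nrow(g)
  chi <- dir <- rep(NA_real_, M)
  testable <- rep(FALSE, M)
  for (m in seq_len(M)) {
    gm <- g[m, ]
    ok <- !is.na(gm)
    if (stats::var(gm[ok]) == 0) next
    X1 <- cbind(X0[ok, , drop = FALSE], g = gm[ok])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X1, y[ok], family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    mu <- fit$fitted.values
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) next   # separation
    d0 <- if (all(ok)) dev0 else
      stats::glm.fit(X0[ok, , drop = FALSE], y[ok],
                     family = stats::binomial())$deviance
    chi[m] <- max(d0 - fit$deviance, 0)
    dir[m] <- sign(fit$coefficients["g"])
    testable[m] <- TRUE
  }
  data.frame(chi2 = chi,
             p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
             direction = dir, testable = testable)
}

#' Stratification-corrected association scan
#'
#' Applies one correction method to a block of markers and tests every
#' marker against the phenotype.
#'
#' Methods: `"none"` (plain Armitage trend), `"popu"` (subtract population
#' means of allele counts, then generalised Armitage), `"eigenstrat"`
#' (regress the top `num_pcs` sample PCs out of the genotype, then
#' generalised Armitage) and `"covariate"` (logistic LRT with population
#' indicators). For the PC-based methods only the genotype is residualised
#' by default, mirroring the correction's definition as an operation on the
#' genotype expansion; set `residualize_phenotype = TRUE` to residualise the
#' phenotype on the same basis as well.
#'
#' @param G Marker x individual genotype matrix.
#' @param y Binary phenotype.
#' @param method One of `"none"`, `"popu"`, `"eigenstrat"`, `"covariate"`.
#' @param labels Population membership (required for `"popu"` and
#'   `"covariate"`).
#' @param pcs Orthonormal sample eigenvectors for `"eigenstrat"`; if NULL
#'   they are computed from `G` itself via [sample_pca()].
#' @param num_pcs Number of sample PCs when `pcs` is NULL (default 2).
#' @param residualize_phenotype Also residualise the phenotype on the
#'   removed basis (default `FALSE`).
#' @param df_loss Degrees of freedom charged in the generalised statistic
#'   (default 0).
#' @return Data frame as [armitage_trend()], one row per marker, with the
#'   method recorded in attribute `"method"`.
#' @export
assoc_scan <- function(G, y, method = c("none", "popu", "eigenstrat", "covariate"),
                       labels = NULL, pcs = NULL, num_pcs = 2,
                       residualize_phenotype = FALSE, df_loss = 0) {
  method <- match.arg(method)
  G <- as.matrix(G)
  res <- switch(
    method,
    none = armitage_trend(G, y),
    covariate = {
      if (is.null(labels)) stop("'labels' required for covariate adjustment")
      covariate_trend(G, y, labels)
    },
    popu = {
      if (is.null(labels)) stop("'labels' required for popu-Eigenstrat")
      Gr <- popu_residual(G, labels)
      yr <- if (residualize_phenotype)
        drop(popu_residual(matrix(y, nrow = 1), labels)) else y
      generalized_armitage(Gr, yr, df_loss = df_loss)
    },
    eigenstrat = {
      if (is.null(pcs)) pcs <- sample_pca(G, m = num_pcs)$vectors
      Gr <- pc_residual(G, pcs)
      yr <- if (residualize_phenotype)
        drop(pc_residual(matrix(y, nrow = 1), pcs)) else y
      generalized_armitage(Gr, yr, df_loss = df_loss)
    })
  attr(res, "method") <- method
  res
}

#' Rejection proportion of an association scan
#'
#' Fraction of testable markers significant at `alpha`; for causal markers,
#' direction-aware power additionally requires the estimated effect
#' direction to match the simulated risk direction (a marker rejected with
#' the disease allele identified as the protective one does not count).
#'
#' @param res Result of [assoc_scan()] or one of the test functions.
#' @param alpha Significance threshold.
#' @param direction Optional vector (or scalar) of true risk directions;
#'   when supplied, only matching rejections are counted.
#' @return Proportion in \[0, 1\] (NA if no marker is testable).
#' @export
rejection_rate <- function(res, alpha = 0.01, direction = NULL) {
  ok <- res$testable
  if (!any(ok)) return(NA_real_)
  hit <- res$p[ok] < alpha
  if (!is.null(direction)) {
    dirv <- rep_len(direction, nrow(res))[ok]
    hit <- hit & res$direction[ok] == dirv
  }
  mean(hit)
}
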