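#' Draw per-marker allele frequencies under the Balding-Nichols model
#'
#' For each marker an ancestral frequency `p` is drawn uniformly on
#' `p_range`, and each population's frequency is drawn independently (given
#' p) from \eqn{Beta(p(1-F_s)/F_s, (1-p)(1-F_s)/F_s)}, so that
#' \eqn{E[f_s|p] = p} and \eqn{Var(f_s|p) = F_s\, p(1-p)}. A zero `F_s` is
#' the degenerate limit \eqn{f_s = p}.
#'
#' @param M Number of markers.
#' @param Fst Differentiation parameter per population (recycled to K if
#'   scalar with `K` supplied).
#' @param K Number of populations (defaults to `length(Fst)`).
#' @param p_range Ancestral-frequency support (default `c(0.1, 0.9)`).
#' @return List with `f` (M x K frequency matrix) and `p` (ancestral
#'   frequencies).
#' @export
draw_freqs_bn <- function(M, Fst, K = length(Fst), p_range = c(0.1, 0.9)) {
  Fst <- rep_len(Fst, K)
  if (any(Fst < 0 | Fst >= 1)) stop("'Fst' must lie in [0, 1)")
  p <- stats::runif(M, p_range[1], p_range[2])
  f <- matrix(0, M, K)
  for (s in seq_len(K)) {
    if (Fst[s] == 0) {
      f[, s] <- p
    } else {
      ratio <- (1 - Fst[s]) / Fst[s]
      f[, s] <- stats::rbeta(M, p * ratio, (1 - p) * ratio)
    }
  }
  colnames(f) <- paste0("P", seq_len(K))
  list(f = f, p = p)
}

#' Genotypes from per-population frequencies under Hardy-Weinberg
#'
#' Each individual's allele count at marker m is
#' \eqn{Binomial(2, f_{m,s})} for its population `s`, independent across
#' individuals and markers given the frequencies.
#'
#' @param f M x K matrix of allele frequencies.
#' @param layout A [pop_layout()].
#' @return M x n integer genotype matrix; individuals are ordered by
#'   population blocks in layout order.
#' @export
genotypes_from_freqs <- function(f, layout) {
  f <- as.matrix(f)
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  if (ncol(f) != layout$K) stop("K mismatch between 'f' and 'layout'")
  M <- nrow(f)
  pop <- rep(seq_len(layout$K), layout$sizes)
  G <- matrix(0L, M, layout$n)
  for (s in seq_len(layout$K)) {
    i <- which(pop == s)
    G[, i] <- stats::rbinom(M * length(i), 2, f[, s])
  }
  G
}

#' Case frequency under the multiplicative risk model
#'
#' With a relative risk `r` per copy of the risk allele and
#' Hardy-Weinberg genotypes in the source population,
#' \eqn{P(g | case) \propto HW(g)\, r^g}, which is again binomial:
#' \eqn{g | case \sim Binomial(2, f')} with
#' \deqn{f' = r f / (1 - f + r f).}
#'
#' @param f Allele frequency (vector allowed).
#' @param r Relative risk per risk-allele copy.
#' @return Case allele frequency `f'`.
#' @export
case_freq <- function(f, r) {
  if (any(r <= 0)) stop("'r' must be positive")
  r * f / (1 - f + r * f)
}

#' Case genotype vector for one marker
#'
#' @param f Population allele frequency at the marker.
#' @param r Relative risk per copy of the counted (risk) allele.
#' @param n_cases Number of cases to draw.
#' @return Integer genotype vector of length `n_cases`.
#' @export
case_genotypes <- function(f, r, n_cases) {
  stats::rbinom(n_cases, 2, case_freq(f, r))
}

#' Case-control study design for the stratified-association simulations
#'
#' Defaults follow the three-population study: expected case counts
#' (30, 60, 150) and control counts (80, 80, 80) per population
#' (disease prevalences in ratio 1:2:5 with equal sampling priors),
#' 10,000 SNPs per category, relative risk 1.5 per risk-allele copy, and
#' the two fixed frequency sets (0.75, 0.30, 0.15) and (0.15, 0.30, 0.75)
#' for the Specific SNP categories.
#'
#' @param cases Expected case count per population.
#' @param controls Expected control count per population.
#' @param relative_risk Multiplicative relative risk for causal SNPs.
#' @param snps_per_category Markers simulated per SNP category.
#' @param specific_freqs List of fixed per-population frequency vectors.
#' @return Object of class `study_design`.
#' @export
study_design <- function(cases = c(30, 60, 150), controls = c(80, 80, 80),
                         relative_risk = 1.5, snps_per_category = 10000,
                         specific_freqs = list(c(0.75, 0.30, 0.15),
                                               c(0.15, 0.30, 0.75))) {
  if (length(cases) != length(controls)) stop("case/control count mismatch")
  if (any(cases < 0) || any(controls < 0)) stop("counts must be nonnegative")
  if (relative_risk <= 0) stop("'relative_risk' must be positive")
  structure(list(cases = cases, controls = controls,
                 relative_risk = relative_risk,
                 snps_per_category = snps_per_category,
                 specific_freqs = specific_freqs,
                 K = length(cases)),
            class = "study_design")
}

# genotype block for fixed (M x K or length-K) frequencies under the design
sim_block_geno <- function(f, design, causal) {
  K <- design$K
  ncase <- design$cases; nctrl <- design$controls
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  M <- nrow(f)
  cols_case <- lapply(seq_len(K), function(s) {
    fs <- if (causal) case_freq(f[, s], design$relative_risk) else f[, s]
    matrix(stats::rbinom(M * ncase[s], 2, fs), M, ncase[s])
  })
  cols_ctrl <- lapply(seq_len(K), function(s)
    matrix(stats::rbinom(M * nctrl[s], 2, f[, s]), M, nctrl[s]))
  do.call(cbind, c(cols_case, cols_ctrl))
}

#' Simulate the four SNP categories of the stratified case-control study
#'
#' Generates, for one differentiation level `Fst`, the four simulated SNP
#' categories: Null-StruInfo and Causal-StruInfo (Balding-Nichols
#' frequencies; structure-informative) and Null-Specific / Causal-Specific
#' (fixed per-population frequency sets). Cases and controls share the same
#' frequencies for Null SNPs; for Causal SNPs the cases are drawn at the
#' multiplicative-risk case frequency. The Null-StruInfo block doubles as
#' the panel from which sample PCs and parameter estimates are inferred.
#' The counted allele is the risk allele, so the true association direction
#' for causal SNPs is +1.
#'
#' @param design A [study_design()].
#' @param Fst Scalar differentiation parameter for the StruInfo categories.
#' @param seed Optional integer seed (set once for the whole study).
#' @param p_range Ancestral-frequency support for the StruInfo draws.
#' @return Object of class `simulated_study`: list with `blocks` (named list
#'   of genotype matrices), `y` (phenotype), `labels` (population
#'   membership), `design`, `Fst`, `panel` (name of the PC-inference block)
#'   and `risk_direction` (+1).
#' @export
simulate_assoc_study <- function(design = study_design(), Fst = 0.01, seed = NULL,
                         p_range = c(0.1, 0.9)) {
  stopifnot(inherits(design, "study_design"))
  if (design$K != 3) stop("the study design uses three populations")
  if (!is.null(seed)) set.seed(seed)
  M <- design$snps_per_category
  labels <- paste0("P", c(rep(seq_len(3), design$cases),
                          rep(seq_len(3), design$controls)))
  y <- c(rep(1, sum(design$cases)), rep(0, sum(design$controls)))

  blocks <- list()
  blocks[["null_struinfo"]] <-
    sim_block_geno(draw_freqs_bn(M, Fst, K = 3, p_range = p_range)$f,
                   design, causal = FALSE)
  blocks[["causal_struinfo"]] <-
    sim_block_geno(draw_freqs_bn(M, Fst, K = 3, p_range = p_range)$f,
                   design, causal = TRUE)
  for (j in seq_along(design$specific_freqs)) {
    fr <- design$specific_freqs[[j]]
    nm <- paste(fr, collapse = ":")
    blocks[[paste0("null_specific_", nm)]] <-
      sim_block_geno(matrix(fr, M, 3, byrow = TRUE), design, causal = FALSE)
    blocks[[paste0("causal_specific_", nm)]] <-
      sim_block_geno(matrix(fr, M, 3, byrow = TRUE), design, causal = TRUE)
  }
  structure(list(blocks = blocks, y = y, labels = labels, design = design,
                 Fst = Fst, panel = "null_struinfo", risk_direction = 1),
            class = "simulated_study")
}

#' Run the full stratification-correction comparison
#'
#' Simulates (or reuses) a [simulate_assoc_study()] study and reports the
#' proportion of markers declared significant for every SNP category under
#' each correction method. For causal categories the proportion is
#' direction-aware power: rejections whose estimated direction contradicts
#' the simulated risk allele are not counted. Sample PCs for the
#' Eigenstrat arm are estimated from the Null-StruInfo panel.
#'
#' @param design A [study_design()].
#' @param Fst Differentiation level for the StruInfo categories.
#' @param alpha Significance threshold (default 0.01).
#' @param methods Correction arms to run.
#' @param num_pcs Sample PCs regressed out in the Eigenstrat arm.
#' @param residualize_phenotype Passed to [assoc_scan()] for the PC-based
#'   arms.
#' @param seed Optional integer seed.
#' @param study Optional pre-simulated `simulated_study` (overrides
#'   `design`/`Fst`/`seed`).
#' @return Object of class `simulation_report`: data frame with one row per
#'   SNP category and one column per method, plus columns `category` and
#'   `type` (null/causal).
#' @export
correction_study <- function(design = study_design(), Fst = 0.01, alpha = 0.01,
                       methods = c("none", "eigenstrat", "popu", "covariate"),
                       num_pcs = 2, residualize_phenotype = FALSE,
                       seed = NULL, study = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(study)) study <- simulate_assoc_study(design, Fst, seed = seed)
  stopifnot(inherits(study, "simulated_study"))
  y <- study$y
  labels <- study$labels
  pcs <- if ("eigenstrat" %in% methods)
    sample_pca(study$blocks[[study$panel]], m = num_pcs)$vectors
  out <- data.frame(category = names(study$blocks),
                    type = ifelse(grepl("^null", names(study$blocks)),
                                  "null", "causal"))
  for (m in methods) {
    rates <- vapply(seq_along(study$blocks), function(b) {
      G <- study$blocks[[b]]
      res <- assoc_scan(G, y, method = m, labels = labels, pcs = pcs,
                        num_pcs = num_pcs,
                        residualize_phenotype = residualize_phenotype)
      dirv <- if (out$type[b] == "causal") study$risk_direction else NULL
      rejection_rate(res, alpha = alpha, direction = dirv)
    }, 0)
    out[[m]] <- rates
  }
  structure(out, class = c("simulation_report", "data.frame"),
            alpha = alpha, Fst = study$Fst)
}

#' Subtle-substructure scenario
#'
#' Generates four labelled populations of which two are nearly identical:
#' P1, P2 and P4 are independent Balding-Nichols populations at the given
#' `Fst`, while P3's frequency vector is P2's plus an independent
#' uniform(-delta, delta) perturbation per marker (clipped to \[0, 1\];
#' the number of clipped frequencies is reported as an attribute). P2+P3
#' behaves as one population carrying a subtle internal structure.
#'
#' The default half-width 0.05 is calibrated so that, at the scenario's
#' scales, the twin contrast is resolvable on sample eigenvector 3 while
#' the twins remain far closer to each other than any pair of outer
#' populations (see the methods vignette for the calibration reasoning).
#'
#' @param M Number of markers.
#' @param n_per_pop Individuals per population (scalar or length 4).
#' @param Fst Differentiation of the three outer populations (default
#'   0.003).
#' @param delta Half-width of the P3 perturbation (default 0.05).
#' @param seed Optional integer seed.
#' @param p_range Ancestral-frequency support.
#' @return List with `G` (M x n genotype matrix), `labels`, `layout` and
#'   `f` (M x 4 frequency matrix); attribute `"clipped"` counts clipped
#'   P3 frequencies.
#' @export
subtle_structure_scenario <- function(M, n_per_pop, Fst = 0.003, delta = 0.05,
                                      seed = NULL, p_range = c(0.1, 0.9)) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(n_per_pop, 4)
  f3 <- draw_freqs_bn(M, Fst, K = 3, p_range = p_range)$f  # P1, P2, P4
  pert <- f3[, 2] + stats::runif(M, -delta, delta)
  clipped <- sum(pert < 0 | pert > 1)
  f <- cbind(f3[, 1], f3[, 2], pmin(pmax(pert, 0), 1), f3[, 3])
  colnames(f) <- paste0("P", 1:4)
  layout <- pop_layout(sizes, labels = paste0("P", 1:4))
  G <- genotypes_from_freqs(f, layout)
  out <- list(G = G, labels = rep(layout$labels, layout$sizes),
              layout = layout, f = f)
  attr(out, "clipped") <- clipped
  out
}

#' @export
print.simulation_report <- function(x, digits = 4, ...) {
  cat("Proportion of associations reported as significant (alpha =",
      attr(x, "alpha"), ", Fst =", attr(x, "Fst"), ")\n")
  print.data.frame(cbind(x[, c("category", "type")],
                         round(x[, -(1:2), drop = FALSE], digits)),
                   row.names = FALSE)
  invisible(x)
}
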