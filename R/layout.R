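#' Population sampling layout
#'
#' Describes how a sample of `n` individuals is partitioned into `K`
#' populations: the per-population sample sizes \eqn{n_s}, the total
#' \eqn{n = \sum_s n_s} and the proportions \eqn{w_s = n_s / n}.
#'
#' @param sizes Positive integer vector of per-population sample sizes.
#' @param labels Optional character vector of population identifiers; defaults
#'   to `names(sizes)` or `"P1", "P2", ...`.
#'
#' @return An object of class `pop_layout`: a list with elements `labels`,
#'   `sizes`, `K`, `n` and `proportions`.
#' @examples
#' pop_layout(c(5, 10, 100))
#' @export
pop_layout <- function(sizes, labels = NULL) {
  if (length(sizes) < 1L) stop("at least one population is required")
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != round(sizes)))
    stop("'sizes' must be positive integers")
  sizes <- as.integer(sizes)
  if (is.null(labels)) labels <- names(sizes)
  if (is.null(labels)) labels <- paste0("P", seq_along(sizes))
  if (length(labels) != length(sizes)) stop("'labels' and 'sizes' lengths differ")
  structure(
    list(labels = as.character(labels), sizes = sizes,
         K = length(sizes), n = sum(sizes),
         proportions = sizes / sum(sizes)),
    class = "pop_layout")
}

#' @export
print.pop_layout <- function(x, ...) {
  cat("Population layout: K =", x$K, ", n =", x$n, "\n")
  print(stats::setNames(x$sizes, x$labels))
  invisible(x)
}

#' Build a layout from individual-level population labels
#'
#' @param labels Vector of population membership, one entry per individual.
#'   Population order follows first appearance.
#' @return A [pop_layout()] object.
#' @export
layout_from_labels <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("population labels must not contain NA")
  lev <- unique(labels)
  pop_layout(vapply(lev, function(l) sum(labels == l), 0L), labels = lev)
}

# index list: which individuals belong to each population, in layout order
pop_index <- function(labels, layout) {
  lapply(layout$labels, function(l) which(as.character(labels) == l))
}
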