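#' Read an EIGENSTRAT text genotype file set
#'
#' Parses the plain-text EIGENSTRAT format: the geno file has one line per
#' SNP with one character per individual (`0`, `1`, `2` allele counts, `9`
#' missing); the snp file one line per SNP (id, chromosome, genetic
#' position, physical position); the ind file one line per individual (id,
#' gender, population label).
#'
#' @param geno_path,snp_path,ind_path File paths.
#' @return Object of class `geno_data`: list with `G` (marker x individual
#'   matrix with NA for missing), `snp` (data frame), `ind` (data frame) and
#'   `labels` (population labels from the ind file's third column).
#' @export
read_geno <- function(geno_path, snp_path, ind_path) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  lines <- readLines(geno_path)
  ind <- utils::read.table(ind_path, header = FALSE,
                           col.names = c("id", "gender", "label"),
                           colClasses = "character")
  snp <- utils::read.table(snp_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"),
                           col.names = c("id", "chrom", "genpos", "physpos"))
  n <- nrow(ind)
  if (length(lines) != nrow(snp))
    stop("geno file has ", length(lines), " rows but snp file lists ",
         nrow(snp), " SNPs")
  widths <- nchar(lines)
  if (any(widths != n)) {
    bad <- which(widths != n)[1]
    stop("geno line ", bad, " has ", widths[bad],
         " genotypes but the ind file lists ", n, " individuals")
  }
  chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(lines), byrow = TRUE)
  invalid <- !(chars %in% c("0", "1", "2", "9"))
  if (any(invalid)) {
    bad <- which(rowSums(matrix(invalid, nrow(chars))) > 0)[1]
    stop("invalid genotype character on geno line ", bad,
         " (allowed: 0, 1, 2, 9)")
  }
  G <- matrix(as.integer(chars), nrow(chars), n)
  G[G == 9L] <- NA_integer_
  rownames(G) <- snp$id
  colnames(G) <- ind$id
  structure(list(G = G, snp = snp, ind = ind, labels = ind$label),
            class = "geno_data")
}

#' Write an EIGENSTRAT text genotype file set
#'
#' @param gd A `geno_data` object (or a list with `G`, optional `snp`,
#'   `ind`, `labels`).
#' @param geno_path,snp_path,ind_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_geno <- function(gd, geno_path, snp_path, ind_path) {
  G <- as.matrix(gd$G)
  Gi <- G
  Gi[is.na(Gi)] <- 9L
  writeLines(apply(Gi, 1, paste, collapse = ""), geno_path)
  snp <- gd$snp
  if (is.null(snp))
    snp <- data.frame(id = rownames(G) %||% paste0("snp", seq_len(nrow(G))),
                      chrom = "1", genpos = 0, physpos = seq_len(nrow(G)))
  utils::write.table(snp, snp_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  ind <- gd$ind
  if (is.null(ind))
    ind <- data.frame(id = colnames(G) %||% paste0("ind", seq_len(ncol(G))),
                      gender = "U",
                      label = gd$labels %||% rep("P1", ncol(G)))
  utils::write.table(ind, ind_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(geno_path, snp_path, ind_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV genotype matrix
#'
#' Markers x individuals table with a header row of individual ids and a
#' first column of marker ids; `.` denotes a missing genotype. An optional
#' sidecar label file has two columns: individual id and population label.
#'
#' @param tsv_path Genotype TSV path.
#' @param labels_path Optional two-column label file.
#' @return A `geno_data` object (with `labels` NULL if no label file).
#' @export
read_geno_tsv <- function(tsv_path, labels_path = NULL) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = ".",
                           row.names = 1)
  G <- as.matrix(tab)
  mode(G) <- "integer"
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = "character")
    i <- match(colnames(G), lab$id)
    if (anyNA(i)) stop("label file is missing individual(s): ",
                       paste(colnames(G)[is.na(i)], collapse = ", "))
    labels <- lab$label[i]
  }
  structure(list(G = G, snp = NULL, ind = NULL, labels = labels),
            class = "geno_data")
}

#' Write a TSV genotype matrix
#'
#' @param gd `geno_data` object or genotype matrix.
#' @param tsv_path Output path (`.` written for missing entries).
#' @param labels_path Optional path for the sidecar label file.
#' @return Invisibly, the path(s) written.
#' @export
write_geno_tsv <- function(gd, tsv_path, labels_path = NULL) {
  G <- if (inherits(gd, "geno_data") || is.list(gd)) gd$G else gd
  ids <- colnames(G) %||% paste0("ind", seq_len(ncol(G)))
  out <- cbind(marker = rownames(G) %||% paste0("snp", seq_len(nrow(G))),
               as.data.frame(G))
  colnames(out) <- c("marker", ids)
  out[is.na(out)] <- "."
  utils::write.table(out, tsv_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  if (!is.null(labels_path)) {
    labels <- if (is.list(gd)) gd$labels else NULL
    if (is.null(labels)) stop("no labels to write")
    utils::write.table(data.frame(id = ids, label = labels), labels_path,
                       quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, labels_path))
}

#' Read a flat key:value parameter configuration
#'
#' The configuration carries population labels, sizes and the raw
#' variance-covariance parameters: keys `labels`, `sizes`, `sigma2`, `c`
#' and `d` (upper triangle of the between-population covariance matrix in
#' row-major order), each a comma-separated list.
#'
#' @param path Config file path.
#' @return List with `layout` ([pop_layout()]) and `params`
#'   ([cov_params()]).
#' @export
read_params_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line: ",
                                  lines[which(lengths(kv) != 3)[1]])
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- vapply(kv, `[`, "", 3)
  cfg <- stats::setNames(as.list(vals), keys)
  need <- c("sizes", "sigma2", "c")
  if (!all(need %in% keys))
    stop("config must define: ", paste(setdiff(need, keys), collapse = ", "))
  num <- function(k) as.numeric(strsplit(cfg[[k]], ",")[[1]])
  sizes <- num("sizes")
  K <- length(sizes)
  labels <- if ("labels" %in% keys)
    trimws(strsplit(cfg$labels, ",")[[1]]) else paste0("P", seq_len(K))
  sigma2 <- num("sigma2")
  cwithin <- num("c")
  d <- matrix(0, K, K)
  if ("d" %in% keys && K > 1) {
    dv <- num("d")
    if (length(dv) != K * (K - 1) / 2)
      stop("'d' must list the ", K * (K - 1) / 2,
           " upper-triangle entries in row-major order")
    perm <- order(row(d)[upper.tri(d)], col(d)[upper.tri(d)])
    tmp <- numeric(length(dv))
    tmp[perm] <- dv                      # row-major input -> column-major cells
    d[upper.tri(d)] <- tmp
    d <- d + t(d)
  }
  list(layout = pop_layout(sizes, labels = labels),
       params = cov_params(sigma2, cwithin, d, labels = labels))
}

#' Write a flat key:value parameter configuration
#'
#' @param params Raw [cov_params()].
#' @param layout A [pop_layout()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_params_config <- function(params, layout, path) {
  K <- layout$K
  d <- params$d
  ut <- d[upper.tri(d)][order(row(d)[upper.tri(d)], col(d)[upper.tri(d)])]
  lines <- c(
    paste0("labels: ", paste(layout$labels, collapse = ",")),
    paste0("sizes: ", paste(layout$sizes, collapse = ",")),
    paste0("sigma2: ", paste(format(params$sigma2, digits = 15), collapse = ",")),
    paste0("c: ", paste(format(params$c, digits = 15), collapse = ",")),
    if (K > 1) paste0("d: ", paste(format(ut, digits = 15), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write eigenvalues and per-population axis coordinates as TSV
#'
#' @param sol A `reduced_eigen` solution.
#' @param values_path,axes_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_axes_tsv <- function(sol, values_path = NULL, axes_path = NULL) {
  stopifnot(inherits(sol, "reduced_eigen"))
  if (!is.null(values_path)) {
    tab <- data.frame(axis = seq_along(sol$values), eigenvalue = sol$values,
                      trivial = seq_along(sol$values) == sol$trivial_index)
    utils::write.table(tab, values_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  if (!is.null(axes_path)) {
    tab <- cbind(population = rownames(sol$coef), as.data.frame(sol$coef))
    utils::write.table(tab, axes_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(c(values_path, axes_path))
}

#' Write a run manifest
#'
#' Records the package version, seed and configuration of a run as a flat
#' key:value text file, so the run can be reproduced exactly.
#'
#' @param path Output path.
#' @param seed Integer seed used.
#' @param config Named list of configuration values (scalars or short
#'   vectors; vectors are comma-joined).
#' @return Invisibly, the path.
#' @export
write_manifest <- function(path, seed, config = list()) {
  vals <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ","), "")
  lines <- c(paste0("package: stratpca ",
                    as.character(utils::packageVersion("stratpca"))),
             paste0("seed: ", seed),
             paste0(names(config), ": ", vals))
  writeLines(lines, path)
  invisible(path)
}
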