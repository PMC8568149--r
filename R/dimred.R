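#' @name dimred
#' @title Sample embeddings of methylation profiles
#'
#' @description
#' Sample-level structure (experimental groups, haplotypes, batch effects) is
#' summarised by embedding the samples of a log-methylation-ratio matrix in
#' two or more dimensions. Following the bisulfite-sequencing workflow
#' convention, only the most variable sites are used; distances between
#' samples are root-mean-square differences of their log ratios over those
#' shared sites ("common" selection), and the embedding is classical
#' (Torgerson) multidimensional scaling or site-centred PCA.
NULL

.as_lmr_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix contains non-finite values",
                               call. = FALSE)
  m
}

#' Retain the most variable sites
#'
#' Keeps the `k` sites (rows) with the largest across-sample variance
#' (denominator n - 1). If fewer than `k` sites exist all are kept; ties are
#' broken by row order, i.e. by site coordinate order.
#'
#' @param m sites x samples numeric matrix (e.g. from [log_methy_ratio()]).
#' @param k number of sites to retain (default 500, the usual workflow
#'   choice).
#' @return The reduced matrix.
#' @export
select_top_variable_sites <- function(m, k = 500L) {
  m <- .as_lmr_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  stopifnot(k >= 2L)
  if (nrow(m) <= k) return(m)
  v <- apply(m, 1L, var)
  ord <- order(v, decreasing = TRUE)  # ties keep row (coordinate) order
  m[sort(ord[seq_len(k)]), , drop = FALSE]
}

.rms_dist <- function(m) {
  # pairwise sample distance: sqrt(mean((x_i - x_j)^2)) over retained sites
  d <- dist(t(m)) / sqrt(nrow(m))
  as.matrix(d)
}

.fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) == 1L && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

.new_embedding <- function(coords, method, explained = NULL, top_sites = NA,
                           degenerate = FALSE) {
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(list(coordinates = coords, explained = explained,
                 method = method, top_sites = top_sites,
                 degenerate = degenerate),
            class = "methy_embedding")
}

#' @export
print.methy_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d samples x %d dimensions (top %s sites)\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              format(x$top_sites)))
  if (!is.null(x$explained)) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  }
  if (x$degenerate) cat("  (degenerate: all samples identical)\n")
  invisible(x)
}

#' Classical MDS embedding of samples
#'
#' Computes root-mean-square distances between samples over the retained
#' sites and embeds them with classical (Torgerson) multidimensional
#' scaling. Dimensions are ordered by eigenvalue; each dimension's sign is
#' fixed so its largest-magnitude coordinate is positive, making plots
#' reproducible across runs. If all samples are identical the coordinates
#' are zero and the embedding is flagged degenerate.
#'
#' @param m sites x samples matrix, typically pre-reduced with
#'   [select_top_variable_sites()].
#' @param k_dims embedding dimensions (>= 2).
#' @return A `methy_embedding` object.
#' @export
mds_embedding <- function(m, k_dims = 2L) {
  m <- .as_lmr_matrix(m)
  stopifnot(k_dims >= 2L)
  if (ncol(m) < 3L) stop("need at least 3 samples for MDS", call. = FALSE)
  d <- .rms_dist(m)
  if (all(d == 0)) {
    coords <- matrix(0, ncol(m), k_dims,
                     dimnames = list(colnames(m), NULL))
    return(.new_embedding(coords, "MDS", top_sites = nrow(m),
                          degenerate = TRUE))
  }
  fit <- cmdscale(d, k = min(k_dims, ncol(m) - 1L), eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < k_dims) {  # pad zero dimensions lost to zero eigenvalues
    coords <- cbind(coords, matrix(0, nrow(coords),
                                   k_dims - ncol(coords)))
  }
  coords <- .fix_signs(coords)
  rownames(coords) <- colnames(m)
  .new_embedding(coords, "MDS", top_sites = nrow(m))
}

#' PCA embedding of samples
#'
#' Site-centred principal component analysis via singular value
#' decomposition: each site's log ratio is centred across samples and the
#' samples' scores on the leading components are returned, together with the
#' fraction of variance each component explains (squared singular values
#' over their total). Signs are fixed as in [mds_embedding()].
#'
#' @inheritParams mds_embedding
#' @return A `methy_embedding` with the `explained` fractions filled in.
#' @export
pca_embedding <- function(m, k_dims = 2L) {
  m <- .as_lmr_matrix(m)
  stopifnot(k_dims >= 2L)
  if (ncol(m) < 3L) stop("need at least 3 samples for PCA", call. = FALSE)
  x <- t(m - rowMeans(m))  # samples x sites, site-centred
  if (all(x == 0)) {
    coords <- matrix(0, ncol(m), k_dims,
                     dimnames = list(colnames(m), NULL))
    return(.new_embedding(coords, "PCA", explained = rep(0, k_dims),
                          top_sites = nrow(m), degenerate = TRUE))
  }
  sv <- svd(x)
  keep <- min(k_dims, length(sv$d))
  coords <- sv$u[, seq_len(keep), drop = FALSE] %*%
    diag(sv$d[seq_len(keep)], keep)
  if (keep < k_dims) {
    coords <- cbind(coords, matrix(0, nrow(coords), k_dims - keep))
  }
  coords <- .fix_signs(coords)
  rownames(coords) <- colnames(m)
  explained <- c(sv$d^2 / sum(sv$d^2), rep(0, max(0L, k_dims -
                                                    length(sv$d))))
  .new_embedding(coords, "PCA", explained = explained[seq_len(k_dims)],
                 top_sites = nrow(m))
}
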