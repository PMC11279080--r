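# Bray-Curtis distances, NMDS ordination and PCA of water chemistry.

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' bounded in \[0, 1\], computed between all sample pairs.
#'
#' @param table a [count_table()], count matrix or relative-abundance
#'   matrix (samples in rows).
#' @return A [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "count_table")) as_count_matrix(table) else as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
    stop_f("abundance matrix must be finite and non-negative")
  totals <- rowSums(m)
  if (any(totals == 0))
    stop_f("zero-total sample(s): %s",
           paste(rownames(m)[totals == 0] %||% which(totals == 0), collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Embeds samples in `k` dimensions so embedded distances are monotone in
#' the input dissimilarities, minimising Kruskal stress-1 by iterative
#' isotonic regression; the best of `n_starts` random starts is kept.
#' Coordinates are centred and rotated to principal axes for a reproducible
#' orientation (stress itself is rotation-invariant).
#'
#' @param dist_matrix a [stats::dist] of sample dissimilarities.
#' @param k embedding dimension.
#' @param n_starts number of random starts.
#' @param max_iter maximum iterations per start.
#' @param seed RNG seed for the random starts.
#' @return List of class `nmds_result`: `points` (samples x k), `stress`
#'   (Kruskal stress-1, in \[0, 1\]), `k`, `n_starts`, `converged`.
#' @export
nmds <- function(dist_matrix, k = 2L, n_starts = 20L, max_iter = 300L, seed = 1L) {
  stopifnot(inherits(dist_matrix, "dist"))
  if (any(!is.finite(dist_matrix))) stop_f("non-finite distances")
  n <- attr(dist_matrix, "Size")
  if (n < k + 2) stop_f("need at least k + 2 = %d samples, have %d", k + 2, n)
  set.seed(seed)
  fit <- suppressMessages(vegan::metaMDS(dist_matrix, k = k, try = n_starts,
                                         trymax = n_starts, maxit = max_iter,
                                         trace = 0, autotransform = FALSE,
                                         wascores = FALSE))
  pts <- fit$points
  rownames(pts) <- attr(dist_matrix, "Labels") %||% rownames(pts)
  structure(list(points = pts, stress = fit$stress, k = k,
                 n_starts = n_starts, converged = isTRUE(fit$converged > 0)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f over %d samples, %d starts%s\n",
              x$k, x$stress, nrow(x$points), x$n_starts,
              if (x$converged) "" else " (no convergent solution)"))
  invisible(x)
}

#' Principal component analysis of water chemistry
#'
#' Columns are z-scored by default since the variables mix units (pH,
#' degrees C, mg/L, uS/cm, NTU). The contribution of variable v to
#' component c is \eqn{100 \cdot loading_{vc}^2 / \sum_v loading_{vc}^2},
#' summing to 100% per component.
#'
#' @param chem chemistry data frame (with `sample_id`) or numeric matrix.
#' @param standardize z-score columns before decomposition.
#' @return List of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance` (proportions), `contributions` (% per variable and
#'   component).
#' @export
chem_pca <- function(chem, standardize = TRUE) {
  m <- chem_matrix(chem)
  if (nrow(m) < 2 || ncol(m) < 2) stop_f("need at least 2 samples and 2 variables")
  if (any(!is.finite(m))) stop_f("missing or non-finite values in chemistry")
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0))
      stop_f("zero-variance variable(s) under standardization: %s",
             paste(colnames(m)[sds == 0], collapse = ", "))
  }
  fit <- prcomp(m, center = TRUE, scale. = standardize)
  contrib <- 100 * sweep(fit$rotation^2, 2, colSums(fit$rotation^2), "/")
  structure(list(scores = fit$x, loadings = fit$rotation,
                 explained_variance = fit$sdev^2 / sum(fit$sdev^2),
                 contributions = contrib, standardized = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- round(100 * x$explained_variance[1:min(3, length(x$explained_variance))], 1)
  cat(sprintf("PCA of %d samples x %d variables; PC1-%d explain %s%%\n",
              nrow(x$scores), nrow(x$loadings), length(ev),
              paste(ev, collapse = "/")))
  invisible(x)
}

# Extract the numeric chemistry matrix (rows labelled by sample_id).
chem_matrix <- function(chem, variables = NULL) {
  if (is.matrix(chem)) {
    m <- chem
  } else {
    vars <- setdiff(names(chem), "sample_id")
    vars <- vars[vapply(chem[vars], is.numeric, logical(1))]
    m <- as.matrix(chem[, vars, drop = FALSE])
    if ("sample_id" %in% names(chem)) rownames(m) <- chem$sample_id
  }
  if (!is.null(variables)) {
    unknown <- setdiff(variables, colnames(m))
    if (length(unknown) > 0)
      stop_f("unknown variable(s): %s", paste(unknown, collapse = ", "))
    m <- m[, variables, drop = FALSE]
  }
  m
}
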