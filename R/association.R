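# Mantel tests linking water properties to community dissimilarity and the
# Pearson screen between chemistry and taxon relative abundances.

#' Euclidean distance on z-scored chemistry variables
#'
#' @param chem chemistry data frame or matrix.
#' @param variables variable names, or `"All"` for all nine.
#' @return A [stats::dist] labelled by sample id.
#' @export
chem_distance <- function(chem, variables = "All") {
  m <- chem_matrix(chem)
  if (identical(variables, "All")) variables <- colnames(m)
  m <- chem_matrix(m, variables)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop_f("zero-variance variable(s): %s", paste(colnames(m)[sds == 0], collapse = ", "))
  dist(scale(m))
}

#' Mantel test between two distance matrices
#'
#' The statistic is the correlation (Pearson by default, Spearman as an
#' option) between the two lower triangles; the permutation p value is
#' one-sided, \eqn{(1 + \#\{R_{perm} \ge R_{obs}\}) / (n_{perm} + 1)},
#' permuting rows and columns of one matrix jointly.
#'
#' @param dist_a,dist_b [stats::dist] objects over the same samples in the
#'   same order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_permutations number of permutations (study default 9999).
#' @param seed RNG seed for the permutations.
#' @param property optional label for the variable being tested.
#' @return List of class `mantel_result`: `statistic`, `p_value`,
#'   `n_permutations`, `method`, `property`.
#' @export
mantel_test <- function(dist_a, dist_b, method = c("pearson", "spearman"),
                        n_permutations = 9999L, seed = 1L, property = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dist_a, "dist"), inherits(dist_b, "dist"))
  n <- attr(dist_a, "Size")
  if (n < 4) stop_f("need at least 4 samples for a Mantel test")
  if (attr(dist_b, "Size") != n) stop_f("distance matrices differ in size")
  la <- attr(dist_a, "Labels"); lb <- attr(dist_b, "Labels")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop_f("sample id mismatch between distance matrices")
  set.seed(seed)
  fit <- vegan::mantel(dist_a, dist_b, method = method,
                       permutations = n_permutations)
  structure(list(statistic = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = n_permutations, method = method,
                 property = property),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel%s: R = %.3f, p = %.4g (%s, %d permutations)\n",
              if (is.null(x$property)) "" else paste0(" [", x$property, "]"),
              x$statistic, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' Mantel table: community dissimilarity vs each water property
#'
#' Reproduces the shape of the study's property-by-community Mantel table:
#' rows "All" plus each chemistry variable, one (R, p) pair per community
#' distance matrix supplied.
#'
#' @param community_dists named list of [stats::dist] (e.g. bacteria,
#'   fungi, protist Bray-Curtis).
#' @param chem chemistry table covering the same samples, in the same order.
#' @param n_permutations permutations per test.
#' @param seed RNG seed.
#' @param method correlation flavour passed to [mantel_test()].
#' @return Data frame: property, then `<group>_R` / `<group>_p` columns.
#' @export
mantel_table <- function(community_dists, chem, n_permutations = 9999L,
                         seed = 1L, method = "pearson") {
  m <- chem_matrix(chem)
  props <- c("All", colnames(m))
  out <- data.frame(property = props, stringsAsFactors = FALSE)
  for (grp in names(community_dists)) {
    labels <- attr(community_dists[[grp]], "Labels")
    chem_grp <- if (!is.null(labels) && "sample_id" %in% names(chem)) {
      missing <- setdiff(labels, chem$sample_id)
      if (length(missing) > 0)
        stop_f("samples absent from chemistry: %s", paste(missing, collapse = ", "))
      chem[match(labels, chem$sample_id), ]
    } else chem
    rs <- ps <- numeric(length(props))
    for (i in seq_along(props)) {
      dchem <- chem_distance(chem_grp, if (props[i] == "All") "All" else props[i])
      res <- mantel_test(community_dists[[grp]], dchem, method = method,
                         n_permutations = n_permutations,
                         seed = derive_seed(seed, paste("mantel", grp, props[i])),
                         property = props[i])
      rs[i] <- res$statistic; ps[i] <- res$p_value
    }
    out[[paste0(grp, "_R")]] <- rs
    out[[paste0(grp, "_p")]] <- ps
  }
  out
}

#' Pearson screen between chemistry variables and taxon abundances
#'
#' Pairwise Pearson r with two-sided p from the t distribution (df = n - 2).
#' p values are left unadjusted by default, mirroring per-cell p < 0.05
#' displays; Benjamini-Hochberg adjustment over all cells is available via
#' `adjust = "BH"`. Genus-level screens are conventionally restricted to the
#' most abundant genera via `top_n`.
#'
#' @param chem chemistry table.
#' @param abundances samples x taxa matrix of (relative) abundances, sample
#'   ids as rownames matching `chem`.
#' @param alpha per-cell significance level.
#' @param top_n if non-NULL, keep only the `top_n` taxa by mean abundance.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List of class `correlation_screen`: `r`, `p` (variables x taxa),
#'   `significant` mask, `undefined` mask (constant columns), `alpha`, `n`.
#' @export
pearson_screen <- function(chem, abundances, alpha = 0.05, top_n = NULL,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- chem_matrix(chem)
  a <- as.matrix(abundances)
  if (!is.null(rownames(m)) && !is.null(rownames(a))) {
    shared <- intersect(rownames(m), rownames(a))
    if (length(shared) < 4) stop_f("fewer than 4 shared samples")
    m <- m[shared, , drop = FALSE]
    a <- a[shared, , drop = FALSE]
  } else if (nrow(m) != nrow(a)) {
    stop_f("chemistry and abundance tables differ in sample count")
  }
  n <- nrow(m)
  if (n < 4) stop_f("fewer than 4 shared samples")
  if (!is.null(top_n) && top_n < ncol(a)) {
    keep <- order(colMeans(a), decreasing = TRUE)[seq_len(top_n)]
    a <- a[, sort(keep), drop = FALSE]
  }
  r <- suppressWarnings(cor(m, a))
  r2 <- pmin(r^2, 1)
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[r2 >= 1 - 1e-15] <- 0
  undefined <- !is.finite(r)
  if (adjust == "BH") {
    ok <- is.finite(p)
    p[ok] <- p.adjust(p[ok], method = "BH")
  }
  significant <- is.finite(p) & p < alpha
  structure(list(r = r, p = p, significant = significant,
                 undefined = undefined, alpha = alpha, n = n, adjust = adjust),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("Pearson screen: %d variables x %d taxa over %d samples; %d significant cells at alpha = %g%s\n",
              nrow(x$r), ncol(x$r), x$n, sum(x$significant), x$alpha,
              if (x$adjust == "BH") " (BH-adjusted)" else ""))
  invisible(x)
}
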