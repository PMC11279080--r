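# Alpha diversity (Chao1, Shannon-Wiener) and site/month group comparisons
# (one-way ANOVA + Tukey HSD with a compact letter display).

#' Shannon-Wiener diversity index
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over taxa with positive count, natural
#' logarithm. Invariant to rescaling all counts by a common factor.
#'
#' @param counts non-negative numeric vector.
#' @return The index (>= 0).
#' @export
shannon <- function(counts) {
  check_abundance_vector(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, with
#' \eqn{F_1} the number of singletons and \eqn{F_2} the number of
#' doubletons. The classic form \eqn{S_{obs} + F_1^2 / (2 F_2)} is available
#' with `bias_corrected = FALSE` (it falls back to the bias-corrected form
#' when there are no doubletons, where it is undefined).
#'
#' @param counts non-negative numeric vector.
#' @param bias_corrected use the bias-corrected estimator (default).
#' @return Estimated richness, always >= observed richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_abundance_vector(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else s_obs + f1^2 / (2 * f2)
}

check_abundance_vector <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0)
    stop_f("counts must be a non-empty numeric vector")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_f("counts must be finite and non-negative")
  if (all(counts == 0)) stop_f("all-zero abundance vector")
  invisible(counts)
}

#' Per-sample alpha diversity table
#'
#' Computes observed richness, Chao1 and Shannon for every sample, joining
#' sample metadata when given. Unequal sample totals trigger a warning,
#' since alpha diversity comparisons assume a rarefied table.
#'
#' @param table a [count_table()].
#' @param metadata optional data frame with a `sample_id` column; every
#'   sample in `table` must appear in it.
#' @return Data frame with sample_id, observed_richness, chao1, shannon and
#'   any metadata columns.
#' @export
alpha_table <- function(table, metadata = NULL) {
  stopifnot(inherits(table, "count_table"))
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (length(unique(totals)) > 1)
    warning("sample totals are unequal; rarefy before comparing alpha diversity",
            call. = FALSE)
  out <- data.frame(
    sample_id = rownames(m),
    observed_richness = as.integer(rowSums(m > 0)),
    chao1 = apply(m, 1, chao1),
    shannon = apply(m, 1, shannon),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    missing <- setdiff(out$sample_id, metadata$sample_id)
    if (length(missing) > 0)
      stop_f("samples absent from metadata: %s", paste(missing, collapse = ", "))
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
  }
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical one-way ANOVA followed by all-pairs Tukey HSD (Tukey-Kramer on
#' unbalanced designs, via [stats::TukeyHSD()]) and an insert-absorb compact
#' letter display: groups sharing no letter differ at `alpha`, groups
#' sharing a letter do not.
#'
#' Degenerate inputs are handled explicitly: if all values are identical the
#' comparison is flat (p = 1 everywhere, one shared letter); if within-group
#' variance is zero but group means differ, F is infinite and p is reported
#' as 0 with a flag.
#'
#' @param values numeric response, one value per sample.
#' @param groups group labels (factor or character), >= 2 groups with
#'   n >= 2 each.
#' @param alpha significance level for the letter display.
#' @return A list of class `group_comparison`: `groups` (per-group n, mean,
#'   letters), `anova` (F, df, p), `tukey` (pairwise comparisons) and
#'   `flags`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop_f("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2))
    stop_f("group(s) with fewer than 2 observations: %s",
           paste(names(ns)[ns < 2], collapse = ", "))
  lev <- levels(g)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  flags <- character(0)

  pair_idx <- t(utils::combn(k, 2))
  pair_names <- paste(lev[pair_idx[, 2]], lev[pair_idx[, 1]], sep = "-")

  ss_within <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  ss_between <- sum(ns * (means - mean(values))^2)
  df1 <- k - 1
  df2 <- length(values) - k

  if (ss_between < 1e-12 && ss_within < 1e-12) {
    # all values identical: flat comparison
    flags <- c(flags, "degenerate: zero variance everywhere")
    f_stat <- 0; p_anova <- 1
    p_pair <- rep(1, nrow(pair_idx))
    diffs <- rep(0, nrow(pair_idx))
  } else if (ss_within < 1e-12) {
    flags <- c(flags, "zero within-group variance: F infinite, p reported as 0")
    f_stat <- Inf; p_anova <- 0
    diffs <- means[pair_idx[, 2]] - means[pair_idx[, 1]]
    p_pair <- ifelse(abs(diffs) > 1e-12, 0, 1)
  } else {
    fit <- aov(values ~ g, data = data.frame(values = values, g = g))
    an <- summary(fit)[[1]]
    f_stat <- an[["F value"]][1]
    p_anova <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    # align TukeyHSD rows with our pair order
    ord <- match(pair_names, rownames(tk))
    diffs <- tk[ord, "diff"]
    p_pair <- tk[ord, "p adj"]
  }

  sig <- !is.na(p_pair) & p_pair < alpha
  letters_out <- cld_insert_absorb(lev, pair_idx[sig, , drop = FALSE],
                                   order_by = -as.numeric(means))
  list_out <- list(
    groups = data.frame(group = lev, n = as.integer(ns), mean = as.numeric(means),
                        letters = letters_out, stringsAsFactors = FALSE),
    anova = data.frame(F = f_stat, df1 = df1, df2 = df2, p = p_anova),
    tukey = data.frame(comparison = pair_names, diff = as.numeric(diffs),
                       p_adj = as.numeric(p_pair), stringsAsFactors = FALSE),
    alpha = alpha,
    flags = flags
  )
  class(list_out) <- "group_comparison"
  list_out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$groups, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Insert-absorb compact letter display. `sig_pairs` is a 2-column matrix of
# group indices declared different. Guarantees: a significant pair shares no
# letter; a non-significant pair shares at least one.
cld_insert_absorb <- function(group_names, sig_pairs, order_by = NULL) {
  ng <- length(group_names)
  M <- matrix(TRUE, nrow = ng, ncol = 1)
  absorb <- function(M) {
    keep <- rep(TRUE, ncol(M))
    for (a in seq_len(ncol(M))) {
      if (!keep[a]) next
      for (b in seq_len(ncol(M))) {
        if (a == b || !keep[b]) next
        # drop column a if its TRUE-set is contained in column b's
        if (all(M[, b][M[, a]])) {
          if (!all(M[, a][M[, b]]) || a > b) { keep[a] <- FALSE; break }
        }
      }
    }
    M[, keep, drop = FALSE]
  }
  if (nrow(sig_pairs) > 0) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      shared <- which(M[i, ] & M[j, ])
      for (cc in shared) {
        newcol <- M[, cc]
        M[i, cc] <- FALSE
        newcol[j] <- FALSE
        M <- cbind(M, newcol)
      }
      if (length(shared)) M <- absorb(M)
    }
  }
  # order letter columns for a stable, readable display
  ord <- order(apply(M, 2, function(col) {
    w <- which(col)
    if (is.null(order_by)) min(w) else min(rank(order_by)[w])
  }))
  M <- M[, ord, drop = FALSE]
  if (ncol(M) > 26) stop_f("compact letter display needs more than 26 letters")
  apply(M, 1, function(row) paste(letters[which(row)], collapse = ""))
}
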