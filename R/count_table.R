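#' Construct and validate a community count table
#'
#' The central community object: a samples-by-taxa matrix of non-negative
#' integer read counts with unique sample and taxon identifiers. All
#' downstream functions use this orientation internally; file readers
#' normalise to it.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return A matrix of class `count_table`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop_f("counts must be numeric")
  if (is.null(sample_ids) || is.null(taxon_ids))
    stop_f("count table needs sample and taxon identifiers")
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop_f("identifier lengths do not match the matrix shape")
  if (anyDuplicated(sample_ids))
    stop_f("duplicate sample ids: %s",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop_f("duplicate taxon ids: %s",
           paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_f("non-integer or negative cells at [sample '%s', taxon '%s']%s",
           sample_ids[bad[1, 1]], taxon_ids[bad[1, 2]],
           if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else "")
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  class(counts) <- c("count_table", class(matrix()))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

as_count_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "class") <- NULL
  m
}

#' Read a delimited count table from disk
#'
#' @param path path to a TSV matrix with header; first column holds row ids.
#' @param orientation `"taxa_as_rows"` (the on-disk convention used by
#'   [write_count_table()]) or `"samples_as_rows"`.
#' @param sep field separator.
#' @return A [count_table()] (samples x taxa).
#' @export
read_count_table <- function(path, orientation = c("taxa_as_rows", "samples_as_rows"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_f("'%s' has no data columns", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_f("non-numeric cells in '%s'", path)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  count_table(m)
}

#' Write a count table as TSV (taxa as rows, first column the ASV id)
#'
#' @param table a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  m <- t(as_count_matrix(table))
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Each sample with at least `depth` reads is subsampled uniformly without
#' replacement to exactly `depth` reads (hypergeometric subsampling, the
#' standard treatment for uneven sequencing depth). Samples below `depth`
#' are dropped; their ids are recorded in the `"dropped_samples"` attribute.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the operation is deterministic given it.
#' @return A rarefied [count_table()].
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop_f("depth must be a single integer >= 1")
  depth <- as.integer(round(depth))
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop_f("no samples retained: every sample total is below depth %d", depth)
  set.seed(seed)
  out <- matrix(0, sum(keep), ncol(m), dimnames = list(rownames(m)[keep], colnames(m)))
  for (i in seq_len(sum(keep))) {
    x <- m[which(keep)[i], ]
    if (sum(x) == depth) {
      out[i, ] <- x
    } else {
      pool <- rep.int(seq_along(x), x)
      drawn <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(drawn, nbins = length(x))
    }
  }
  res <- count_table(out)
  attr(res, "dropped_samples") <- rownames(m)[!keep]
  attr(res, "depth") <- depth
  res
}

#' Remove non-target lineages from a eukaryotic ASV table
#'
#' Drops ASVs whose assigned lineage contains any of the non-target groups
#' (by default Metazoa, Opisthokonta, Rhodophyta and Streptophyta — the
#' multicellular/plant/red-algal lineages amplified by broad 18S primers
#' that are not part of the protist community) or whose lineage is
#' unassigned at `unassigned_rank`. Column order is preserved.
#'
#' @param table a [count_table()].
#' @param taxonomy a taxonomy data frame as returned by [read_taxonomy()].
#' @param nontarget lineage names to remove wherever they occur in a lineage.
#' @param unassigned_rank rank at which an `"unassigned"` label also removes
#'   the ASV.
#' @return The filtered [count_table()], with removed ids in the
#'   `"removed_taxa"` attribute.
#' @export
filter_nontarget_protists <- function(table, taxonomy,
                                      nontarget = c("Metazoa", "Opisthokonta",
                                                    "Rhodophyta", "Streptophyta"),
                                      unassigned_rank = "phylum") {
  stopifnot(inherits(table, "count_table"))
  taxa <- colnames(table)
  missing <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing) > 0)
    stop_f("taxa missing from taxonomy: %s", paste(missing, collapse = ", "))
  ranks <- intersect(TAXONOMY_RANKS, names(taxonomy))
  lin <- taxonomy[match(taxa, taxonomy$taxon_id), ranks, drop = FALSE]
  hit_nontarget <- apply(lin, 1, function(r) any(r %in% nontarget))
  unassigned <- rep(FALSE, length(taxa))
  if (unassigned_rank %in% ranks)
    unassigned <- tolower(as.character(lin[[unassigned_rank]])) %in%
      c("unassigned", "na", "") | is.na(lin[[unassigned_rank]])
  drop <- hit_nontarget | unassigned
  res <- count_table(as_count_matrix(table)[, !drop, drop = FALSE])
  attr(res, "removed_taxa") <- taxa[drop]
  res
}

#' Prevalence and abundance filter for the network stage
#'
#' Applied to one site's monthly sample series before correlation: retains
#' taxa detected (count > 0) in at least `min_months` samples AND with at
#' least `min_total_reads` reads summed over the series. Both bounds are
#' inclusive.
#'
#' @param table a [count_table()] holding one site's monthly samples.
#' @param min_months minimum number of samples with non-zero count.
#' @param min_total_reads minimum total reads across the series.
#' @return The filtered [count_table()].
#' @export
prevalence_abundance_filter <- function(table, min_months = 7L, min_total_reads = 12L) {
  stopifnot(inherits(table, "count_table"))
  m <- as_count_matrix(table)
  keep <- colSums(m > 0) >= min_months & colSums(m) >= min_total_reads
  res <- count_table(m[, keep, drop = FALSE])
  attr(res, "removed_taxa") <- colnames(m)[!keep]
  res
}

#' Aggregate a count table to rank-level relative abundances
#'
#' @param table a [count_table()].
#' @param taxonomy taxonomy data frame covering all taxa in `table`.
#' @param rank one of the lineage ranks (e.g. `"phylum"`, `"genus"`).
#' @param unassigned_label bucket name for taxa without a label at `rank`.
#' @return A samples x rank-labels matrix of relative abundances; every row
#'   sums to 1.
#' @export
aggregate_relative_abundance <- function(table, taxonomy, rank = "phylum",
                                         unassigned_label = "unassigned") {
  stopifnot(inherits(table, "count_table"))
  if (!rank %in% TAXONOMY_RANKS) stop_f("unknown rank '%s'", rank)
  if (!rank %in% names(taxonomy)) stop_f("taxonomy lacks rank column '%s'", rank)
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop_f("zero-total sample(s): %s",
           paste(rownames(m)[totals == 0], collapse = ", "))
  missing <- setdiff(colnames(m), taxonomy$taxon_id)
  if (length(missing) > 0)
    stop_f("taxa missing from taxonomy: %s", paste(missing, collapse = ", "))
  labels <- as.character(taxonomy[[rank]][match(colnames(m), taxonomy$taxon_id)])
  labels[is.na(labels) | labels == "" | tolower(labels) == "unassigned"] <- unassigned_label
  agg <- t(rowsum(t(m), group = labels))
  sweep(agg, 1, rowSums(agg), "/")
}

#' Lineage ranks used by taxonomy tables
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read / write a taxonomy table
#'
#' TSV with columns `taxon_id`, the lineage ranks (domain ... genus) and
#' optionally `marker` and `group` annotations.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop_f("taxonomy file lacks a 'taxon_id' column")
  if (anyDuplicated(df$taxon_id)) stop_f("duplicate taxon ids in taxonomy")
  df
}

#' @rdname read_taxonomy
#' @param taxonomy a taxonomy data frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
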