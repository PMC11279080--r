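# End-to-end orchestration: simulate/ingest -> validate -> rarefy -> filter
# -> diversity -> ordination -> association -> per-site networks, with a
# reconciled run report and deterministic outputs under a fixed seed.

#' Pipeline configuration
#'
#' Defaults are the study's analysis parameters: rarefaction depths 44465
#' (16S) and 39865 (18S), network-stage prevalence/abundance filter (7
#' months, 12 reads), edge criteria (|r| > 0.7, adjusted p < 0.01), 9999
#' Mantel permutations, alpha 0.05, and Zi/Pi role thresholds 2.5/0.62.
#' When simulating, rarefaction depths are rescaled to the simulated
#' sequencing depth (the minimum sample total, as for real data rarefied at
#' the minimum number of sequences); the resolved values are recorded.
#'
#' @param scenario a [scenario_config()] to simulate, or NULL.
#' @param input_dir directory of input tables (as written by
#'   [write_scenario()]), or NULL when simulating.
#' @param output_dir where all outputs are written.
#' @param rarefaction_depth_16s,rarefaction_depth_18s reads/sample.
#' @param min_months,min_total_reads network-stage filter.
#' @param r_threshold,p_threshold network edge criteria.
#' @param use_adjusted_p threshold edges on BH-adjusted p (default) or raw.
#' @param mantel_permutations permutations for every Mantel test.
#' @param alpha significance level for group comparisons and screens.
#' @param zi_threshold,pi_threshold keystone role thresholds.
#' @param nmds_k,nmds_starts NMDS embedding dimension and random starts.
#' @param top_n_genera genus-level Pearson screen restriction.
#' @param seed master seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, input_dir = NULL,
                            output_dir = tempfile("poolnet_run_"),
                            rarefaction_depth_16s = 44465L,
                            rarefaction_depth_18s = 39865L,
                            min_months = 7L, min_total_reads = 12L,
                            r_threshold = 0.7, p_threshold = 0.01,
                            use_adjusted_p = TRUE,
                            mantel_permutations = 9999L,
                            alpha = 0.05,
                            zi_threshold = 2.5, pi_threshold = 0.62,
                            nmds_k = 2L, nmds_starts = 20L,
                            top_n_genera = 20L,
                            seed = 1L) {
  if (is.null(scenario) && is.null(input_dir))
    stop_f("supply either a simulation scenario or an input directory")
  structure(list(scenario = scenario, input_dir = input_dir,
                 output_dir = output_dir,
                 rarefaction_depth_16s = as.integer(rarefaction_depth_16s),
                 rarefaction_depth_18s = as.integer(rarefaction_depth_18s),
                 min_months = as.integer(min_months),
                 min_total_reads = as.integer(min_total_reads),
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 use_adjusted_p = use_adjusted_p,
                 mantel_permutations = as.integer(mantel_permutations),
                 alpha = alpha, zi_threshold = zi_threshold,
                 pi_threshold = pi_threshold,
                 nmds_k = as.integer(nmds_k), nmds_starts = as.integer(nmds_starts),
                 top_n_genera = as.integer(top_n_genera),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Cross-check sample ids across community, chemistry and metadata tables
#'
#' Report-only: returns a data frame of issues (orphans and duplicates)
#' without mutating any table. An empty data frame means fully consistent.
#'
#' @param metadata,chemistry data frames with a `sample_id` column.
#' @param counts named list of [count_table()]s.
#' @return Data frame with columns `issue`, `table`, `id`.
#' @export
validate_inputs <- function(metadata, chemistry, counts) {
  issues <- list()
  note <- function(issue, table, id)
    issues[[length(issues) + 1]] <<- data.frame(issue = issue, table = table,
                                                id = id, stringsAsFactors = FALSE)
  ref <- metadata$sample_id
  id_sets <- list(metadata = metadata$sample_id, chemistry = chemistry$sample_id)
  for (d in names(id_sets)) {
    dup <- unique(id_sets[[d]][duplicated(id_sets[[d]])])
    for (x in dup) note("duplicate_sample", d, x)
  }
  for (x in setdiff(ref, chemistry$sample_id)) note("missing_sample", "chemistry", x)
  for (x in setdiff(chemistry$sample_id, ref)) note("orphan_sample", "chemistry", x)
  for (nm in names(counts)) {
    ids <- rownames(counts[[nm]])
    for (x in setdiff(ref, ids)) note("missing_sample", nm, x)
    for (x in setdiff(ids, ref)) note("orphan_sample", nm, x)
  }
  if (length(issues) == 0)
    return(data.frame(issue = character(0), table = character(0),
                      id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on simulated or on-disk inputs, writing
#' TSV tables, GraphML networks, a resolved-configuration file and a JSON
#' run report under `config$output_dir`. Per-site networks are built only
#' for sites with the complete monthly series. Fully deterministic under a
#' fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return The run report (list of class `run_report`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), warnings = character(0), outputs = character(0),
                 seeds = list(master = config$seed))
  add_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }
  emit <- function(df, name) {
    p <- write_tsv(df, file.path(out_dir, name))
    report$outputs <<- c(report$outputs, name)
    p
  }

  ## ---- inputs -------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- simulate_scenario(config$scenario)
    input_dir <- file.path(out_dir, "input")
    write_scenario(sim, input_dir)
    metadata <- sim$metadata; chemistry <- sim$chemistry
    counts <- list(asv_16s = sim$counts_16s, asv_18s = sim$counts_18s)
    taxonomy <- sim$taxonomy; truth <- sim$truth
    months <- config$scenario$months
  } else {
    input_dir <- config$input_dir
    need <- c("asv_16s.tsv", "asv_18s.tsv", "taxonomy.tsv", "metadata.tsv",
              "chemistry.tsv")
    missing <- need[!file.exists(file.path(input_dir, need))]
    if (length(missing) > 0)
      stop_f("missing required table(s): %s", paste(missing, collapse = ", "))
    metadata <- read.delim(file.path(input_dir, "metadata.tsv"),
                           stringsAsFactors = FALSE)
    chemistry <- read.delim(file.path(input_dir, "chemistry.tsv"),
                            stringsAsFactors = FALSE)
    counts <- list(asv_16s = read_count_table(file.path(input_dir, "asv_16s.tsv")),
                   asv_18s = read_count_table(file.path(input_dir, "asv_18s.tsv")))
    taxonomy <- read_taxonomy(file.path(input_dir, "taxonomy.tsv"))
    truth <- NULL
    months <- unique(metadata$month)
  }
  add_stage("input", n_samples = nrow(metadata),
            n_taxa_16s = ncol(counts$asv_16s), n_taxa_18s = ncol(counts$asv_18s),
            source = if (is.null(config$scenario)) "files" else "simulation")

  issues <- validate_inputs(metadata, chemistry, counts)
  add_stage("validate", n_issues = nrow(issues),
            issues = if (nrow(issues)) issues else NULL)
  # orphan samples (present in a count table but not in the metadata) are
  # reported above and excluded from analysis
  for (nm in names(counts)) {
    keep <- rownames(counts[[nm]]) %in% metadata$sample_id
    if (!all(keep))
      counts[[nm]] <- count_table(as_count_matrix(counts[[nm]])[keep, , drop = FALSE])
  }

  ## ---- rarefaction --------------------------------------------------
  depth_16s <- config$rarefaction_depth_16s
  depth_18s <- config$rarefaction_depth_18s
  if (!is.null(config$scenario)) {
    depth_16s <- min(rowSums(counts$asv_16s))
    depth_18s <- min(rowSums(counts$asv_18s))
  }
  rar_16s <- rarefy(counts$asv_16s, depth_16s,
                    seed = derive_seed(config$seed, "rarefy_16s"))
  rar_18s <- rarefy(counts$asv_18s, depth_18s,
                    seed = derive_seed(config$seed, "rarefy_18s"))
  add_stage("rarefaction",
            depth_16s = depth_16s, depth_18s = depth_18s,
            samples_dropped_16s = length(attr(rar_16s, "dropped_samples")),
            samples_dropped_18s = length(attr(rar_18s, "dropped_samples")))

  ## ---- non-target filter (18S) --------------------------------------
  taxa_in <- ncol(rar_18s)
  rar_18s <- filter_nontarget_protists(rar_18s, taxonomy)
  add_stage("nontarget_filter", taxa_in = taxa_in, taxa_out = ncol(rar_18s),
            taxa_removed = taxa_in - ncol(rar_18s))

  ## ---- split organism groups ----------------------------------------
  grp_of <- setNames(taxonomy$group, taxonomy$taxon_id)
  tables <- list(
    bacteria = rar_16s,
    fungi = count_table(as_count_matrix(rar_18s)[, grp_of[colnames(rar_18s)] == "fungi",
                                                 drop = FALSE]),
    protist = count_table(as_count_matrix(rar_18s)[, grp_of[colnames(rar_18s)] == "protist",
                                                   drop = FALSE])
  )

  ## ---- alpha diversity ----------------------------------------------
  for (grp in names(tables)) {
    at <- suppressWarnings(alpha_table(tables[[grp]], metadata))
    emit(at, sprintf("alpha_%s.tsv", grp))
    for (fac in c("site", "month")) {
      cmp <- anova_tukey(at$shannon, at[[fac]], alpha = config$alpha)
      emit(cbind(factor = fac, cmp$groups,
                 anova_F = cmp$anova$F, anova_p = cmp$anova$p),
           sprintf("anova_shannon_%s_by_%s.tsv", grp, fac))
    }
  }
  add_stage("diversity", groups = names(tables))

  ## ---- ordination ----------------------------------------------------
  dists <- list()
  for (grp in names(tables)) {
    dists[[grp]] <- bray_curtis(tables[[grp]])
    nm <- nmds(dists[[grp]], k = config$nmds_k, n_starts = config$nmds_starts,
               seed = derive_seed(config$seed, paste0("nmds_", grp)))
    emit(data.frame(sample_id = rownames(nm$points), nm$points,
                    stringsAsFactors = FALSE),
         sprintf("nmds_%s.tsv", grp))
    report$stages[[paste0("nmds_", grp)]] <- list(stress = nm$stress,
                                                  converged = nm$converged)
  }
  pca <- chem_pca(chemistry)
  emit(data.frame(sample_id = rownames(pca$scores), pca$scores), "pca_scores.tsv")
  emit(data.frame(variable = rownames(pca$loadings), pca$loadings), "pca_loadings.tsv")
  emit(data.frame(variable = rownames(pca$contributions), pca$contributions),
       "pca_contributions.tsv")
  add_stage("ordination",
            pca_pc1_explained = pca$explained_variance[1],
            pca_pc2_explained = pca$explained_variance[2])

  ## ---- association ----------------------------------------------------
  chem_ord <- chemistry[match(rownames(as_count_matrix(tables$bacteria)),
                              chemistry$sample_id), ]
  mt <- mantel_table(dists, chem_ord,
                     n_permutations = config$mantel_permutations,
                     seed = derive_seed(config$seed, "mantel"))
  emit(mt, "mantel_table.tsv")

  phylum_ra <- do.call(cbind, lapply(names(tables), function(grp)
    aggregate_relative_abundance(tables[[grp]], taxonomy, "phylum")))
  scr_phylum <- pearson_screen(chem_ord, phylum_ra, alpha = config$alpha)
  emit(screen_to_long(scr_phylum), "pearson_screen_phylum.tsv")
  genus_ra <- aggregate_relative_abundance(tables$bacteria, taxonomy, "genus")
  scr_genus <- pearson_screen(chem_ord, genus_ra, alpha = config$alpha,
                              top_n = config$top_n_genera)
  emit(screen_to_long(scr_genus), "pearson_screen_genus.tsv")
  add_stage("association",
            mantel_permutations = config$mantel_permutations,
            n_significant_phylum_cells = sum(scr_phylum$significant))

  ## ---- per-site networks ---------------------------------------------
  pooled <- do.call(cbind, lapply(tables, as_count_matrix))
  colnames(pooled) <- unlist(lapply(tables, colnames), use.names = FALSE)
  summaries <- list()
  recoveries <- list()
  skipped <- character(0)
  for (site in unique(metadata$site)) {
    rows <- metadata$sample_id[metadata$site == site]
    have <- rows[rows %in% rownames(pooled)]
    if (length(have) < length(months) ||
        !setequal(metadata$month[match(have, metadata$sample_id)], months)) {
      skipped <- c(skipped, site)
      next
    }
    # order samples chronologically within the site
    have <- have[order(match(metadata$month[match(have, metadata$sample_id)], months))]
    net <- site_network(count_table(pooled[have, , drop = FALSE]),
                        min_months = config$min_months,
                        min_total_reads = config$min_total_reads,
                        r_threshold = config$r_threshold,
                        p_threshold = config$p_threshold,
                        use_adjusted_p = config$use_adjusted_p,
                        taxonomy = taxonomy,
                        seed = derive_seed(config$seed, paste0("louvain_", site)))
    summaries[[site]] <- net$summary
    if (!is.null(net$nodes)) {
      emit(cbind(site = site, net$nodes), sprintf("network_nodes_%s.tsv", site))
      export_graphml(net$graph, file.path(out_dir, sprintf("network_%s.graphml", site)),
                     node_table = net$nodes)
      report$outputs <- c(report$outputs, sprintf("network_%s.graphml", site))
    }
    if (!is.null(truth)) recoveries[[site]] <- score_network_recovery(net, truth)
  }
  if (length(summaries) > 0) {
    topo <- do.call(rbind, summaries)
    topo <- cbind(site = names(summaries), topo)
    emit(topo, "network_topology.tsv")
  }
  add_stage("networks", sites_built = names(summaries), sites_skipped = skipped,
            recovery = if (length(recoveries)) recoveries else NULL)

  ## ---- resolved config + report ---------------------------------------
  resolved <- list(
    rarefaction_depth_16s = depth_16s, rarefaction_depth_18s = depth_18s,
    min_months = config$min_months, min_total_reads = config$min_total_reads,
    r_threshold = config$r_threshold, p_threshold = config$p_threshold,
    use_adjusted_p = config$use_adjusted_p,
    mantel_permutations = config$mantel_permutations, alpha = config$alpha,
    zi_threshold = config$zi_threshold, pi_threshold = config$pi_threshold,
    nmds_k = config$nmds_k, nmds_starts = config$nmds_starts,
    top_n_genera = config$top_n_genera, seed = config$seed
  )
  writeLines(paste(names(resolved), unlist(resolved), sep = " = "),
             file.path(out_dir, "resolved_config.txt"))
  report$resolved_config <- resolved
  report$outputs <- sort(unique(c(report$outputs, "resolved_config.txt")))
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

screen_to_long <- function(scr) {
  long <- expand.grid(variable = rownames(scr$r), taxon = colnames(scr$r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.vector(scr$r)
  long$p <- as.vector(scr$p)
  long$significant <- as.vector(scr$significant)
  long
}

#' @export
print.run_report <- function(x, ...) {
  cat("poolnet run report\n")
  cat(sprintf("  stages: %s\n", paste(names(x$stages), collapse = ", ")))
  cat(sprintf("  outputs: %d files\n", length(x$outputs)))
  invisible(x)
}
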