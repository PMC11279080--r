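# Synthetic community generator emulating the 8-site x 11-month breeding
# pool survey: core/edge diversity gradient, seasonal temperature forcing,
# eutrophication covariates elevated in core sites and summer, and planted
# co-occurring ASV guilds, with a ground-truth record for recovery scoring.

#' Default monthly design (sampling suspended in February)
#' @export
MONTHS_DEFAULT <- c("Jan", "Mar", "Apr", "May", "Jun", "Jul", "Aug",
                    "Sep", "Oct", "Nov", "Dec")

MONTH_NUMBER <- c(Jan = 1, Feb = 2, Mar = 3, Apr = 4, May = 5, Jun = 6,
                  Jul = 7, Aug = 8, Sep = 9, Oct = 10, Nov = 11, Dec = 12)

#' Map month labels to seasons
#'
#' Spring: March-May; Summer: June-August; Autumn: September-November;
#' Winter: December and January (and February, outside the default design).
#'
#' @param month character vector of three-letter month labels.
#' @return Character vector of season names.
#' @export
month_season <- function(month) {
  n <- MONTH_NUMBER[month]
  if (anyNA(n)) stop_f("unknown month label(s): %s",
                       paste(month[is.na(n)], collapse = ", "))
  unname(c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
           "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")[n])
}

default_site_labels <- function(n_sites) {
  if (n_sites == 8) c("Inlet", paste0("Site", 1:6), "Outlet")
  else paste0("Site", seq_len(n_sites))
}

#' Scenario configuration for the synthetic generator
#'
#' Encodes the study conditions the generator emulates. Defaults give the
#' 8-site (Inlet, Site 1-6, Outlet) by 11-month (no February) design with a
#' core-vs-edge evenness gradient, sinusoidal water temperature peaking in
#' July, eutrophication covariates (TN, TP, CODMn, Chla) elevated in core
#' sites and in summer, chemistry-linked taxa and co-occurring ASV guilds.
#'
#' @param seed master integer seed; fully determines all outputs.
#' @param n_sites number of sampling sites.
#' @param months month labels sampled (February is rejected).
#' @param n_asvs_bacteria,n_asvs_euk ASV counts for the 16S and 18S tables.
#' @param sequencing_depth_mean mean reads per sample (totals are Poisson
#'   around this).
#' @param diversity_gradient multiplier (>= 0) by which the spread of taxon
#'   log-baselines grows in core sites, reducing evenness (hence Shannon and
#'   effective richness) there.
#' @param eutrophication_effect uplift (in units of each variable's baseline
#'   SD) applied to TN, TP, CODMn and Chla in core sites and in summer.
#' @param temperature_amplitude seasonal temperature half-range in degrees C.
#' @param n_guilds,guild_size number and size of planted co-occurring guilds
#'   (within the bacterial table).
#' @param guild_noise_sd per-member log-abundance noise around the shared
#'   guild trajectory.
#' @param chem_link_effect strength (log-units per SD of the variable) of the
#'   planted chemistry-taxon links.
#' @param core_sites site labels forming the wetland core (default Site 3-5).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_sites = 8L,
                            months = MONTHS_DEFAULT,
                            n_asvs_bacteria = 150L,
                            n_asvs_euk = 130L,
                            sequencing_depth_mean = 50000L,
                            diversity_gradient = 0.5,
                            eutrophication_effect = 1.5,
                            temperature_amplitude = 10,
                            n_guilds = 3L,
                            guild_size = 10L,
                            guild_noise_sd = 0.15,
                            chem_link_effect = 1.2,
                            core_sites = NULL) {
  if ("Feb" %in% months) stop_f("months must not contain February (design: sampling suspended)")
  if (anyDuplicated(months)) stop_f("duplicate month labels")
  month_season(months)  # validates labels
  stopifnot(n_sites >= 1, n_asvs_bacteria >= 1, n_asvs_euk >= 20,
            sequencing_depth_mean >= 100)
  for (nm in c("diversity_gradient", "eutrophication_effect",
               "temperature_amplitude", "guild_noise_sd", "chem_link_effect"))
    check_nonneg(get(nm), nm)
  if (n_guilds > 0 && n_guilds * guild_size > n_asvs_bacteria)
    stop_f("n_guilds x guild_size (%d) exceeds n_asvs_bacteria (%d)",
           n_guilds * guild_size, n_asvs_bacteria)
  sites <- default_site_labels(n_sites)
  core_sites <- core_sites %||% intersect(c("Site3", "Site4", "Site5"), sites)
  if (!all(core_sites %in% sites)) stop_f("core_sites outside the site set")
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 months = months, sites = sites, core_sites = core_sites,
                 n_asvs_bacteria = as.integer(n_asvs_bacteria),
                 n_asvs_euk = as.integer(n_asvs_euk),
                 sequencing_depth_mean = as.integer(sequencing_depth_mean),
                 diversity_gradient = diversity_gradient,
                 eutrophication_effect = eutrophication_effect,
                 temperature_amplitude = temperature_amplitude,
                 n_guilds = as.integer(n_guilds),
                 guild_size = as.integer(guild_size),
                 guild_noise_sd = guild_noise_sd,
                 chem_link_effect = chem_link_effect),
            class = "scenario_config")
}

#' Null scenario: all planted effects switched off
#'
#' Same design matrix, but no diversity gradient, no eutrophication or
#' temperature forcing, no chemistry-taxon links and no guilds. Used to
#' measure the pipeline's false-positive behaviour.
#'
#' @param seed master seed.
#' @param ... further overrides passed to [scenario_config()].
#' @export
null_scenario <- function(seed = 1L, ...) {
  scenario_config(seed = seed, diversity_gradient = 0,
                  eutrophication_effect = 0, temperature_amplitude = 0,
                  n_guilds = 0L, guild_noise_sd = 0, chem_link_effect = 0, ...)
}

#' Generate the sample metadata frame
#'
#' One row per (site, month) with derived season and core/edge zone.
#'
#' @param config a [scenario_config()].
#' @return Data frame with columns sample_id, site, month, season, zone.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  df <- expand.grid(month = config$months, site = config$sites,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("site", "month")]
  if (anyDuplicated(df)) stop_f("duplicate (site, month) combinations")
  df$sample_id <- paste(df$site, df$month, sep = "_")
  df$season <- month_season(df$month)
  df$zone <- ifelse(df$site %in% config$core_sites, "core", "edge")
  rownames(df) <- NULL
  df[, c("sample_id", "site", "month", "season", "zone")]
}

# Baseline mean and SD for each chemistry variable (units as in
# CHEM_VARIABLES); temperature handled separately by the sinusoid.
CHEM_BASELINES <- list(
  pH    = c(mean = 6.2,  sd = 0.25),
  Temp  = c(mean = 13,   sd = 1.0),
  DO    = c(mean = 8.0,  sd = 0.8),
  EC    = c(mean = 55,   sd = 8),
  NTU   = c(mean = 6.0,  sd = 1.5),
  TN    = c(mean = 0.9,  sd = 0.25),
  TP    = c(mean = 0.05, sd = 0.015),
  CODMn = c(mean = 4.5,  sd = 0.9),
  Chla  = c(mean = 6.0,  sd = 1.8)
)

EUTROPHIC_VARS <- c("TN", "TP", "CODMn", "Chla")

#' Generate per-sample water chemistry
#'
#' Temperature follows a sinusoid over calendar months peaking in July with
#' half-range `temperature_amplitude`; TN, TP, CODMn and Chla receive an
#' uplift of `eutrophication_effect` baseline SDs in core sites and in
#' summer; all variables carry seeded Gaussian noise.
#'
#' @param config a [scenario_config()].
#' @param frame metadata from [generate_metadata()].
#' @return Data frame: sample_id plus the nine [CHEM_VARIABLES].
#' @export
generate_chemistry <- function(config, frame) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(derive_seed(config$seed, "chemistry"))
  n <- nrow(frame)
  out <- data.frame(sample_id = frame$sample_id, stringsAsFactors = FALSE)
  mnum <- MONTH_NUMBER[frame$month]
  for (v in CHEM_VARIABLES) {
    b <- CHEM_BASELINES[[v]]
    x <- if (v == "Temp") {
      b["mean"] + config$temperature_amplitude * cospi((mnum - 7) / 6) +
        rnorm(n, 0, b["sd"])
    } else {
      rnorm(n, b["mean"], b["sd"])
    }
    if (v %in% EUTROPHIC_VARS) {
      x <- x + config$eutrophication_effect * b["sd"] *
        ((frame$zone == "core") + (frame$season == "Summer"))
    }
    if (!v %in% c("pH", "Temp")) x <- pmax(x, 0.02 * b["mean"])
    out[[v]] <- unname(x)
  }
  out
}

# Composition of the 18S table by phylum; contaminant lineages included to
# exercise the non-target filter.
euk_phylum_plan <- function(n) {
  base <- c(Chytridiomycota = 18, Basidiomycota = 12, Ascomycota = 10,
            Alveolata = 25, Stramenopiles = 25, Chlorophyta = 14, Rhizaria = 14,
            Metazoa = 4, Streptophyta = 3, Rhodophyta = 2, Opisthokonta = 1,
            unassigned = 2)
  plan <- round(base / sum(base) * n)
  plan[1] <- plan[1] + n - sum(plan)
  plan
}

FUNGAL_PHYLA <- c("Chytridiomycota", "Basidiomycota", "Ascomycota")
CONTAMINANT_PHYLA <- c("Metazoa", "Streptophyta", "Rhodophyta", "Opisthokonta",
                       "unassigned")

#' Generate the ASV count tables, taxonomy and planted truth
#'
#' Per sample, taxon log-abundances follow a log-normal compositional model:
#' a taxon baseline whose spread is widened by `diversity_gradient` in core
#' sites (lower evenness), plus planted chemistry links (log-linear in the
#' z-scored variable), plus a shared AR(1) monthly guild trajectory per
#' guild and site, plus Gaussian noise. Relative abundances are the softmax
#' of these log-abundances and counts are multinomial at Poisson sequencing
#' depth. Taxonomy includes the dominant field lineages and contaminant
#' lineages for filter testing.
#'
#' @param config a [scenario_config()].
#' @param frame metadata from [generate_metadata()].
#' @param chem chemistry from [generate_chemistry()].
#' @return List with `counts_16s`, `counts_18s` ([count_table()]s),
#'   `taxonomy` (one table covering both markers, with `marker` and `group`
#'   columns) and `truth` (a `planted_truth` list).
#' @export
generate_asv_tables <- function(config, frame, chem) {
  stopifnot(inherits(config, "scenario_config"),
            identical(frame$sample_id, chem$sample_id))
  nB <- config$n_asvs_bacteria
  nE <- config$n_asvs_euk

  ## ---- taxonomy -----------------------------------------------------
  set.seed(derive_seed(config$seed, "taxonomy"))
  ids_b <- sprintf("ASV_B%03d", seq_len(nB))
  n_cyano <- min(12L, max(2L, nB %/% 12))
  n_actino <- min(10L, max(2L, nB %/% 15))
  phyla_b <- character(nB)
  phyla_b[seq_len(n_cyano)] <- "Cyanobacteria"
  phyla_b[n_cyano + seq_len(n_actino)] <- "Actinobacteria"
  rest <- which(phyla_b == "")
  phyla_b[rest] <- sample(c("Proteobacteria", "Bacteroidetes", "Firmicutes",
                            "Verrucomicrobia", "Acidobacteria", "Planctomycetes"),
                          length(rest), replace = TRUE,
                          prob = c(0.45, 0.18, 0.1, 0.1, 0.09, 0.08))
  ids_e <- sprintf("ASV_E%03d", seq_len(nE))
  plan <- euk_phylum_plan(nE)
  phyla_e <- rep(names(plan), plan)
  # TP-linked protists: a block of Alveolata ASVs
  alv_idx <- which(phyla_e == "Alveolata")
  tp_linked <- ids_e[alv_idx[seq_len(min(12L, length(alv_idx)))]]

  taxonomy <- data.frame(
    taxon_id = c(ids_b, ids_e),
    domain = c(rep("Bacteria", nB), rep("Eukaryota", nE)),
    phylum = c(phyla_b, phyla_e),
    stringsAsFactors = FALSE
  )
  taxonomy$class <- ifelse(taxonomy$phylum == "unassigned", "unassigned",
                           paste0(taxonomy$phylum, "_cls"))
  taxonomy$order <- ifelse(taxonomy$phylum == "unassigned", "unassigned",
                           paste0(taxonomy$phylum, "_ord"))
  taxonomy$family <- ifelse(taxonomy$phylum == "unassigned", "unassigned",
                            paste0(taxonomy$phylum, "_fam"))
  taxonomy$genus <- ifelse(taxonomy$phylum == "unassigned", "unassigned",
                           paste0("g_", taxonomy$taxon_id))
  taxonomy$marker <- c(rep("16S", nB), rep("18S", nE))
  taxonomy$group <- ifelse(taxonomy$marker == "16S", "bacteria",
                    ifelse(taxonomy$phylum %in% FUNGAL_PHYLA, "fungi",
                    ifelse(taxonomy$phylum %in% CONTAMINANT_PHYLA, "nontarget",
                           "protist")))

  ## ---- planted truth ------------------------------------------------
  guild_ids <- integer(0)
  guild_members <- character(0)
  if (config$n_guilds > 0) {
    # guild members drawn from bacterial ASVs outside the chemistry-linked
    # blocks so the two kinds of planted structure stay separable
    pool <- ids_b[(n_cyano + n_actino + 1):nB]
    guild_members <- pool[seq_len(config$n_guilds * config$guild_size)]
    guild_ids <- rep(seq_len(config$n_guilds), each = config$guild_size)
  }
  names(guild_ids) <- guild_members
  planted_pairs <- NULL
  if (length(guild_members) > 0 && config$guild_size >= 2) {
    planted_pairs <- do.call(rbind, lapply(seq_len(config$n_guilds), function(g) {
      mem <- guild_members[guild_ids == g]
      cmb <- t(utils::combn(mem, 2))
      data.frame(taxon_a = cmb[, 1], taxon_b = cmb[, 2], guild = g,
                 stringsAsFactors = FALSE)
    }))
  }
  chem_links <- if (config$chem_link_effect > 0) {
    data.frame(variable = c("Temp", "Temp", "TP"),
               taxon = c("Cyanobacteria", "Actinobacteria", "Alveolata"),
               rank = "phylum", sign = c(-1, 1, 1), stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(0), taxon = character(0),
               rank = character(0), sign = numeric(0))
  }
  truth <- structure(list(
    site_zone = setNames(ifelse(config$sites %in% config$core_sites,
                                "core", "edge"), config$sites),
    guild_membership = guild_ids,
    planted_pairs = planted_pairs,
    chem_taxon_links = chem_links,
    expected_diversity_order = list(lower = config$core_sites,
                                    higher = setdiff(config$sites, config$core_sites))
  ), class = "planted_truth")

  ## ---- per-ASV slopes and baselines ---------------------------------
  link_sign <- setNames(rep(0, nB + nE), c(ids_b, ids_e))
  link_sign[ids_b[seq_len(n_cyano)]] <- -1                      # Temp-
  link_sign[ids_b[n_cyano + seq_len(n_actino)]] <- +1           # Temp+
  link_sign[tp_linked] <- +1                                    # TP+
  link_var <- setNames(rep("", nB + nE), c(ids_b, ids_e))
  link_var[ids_b[seq_len(n_cyano + n_actino)]] <- "Temp"
  link_var[tp_linked] <- "TP"

  z_temp <- as.numeric(scale(chem$Temp))
  z_tp <- as.numeric(scale(chem$TP))
  if (anyNA(z_temp)) z_temp <- rep(0, nrow(chem))
  if (anyNA(z_tp)) z_tp <- rep(0, nrow(chem))

  make_table <- function(ids, stream) {
    set.seed(derive_seed(config$seed, stream))
    n_taxa <- length(ids)
    mu <- rnorm(n_taxa, 0, 1.1)
    is_guild <- ids %in% guild_members
    # guild members get a high enough baseline that their counts stay off
    # zero through trajectory troughs (rank correlation would otherwise be
    # degraded by ties at zero) and survive the prevalence/abundance filter
    mu[is_guild] <- rnorm(sum(is_guild), 1.3, 0.3)
    beta <- config$chem_link_effect * runif(n_taxa, 0.8, 1.2) *
      link_sign[ids]
    zvar <- ifelse(link_var[ids] == "TP", 1, 0)  # 1 -> TP, 0 -> Temp

    # shared guild trajectories: one AR(1) series per guild per site,
    # unit marginal variance, amplified by a fixed gain
    gain <- 2.2
    rho <- 0.3
    n_months <- length(config$months)
    traj <- array(0, dim = c(max(1, config$n_guilds), length(config$sites), n_months))
    if (config$n_guilds > 0) {
      for (g in seq_len(config$n_guilds)) for (s in seq_along(config$sites)) {
        e <- rnorm(n_months)
        t_ <- numeric(n_months)
        t_[1] <- e[1]
        for (m in 2:n_months) t_[m] <- rho * t_[m - 1] + sqrt(1 - rho^2) * e[m]
        # standardize the realized series so every guild/site trajectory
        # carries the same signal variance (gain^2)
        traj[g, s, ] <- gain * (t_ - mean(t_)) / sd(t_)
      }
    }

    core <- frame$zone == "core"
    site_idx <- match(frame$site, config$sites)
    month_idx <- match(frame$month, config$months)
    depth <- rpois(nrow(frame), config$sequencing_depth_mean)
    counts <- matrix(0, nrow(frame), n_taxa,
                     dimnames = list(frame$sample_id, ids))
    for (i in seq_len(nrow(frame))) {
      eta <- mu * (1 + config$diversity_gradient * core[i]) +
        beta * ifelse(zvar == 1, z_tp[i], z_temp[i]) +
        rnorm(n_taxa, 0, 0.4)
      if (config$n_guilds > 0 && any(is_guild)) {
        # guild members: shared trajectory plus exactly guild_noise_sd of
        # idiosyncratic noise (replacing the generic cell noise, so the
        # noise around the shared signal is the configured one)
        g_of <- guild_ids[ids[is_guild]]
        eta[is_guild] <- mu[is_guild] * (1 + config$diversity_gradient * core[i]) +
          traj[cbind(g_of, site_idx[i], month_idx[i])] +
          rnorm(sum(is_guild), 0, config$guild_noise_sd)
      }
      p <- exp(eta - max(eta))
      counts[i, ] <- rmultinom(1, depth[i], p / sum(p))
    }
    count_table(counts)
  }

  list(counts_16s = make_table(ids_b, "asv_16S"),
       counts_18s = make_table(ids_e, "asv_18S"),
       taxonomy = taxonomy,
       truth = truth)
}

#' Simulate a full scenario bundle
#'
#' Convenience wrapper chaining [generate_metadata()],
#' [generate_chemistry()] and [generate_asv_tables()].
#'
#' @param config a [scenario_config()].
#' @return List with config, metadata, chemistry, counts_16s, counts_18s,
#'   taxonomy and truth.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  frame <- generate_metadata(config)
  chem <- generate_chemistry(config, frame)
  tabs <- generate_asv_tables(config, frame, chem)
  c(list(config = config, metadata = frame, chemistry = chem), tabs)
}

#' Write a simulated bundle to disk as plain-text tables
#'
#' ASV tables as TSV (taxa x samples, first column the ASV id), taxonomy,
#' metadata and chemistry as TSV, and the planted truth as JSON.
#'
#' @param sim a bundle from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts_16s, file.path(dir, "asv_16s.tsv"))
  write_count_table(sim$counts_18s, file.path(dir, "asv_18s.tsv"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write.table(sim$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$chemistry, file.path(dir, "chemistry.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth_json <- list(
    site_zone = as.list(truth$site_zone),
    guild_membership = as.list(truth$guild_membership),
    planted_pairs = truth$planted_pairs,
    chem_taxon_links = truth$chem_taxon_links,
    expected_diversity_order = truth$expected_diversity_order
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
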