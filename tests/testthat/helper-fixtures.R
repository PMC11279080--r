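# Shared fixtures. Unit tests run on a scaled-down scenario (fewer ASVs,
# shallower sequencing) for speed; the planted-structure acceptance checks
# use the full default scenario.

small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_asvs_bacteria = 60L, n_asvs_euk = 40L,
               sequencing_depth_mean = 4000L, n_guilds = 2L, guild_size = 5L)
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

# memoised simulations keyed by config hash, reused across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(config) {
  key <- paste(deparse(unclass(config)), collapse = "")
  key <- digest_key(key)
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_scenario(config)
  .sim_cache[[key]]
}
digest_key <- function(s) sprintf("k%d", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9)

# pooled per-site table (16S + filtered 18S, rarefied to min totals)
pooled_site_table <- function(sim, site, seed = 1L) {
  md <- sim$metadata
  r16 <- rarefy(sim$counts_16s, min(rowSums(sim$counts_16s)),
                seed = derive_seed(seed, "r16"))
  r18 <- filter_nontarget_protists(
    rarefy(sim$counts_18s, min(rowSums(sim$counts_18s)),
           seed = derive_seed(seed, "r18")),
    sim$taxonomy)
  ids <- md$sample_id[md$site == site]
  pooled <- cbind(as.matrix(unclass(r16))[ids, , drop = FALSE],
                  as.matrix(unclass(r18))[ids, , drop = FALSE])
  count_table(pooled)
}
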