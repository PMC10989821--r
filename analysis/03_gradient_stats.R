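#!/usr/bin/env Rscript
# Step 3 — environmental-gradient statistics.
#
# Asks whether salinity behaves as the dominant stress axis: per-transect
# correlation between geographic distance and salinity difference, a Mantel
# test between Bray-Curtis community distance and salinity distance, and
# linear trends of alpha diversity against salinity. Writes results under
# results/gradient/.

suppressMessages(library(salinet))

tab <- read_abundance_tsv("results/prep/rarefied.tsv")
meta <- read_metadata_tsv("results/data/metadata.tsv")
meta <- meta[match(colnames(tab), meta$sample_id), ]

geo <- do.call(rbind, lapply(split(meta, meta$transect), function(m) {
  g <- geo_env_correlation(m, "salinity")
  data.frame(transect = m$transect[1], r = g$r, p = g$p_value)
}))

mt <- mantel_test(community_distance(tab),
                  environment_distance(meta, "salinity"),
                  n_perm = 999, seed = derive_seed(1, "mantel"))

rich <- alpha_diversity(tab, "richness")
shan <- alpha_diversity(tab, "shannon")
tr_rich <- linear_trend(meta$salinity, rich)
tr_shan <- linear_trend(meta$salinity, shan)

dir.create("results/gradient", showWarnings = FALSE, recursive = TRUE)
write.csv(geo, "results/gradient/geo_env.csv", row.names = FALSE)
write.csv(data.frame(metric = c("richness", "shannon"),
                     slope = c(tr_rich$slope, tr_shan$slope),
                     r_squared = c(tr_rich$r_squared, tr_shan$r_squared),
                     p_value = c(tr_rich$p_value, tr_shan$p_value)),
          "results/gradient/alpha_trends.csv", row.names = FALSE)
jsonlite::write_json(unclass(mt), "results/gradient/mantel.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("geographic distance vs salinity difference, per transect:\n")
print(geo, row.names = FALSE)
cat(sprintf("Mantel (community vs salinity distance): r = %.3f, p = %.4g\n",
            mt$r, mt$p_value))
cat(sprintf("richness vs salinity: slope %.2f (p = %.3g)\n",
            tr_rich$slope, tr_rich$p_value))
cat(sprintf("Shannon vs salinity: slope %.3f (p = %.3g)\n",
            tr_shan$slope, tr_shan$p_value))
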