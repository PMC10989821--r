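#!/usr/bin/env Rscript
# Step 5 — per-group co-occurrence networks.
#
# For each of the six salinity groups: keep taxa present in all eight
# samples, CLR-transform, correlate all taxon pairs across the group's
# samples, and keep links with |r| >= 0.96. Reports the topology of each
# network and the linear trend of every topological property against the
# group mean salinity. Networks are written as GraphML under
# results/networks/.

suppressMessages(library(salinet))

tab <- read_abundance_tsv("results/prep/rarefied.tsv")
groups <- read.csv("results/prep/groups.csv")
assign <- read.csv("results/prep/group_assignment.csv")

dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
nets <- list()
for (i in seq_len(nrow(groups))) {
  gid <- groups$group[i]
  ids <- assign$sample_id[assign$group == gid]
  sub <- prevalence_filter(tab, ids, min_prevalence = 1)
  net <- build_network(clr_transform(sub), threshold = 0.96,
                       group_salinity = groups$mean_salinity[i],
                       group_id = gid)
  write_network(net, sprintf("results/networks/network_%s.graphml", gid))
  nets[[gid]] <- net
}

topo <- cbind(group = names(nets),
              mean_salinity = groups$mean_salinity,
              do.call(rbind, lapply(nets, topology)))
rownames(topo) <- NULL
trends <- do.call(rbind, lapply(
  c("n_nodes", "n_links", "avg_degree", "avg_clustering", "density",
    "connectedness", "modularity", "n_modules"),
  function(m) {
    tr <- linear_trend(topo$mean_salinity, topo[[m]])
    data.frame(quantity = m, slope = tr$slope, r_squared = tr$r_squared,
               p_value = tr$p_value)
  }))

write.csv(topo, "results/networks/topology.csv", row.names = FALSE)
write.csv(trends, "results/networks/topology_trends.csv", row.names = FALSE)

print(topo[, c("group", "mean_salinity", "n_nodes", "n_links",
               "avg_degree", "connectedness", "modularity")],
      row.names = FALSE)
cat("\ntrends vs salinity:\n")
print(trends, row.names = FALSE)
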