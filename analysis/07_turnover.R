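#!/usr/bin/env Rscript
# Step 7 — turnover of network communities.
#
# Treats each network's node set as a "network community", walks the
# adjacent pairs n1->n2->...->n6 to decompose shared versus replaced nodes
# by abundance class, and regresses the Bray-Curtis similarity between all
# community pairs on their salinity span. Writes results under
# results/turnover/.

suppressMessages(library(salinet))

tab <- read_abundance_tsv("results/prep/rarefied.tsv")
classes_df <- read.csv("results/prep/classes.csv")
classes <- setNames(factor(classes_df$class,
                           levels = c("abundant", "intermediate", "rare")),
                    classes_df$taxon)
groups <- read.csv("results/prep/groups.csv")
assign <- read.csv("results/prep/group_assignment.csv")

communities <- lapply(seq_len(nrow(groups)), function(i) {
  gid <- groups$group[i]
  net <- read_network(sprintf("results/networks/network_%s.graphml", gid))
  ids <- assign$sample_id[assign$group == gid]
  ab <- rowMeans(sweep(tab[, ids], 2, colSums(tab[, ids]), "/"))
  network_community(net, classes, ab)
})

adjacent <- do.call(rbind, lapply(seq_len(length(communities) - 1),
  function(i) {
    ov <- community_overlap(communities[[i]], communities[[i + 1]])
    data.frame(pair = sprintf("%s-%s", groups$group[i], groups$group[i + 1]),
               n_overlap = length(ov$overlap),
               overlap_abundant = round(ov$proportions$overlap[["abundant"]], 3),
               overlap_rare = round(ov$proportions$overlap[["rare"]], 3))
  }))

member_classes <- do.call(rbind, lapply(communities, function(cc)
  data.frame(group = cc$id, n_nodes = length(cc$nodes),
             prop_abundant = round(mean(cc$classes == "abundant"), 3),
             prop_rare = round(mean(cc$classes == "rare"), 3))))

tt <- turnover_trend(communities)

dir.create("results/turnover", showWarnings = FALSE, recursive = TRUE)
write.csv(adjacent, "results/turnover/adjacent_overlap.csv",
          row.names = FALSE)
write.csv(member_classes, "results/turnover/community_classes.csv",
          row.names = FALSE)
write.csv(tt$pairs, "results/turnover/similarity_pairs.csv",
          row.names = FALSE)

cat("abundance-class shares inside each network community:\n")
print(member_classes, row.names = FALSE)
cat("\nshares inside the overlap of adjacent communities:\n")
print(adjacent, row.names = FALSE)
cat(sprintf("\nsimilarity vs salinity span: slope %.4f (p = %.3g)\n",
            tt$trend$slope, tt$trend$p_value))
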