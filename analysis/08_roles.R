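#!/usr/bin/env Rscript
# Step 8 — roles of the abundant and rare biospheres.
#
# Computes each node's relative degree (degree / network average degree),
# contrasts the abundant and rare biospheres per network (class gap and
# Freeman's theta), regresses all four role statistics on salinity, and
# compares Levins niche breadths between the two biospheres with a
# Wilcoxon rank-sum test. Writes results under results/roles/.

suppressMessages(library(salinet))

tab <- read_abundance_tsv("results/prep/rarefied.tsv")
classes_df <- read.csv("results/prep/classes.csv")
classes <- setNames(factor(classes_df$class,
                           levels = c("abundant", "intermediate", "rare")),
                    classes_df$taxon)
groups <- read.csv("results/prep/groups.csv")

records <- lapply(seq_len(nrow(groups)), function(i)
  relative_degree(read_network(sprintf("results/networks/network_%s.graphml",
                                       groups$group[i])), classes))
rt <- role_trends(records, salinities = groups$mean_salinity)

nb <- levins_breadth(tab, classes)
bc <- breadth_comparison(nb)

dir.create("results/roles", showWarnings = FALSE, recursive = TRUE)
write.csv(do.call(rbind, records), "results/roles/role_records.csv",
          row.names = FALSE)
write.csv(rt$per_network, "results/roles/per_network.csv",
          row.names = FALSE)
write.csv(nb, "results/roles/niche_breadth.csv", row.names = FALSE)

fmt <- function(name, tr) sprintf("  %-22s slope %+.4f  (p = %.3g)",
                                  name, tr$slope, tr$p_value)
cat("role trends vs salinity:\n")
cat(fmt("abundant relative degree", rt$abundant_rd), "\n")
cat(fmt("rare relative degree", rt$rare_rd), "\n")
cat(fmt("abundant - rare gap", rt$class_gap), "\n")
cat(fmt("Freeman's theta", rt$theta), "\n")
cat("\nper-network gap and theta:\n")
print(rt$per_network, row.names = FALSE, digits = 3)
med <- tapply(nb$levins_B, nb$abundance_class, median)
cat(sprintf("\nLevins B median: abundant %.1f vs rare %.1f (Wilcoxon p = %.3g)\n",
            med[["abundant"]], med[["rare"]], bc$p_value))
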