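#!/usr/bin/env Rscript
# Step 2 — community preparation.
#
# Rarefies the simulated table to even depth, assigns every taxon to the
# abundant (> 0.1 %), intermediate or rare (< 0.01 %) biosphere by mean
# relative abundance, and partitions the samples into six salinity-ordered
# groups of eight. Writes the rarefied table, classes and groups under
# results/prep/.

suppressMessages(library(salinet))

tab <- read_abundance_tsv("results/data/abundance.tsv")
meta <- read_metadata_tsv("results/data/metadata.tsv")

res <- rarefy(tab, min(colSums(tab)), seed = derive_seed(1, "rarefy"))
classes <- classify_abundance(res$table)
groups <- assign_salinity_groups(meta, 6)

dir.create("results/prep", showWarnings = FALSE, recursive = TRUE)
write_abundance_tsv(res$table, "results/prep/rarefied.tsv")
write.csv(data.frame(taxon = names(classes), class = as.character(classes)),
          "results/prep/classes.csv", row.names = FALSE)
write.csv(groups$assignment, "results/prep/group_assignment.csv",
          row.names = FALSE)
write.csv(groups$groups, "results/prep/groups.csv", row.names = FALSE)

cat(sprintf("rarefied to %d reads/sample; %d samples dropped\n",
            min(colSums(tab)), nrow(res$dropped)))
print(table(classes))
print(groups)
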