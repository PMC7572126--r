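#!/usr/bin/env Rscript
# Alpha diversity (Chao1, Shannon, evenness), Bray-Curtis beta diversity on
# square-root-transformed abundances, one-factor PERMANOVA of island, and
# NMDS ordination. Requires analysis/01_simulate.R to have been run.

library(miomed)

species <- read_metaphlan_table("results/fixtures/species_metaphlan.tsv")
meta <- read_cohort_csv("results/fixtures/metadata.csv")
al <- align_tables(meta, species)
filt <- filter_rare_taxa(al$table)
cat(sprintf("Rare-taxon filter: %d -> %d species\n",
            ncol(al$table$values), ncol(filt$table$values)))

alpha <- alpha_diversity(filt$table)
write.table(alpha, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Alpha diversity medians: Chao1 %.1f, Shannon %.2f, evenness %.2f\n",
            median(alpha$chao1), median(alpha$shannon), median(alpha$evenness)))

d <- bray_curtis(filt$table)
perma <- permanova(d, al$cohort$island, n_perm = 9999, seed = 42)
print(perma)

ord <- nmds(d, k = 2, n_restarts = 50, seed = 42)
write.table(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
            "results/nmds_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("NMDS stress %.3f (%sconverged)\n", ord$stress,
            if (ord$converged) "" else "NOT "))
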