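#!/usr/bin/env Rscript
# Cohort characteristics table (medians with unadjusted ANOVA and
# age-adjusted ANCOVA p-values; biomarkers tested on the log scale) and the
# Spearman screen of biomarkers against species abundances
# (|rho| >= 0.3 and BH q <= 0.05).

library(miomed)

species <- read_metaphlan_table("results/fixtures/species_metaphlan.tsv")
meta <- read_cohort_csv("results/fixtures/metadata.csv")
al <- align_tables(meta, species)
filt <- filter_rare_taxa(al$table)

bm <- unlist(paper_biomarker_blocks(), use.names = FALSE)
t1 <- table1_compare(al$cohort,
                     c("age", "ssb", "fruit", "vegetables", "takeaway",
                       "seafood", "alcohol", "smoking", "activity", "bmi",
                       "sbp", "map", "glucose", bm),
                     group = "island", log_vars = c("glucose", bm))
write.table(t1, "results/table1.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
sig <- t1$variable[!is.na(t1$p_adjusted) & t1$p_adjusted < 0.05]
cat("Variables differing between islands after age adjustment:\n  ",
    paste(sig, collapse = ", "), "\n")

screen <- spearman_screen(al$cohort[, bm], filt$table$values)
write.table(screen, "results/spearman_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hits <- screen[screen$passed, ]
cat(sprintf("Spearman screen: %d of %d biomarker x species pairs pass\n",
            nrow(hits), nrow(screen)))
print(head(hits[order(-abs(hits$rho)),
                c("biomarker", "feature", "rho", "q")], 8), row.names = FALSE)
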