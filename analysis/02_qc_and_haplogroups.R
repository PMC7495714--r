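#!/usr/bin/env Rscript
# Genotype QC and haplogroup assignment on the simulated raw calls:
# intensity acceptance (> 5 over baseline), > 95% call-rate sample
# filter, sequential-descent calling with disjoint-clade conflict
# detection, European filter, super-haplogroup mapping.  Compares the
# resulting control-column haplogroup frequencies with the published
# ones.

suppressPackageStartupMessages(library(mthaplotau))

tree <- default_tree()
raw <- read_genotype_tsv("results/sim/genotypes.tsv")
subjects <- read.delim("results/sim/subjects.tsv", stringsAsFactors = FALSE)

qc <- qc_cohort(raw, tree$panel)
message(sprintf("QC: %d of %d samples pass the call-rate filter",
                sum(qc$qc_table$passed_qc), nrow(qc$qc_table)))

assignments <- call_haplogroups(qc$genotypes, tree, qc$qc_table)
part <- filter_european(assignments, tree)
message(sprintf("assigned: %d; removed: %d (%s)",
                nrow(part$kept), nrow(part$removed),
                paste(names(table(part$removed$removal_reason)),
                      table(part$removed$removal_reason),
                      sep = "=", collapse = ", ")))

dir.create("results", showWarnings = FALSE)
write.table(part$kept, "results/assignments.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(part$removed, "results/assignments_removed.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# observed control frequencies vs the published control column
ctrl_ids <- subjects$subject_id[subjects$group == "control"]
obs <- table(part$kept$haplogroup[part$kept$sample_id %in% ctrl_ids])
freqs <- control_haplogroup_freqs(tree)
cmp <- data.frame(haplogroup = names(freqs),
                  expected_freq = round(as.numeric(freqs), 4),
                  observed_freq = round(as.numeric(
                    obs[names(freqs)] / sum(obs)), 4))
cmp$observed_freq[is.na(cmp$observed_freq)] <- 0
write.table(cmp, "results/control_frequencies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("largest |observed - expected| control frequency gap: ",
        max(abs(cmp$observed_freq - cmp$expected_freq)))
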