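#!/usr/bin/env Rscript
# Distance shells around the cofactor and the distance-and-variability
# (D&V) position selection: columns whose mapped residue lies <15 A from
# the cofactor and whose modal residue occupies 25-75% of the aligned
# sequences.

suppressMessages(library(specswap))
inp <- "results/synthetic"

msa <- read_alignment(file.path(inp, "alignment.fasta"))
s <- read_structure(file.path(inp, "structure.pdb"))

dist <- residue_min_distances(s, "PLP")
shells <- assign_shells(dist)
first_shell <- residues_within(dist, 3.4, closed = TRUE)

prof <- column_profiles(msa)
map <- map_columns_to_reference(msa, "REF_1", dist)
pos <- select_dv_positions(prof, map, dist)

dir.create("results", showWarnings = FALSE)
write.table(as.data.frame(shells), "results/shells.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(as.data.frame(pos), "results/dv_positions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("First shell (<= 3.40 A): %d residues: %s\n",
            length(first_shell), paste(first_shell, collapse = ", ")))
tabs <- table(shells$shell, useNA = "ifany")
cat("Shell occupancy:", paste(sprintf("%s=%d", names(tabs), tabs),
                              collapse = ", "), "\n")
cat(sprintf("D&V positions (<15 A and 25-75%% modal): %d of %d columns\n",
            nrow(pos), msa$n_col))
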