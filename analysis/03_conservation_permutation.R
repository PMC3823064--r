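#!/usr/bin/env Rscript
# Active-site conservation: per-column q-scores, the summed score of the
# first-shell columns, and a permutation test drawing equally sized
# column sets without replacement from the reference-ungapped columns.
# Also the Venn partition of conserved columns between two sequence
# groups standing in for the AATase/TATase split.

suppressMessages(library(specswap))
inp <- "results/synthetic"

msa <- read_alignment(file.path(inp, "alignment.fasta"))
s <- read_structure(file.path(inp, "structure.pdb"))

q <- qscores(msa)
dist <- residue_min_distances(s, "PLP")
map <- map_columns_to_reference(msa, "REF_1", dist)
first_shell <- residues_within(dist, 3.4, closed = TRUE)
obs_cols <- map$column[map$residue_number %in% first_shell]

perm <- permutation_test(q, obs_cols, map$column, n_perm = 100000L,
                         seed = 11L)
cat(sprintf("Observed q-score sum over %d first-shell columns: %.1f (max %d)\n",
            length(obs_cols), perm$observed_sum, 100 * length(obs_cols)))
cat(sprintf("Largest of %d random sums: %.1f -> p = %.3g\n",
            perm$null_samples, perm$null_max, perm$p_value))

# group-conditional conservation (first 12 vs next 7 non-reference ids,
# the group sizes of the characterized AATase/TATase panels)
ids <- setdiff(msa$ids, "REF_1")
venn <- venn_partition(msa, ids[1:12], ids[13:19])
cat(sprintf("Venn counts at level 0.75 (thresholds %s): both=%d, A-only=%d, B-only=%d\n",
            paste(venn$thresholds, collapse = "/"),
            length(venn$set_intersection), length(venn$set_A_only),
            length(venn$set_B_only)))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(
  observed_sum = perm$observed_sum, null_max = perm$null_max,
  p_value = perm$p_value, n_perm = perm$null_samples,
  observed_columns = obs_cols,
  venn = list(thresholds = as.list(venn$thresholds),
              intersection = venn$set_intersection,
              A_only = venn$set_A_only, B_only = venn$set_B_only)),
  "results/conservation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/conservation.json\n")
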