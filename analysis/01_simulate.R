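#!/usr/bin/env Rscript
# Step 1: write a complete synthetic dataset (gene annotations, CpG islands,
# CTCF sites, promoter sequences, expression, and four read tracks) under
# results/fixtures/. All later steps read only these files.

suppressMessages(library(cpgchrom))

out_dir <- file.path("results", "fixtures")
cfg <- synth_config(n_genes = 200L, read_depth = 30000L, seed = 41L)
paths <- make_fixtures(out_dir, cfg)

cat("wrote", length(paths), "fixture files to", out_dir, "\n")
for (nm in names(paths)) cat(sprintf("  %-12s %s\n", nm, paths[[nm]]))
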