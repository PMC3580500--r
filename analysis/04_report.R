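#!/usr/bin/env Rscript
# Step 4: condense the pipeline's statistical reports into a single
# readable summary at results/summary.txt.

suppressMessages(library(jsonlite))

rep_path <- file.path("results", "pipeline", "stats", "reports.json")
stopifnot(file.exists(rep_path))  # run analysis/02_pipeline.R first
rep <- read_json(rep_path, simplifyVector = TRUE)

lines <- c("Comparative chromatin-profiling summary", "")

for (mk in names(rep$asymmetry)) {
  a <- rep$asymmetry[[mk]]
  lines <- c(lines, sprintf(
    "asymmetry  %-14s median CpG %.3f vs non-CpG %.3f (%s p = %.3g, n = %d + %d)",
    mk, a$median_cpg, a$median_noncpg, a$method, a$p_value, a$n_cpg, a$n_noncpg))
}
for (nm in names(rep$peak_shift)) {
  p <- rep$peak_shift[[nm]]
  lines <- c(lines, sprintf(
    "peak shift %-22s Spearman rho %.3f (p = %.3g, n = %d)",
    nm, p$rho, p$p_value, p$n))
}
if (!is.null(rep$ctcf)) {
  lines <- c(lines, sprintf(
    "CTCF       chi-squared %.2f (p = %.3g)",
    rep$ctcf$chi2_statistic, rep$ctcf$chi2_p))
}

writeLines(lines, file.path("results", "summary.txt"))
writeLines(lines)
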