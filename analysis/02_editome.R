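#!/usr/bin/env Rscript
# The editome analysis: read the simulated per-site tables, run the
# filtering and classification cascade (control subtraction, basic and
# consistency filters, coverage filter, efficiency calls, preference
# labels, log2FD, Welch tests with Storey q-values, region and repeat
# annotation), and write the classification with its summaries. Finishes
# by scoring the labels against the planted truth.

suppressMessages(library(isoedit))

sim <- "results/sim"
out <- "results/editome"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sample_map <- read.delim(file.path(sim, "sample_map.tsv"))
sites <- read_site_table(file.path(sim, "editome_sites.tsv"), sample_map)
gene_models <- read_gene_models(file.path(sim, "gene_models.tsv"))
repeats <- read_repeat_table(file.path(sim, "repeats.tsv"))

res <- run_editome(sites, sample_map, gene_models, repeats)
message("filtering funnel: ",
        paste(names(res$funnel), res$funnel, sep = "=", collapse = " -> "))
message("Storey pi0 estimate: ", round(res$pi0, 3))

write.table(res$classification, file.path(out, "classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$excluded_control, file.path(out, "excluded_control.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
s <- summarize_editome(res$classification)
for (nm in names(s)) {
  write.table(s[[nm]], file.path(out, paste0("summary_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
for (subset in c("efficient_p150", "efficient_p110", "preferred_p150",
                 "preferred_p110")) {
  ev <- events_per_region(res$classification, subset)
  write.table(ev$counts,
              file.path(out, paste0("events_per_gene_", subset, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

truth <- read.delim(file.path(sim, "editome_truth.tsv"))
message("control-positive exclusions: ", nrow(res$excluded_control),
        " (", sum(truth$category == "snp_artifact"), " SNP-like planted)")
m <- merge(res$classification, truth[, c("site", "category")], by = "site")
for (iso in c("p150", "p110")) {
  lab <- paste0(iso, "_preferential")
  cat_ <- paste0(iso, "_specific")
  tp <- sum(m$label == lab & m$category == cat_)
  message(sprintf("%s: sensitivity %.3f, precision %.3f", iso,
                  tp / sum(truth$category == cat_),
                  tp / sum(m$label == lab)))
}
message("wrote ", out)
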