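#!/usr/bin/env Rscript
# Cross-dataset comparisons: intersect classified editing sites with the
# final RIP peaks, compare gene sets (optionally restricted to
# non-repetitive editing), group sites by replicate support, and apply
# the coverage gate.

suppressMessages(library(isoedit))

out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cls <- read.delim("results/editome/classification.tsv")
gene_models <- read_gene_models("results/sim/gene_models.tsv")

report <- list()
for (cond in c("p150", "p110")) {
  peaks <- read_intervals(file.path("results/rip",
                                    paste0("peaks_", cond, ".bed")))
  hit <- intersect_sites_peaks(cls, peaks, strand_mode = "stranded")
  message(cond, " peaks overlap ", hit$n_hit, "/", hit$n_sites,
          " classified sites (", round(100 * hit$fraction, 1), "%)")
  report[[paste0("site_overlap_", cond)]] <-
    data.frame(what = paste0("sites_in_", cond, "_peaks"),
               n = hit$n_hit, total = hit$n_sites,
               fraction = hit$fraction)

  pg <- genes_for_peaks(peaks, gene_models)
  qualifying <- cls[[paste0("efficient_", cond)]]
  go <- gene_level_overlap(cls, pg, qualifying = qualifying,
                           restrict = "nonrepetitive")
  message(cond, ": ", go$n_overlap, " of ",
          length(go$editome_genes),
          " genes with non-repetitive efficient editing are also ",
          "peak-bound (", round(100 * go$fraction, 1), "%)")
  report[[paste0("gene_overlap_", cond)]] <-
    data.frame(what = paste0("nonrepetitive_gene_overlap_", cond),
               n = go$n_overlap, total = length(go$editome_genes),
               fraction = go$fraction)
  writeLines(go$overlap, file.path(out, paste0("genes_", cond, ".txt")))
}
write.table(do.call(rbind, report), file.path(out, "overlap_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# replicate-support grouping on the simulated editome table
sites <- read_site_table("results/sim/editome_sites.tsv")
wide <- reshape(sites[, c("site", "sample_id", "frequency")],
                idvar = "site", timevar = "sample_id",
                direction = "wide")
names(wide) <- sub("^frequency\\.", "", names(wide))
groups <- group_by_support(wide, list(
  exclusive_p150 = list(support_rule("p150", min_edited = 2),
                        support_rule("p110", max_edited = 0)),
  both_isoforms = list(support_rule("p150", min_edited = 2),
                       support_rule("p110", min_edited = 1))))
message("support groups: ",
        paste(names(groups), lengths(groups), sep = "=", collapse = ", "))

# coverage gate across the two isoform "genotypes"
cov_wide <- reshape(sites[, c("site", "sample_id", "coverage")],
                    idvar = "site", timevar = "sample_id",
                    direction = "wide")
names(cov_wide) <- sub("^coverage\\.", "", names(cov_wide))
gated <- coverage_gate(cov_wide, list(
  p150 = grep("^p150", names(cov_wide), value = TRUE),
  p110 = grep("^p110", names(cov_wide), value = TRUE)))
message("coverage gate keeps ", nrow(gated), "/", nrow(cov_wide),
        " sites (mean >= 10 reads in both isoform datasets)")
message("wrote ", out)
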