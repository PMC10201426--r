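#!/usr/bin/env Rscript
# The RIP-seq peak analysis: read the simulated IP/input fragment files,
# run the post-processing chain (pair splitting, strand-split calling
# with the internal Poisson caller, replicate adjacency consensus, MOCK
# subtraction, size/reference filters), write per-condition peak BEDs and
# summary statistics, and score the final peaks against the planted truth.

suppressMessages(library(isoedit))

sim <- "results/sim"
out <- "results/rip"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

frag_files <- list.files(sim, pattern = "^fragments_.*\\.bed$",
                         full.names = TRUE)
fragments <- lapply(frag_files, read_intervals)
names(fragments) <- sub("^fragments_(.*)\\.bed$", "\\1",
                        basename(frag_files))
message("loaded ", length(fragments), " fragment samples")

gene_models <- read_gene_models(file.path(sim, "gene_models.tsv"))
repeats <- read_repeat_table(file.path(sim, "repeats.tsv"))
chrom_sizes <- tapply(gene_models$end, gene_models$chrom, max) + 10000
cfg <- peak_call_config(gsize = 2 * sum(chrom_sizes))

res <- run_rip(fragments, cfg = cfg)
for (cond in names(res$funnel)) {
  message(cond, " funnel: ",
          paste(names(res$funnel[[cond]]), res$funnel[[cond]],
                sep = "=", collapse = " -> "))
}
for (cond in names(res$peaks)) {
  pk <- res$peaks[[cond]]
  S4Vectors::mcols(pk)$name <- cond
  # consensus peaks carry replicate support, not caller scores
  S4Vectors::mcols(pk)$score <- S4Vectors::mcols(pk)$n_support
  write_intervals(pk, file.path(out, paste0("peaks_", cond, ".bed")))
}

st <- peak_stats(res$peaks, gene_models, repeats)
write.table(st$sizes, file.path(out, "peak_sizes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st$overlaps, file.path(out, "peak_overlaps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st$regions, file.path(out, "peak_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st$repeats, file.path(out, "peak_repeats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean peak size: ",
        paste(st$sizes$set, round(st$sizes$mean_size), collapse = ", "))

truth <- read_intervals(file.path(sim, "truth_peaks.bed"))
cond_of <- S4Vectors::mcols(truth)$name
for (cond in names(res$peaks)) {
  m <- match_truth_peaks(res$peaks[[cond]], truth[cond_of == cond])
  message(sprintf("%s: recall %.3f, precision %.3f (%d called / %d truth)",
                  cond, m$recall, m$precision, m$n_called, m$n_truth))
}
message("wrote ", out)
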