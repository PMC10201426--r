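#!/usr/bin/env Rscript
# The amplicon-seq analysis: quantify editing at the known-site panel per
# construct, subtract the negative-control background, apply the 0.5%
# inclusion filter, max-normalize each site across constructs, and write
# the raw/adjusted/normalized matrices.

suppressMessages(library(isoedit))

sim <- "results/sim"
out <- "results/amplicon"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pileups <- read.delim(file.path(sim, "amplicon_pileups.tsv"),
                      check.names = FALSE)
truth <- read.delim(file.path(sim, "amplicon_truth.tsv"))
known <- truth[, c("chrom", "pos", "strand")]

am <- quantify_sites(pileups, known)
write_amplicon_matrix(am, file.path(out, "amplicon"))
am <- subtract_background(am)
am <- inclusion_filter(am)
message(nrow(am$freq), " of ", nrow(known),
        " panel sites pass the 0.5% inclusion filter")
am <- normalize_rows(am)
write_amplicon_matrix(am, file.path(out, "amplicon_final"))

top <- colnames(am$normalized)[apply(
  am$normalized[, setdiff(colnames(am$normalized), "control"),
                drop = FALSE], 1, which.max)]
message("per-site maximal editase: ",
        paste(names(table(top)), table(top), sep = "=", collapse = ", "))
message("wrote ", out)
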