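#!/usr/bin/env Rscript
# Stage 3: collapse probe signals to per-transcript m6A methylation level,
# m6A quantity, and expression level for every sample.

library(m6Aarray)

dat <- "results/data"
out <- "results"

ip <- read_channel_matrix(file.path(dat, "ip.tsv"), "IP")
sup <- read_channel_matrix(file.path(dat, "sup.tsv"), "Sup")
panel <- read_probe_panel(file.path(dat, "panel.tsv"))
targets <- readLines("results/preprocess/selected_probes.txt")

quant <- compute_quant(normalize_spikein(ip, panel),
                       normalize_spikein(sup, panel), panel, targets)
write_quant_table(quant, file.path(out, "quant.tsv"))

cat(sprintf(
  "quantified %d transcripts x %d samples; median m6A level %.2f (IQR %.2f-%.2f)\n",
  nrow(quant$transcripts), length(quant$samples),
  median(quant$level), quantile(quant$level, 0.25),
  quantile(quant$level, 0.75)))
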