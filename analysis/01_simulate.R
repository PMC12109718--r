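#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-channel array study and write every
# on-disk artifact the downstream stages read. Design mirrors the study:
# three groups (Ctrl, FS, FS-DBS) x triplicate arrays, spike-in controls,
# ~80:20 hyper:hypo planting after the insult, half of the insult effects
# reversed by the treatment.

library(m6Aarray)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(n_genes = 2000, seed = 20250901)
d <- generate_dataset(cfg)

write_channel_matrix(d$ip, file.path(out, "ip.tsv"))
write_channel_matrix(d$sup, file.path(out, "sup.tsv"))
write_probe_panel(d$panel, file.path(out, "panel.tsv"))
write_design_table(d$design, file.path(out, "design.tsv"))
write_ground_truth(d$truth, file.path(out, "ground_truth.tsv"))

tr1 <- d$truth[d$truth$comparison == cfg$comparisons[1], ]
cat(sprintf(
  "simulated %d genes + %d spike-ins x %d arrays; planted %d hyper / %d hypo (%s), %d reversed\n",
  cfg$n_genes, cfg$n_spikeins, nrow(d$design),
  sum(tr1$true_class == "hyper"), sum(tr1$true_class == "hypo"),
  cfg$comparisons[1], sum(tr1$reversed)))
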