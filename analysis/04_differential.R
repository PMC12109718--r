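#!/usr/bin/env Rscript
# Stage 4: classify hyper-/hypomethylation and expression changes for the
# three group comparisons at the 1.5-fold cut-off, report direction
# proportions, and measure how quantity and level fold changes track
# expression.

library(m6Aarray)

dat <- "results/data"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

d <- list(ip = read_channel_matrix(file.path(dat, "ip.tsv"), "IP"),
          sup = read_channel_matrix(file.path(dat, "sup.tsv"), "Sup"),
          panel = read_probe_panel(file.path(dat, "panel.tsv")),
          design = read_design_table(file.path(dat, "design.tsv")))
res <- run_pipeline_full(d)

for (nm in names(res$methylation)) {
  write_diff_table(res$methylation[[nm]],
                   file.path(out, paste0("methylation_", nm, ".tsv")))
  write_diff_table(res$expression[[nm]],
                   file.path(out, paste0("expression_", nm, ".tsv")))
  pr <- direction_proportions(res$methylation[[nm]])
  pe <- direction_proportions(res$expression[[nm]])
  cat(sprintf(
    "%s: %d changed (%.1f%% hyper / %.1f%% hypo); expression %d changed (%.1f%% up)\n",
    nm, pr$n_changed, pr$pct_hyper, pr$pct_hypo, pe$n_changed,
    pe$pct_hyper))
}

cc <- concordance(res$methylation[[1]], res$expression[[1]],
                  res$level[[1]])
write.table(cc, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "fold-change concordance with expression: quantity rho = %.2f, level rho = %.2f\n",
  cc$rho[cc$pair == "quantity_vs_expression"],
  cc$rho[cc$pair == "level_vs_expression"]))
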