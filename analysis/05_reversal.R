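#!/usr/bin/env Rscript
# Stage 5: directional reversal intersections — transcripts the insult
# shifted one way and the treatment shifted back — in both directions,
# checked against the planted ground truth.

library(m6Aarray)

dat <- "results/data"
out <- "results/reversal"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

d <- list(ip = read_channel_matrix(file.path(dat, "ip.tsv"), "IP"),
          sup = read_channel_matrix(file.path(dat, "sup.tsv"), "Sup"),
          panel = read_probe_panel(file.path(dat, "panel.tsv")),
          design = read_design_table(file.path(dat, "design.tsv")))
res <- run_pipeline_full(d)
ab <- res$methylation[[1]]          # insult vs control
cb <- res$methylation[[3]]          # treated vs insult

truth <- read.delim(file.path(dat, "ground_truth.tsv"))
cmp <- unique(truth$comparison)
tr1 <- truth[truth$comparison == cmp[1], ]
tr2 <- truth[truth$comparison == cmp[2], ]

for (dir_ in c("attenuation", "enhancement")) {
  rv <- reversal_intersection(ab, cb, dir_)
  write_reversal_summary(rv, file.path(out, paste0(dir_, ".json")))
  cls <- if (dir_ == "attenuation") c("hyper", "hypo") else
    c("hypo", "hyper")
  planted <- tr1$gene_id[tr1$true_class == cls[1] &
                           tr2$true_class[match(tr1$gene_id,
                                                tr2$gene_id)] == cls[2]]
  cat(sprintf(
    "%s: |A| = %d, |B| = %d, overlap = %d (%.1f%% of union); %d/%d planted reversals found\n",
    dir_, rv$size_a, rv$size_b, rv$intersection, rv$pct_of_union,
    length(intersect(rv$members, planted)), length(planted)))
}
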