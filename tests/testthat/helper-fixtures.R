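# Small hand-built fixtures shared across test files.

# a 2-group design with triplicates
tiny_design <- function(groups = c("Ctrl", "FS"), reps = 3) {
  design_table(sample_id = paste0(rep(gsub("-", ".", groups), each = reps),
                                  "_", rep(seq_len(reps), length(groups))),
               group = rep(groups, each = reps),
               replicate = rep(seq_len(reps), length(groups)))
}

# channel matrix with constant flags; values given as probes x samples
tiny_channel <- function(values, fraction = "IP", flags = NULL) {
  if (is.null(flags))
    flags <- matrix("P", nrow(values), ncol(values),
                    dimnames = dimnames(values))
  channel_matrix(values, flags, fraction)
}

# panel of n gene probes (1:1 probe:transcript) plus s spike-ins
tiny_panel <- function(n, s = 2) {
  g <- sprintf("g%02d", seq_len(n))
  sp <- sprintf("sp%02d", seq_len(s))
  probe_panel(probe_id = paste0("p_", c(g, sp)),
              transcript_id = c(g, sp),
              gene_symbol = c(toupper(g), rep(NA_character_, s)),
              is_spikein = c(rep(FALSE, n), rep(TRUE, s)),
              rna_class = c(rep("mRNA", n), rep(NA_character_, s)))
}

# quant_table built directly from linear IP / Sup per-transcript matrices
tiny_quant <- function(ip, sup, rna_class = "mRNA") {
  tid <- rownames(ip)
  ann <- data.frame(transcript_id = tid, gene_symbol = toupper(tid),
                    rna_class = rna_class, stringsAsFactors = FALSE)
  structure(list(transcripts = ann, level = ip / (ip + sup),
                 quantity = ip, expression = ip + sup,
                 samples = colnames(ip)),
            class = "quant_table")
}

# diff_table with prescribed classes (for set-level operations)
diff_fixture <- function(transcript_id, class,
                         measure = "quantity", rna_class = "mRNA") {
  out <- data.frame(transcript_id = transcript_id,
                    gene_symbol = toupper(transcript_id),
                    rna_class = rna_class,
                    mean_log2_test = 0, mean_log2_ref = 0, log2fc = 0,
                    class = class, stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(test = "FS", ref = "Ctrl")
  attr(out, "measure") <- measure
  attr(out, "fc_threshold") <- 1.5
  class(out) <- c("diff_table", "data.frame")
  out
}

# diff_table pair with planted set sizes and intersection, for reversal
# checks: n total transcripts; a first size_a are "hyper" in table ab; the
# last size_b are "hypo" in table cb, overlapping the first set in exactly
# n_int transcripts
reversal_fixture <- function(size_a, size_b, n_int, n_total) {
  stopifnot(size_a + size_b - n_int <= n_total)
  ids <- sprintf("t%06d", seq_len(n_total))
  a_ids <- ids[seq_len(size_a)]
  b_ids <- ids[c(seq(size_a - n_int + 1, size_a),
                 seq(size_a + 1, size_a + size_b - n_int))]
  cls_ab <- ifelse(ids %in% a_ids, "hyper", "unchanged")
  cls_cb <- ifelse(ids %in% b_ids, "hypo", "unchanged")
  list(ab = diff_fixture(ids, cls_ab), cb = diff_fixture(ids, cls_cb))
}
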