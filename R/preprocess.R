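#' Select analyzable probes by detection flags
#'
#' A probe is retained when it carries a present (`"P"`), marginal (`"M"`)
#' or quality-control (`"QC"`) flag in at least one sample of either
#' fraction; probes flagged absent (`"A"`) everywhere are dropped. Spike-in
#' control probes are excluded from the returned set (they are retained
#' internally for normalization only and must never enter differential
#' tables).
#'
#' @param flags_ip,flags_sup character flag matrices (probes x samples),
#'   e.g. the `flags` element of a [channel_matrix()].
#' @param design a [design_table()] whose sample IDs match the flag columns.
#' @param panel a [probe_panel()] used to exclude spike-ins; may be `NULL`
#'   if the matrices contain no spike-in rows.
#' @return character vector of selected probe IDs, in input row order.
#' @export
select_targets <- function(flags_ip, flags_sup, design, panel = NULL) {
  if (!identical(dim(flags_ip), dim(flags_sup)) ||
      !identical(rownames(flags_ip), rownames(flags_sup)))
    stop("IP and Sup flag matrices must share probe and sample indices")
  if (!all(design$sample_id %in% colnames(flags_ip)))
    stop("flag matrices are missing design samples: ",
         paste(setdiff(design$sample_id, colnames(flags_ip)),
               collapse = ", "))
  keep_flags <- c("P", "M", "QC")
  detected <- function(fl)
    rowSums(matrix(fl[, design$sample_id, drop = FALSE] %in% keep_flags,
                   nrow = nrow(fl))) > 0
  hit <- detected(flags_ip) | detected(flags_sup)
  sel <- rownames(flags_ip)[hit]
  if (!is.null(panel))
    sel <- setdiff(sel, panel$probe_id[panel$is_spikein])
  if (length(sel) == 0)
    stop("no probes pass selection: every probe is flagged absent in all ",
         "samples")
  sel
}

#' Normalize one channel against its spike-in controls
#'
#' Raw intensities are floored at 1 fluorescence unit, log2-transformed,
#' and each sample is shifted so that its mean log2 spike-in intensity
#' equals the grand mean of the spike-in intensities across all samples of
#' the channel. This removes per-array scale drift while leaving the
#' within-sample ordering of probes untouched (a per-sample additive shift
#' on the log2 scale). Normalizing an already normalized matrix is a no-op.
#'
#' @param raw a [channel_matrix()].
#' @param panel a [probe_panel()] marking spike-in probes present in `raw`.
#' @return a list of class `normalized_matrix` with elements `fraction`,
#'   `values` (log2 normalized intensities) and `normalization_offsets`
#'   (the per-sample log2 shift that was subtracted).
#' @export
normalize_spikein <- function(raw, panel) {
  if (!inherits(raw, "channel_matrix"))
    stop("'raw' must be a channel_matrix")
  spikes <- intersect(panel$probe_id[panel$is_spikein], rownames(raw$values))
  if (length(spikes) < 2)
    stop("normalization requires >= 2 spike-in probes; found ",
         length(spikes))
  sflags <- raw$flags[spikes, , drop = FALSE]
  if (any(sflags == "A")) {
    bad <- which(sflags == "A", arr.ind = TRUE)[1, ]
    stop(sprintf(
      "spike-in probe '%s' is flagged absent in sample '%s'; cannot anchor",
      spikes[bad[1]], colnames(sflags)[bad[2]]))
  }
  log2v <- log2(pmax(raw$values, 1))
  spike_means <- colMeans(log2v[spikes, , drop = FALSE])
  offsets <- spike_means - mean(spike_means)
  values <- sweep(log2v, 2, offsets, "-")
  structure(list(fraction = raw$fraction, values = values,
                 normalization_offsets = offsets),
            class = "normalized_matrix")
}

#' Per-transcript m6A quantification from normalized IP and Sup signals
#'
#' For each transcript and sample the selected probes are averaged on the
#' linear scale within each channel, giving `IP` and `Sup` signal
#' estimates. The three reported quantities are then: m6A quantity = `IP`
#' (the amount of methylated copies), expression = `IP + Sup` (methylated
#' plus unmethylated copies), and m6A methylation level = `IP / (IP + Sup)`
#' (the fraction of copies carrying the mark). Transcripts with no selected
#' probe are omitted with a message rather than an error.
#'
#' @param ip,sup `normalized_matrix` objects from [normalize_spikein()]
#'   sharing probe and sample indices.
#' @param panel a [probe_panel()] mapping probes to transcripts.
#' @param targets character vector of selected probe IDs, from
#'   [select_targets()].
#' @return a list of class `quant_table` with `transcripts` (data.frame:
#'   `transcript_id`, `gene_symbol`, `rna_class`) and three transcripts x
#'   samples matrices `level`, `quantity`, `expression` (linear normalized
#'   intensity units; `level` is a unitless fraction in (0,1)).
#' @export
compute_quant <- function(ip, sup, panel, targets) {
  if (!identical(rownames(ip$values), rownames(sup$values)) ||
      !identical(colnames(ip$values), colnames(sup$values)))
    stop("IP and Sup matrices must share probe and sample indices")
  if (length(targets) == 0)
    stop("no target probes supplied")
  panel <- panel[!panel$is_spikein, , drop = FALSE]
  missing_t <- setdiff(unique(panel$transcript_id),
                       panel$transcript_id[panel$probe_id %in% targets])
  if (length(missing_t) > 0)
    message(length(missing_t),
            " transcript(s) had no selected probe and were omitted")
  panel <- panel[panel$probe_id %in% targets, , drop = FALSE]
  if (nrow(panel) == 0)
    stop("no target probes remain after excluding spike-ins")

  ip_lin <- 2^ip$values[panel$probe_id, , drop = FALSE]
  sup_lin <- 2^sup$values[panel$probe_id, , drop = FALSE]
  tid <- factor(panel$transcript_id, levels = unique(panel$transcript_id))
  collapse <- function(m)
    rowsum(m, tid, reorder = FALSE) / as.vector(table(tid))
  ip_t <- collapse(ip_lin)
  sup_t <- collapse(sup_lin)

  ann <- panel[!duplicated(panel$transcript_id),
               c("transcript_id", "gene_symbol", "rna_class")]
  rownames(ann) <- NULL
  quantity <- ip_t
  expression <- ip_t + sup_t
  level <- ip_t / expression
  structure(list(transcripts = ann, level = level, quantity = quantity,
                 expression = expression,
                 samples = colnames(ip$values)),
            class = "quant_table")
}
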