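#' Construct a two-channel array intensity matrix for one RNA fraction
#'
#' A `channel_matrix` holds raw (linear-scale) fluorescence intensities and
#' per-cell detection flags for one fraction of a MeRIP two-channel array:
#' either the immunoprecipitated, m6A-carrying pool (`"IP"`, Cy5) or the
#' unbound supernatant pool (`"Sup"`, Cy3).
#'
#' @param values numeric matrix, probes x samples, strictly positive
#'   fluorescence intensities. Must have row names (probe IDs) and column
#'   names (sample IDs).
#' @param flags character matrix of the same dimensions with per-cell
#'   detection calls: `"P"` (present), `"M"` (marginal), `"A"` (absent) or
#'   `"QC"` (quality-control).
#' @param fraction `"IP"` or `"Sup"`.
#' @return an object of class `channel_matrix`: a list with elements
#'   `fraction`, `values` and `flags`.
#' @export
channel_matrix <- function(values, flags, fraction = c("IP", "Sup")) {
  fraction <- match.arg(fraction)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe row names and sample column names")
  if (!is.matrix(flags) || !identical(dim(values), dim(flags)))
    stop("'flags' must be a matrix with the same dimensions as 'values'")
  bad <- which(!(values > 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive intensity at probe '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  unknown <- setdiff(unique(as.vector(flags)), c("P", "M", "A", "QC"))
  if (length(unknown) > 0)
    stop("unknown detection flag symbol(s): ",
         paste(unknown, collapse = ", "))
  dimnames(flags) <- dimnames(values)
  structure(list(fraction = fraction, values = values, flags = flags),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("channel_matrix [%s]: %d probes x %d samples\n",
              x$fraction, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a probe annotation panel
#'
#' Maps probe IDs to transcripts and gene symbols and marks spike-in control
#' probes (exogenous RNAs at known amounts used only for normalization).
#'
#' @param probe_id,transcript_id,gene_symbol character vectors of equal
#'   length; spike-in probes carry `NA` gene symbols.
#' @param is_spikein logical vector.
#' @param rna_class `"mRNA"` or `"lncRNA"` per probe (ignored, set to `NA`,
#'   for spike-ins).
#' @return a `data.frame` with class `probe_panel` prepended.
#' @export
probe_panel <- function(probe_id, transcript_id, gene_symbol, is_spikein,
                        rna_class) {
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id: ",
         probe_id[duplicated(probe_id)][1])
  if (any(is_spikein & !is.na(gene_symbol)))
    stop("spike-in probes must have no gene_symbol")
  ok_class <- is.na(rna_class) | rna_class %in% c("mRNA", "lncRNA")
  if (!all(ok_class))
    stop("rna_class must be 'mRNA' or 'lncRNA' (or NA for spike-ins)")
  out <- data.frame(probe_id = as.character(probe_id),
                    transcript_id = as.character(transcript_id),
                    gene_symbol = as.character(gene_symbol),
                    is_spikein = as.logical(is_spikein),
                    rna_class = as.character(rna_class),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_panel", "data.frame")
  out
}

#' Construct a sample design table
#'
#' @param sample_id character vector of unique sample IDs matching the
#'   intensity matrix columns.
#' @param group character vector of group labels (e.g. `"Ctrl"`, `"FS"`,
#'   `"FS-DBS"`).
#' @param replicate integer replicate index within group.
#' @return a `data.frame` with class `design_table` prepended.
#' @export
design_table <- function(sample_id, group, replicate) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id")
  if (anyDuplicated(paste(group, replicate)))
    stop("(group, replicate) pairs must be unique")
  n_per <- table(group)
  if (any(n_per < 2))
    stop("every group needs >= 2 samples for differential analysis; got ",
         paste(names(n_per)[n_per < 2], collapse = ", "), " with fewer")
  out <- data.frame(sample_id = as.character(sample_id),
                    group = as.character(group),
                    replicate = as.integer(replicate),
                    stringsAsFactors = FALSE)
  class(out) <- c("design_table", "data.frame")
  out
}

# internal: samples of one group, in design order
group_samples <- function(design, group) {
  if (!group %in% design$group)
    stop(sprintf("unknown group '%s'; available groups: %s", group,
                 paste(unique(design$group), collapse = ", ")))
  design$sample_id[design$group == group]
}
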