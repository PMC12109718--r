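#' Run the full analysis pipeline on a two-channel dataset
#'
#' Orchestrates the end-to-end analysis: detection-flag probe selection,
#' spike-in normalization of both channels, per-transcript quantification,
#' differential classification of m6A quantity and expression for each
#' requested comparison, both directional reversal intersections, and
#' (optionally) over-representation analysis of the reversal gene lists.
#' All computation is deterministic given the input dataset; with `out_dir`
#' set every stage output is written to disk.
#'
#' @param dataset a list with elements `ip`, `sup` ([channel_matrix()]),
#'   `panel` ([probe_panel()]) and `design` ([design_table()]), e.g. the
#'   output of [generate_dataset()].
#' @param comparisons list of `c(test, ref)` group pairs. Defaults to the
#'   insult-vs-control, treated-vs-control and treated-vs-insult contrasts
#'   implied by the design's group order.
#' @param reversal_pair indices into `comparisons` giving the
#'   insult-vs-control table (first) and treated-vs-insult table (second)
#'   used for the reversal intersections; `NULL` skips that stage.
#' @param fc_threshold linear fold-change cut-off for all classifications.
#' @param gene_sets optional named list of gene sets (see [read_gmt()]) to
#'   test for over-representation in each reversal member list.
#' @param out_dir optional output directory; created if missing.
#' @return a manifest list: `n_probes_selected`, `n_transcripts`,
#'   `comparisons` (per comparison: hyper/hypo/unchanged counts and
#'   direction percentages for methylation, up/down for expression),
#'   `reversal` (both `reversal_summary` objects), `enrichment` (per
#'   direction, if requested), and `outputs` (paths written).
#' @export
run_pipeline <- function(dataset,
                         comparisons = NULL,
                         reversal_pair = c(1L, 3L),
                         fc_threshold = 1.5,
                         gene_sets = NULL,
                         out_dir = NULL) {
  for (el in c("ip", "sup", "panel", "design"))
    if (is.null(dataset[[el]]))
      stop("dataset is missing element '", el, "'")
  design <- dataset$design
  grp <- unique(design$group)
  if (is.null(comparisons)) {
    if (length(grp) < 3)
      stop("default comparisons need three groups; supply 'comparisons'")
    comparisons <- list(c(grp[2], grp[1]), c(grp[3], grp[1]),
                        c(grp[3], grp[2]))
  }
  if (length(comparisons) == 0)
    stop("'comparisons' must list at least one (test, ref) group pair")
  for (cmp in comparisons)
    for (g in cmp)
      if (!g %in% grp)
        stop(sprintf("comparison group '%s' not in design (groups: %s)",
                     g, paste(grp, collapse = ", ")))

  targets <- select_targets(dataset$ip$flags, dataset$sup$flags, design,
                            dataset$panel)
  ip_n <- normalize_spikein(dataset$ip, dataset$panel)
  sup_n <- normalize_spikein(dataset$sup, dataset$panel)
  quant <- compute_quant(ip_n, sup_n, dataset$panel, targets)

  cmp_names <- vapply(comparisons, function(p)
    paste0(p[1], "_vs_", p[2]), character(1))
  meth <- expr <- list()
  summaries <- list()
  for (i in seq_along(comparisons)) {
    p <- comparisons[[i]]
    dm <- diff_methylation(quant, design, p[1], p[2], fc_threshold)
    de <- diff_expression(quant, design, p[1], p[2], fc_threshold)
    meth[[cmp_names[i]]] <- dm
    expr[[cmp_names[i]]] <- de
    pm <- direction_proportions(dm)
    pe <- direction_proportions(de)
    summaries[[cmp_names[i]]] <- list(
      n_hyper = sum(dm$class == "hyper"),
      n_hypo = sum(dm$class == "hypo"),
      n_unchanged = sum(dm$class == "unchanged"),
      pct_hyper = pm$pct_hyper, pct_hypo = pm$pct_hypo,
      n_up = sum(de$class == "up"), n_down = sum(de$class == "down"),
      pct_up = pe$pct_hyper, pct_down = pe$pct_hypo)
  }

  reversal <- NULL
  if (!is.null(reversal_pair)) {
    if (any(reversal_pair > length(comparisons)))
      stop("'reversal_pair' indexes beyond 'comparisons'")
    ab <- meth[[reversal_pair[1]]]
    cb <- meth[[reversal_pair[2]]]
    reversal <- list(
      attenuation = reversal_intersection(ab, cb, "attenuation"),
      enhancement = reversal_intersection(ab, cb, "enhancement"))
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && !is.null(reversal)) {
    universe <- quant$transcripts$gene_symbol[
      quant$transcripts$rna_class %in% "mRNA"]
    enrichment <- lapply(reversal, function(rv) {
      q <- intersect(rv$member_symbols, universe)
      if (length(q) == 0) NULL else ora(q, universe, gene_sets)
    })
  }

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, paste0(...))
    write_quant_table(quant, p("quant.tsv"))
    outputs <- p("quant.tsv")
    for (nm in cmp_names) {
      f1 <- p("diff_methylation_", nm, ".tsv")
      f2 <- p("diff_expression_", nm, ".tsv")
      write_diff_table(meth[[nm]], f1)
      write_diff_table(expr[[nm]], f2)
      outputs <- c(outputs, f1, f2)
    }
    if (!is.null(reversal))
      for (nm in names(reversal)) {
        f <- p("reversal_", nm, ".json")
        write_reversal_summary(reversal[[nm]], f)
        outputs <- c(outputs, f)
      }
    if (!is.null(enrichment))
      for (nm in names(enrichment))
        if (!is.null(enrichment[[nm]])) {
          f <- p("enrichment_", nm, ".tsv")
          utils::write.table(enrichment[[nm]], f, sep = "\t",
                             quote = FALSE, row.names = FALSE)
          outputs <- c(outputs, f)
        }
  }

  manifest <- list(n_probes_selected = length(targets),
                   n_transcripts = nrow(quant$transcripts),
                   fc_threshold = fc_threshold,
                   comparisons = summaries,
                   reversal = reversal,
                   enrichment = enrichment,
                   outputs = outputs)
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      c(manifest[c("n_probes_selected", "n_transcripts", "fc_threshold",
                   "comparisons")],
        list(reversal = lapply(reversal, function(rv)
          rv[c("direction", "size_a", "size_b", "intersection", "union",
               "pct_of_union")]))),
      mpath, auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, mpath)
  }
  invisible(manifest)
}

# full result objects (quant + diff tables) for callers that need them
#' Run the pipeline and return intermediate objects
#'
#' Like [run_pipeline()] but returns the quantification table and every
#' differential table alongside the manifest, for programmatic use.
#'
#' @inheritParams run_pipeline
#' @return list with `quant`, `methylation` (list of `diff_table`s),
#'   `expression`, `level` and `manifest`.
#' @export
run_pipeline_full <- function(dataset, comparisons = NULL,
                              reversal_pair = c(1L, 3L),
                              fc_threshold = 1.5) {
  design <- dataset$design
  grp <- unique(design$group)
  if (is.null(comparisons))
    comparisons <- list(c(grp[2], grp[1]), c(grp[3], grp[1]),
                        c(grp[3], grp[2]))
  manifest <- run_pipeline(dataset, comparisons, reversal_pair,
                           fc_threshold)
  targets <- select_targets(dataset$ip$flags, dataset$sup$flags, design,
                            dataset$panel)
  ip_n <- normalize_spikein(dataset$ip, dataset$panel)
  sup_n <- normalize_spikein(dataset$sup, dataset$panel)
  quant <- compute_quant(ip_n, sup_n, dataset$panel, targets)
  cmp_names <- vapply(comparisons, function(p)
    paste0(p[1], "_vs_", p[2]), character(1))
  meth <- expr <- lev <- list()
  for (i in seq_along(comparisons)) {
    p <- comparisons[[i]]
    meth[[cmp_names[i]]] <- diff_methylation(quant, design, p[1], p[2],
                                             fc_threshold)
    expr[[cmp_names[i]]] <- diff_expression(quant, design, p[1], p[2],
                                            fc_threshold)
    lev[[cmp_names[i]]] <- diff_level(quant, design, p[1], p[2],
                                      fc_threshold)
  }
  list(quant = quant, methylation = meth, expression = expr, level = lev,
       manifest = manifest)
}
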