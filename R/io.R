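#' Read and write channel intensity/flag tables
#'
#' On-disk format: tab-separated with a header row; first column
#' `probe_id`, then a `<sample_id>.value` and `<sample_id>.flag` column
#' pair per sample. Readers validate rather than repair: a non-positive
#' intensity or an unknown flag symbol is an error naming the offending
#' cell.
#'
#' @param path file path.
#' @param fraction `"IP"` or `"Sup"`.
#' @return [read_channel_matrix()] returns a [channel_matrix()];
#'   `write_channel_matrix` returns `path` invisibly.
#' @export
read_channel_matrix <- function(path, fraction = c("IP", "Sup")) {
  fraction <- match.arg(fraction)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("first column must be 'probe_id', got '", names(df)[1], "'")
  vcols <- grep("\\.value$", names(df), value = TRUE)
  fcols <- grep("\\.flag$", names(df), value = TRUE)
  samples <- sub("\\.value$", "", vcols)
  if (!setequal(sub("\\.flag$", "", fcols), samples) ||
      length(samples) == 0)
    stop("each sample needs a paired '<sample>.value' / '<sample>.flag' ",
         "column")
  values <- as.matrix(df[, paste0(samples, ".value"), drop = FALSE])
  flags <- as.matrix(df[, paste0(samples, ".flag"), drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- dimnames(flags) <- list(df$probe_id, samples)
  channel_matrix(values, flags, fraction)
}

#' @param cm a [channel_matrix()].
#' @rdname read_channel_matrix
#' @export
write_channel_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "channel_matrix"))
  samples <- colnames(cm$values)
  out <- data.frame(probe_id = rownames(cm$values),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) {
    out[[paste0(s, ".value")]] <- cm$values[, s]
    out[[paste0(s, ".flag")]] <- cm$flags[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write probe annotation and sample design tables
#'
#' Plain tab-separated tables with header rows; columns as produced by
#' [probe_panel()] and [design_table()].
#'
#' @param path file path.
#' @return the corresponding validated object.
#' @export
read_probe_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "transcript_id", "gene_symbol", "is_spikein",
            "rna_class")
  if (!all(need %in% names(df)))
    stop("probe panel file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$gene_symbol[df$gene_symbol == ""] <- NA_character_
  df$rna_class[df$rna_class == ""] <- NA_character_
  probe_panel(df$probe_id, df$transcript_id, df$gene_symbol,
              as.logical(df$is_spikein), df$rna_class)
}

#' @param x the object to serialize.
#' @rdname read_probe_panel
#' @export
write_probe_panel <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_probe_panel
#' @export
read_design_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% names(df)))
    stop("design file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  design_table(df$sample_id, df$group, df$replicate)
}

#' @rdname read_probe_panel
#' @export
write_design_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more member gene symbols. Malformed
#' lines (fewer than three fields) and duplicate set names are errors, not
#' silently repaired.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character member vectors with
#'   a `descriptions` attribute; an empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), nms)
  sets
}

#' @param sets named list of member vectors; an optional `descriptions`
#'   attribute supplies the second GMT field.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write pipeline stage outputs
#'
#' `write_quant_table` serializes the three per-transcript matrices as one
#' wide TSV (`<sample>.level` / `.quantity` / `.expression` columns);
#' `write_diff_table` writes a differential table with its comparison
#' metadata as a header comment; `write_reversal_summary` writes the
#' summary counts as JSON plus the member list as TSV.
#'
#' @param quant,diff,rev the objects to serialize.
#' @param path output file path (for the reversal summary, the JSON path;
#'   the member TSV takes the same path with extension `.members.tsv`).
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  stopifnot(inherits(quant, "quant_table"))
  out <- quant$transcripts
  for (s in quant$samples) {
    out[[paste0(s, ".level")]] <- quant$level[, s]
    out[[paste0(s, ".quantity")]] <- quant$quantity[, s]
    out[[paste0(s, ".expression")]] <- quant$expression[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_quant_table
#' @export
write_diff_table <- function(diff, path) {
  cmp <- attr(diff, "comparison")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# comparison: %s vs %s; measure: %s; fc_threshold: %g",
                     cmp["test"], cmp["ref"], attr(diff, "measure"),
                     attr(diff, "fc_threshold")), con)
  utils::write.table(as.data.frame(diff), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_quant_table
#' @export
write_reversal_summary <- function(rev, path) {
  stopifnot(inherits(rev, "reversal_summary"))
  jsonlite::write_json(
    list(direction = rev$direction, size_a = rev$size_a,
         size_b = rev$size_b, intersection = rev$intersection,
         union = rev$union, pct_of_union = rev$pct_of_union),
    path, auto_unbox = TRUE, digits = NA)
  members <- data.frame(transcript_id = rev$members,
                        gene_symbol = rev$member_symbols,
                        stringsAsFactors = FALSE)
  utils::write.table(members, sub("\\.json$", "", path) |>
                       paste0(".members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @param truth ground-truth data.frame from [generate_dataset()].
#' @rdname write_quant_table
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
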