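#' Differential methylation / expression classification between two groups
#'
#' Computes, per transcript, the difference of group-mean log2 signals
#' (equivalently the log2 fold change of geometric means on the linear
#' scale) and classifies transcripts by a linear fold-change threshold:
#' fold change >= `fc_threshold` (i.e. log2fc >= log2(fc_threshold),
#' boundary inclusive) is called hyper (up), <= the negated threshold hypo
#' (down), anything in between unchanged. No per-transcript variance test
#' is performed; classification is fold-change-only, as is conventional for
#' this array platform.
#'
#' `diff_methylation` operates on m6A quantity (methylated-copy signal),
#' `diff_expression` on total expression with classes relabelled
#' up/down/unchanged, and `diff_level` on the m6A methylation-level
#' fraction.
#'
#' @param quant a `quant_table` from [compute_quant()].
#' @param design a [design_table()].
#' @param test,ref group labels; fold changes are test over reference.
#' @param fc_threshold linear fold-change cut-off (default 1.5).
#' @return a data.frame of class `diff_table` with columns `transcript_id`,
#'   `gene_symbol`, `rna_class`, `mean_log2_test`, `mean_log2_ref`,
#'   `log2fc`, `class`; attributes `comparison`, `measure`, `fc_threshold`.
#' @export
diff_methylation <- function(quant, design, test, ref, fc_threshold = 1.5) {
  diff_table(quant, design, test, ref, "quantity", fc_threshold,
             labels = c("hyper", "hypo"))
}

#' @rdname diff_methylation
#' @export
diff_expression <- function(quant, design, test, ref, fc_threshold = 1.5) {
  diff_table(quant, design, test, ref, "expression", fc_threshold,
             labels = c("up", "down"))
}

#' @rdname diff_methylation
#' @export
diff_level <- function(quant, design, test, ref, fc_threshold = 1.5) {
  diff_table(quant, design, test, ref, "level", fc_threshold,
             labels = c("hyper", "hypo"))
}

diff_table <- function(quant, design, test, ref, measure, fc_threshold,
                       labels) {
  stopifnot(inherits(quant, "quant_table"))
  if (!is.finite(fc_threshold) || fc_threshold <= 0)
    stop("'fc_threshold' must be a positive real")
  s_test <- group_samples(design, test)
  s_ref <- group_samples(design, ref)
  if (length(s_test) < 2 || length(s_ref) < 2)
    stop("both groups need >= 2 samples")
  m <- log2(quant[[measure]])
  mean_test <- rowMeans(m[, s_test, drop = FALSE])
  mean_ref <- rowMeans(m[, s_ref, drop = FALSE])
  log2fc <- mean_test - mean_ref
  # inclusive boundary: a fold change of exactly fc_threshold is called;
  # the epsilon absorbs log2 round-off so the boundary stays inclusive
  cut <- log2(fc_threshold) - 1e-9
  cls <- ifelse(log2fc >= cut, labels[1],
                ifelse(log2fc <= -cut, labels[2], "unchanged"))
  out <- data.frame(quant$transcripts,
                    mean_log2_test = mean_test,
                    mean_log2_ref = mean_ref,
                    log2fc = log2fc,
                    class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparison") <- c(test = test, ref = ref)
  attr(out, "measure") <- measure
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Direction proportions among changed transcripts
#'
#' Summarizes a differential table as the percentage of changed transcripts
#' in each direction (e.g. 80% hyper / 20% hypo). With zero changed
#' transcripts an explicit empty summary is returned rather than a division
#' error.
#'
#' @param diff a `diff_table`.
#' @return a list with `n_changed`, `pct_hyper`, `pct_hypo` (percentages
#'   rounded to one decimal and summing to 100 when `n_changed > 0`;
#'   both `NA` otherwise). For expression tables the up/down classes fill
#'   the hyper/hypo slots.
#' @export
direction_proportions <- function(diff) {
  up_lab <- if ("up" %in% diff$class) "up" else "hyper"
  dn_lab <- if ("down" %in% diff$class) "down" else "hypo"
  n_up <- sum(diff$class == up_lab)
  n_dn <- sum(diff$class == dn_lab)
  n_changed <- n_up + n_dn
  if (n_changed == 0)
    return(list(n_changed = 0L, pct_hyper = NA_real_, pct_hypo = NA_real_))
  pct_hyper <- round(100 * n_up / n_changed, 1)
  list(n_changed = as.integer(n_changed),
       pct_hyper = pct_hyper, pct_hypo = 100 - pct_hyper)
}

#' Directional reversal intersection of two differential comparisons
#'
#' Identifies transcripts the insult shifted in one direction and the
#' treatment shifted back: for `direction = "attenuation"` the overlap of
#' transcripts hypermethylated in the insult-vs-control table (`diff_ab`)
#' with those hypomethylated in the treated-vs-insult table (`diff_cb`);
#' for `direction = "enhancement"` the mirror overlap (hypo then hyper).
#' The percentage is reported relative to the union of the two sets. When
#' the tables carry an `rna_class` column the analysis is restricted to
#' mRNAs.
#'
#' @param diff_ab,diff_cb `diff_table`s over the same transcript universe.
#' @param direction `"attenuation"` or `"enhancement"`.
#' @return a list of class `reversal_summary`: `direction`, `size_a`,
#'   `size_b`, `intersection`, `union`, `pct_of_union` (one decimal),
#'   `members` (transcript IDs) and `member_symbols`.
#' @export
reversal_intersection <- function(diff_ab, diff_cb,
                                  direction = c("attenuation",
                                                "enhancement")) {
  direction <- match.arg(direction)
  miss <- c(setdiff(diff_ab$transcript_id, diff_cb$transcript_id),
            setdiff(diff_cb$transcript_id, diff_ab$transcript_id))
  if (length(miss) > 0)
    stop("differential tables cover different transcript universes; ",
         "missing: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  keep_mrna <- function(d) {
    if ("rna_class" %in% names(d) && !all(is.na(d$rna_class)))
      d[d$rna_class == "mRNA", , drop = FALSE] else d
  }
  diff_ab <- keep_mrna(diff_ab); diff_cb <- keep_mrna(diff_cb)
  cls <- if (direction == "attenuation") c("hyper", "hypo")
         else c("hypo", "hyper")
  set_a <- diff_ab$transcript_id[diff_ab$class == cls[1]]
  set_b <- diff_cb$transcript_id[diff_cb$class == cls[2]]
  members <- sort(intersect(set_a, set_b))
  uni <- length(set_a) + length(set_b) - length(members)
  pct <- if (uni == 0) 0 else round(100 * length(members) / uni, 1)
  sym <- diff_ab$gene_symbol[match(members, diff_ab$transcript_id)]
  structure(list(direction = direction,
                 size_a = length(set_a), size_b = length(set_b),
                 intersection = length(members), union = uni,
                 pct_of_union = pct, members = members,
                 member_symbols = sym),
            class = "reversal_summary")
}

#' @export
print.reversal_summary <- function(x, ...) {
  cat(sprintf(
    "reversal [%s]: |A| = %d, |B| = %d, overlap = %d (%.1f%% of union %d)\n",
    x$direction, x$size_a, x$size_b, x$intersection, x$pct_of_union,
    x$union))
  invisible(x)
}

#' Rank concordance between fold-change vectors of paired comparisons
#'
#' Measures how the m6A-quantity and m6A-level fold changes track the
#' expression fold changes over the shared transcripts, using Spearman rank
#' correlation (fold changes are heavy-tailed). On real data the quantity
#' is expected to move with expression while the level — a within-transcript
#' fraction — need not.
#'
#' @param diff_quantity,diff_expression,diff_level `diff_table`s over a
#'   shared transcript universe (`diff_level` may be `NULL`).
#' @return a data.frame with one row per tested pair: `pair`, `rho`,
#'   `p_value`, `n`.
#' @export
concordance <- function(diff_quantity, diff_expression, diff_level = NULL) {
  one <- function(a, b, label) {
    shared <- intersect(a$transcript_id, b$transcript_id)
    if (length(shared) < 3)
      stop("fewer than 3 shared transcripts for pair ", label)
    x <- a$log2fc[match(shared, a$transcript_id)]
    y <- b$log2fc[match(shared, b$transcript_id)]
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(pair = label, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(shared),
               stringsAsFactors = FALSE)
  }
  out <- one(diff_quantity, diff_expression, "quantity_vs_expression")
  if (!is.null(diff_level))
    out <- rbind(out, one(diff_level, diff_expression,
                          "level_vs_expression"))
  out
}
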