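#' Configuration for the synthetic two-channel array generator
#'
#' Defines the simulated study: three groups (control, insult, treated
#' insult) with triplicate arrays each, log-normal probe intensities,
#' spike-in control probes subject to per-array scale drift, and planted
#' group-specific shifts in m6A quantity (IP fraction) and expression.
#'
#' Planted effects are expressed per ordered comparison, named
#' `"<test>_vs_<ref>"`. Effects for the first comparison (insult vs control)
#' are applied to the test group; a fraction `frac_reversed` of those genes
#' returns to the control baseline in the third group, so they show the
#' opposite change in the treated-vs-insult comparison. Effects for the
#' second comparison are planted directly in the third group among genes
#' untouched by the first.
#'
#' @param n_genes number of target genes (one probe per gene).
#' @param n_spikeins number of spike-in control probes (>= 2).
#' @param replicates_per_group arrays per group.
#' @param groups ordered group labels; the first is the reference/control,
#'   the second the insult, the third the treated insult.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of baseline
#'   per-gene total-RNA abundance on the log2 intensity scale.
#' @param noise_log2_sd sd of iid per-cell replicate noise (log2 units).
#' @param array_offset_sd sd of the per-array, per-channel scale offset
#'   (log2 units) that spike-in normalization must remove.
#' @param frac_hyper,frac_hypo named numeric vectors giving, per comparison,
#'   the fraction of genes planted hyper-/hypomethylated. Names must be
#'   `"<groups[2]>_vs_<groups[1]>"` and `"<groups[3]>_vs_<groups[2]>"`.
#' @param effect_log2 absolute planted log2 shift of IP quantity.
#' @param frac_reversed fraction of comparison-1 planted genes whose
#'   methylation the third group returns to the control baseline.
#' @param expr_coupling fraction of planted genes whose total expression
#'   shifts together with m6A quantity (methylation level held fixed); the
#'   rest shift methylation level at fixed expression.
#' @param dropout_rate fraction of gene-probe cells flagged Absent.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_spikeins = 8,
                             replicates_per_group = 3,
                             groups = c("Ctrl", "FS", "FS-DBS"),
                             baseline_log2_mean = 10,
                             baseline_log2_sd = 1.5,
                             noise_log2_sd = 0.2,
                             array_offset_sd = 0.3,
                             frac_hyper = NULL,
                             frac_hypo = NULL,
                             effect_log2 = 2,
                             frac_reversed = 0.5,
                             expr_coupling = 0.5,
                             dropout_rate = 0.02,
                             seed = 1L) {
  if (length(groups) != 3 || anyDuplicated(groups))
    stop("config field 'groups': exactly three distinct labels required")
  cmp <- c(paste0(groups[2], "_vs_", groups[1]),
           paste0(groups[3], "_vs_", groups[2]))
  # default planting: ~80:20 hyper:hypo after the insult, a mixed response
  # to treatment (reversal supplies most of the treated-vs-insult signal)
  if (is.null(frac_hyper)) frac_hyper <- stats::setNames(c(0.10, 0.04), cmp)
  if (is.null(frac_hypo))  frac_hypo  <- stats::setNames(c(0.025, 0.02), cmp)
  cfg <- list(n_genes = n_genes, n_spikeins = n_spikeins,
              replicates_per_group = replicates_per_group, groups = groups,
              comparisons = cmp,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              array_offset_sd = array_offset_sd,
              frac_hyper = frac_hyper, frac_hypo = frac_hypo,
              effect_log2 = effect_log2, frac_reversed = frac_reversed,
              expr_coupling = expr_coupling, dropout_rate = dropout_rate,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("config field '%s': positive count required", nm))
  }
  chk_pos <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("config field '%s': positive real required", nm))
  }
  chk_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("config field '%s': fraction(s) in [0,1] required", nm))
  }
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$n_spikeins, "n_spikeins", min = 2)
  chk_count(cfg$replicates_per_group, "replicates_per_group", min = 2)
  chk_pos(cfg$baseline_log2_sd, "baseline_log2_sd")
  if (!is.finite(cfg$noise_log2_sd) || cfg$noise_log2_sd < 0)
    stop("config field 'noise_log2_sd': non-negative real required")
  if (!is.finite(cfg$array_offset_sd) || cfg$array_offset_sd < 0)
    stop("config field 'array_offset_sd': non-negative real required")
  chk_pos(cfg$effect_log2, "effect_log2")
  if (cfg$effect_log2 > 5)
    stop("config field 'effect_log2': must be <= 5 so uncoupled planted ",
         "methylation levels stay inside (0,1)")
  chk_frac(cfg$frac_reversed, "frac_reversed")
  chk_frac(cfg$expr_coupling, "expr_coupling")
  chk_frac(cfg$dropout_rate, "dropout_rate")
  for (nm in c("frac_hyper", "frac_hypo")) {
    v <- cfg[[nm]]
    if (!all(cfg$comparisons %in% names(v)))
      stop(sprintf("config field '%s': needs entries named %s", nm,
                   paste(cfg$comparisons, collapse = ", ")))
    chk_frac(v, nm)
  }
  over <- cfg$frac_hyper[cfg$comparisons] + cfg$frac_hypo[cfg$comparisons]
  if (any(over > 1))
    stop("config fields 'frac_hyper'/'frac_hypo': frac_hyper + frac_hypo ",
         "must be <= 1 per comparison")
  invisible(cfg)
}

#' Generate a synthetic two-channel MeRIP array dataset with ground truth
#'
#' Simulates the full measurement chain on the log2 scale: per-gene baseline
#' total abundance and methylated fraction, planted group effects on m6A
#' quantity, a per-array per-channel scale offset (which hits spike-ins and
#' genes alike and is what spike-in normalization removes), and iid
#' replicate noise; intensities are then exponentiated so they are strictly
#' positive. The Sup channel carries total minus methylated amount, so
#' IP + Sup equals total expression by construction. Spike-in probes receive
#' the array offset and noise but never any group effect. Dropout cells keep
#' a small positive intensity and are marked by flag `"A"` only — flag-based
#' filtering, not value masking, is the downstream selection mechanism.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `ip` and `sup` ([channel_matrix()]),
#'   `panel` ([probe_panel()]), `design` ([design_table()]) and `truth`, a
#'   data.frame with one row per gene per comparison: `gene_id`,
#'   `comparison`, `true_class` (hyper/hypo/unchanged), `reversed`,
#'   `expr_shift`; plus `true_level`, the genes x groups matrix of planted
#'   methylated fractions, and the `config` used.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  set.seed(cfg$seed)

  g_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  s_ids <- sprintf("spikein_%02d", seq_len(cfg$n_spikeins))
  probe_ids <- c(sprintf("p_%s", g_ids), sprintf("p_%s", s_ids))

  groups <- cfg$groups
  reps <- cfg$replicates_per_group
  design <- design_table(
    sample_id = paste0(rep(gsub("-", ".", groups), each = reps), "_",
                       rep(seq_len(reps), times = length(groups))),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), times = length(groups)))
  n_samp <- nrow(design)

  # baseline: total abundance (log2) and methylated fraction per gene
  t0 <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  lev0 <- stats::runif(cfg$n_genes, 0.2, 0.8)

  # plant classes for the two configured comparisons
  cmp1 <- cfg$comparisons[1]; cmp2 <- cfg$comparisons[2]
  n_hyper1 <- round(cfg$frac_hyper[[cmp1]] * cfg$n_genes)
  n_hypo1 <- round(cfg$frac_hypo[[cmp1]] * cfg$n_genes)
  planted1 <- sample.int(cfg$n_genes, n_hyper1 + n_hypo1)
  hyper1 <- planted1[seq_len(n_hyper1)]
  hypo1 <- setdiff(planted1, hyper1)
  class1 <- rep("unchanged", cfg$n_genes)
  class1[hyper1] <- "hyper"; class1[hypo1] <- "hypo"

  reversed <- rep(FALSE, cfg$n_genes)
  if (length(planted1) > 0 && cfg$frac_reversed > 0)
    reversed[sample(planted1,
                    round(cfg$frac_reversed * length(planted1)))] <- TRUE

  untouched <- which(class1 == "unchanged")
  n_hyper2 <- round(cfg$frac_hyper[[cmp2]] * cfg$n_genes)
  n_hypo2 <- round(cfg$frac_hypo[[cmp2]] * cfg$n_genes)
  if (n_hyper2 + n_hypo2 > length(untouched))
    stop("config: comparison-2 planting exceeds genes left unchanged by ",
         "comparison 1")
  planted2 <- if (n_hyper2 + n_hypo2 > 0)
    sample(untouched, n_hyper2 + n_hypo2) else integer(0)
  hyper2 <- planted2[seq_len(n_hyper2)]
  hypo2 <- setdiff(planted2, hyper2)

  # log2 shift of m6A quantity per gene per group (control = 0)
  e <- cfg$effect_log2
  delta <- matrix(0, cfg$n_genes, 3, dimnames = list(g_ids, groups))
  delta[hyper1, 2] <- e
  delta[hypo1, 2] <- -e
  # treated group: reversed genes regress to control; persistent genes keep
  # the insult shift; directly planted genes shift relative to the insult
  delta[, 3] <- delta[, 2]
  delta[reversed, 3] <- 0
  delta[hyper2, 3] <- e
  delta[hypo2, 3] <- -e

  # class in the treated-vs-insult comparison follows from the deltas
  d23 <- delta[, 3] - delta[, 2]
  class2 <- ifelse(d23 > 0, "hyper", ifelse(d23 < 0, "hypo", "unchanged"))

  # expression coupling: an exact fraction of all planted genes shifts
  # total expression along with quantity (level fixed); the rest shift the
  # methylated fraction at fixed expression
  planted_any <- sort(unique(c(planted1, planted2)))
  coupled <- rep(FALSE, cfg$n_genes)
  if (length(planted_any) > 0 && cfg$expr_coupling > 0)
    coupled[sample(planted_any,
                   round(cfg$expr_coupling * length(planted_any)))] <- TRUE

  # uncoupled planted genes need lev0 * 2^delta inside (0,1) for every group
  unc <- planted_any[!coupled[planted_any]]
  if (length(unc) > 0) {
    dmax <- apply(delta[unc, , drop = FALSE], 1, max)
    dmin <- apply(delta[unc, , drop = FALSE], 1, min)
    lo <- pmax(0.05, 0.02 * 2^(-dmin))
    hi <- pmin(0.9, 0.9 * 2^(-dmax))
    lev0[unc] <- lo + (hi - lo) * stats::runif(length(unc))
  }

  # true linear amounts per gene x group for each channel
  ip_amt <- sup_amt <- true_level <-
    matrix(0, cfg$n_genes, 3, dimnames = list(g_ids, groups))
  for (k in 1:3) {
    d <- delta[, k]
    tot <- 2^t0
    lev <- lev0
    shift_tot <- coupled              # level fixed, expression moves
    tot[shift_tot] <- 2^(t0[shift_tot] + d[shift_tot])
    lev[!shift_tot] <- pmin(0.99, pmax(0.005, lev0[!shift_tot] *
                                         2^(d[!shift_tot])))
    true_level[, k] <- lev
    ip_amt[, k] <- lev * tot
    sup_amt[, k] <- (1 - lev) * tot
  }

  # spike-ins: fixed known amounts, identical across groups and channels
  spike_log2 <- stats::rnorm(cfg$n_spikeins, cfg$baseline_log2_mean, 1)

  sample_group_idx <- match(design$group, groups)
  # one scale offset per array: both dye channels of a sample share it, so
  # the IP/Sup ratio is offset-free once each channel is normalized
  offs <- stats::rnorm(n_samp, 0, cfg$array_offset_sd)
  build_channel <- function(amt, fraction) {
    true_log2 <- rbind(log2(amt)[, sample_group_idx, drop = FALSE],
                       matrix(spike_log2, cfg$n_spikeins, n_samp))
    noise <- matrix(stats::rnorm(length(true_log2), 0, cfg$noise_log2_sd),
                    nrow(true_log2), n_samp)
    vals <- 2^(sweep(true_log2, 2, offs, "+") + noise)
    dimnames(vals) <- list(probe_ids, design$sample_id)
    flags <- matrix("P", nrow(vals), n_samp, dimnames = dimnames(vals))
    if (cfg$dropout_rate > 0) {
      gene_cells <- cfg$n_genes * n_samp
      n_drop <- round(cfg$dropout_rate * gene_cells)
      if (n_drop > 0) {
        drop_idx <- sample.int(gene_cells, n_drop)
        row_i <- ((drop_idx - 1) %% cfg$n_genes) + 1
        col_i <- ((drop_idx - 1) %/% cfg$n_genes) + 1
        flags[cbind(row_i, col_i)] <- "A"
        vals[cbind(row_i, col_i)] <- stats::runif(n_drop, 0.5, 2)
      }
    }
    channel_matrix(vals, flags, fraction)
  }
  ip <- build_channel(ip_amt, "IP")
  sup <- build_channel(sup_amt, "Sup")

  panel <- probe_panel(
    probe_id = probe_ids,
    transcript_id = c(g_ids, s_ids),
    gene_symbol = c(toupper(g_ids), rep(NA_character_, cfg$n_spikeins)),
    is_spikein = c(rep(FALSE, cfg$n_genes), rep(TRUE, cfg$n_spikeins)),
    rna_class = c(rep("mRNA", cfg$n_genes),
                  rep(NA_character_, cfg$n_spikeins)))

  truth <- data.frame(
    gene_id = rep(g_ids, 2),
    comparison = rep(c(cmp1, cmp2), each = cfg$n_genes),
    true_class = c(class1, class2),
    reversed = rep(reversed, 2),
    expr_shift = rep(coupled, 2),
    stringsAsFactors = FALSE)

  list(ip = ip, sup = sup, panel = panel, design = design, truth = truth,
       true_level = true_level, config = cfg)
}
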