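quant_from_groupmeans <- function(means_a, means_b, reps = 3) {
  # transcripts x samples quantity matrix with exact group means and no
  # within-group spread; Sup set equal to IP so level is 1/2 throughout
  n <- length(means_a)
  ids <- sprintf("g%02d", seq_len(n))
  des <- tiny_design(groups = c("Ctrl", "FS"), reps = reps)
  ip <- cbind(matrix(rep(means_b, reps), n),
              matrix(rep(means_a, reps), n))
  dimnames(ip) <- list(ids, des$sample_id)
  list(quant = tiny_quant(ip, ip), design = des)
}

test_that("log2 fold change and classes follow the 1.5-fold rule", {
  fx <- quant_from_groupmeans(means_a = c(200, 150, 100, 50, 100),
                              means_b = c(100, 100, 100, 100, 100))
  dm <- diff_methylation(fx$quant, fx$design, "FS", "Ctrl")
  expect_equal(dm$log2fc,
               log2(c(200, 150, 100, 50, 100) / 100), tolerance = 1e-12)
  # 2-fold up is hyper; exactly 1.5-fold sits on the inclusive boundary;
  # 2-fold down is hypo; unchanged means stay unchanged
  expect_identical(dm$class,
                   c("hyper", "hyper", "unchanged", "hypo", "unchanged"))
  expect_lt(max(abs(dm$log2fc - (dm$mean_log2_test - dm$mean_log2_ref))),
            1e-9)
  expect_error(diff_methylation(fx$quant, fx$design, "FS", "Nope"),
               "available groups")
})

test_that("expression tables relabel classes up/down", {
  fx <- quant_from_groupmeans(c(300, 100, 40), c(100, 100, 100))
  de <- diff_expression(fx$quant, fx$design, "FS", "Ctrl")
  expect_identical(de$class, c("up", "unchanged", "down"))
})

test_that("swapping test and reference negates fold changes and swaps classes", {
  set.seed(33)
  n <- 40
  ids <- sprintf("g%02d", 1:n)
  des <- tiny_design(groups = c("Ctrl", "FS"), reps = 3)
  ip <- matrix(2^rnorm(n * 6, 9, 1), n, 6,
               dimnames = list(ids, des$sample_id))
  q <- tiny_quant(ip, ip)
  fwd <- diff_methylation(q, des, "FS", "Ctrl")
  rev <- diff_methylation(q, des, "Ctrl", "FS")
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_identical(sum(fwd$class == "hyper"), sum(rev$class == "hypo"))
  expect_identical(sum(fwd$class == "hypo"), sum(rev$class == "hyper"))
})

test_that("direction proportions match brute-force counts and edge cases", {
  d <- diff_fixture(sprintf("t%03d", 1:100),
                    c(rep("hyper", 80), rep("hypo", 20)))
  pr <- direction_proportions(d)
  expect_equal(pr$pct_hyper, 80.0)
  expect_equal(pr$pct_hypo, 20.0)

  set.seed(51)
  cls <- sample(c("hyper", "hypo", "unchanged"), 50, TRUE)
  pr2 <- direction_proportions(diff_fixture(sprintf("t%03d", 1:50), cls))
  n_hyper <- sum(cls == "hyper"); n_hypo <- sum(cls == "hypo")
  expect_equal(pr2$pct_hyper, round(100 * n_hyper / (n_hyper + n_hypo), 1))
  expect_equal(pr2$pct_hyper + pr2$pct_hypo, 100)

  all_hyper <- direction_proportions(
    diff_fixture(c("a", "b"), c("hyper", "hyper")))
  expect_equal(all_hyper$pct_hyper, 100.0)
  expect_equal(all_hyper$pct_hypo, 0.0)

  none <- direction_proportions(
    diff_fixture(c("a", "b"), c("unchanged", "unchanged")))
  expect_identical(none$n_changed, 0L)
  expect_true(is.na(none$pct_hyper))
})

test_that("reversal intersection reproduces the published set arithmetic", {
  # insult-hypermethylated then treatment-hypomethylated transcripts
  fx <- reversal_fixture(3734, 2605, 613, 12000)
  rv <- reversal_intersection(fx$ab, fx$cb, "attenuation")
  expect_identical(rv$intersection, 613L)
  expect_identical(rv$union, 5726L)
  expect_equal(rv$pct_of_union, 10.7)

  # the mirror direction: insult-hypo then treatment-hyper
  fx2 <- reversal_fixture(1956, 7714, 1063, 12000)
  fx2$ab$class[fx2$ab$class == "hyper"] <- "hypo"
  fx2$cb$class[fx2$cb$class == "hypo"] <- "hyper"
  rv2 <- reversal_intersection(fx2$ab, fx2$cb, "enhancement")
  expect_identical(rv2$intersection, 1063L)
  expect_identical(rv2$union, 8607L)
  expect_equal(rv2$pct_of_union, 12.4)

  expect_identical(rv$union, rv$size_a + rv$size_b - rv$intersection)
  expect_lte(rv$intersection, min(rv$size_a, rv$size_b))
})

test_that("disjoint sets give zero intersection and zero percent", {
  ab <- diff_fixture(c("a", "b", "c"), c("hyper", "unchanged", "unchanged"))
  cb <- diff_fixture(c("a", "b", "c"), c("unchanged", "hypo", "unchanged"))
  rv <- reversal_intersection(ab, cb, "attenuation")
  expect_identical(rv$intersection, 0L)
  expect_equal(rv$pct_of_union, 0.0)
})

test_that("reversal respects transcript universes, mRNA filter, and relabeling", {
  ab <- diff_fixture(c("a", "b"), c("hyper", "hyper"))
  cb <- diff_fixture(c("a", "z"), c("hypo", "hypo"))
  expect_error(reversal_intersection(ab, cb), "universes")

  # lncRNA rows are excluded from the mRNA reversal counts
  ab2 <- diff_fixture(c("a", "b", "c"), rep("hyper", 3),
                      rna_class = c("mRNA", "lncRNA", "mRNA"))
  cb2 <- diff_fixture(c("a", "b", "c"), rep("hypo", 3),
                      rna_class = c("mRNA", "lncRNA", "mRNA"))
  rv <- reversal_intersection(ab2, cb2, "attenuation")
  expect_identical(rv$intersection, 2L)

  # renaming transcripts leaves the percentage untouched
  fx <- reversal_fixture(40, 30, 10, 100)
  rv1 <- reversal_intersection(fx$ab, fx$cb)
  relab <- function(d) { d$transcript_id <- paste0("X", d$transcript_id); d }
  rv2 <- reversal_intersection(relab(fx$ab), relab(fx$cb))
  expect_identical(rv1$pct_of_union, rv2$pct_of_union)
})

test_that("a transcript cannot be in both directions' member lists", {
  set.seed(71)
  ids <- sprintf("t%03d", 1:200)
  ab <- diff_fixture(ids, sample(c("hyper", "hypo", "unchanged"), 200, TRUE))
  cb <- diff_fixture(ids, sample(c("hyper", "hypo", "unchanged"), 200, TRUE))
  att <- reversal_intersection(ab, cb, "attenuation")
  enh <- reversal_intersection(ab, cb, "enhancement")
  expect_length(intersect(att$members, enh$members), 0)
})

test_that("concordance reports rank correlation of fold-change vectors", {
  ids <- sprintf("g%02d", 1:20)
  base <- diff_fixture(ids, rep("unchanged", 20))
  base$log2fc <- seq(-2, 2, length.out = 20)
  other <- base
  cc <- concordance(base, other)
  expect_equal(cc$rho[cc$pair == "quantity_vs_expression"], 1.0)

  too_few <- diff_fixture(c("a", "b"), c("unchanged", "unchanged"))
  expect_error(concordance(too_few, too_few), "fewer than 3")
})

test_that("noise-free synthetic classes are recovered exactly end to end", {
  cfg <- synthetic_config(n_genes = 300, noise_log2_sd = 0,
                          dropout_rate = 0, effect_log2 = 0.7, seed = 37)
  d <- generate_dataset(cfg)
  res <- run_pipeline_full(d)
  for (i in c(1, 3)) {
    cmp <- cfg$comparisons[if (i == 1) 1 else 2]
    dm <- res$methylation[[i]]
    tr <- d$truth[d$truth$comparison == cmp, ]
    expect_identical(dm$class,
                     tr$true_class[match(dm$transcript_id, tr$gene_id)])
  }
  # expression shifts land only on the coupled genes
  de <- res$expression[[1]]
  tr <- d$truth[d$truth$comparison == cfg$comparisons[1], ]
  coupled_changed <- tr$gene_id[tr$expr_shift & tr$true_class != "unchanged"]
  expect_setequal(de$transcript_id[de$class != "unchanged"],
                  coupled_changed)
})
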