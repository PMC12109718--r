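make_flag_fixture <- function(flag_rows, design) {
  m <- do.call(rbind, flag_rows)
  dimnames(m) <- list(paste0("p", seq_along(flag_rows)), design$sample_id)
  m
}

test_that("flag selection keeps P/M/QC in at least one sample", {
  des <- tiny_design(groups = "G1", reps = 3)
  # a single present call in a triplicate suffices; all-absent is dropped
  fl <- make_flag_fixture(list(c("P", "A", "A"),
                               c("A", "A", "A"),
                               c("A", "M", "A"),
                               c("QC", "A", "A")), des)
  sel <- select_targets(fl, fl, des)
  expect_setequal(sel, c("p1", "p3", "p4"))

  # detection in the other fraction alone also selects
  fl_ip <- make_flag_fixture(list(c("A", "A", "A")), des)
  fl_sup <- make_flag_fixture(list(c("A", "P", "A")), des)
  expect_identical(select_targets(fl_ip, fl_sup, des), "p1")

  # every probe absent everywhere is an explicit error
  fl_all_a <- make_flag_fixture(list(c("A", "A", "A")), des)
  expect_error(select_targets(fl_all_a, fl_all_a, des), "no probes pass")
})

test_that("flag selection matches a brute-force scan on a random fixture", {
  set.seed(13)
  des <- tiny_design()
  fl_ip <- matrix(sample(c("P", "M", "A", "QC"), 20 * 6, TRUE,
                         prob = c(0.2, 0.1, 0.6, 0.1)), 20, 6,
                  dimnames = list(paste0("p", 1:20), des$sample_id))
  fl_sup <- matrix(sample(c("P", "A"), 20 * 6, TRUE, prob = c(0.2, 0.8)),
                   20, 6, dimnames = dimnames(fl_ip))
  brute <- character(0)
  for (p in rownames(fl_ip)) {
    hit <- FALSE
    for (s in des$sample_id)
      for (m in list(fl_ip, fl_sup))
        if (m[p, s] %in% c("P", "M", "QC")) hit <- TRUE
    if (hit) brute <- c(brute, p)
  }
  expect_identical(select_targets(fl_ip, fl_sup, des), brute)
})

test_that("spike-ins are excluded from the selected set", {
  d <- generate_dataset(synthetic_config(n_genes = 25, seed = 6))
  sel <- select_targets(d$ip$flags, d$sup$flags, d$design, d$panel)
  expect_length(intersect(sel, d$panel$probe_id[d$panel$is_spikein]), 0)
  expect_gt(length(sel), 0)
})

test_that("spike-in normalization equalizes per-sample spike-in means", {
  pan <- tiny_panel(2, 2)
  vals <- matrix(2^c(8, 9, 10, 11,     # g01
                     7, 7, 7, 7,       # g02
                     10, 11, 10.5, 12, # sp01
                     10, 11, 10.5, 12),# sp02
                 4, 4, byrow = TRUE,
                 dimnames = list(pan$probe_id, paste0("s", 1:4)))
  nm <- normalize_spikein(tiny_channel(vals), pan)
  spike_means <- colMeans(nm$values[pan$probe_id[pan$is_spikein], ])
  expect_lt(diff(range(spike_means)), 1e-9)
  # sample s1 sits 0.875 log2 units below the grand spike mean (10.875),
  # so normalization shifts it up by exactly that amount
  expect_equal(unname(nm$normalization_offsets[["s1"]]), -0.875)
  expect_equal(unname(nm$values["p_g02", "s1"]), 7 + 0.875)
})

test_that("a sample already on the grand mean gets offset zero", {
  pan <- tiny_panel(1, 2)
  vals <- matrix(2^c(5, 5,
                     10, 10,
                     12, 12), 3, 2, byrow = TRUE,
                 dimnames = list(pan$probe_id, c("a", "b")))
  nm <- normalize_spikein(tiny_channel(vals), pan)
  expect_equal(unname(nm$normalization_offsets), c(0, 0))
  expect_equal(nm$values, log2(vals))
})

test_that("normalization is idempotent and order-preserving", {
  d <- generate_dataset(synthetic_config(n_genes = 80, dropout_rate = 0,
                                         seed = 14))
  nm1 <- normalize_spikein(d$ip, d$panel)
  # re-normalizing the normalized (linear-scale) matrix changes nothing
  renorm_input <- channel_matrix(2^nm1$values, d$ip$flags, "IP")
  nm2 <- normalize_spikein(renorm_input, d$panel)
  expect_equal(nm2$values, nm1$values, tolerance = 1e-9)
  expect_lt(max(abs(nm2$normalization_offsets)), 1e-9)
  # per-sample monotone transform: within-sample probe order preserved
  for (s in colnames(nm1$values))
    expect_identical(order(nm1$values[, s]), order(d$ip$values[, s]))
})

test_that("normalization requires healthy spike-ins", {
  pan <- tiny_panel(2, 2)
  vals <- matrix(2^rnorm(8, 8), 4, 2,
                 dimnames = list(pan$probe_id, c("a", "b")))
  fl <- matrix("P", 4, 2, dimnames = dimnames(vals))
  fl["p_sp01", "b"] <- "A"
  expect_error(normalize_spikein(channel_matrix(vals, fl, "IP"), pan),
               "flagged absent")
  pan1 <- tiny_panel(3, 1)
  vals1 <- matrix(2^rnorm(8, 8), 4, 2,
                  dimnames = list(pan1$probe_id, c("a", "b")))
  expect_error(normalize_spikein(tiny_channel(vals1), pan1),
               ">= 2 spike-in")
})

test_that("intensities below one fluorescence unit are floored before log2", {
  pan <- tiny_panel(1, 2)
  vals <- matrix(c(0.01, 4, 2^10, 2^10, 2^10, 2^10), 3, 2, byrow = TRUE,
                 dimnames = list(pan$probe_id, c("a", "b")))
  nm <- normalize_spikein(tiny_channel(vals), pan)
  expect_equal(unname(nm$values["p_g01", "a"]), 0)  # log2(1) - 0 offset
})
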