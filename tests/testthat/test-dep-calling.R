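test_that("paired log2 fold changes are exact ratios with NA propagation", {
  d <- toy_design(groups = "LPS50", n_animals = 3)
  m <- matrix(c(10, 40,    # log2(40/10) = 2
                NA, 40,    # missing baseline -> missing fc
                8, 8),     # unchanged -> 0
              nrow = 3, byrow = TRUE)
  # column order of toy_design: per animal T0 then T50
  q <- toy_quant(matrix(c(10, 40, NA, 40, 8, 8,
                          5, 5, 5, 5, 5, 5),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(NULL, d$sample_id)),
                 protein_ids = c("P1", "P2"))
  fc <- paired_log2fc(q, d)
  p1 <- fc[fc$protein_id == "P1", ]
  expect_equal(p1$log2fc, c(2, NA, 0))
  expect_equal(fc$log2fc[fc$protein_id == "P2"], rep(0, 3))
})

test_that("pairing makes fold changes invariant to per-animal scaling", {
  d <- toy_design(groups = "LPS50", n_animals = 2)
  q <- toy_quant(matrix(c(10, 40, 6, 18), nrow = 1,
                        dimnames = list(NULL, d$sample_id)))
  q3 <- q
  a1_cols <- d$sample_id[d$animal_id == d$animal_id[1]]
  for (cc in a1_cols) q3[[cc]] <- q3[[cc]] * 3
  expect_equal(paired_log2fc(q, d)$log2fc, paired_log2fc(q3, d)$log2fc)
})

test_that("a zero intensity within a pair refuses to compute", {
  d <- toy_design(groups = "LPS50", n_animals = 1)
  q <- toy_quant(matrix(c(0, 40), nrow = 1,
                        dimnames = list(NULL, d$sample_id)))
  expect_error(paired_log2fc(q, d), class = "pairedDEP_zero_intensity")
})

test_that("the caller reproduces a published-style summary row", {
  # five of six animals at or above +1: up, n = 5, min qualifying 1.02
  fc <- toy_fc(c(3.31, 1.02, 5.20, 2.5, 4.0, 0.5))
  call <- call_dep(fc)
  expect_identical(call$direction, "up")
  expect_identical(call$n_qualifying, 5L)
  expect_equal(call$log2fc_min, 1.02)
  expect_equal(call$log2fc_max, 5.20)
  expect_equal(call$log2fc_median, 3.31)
})

test_that("flat and missing-value vectors resolve correctly", {
  expect_identical(call_dep(toy_fc(rep(0, 6)))$direction, "none")
  # NA animals count toward neither tally; denominator stays 6
  call <- call_dep(toy_fc(c(1.5, 1.2, -1.3, 1.1, NA, 1.4)))
  expect_identical(call$direction, "up")
  expect_identical(call$n_qualifying, 4L)
  expect_identical(call$n_animals, 6L)
  # threshold is inclusive on both sides
  expect_identical(call_dep(toy_fc(c(1, 1, 1, 1, 0, 0)))$direction, "up")
  expect_identical(call_dep(toy_fc(c(-1, -1, -1, -1, 0, 0)))$direction,
                   "down")
})

test_that("down calls report the range in magnitude orientation", {
  call <- call_dep(toy_fc(c(-1.19, -5.20, -1.96, -2.5, -3.1, 0.2)))
  expect_identical(call$direction, "down")
  expect_equal(call$log2fc_min, -1.19)
  expect_equal(call$log2fc_max, -5.20)
})

test_that("min_qualifying larger than the group is a configuration error", {
  expect_error(call_dep(toy_fc(rep(2, 6)), min_qualifying = 7),
               class = "pairedDEP_config")
})

test_that("caller agrees with the brute-force oracle on random vectors", {
  vectors <- random_fc_vectors(2000, seed = 42)
  fc <- dplyr::bind_rows(lapply(seq_along(vectors), function(i) {
    toy_fc(vectors[[i]], protein_id = sprintf("P%05d", i))
  }))
  calls <- call_dep(fc)
  expected <- vapply(vectors, brute_force_call, character(1))
  expect_identical(calls$direction[match(sprintf("P%05d",
                                                 seq_along(vectors)),
                                         calls$protein_id)],
                   expected)
})

test_that("control-deregulated proteins are excluded per endpoint", {
  lps <- call_dep(dplyr::bind_rows(
    toy_fc(rep(2, 6), protein_id = "BOTH", group = "LPS50"),
    toy_fc(rep(2, 6), protein_id = "LPS_ONLY", group = "LPS50"),
    toy_fc(rep(0, 6), protein_id = "CT_ONLY", group = "LPS50")
  ))
  ct <- call_dep(dplyr::bind_rows(
    toy_fc(rep(2, 6), protein_id = "BOTH", group = "CT50"),
    toy_fc(rep(0, 6), protein_id = "LPS_ONLY", group = "CT50"),
    toy_fc(rep(-2, 6), protein_id = "CT_ONLY", group = "CT50")
  ))
  res <- exclude_control_dep(lps, ct)
  expect_setequal(res$excluded_ids, c("BOTH", "CT_ONLY"))
  expect_setequal(res$retained$protein_id, "LPS_ONLY")
  # endpoint mismatch refuses
  ct90 <- dplyr::mutate(ct, group = "CT90")
  expect_error(exclude_control_dep(lps, ct90),
               class = "pairedDEP_group_mismatch")
})

test_that("set partitioning is plain set algebra", {
  p <- partition_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(p$common_ids, c("B", "C"))
  expect_identical(p$t50_specific_ids, "A")
  expect_identical(p$t90_specific_ids, "D")
  same <- partition_sets(c("A", "B"), c("B", "A"))
  expect_length(same$t50_specific_ids, 0)
  expect_length(same$t90_specific_ids, 0)
  # sizes compose: 140 and 132 with 79 shared -> 61 and 53 specific
  ids50 <- sprintf("P%03d", 1:140)
  ids90 <- sprintf("P%03d", c(1:79, 200:252))
  big <- partition_sets(ids50, ids90)
  expect_length(big$common_ids, 79)
  expect_length(big$t50_specific_ids, 61)
  expect_length(big$t90_specific_ids, 53)
})

test_that("summary tables sort up first and never leak excluded proteins", {
  calls <- call_dep(dplyr::bind_rows(
    toy_fc(c(2, 2, 2, 2, 0, 0), protein_id = "UP4"),
    toy_fc(rep(3, 6), protein_id = "UP6"),
    toy_fc(rep(-2, 6), protein_id = "DOWN6"),
    toy_fc(rep(0, 6), protein_id = "NONE"),
    toy_fc(rep(5, 6), protein_id = "EXCL")
  ))
  p <- partition_sets(c("UP4", "UP6", "DOWN6", "NONE", "EXCL"),
                      character(0), calls = calls,
                      control_excluded_ids = "EXCL")
  tab <- summarize_dep(calls, partition = p)$t50_specific
  expect_identical(tab$protein_id, c("UP6", "UP4", "DOWN6"))
  expect_false("EXCL" %in% tab$protein_id)
  expect_false("NONE" %in% tab$protein_id)
  expect_identical(tab$n_of_n, c("6/6", "4/6", "6/6"))
  expect_identical(tab$summary[3], "-2.00 (-2.00; -2.00)")
  # every reported row satisfies the qualifying invariant
  expect_true(all(calls$n_qualifying[match(tab$protein_id,
                                           calls$protein_id)] >= 4))
  # empty calls give an empty table with the full header
  empty <- summarize_dep(calls[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("protein_id", "summary", "n_of_n") %in% names(empty)))
})

test_that("planted deregulations are fully recovered without missingness", {
  cfg <- simulation_config(n_proteins = 150L, effect_log2fc = 2,
                           missing_rate = 0, seed = 13L)
  ds <- generate_dataset(cfg)
  res <- run_pipeline(cfg, data = ds)
  truth <- ds$truth
  for (g in c("LPS50", "LPS90")) {
    calls_g <- res$calls[res$calls$group == g, ]
    up_called <- calls_g$protein_id[calls_g$direction == "up"]
    down_called <- calls_g$protein_id[calls_g$direction == "down"]
    expect_setequal(up_called,
                    truth$protein_id[truth$planted_class == "up"])
    expect_setequal(down_called,
                    truth$protein_id[truth$planted_class == "down"])
  }
  # drift proteins were flagged by the control groups, not reported
  drift <- truth$protein_id[truth$planted_class == "control_drift"]
  expect_true(all(drift %in% res$partition$control_excluded_ids))
  expect_false(any(drift %in% res$calls$protein_id))
})

test_that("DEP calls are invariant to rescaling any raw sample column", {
  cfg <- simulation_config(n_proteins = 60L, missing_rate = 0.1, seed = 17L)
  ds <- generate_dataset(cfg)
  res_a <- run_pipeline(cfg, data = ds)
  scaled <- ds
  victim <- sample_columns(ds$quant)[5]
  scaled$quant[[victim]] <- scaled$quant[[victim]] * 11.3
  res_b <- run_pipeline(cfg, data = scaled)
  expect_equal(res_b$calls$direction, res_a$calls$direction)
  expect_equal(res_b$calls$n_qualifying, res_a$calls$n_qualifying)
  expect_equal(res_b$calls$log2fc_median, res_a$calls$log2fc_median)
})
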