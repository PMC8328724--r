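spiked_toy <- function() {
  toy_quant(
    matrix(c(100, 200,
             10, 40),
           nrow = 2, byrow = TRUE,
           dimnames = list(NULL, c("s1", "s2"))),
    protein_ids = c("P00924", "PROT1")
  )
}

test_that("a spike constant across samples leaves the matrix unchanged", {
  q <- toy_quant(matrix(c(50, 50, 7, 13), nrow = 2, byrow = TRUE,
                        dimnames = list(NULL, c("s1", "s2"))),
                 protein_ids = c("P00924", "PROT1"))
  expect_equal(normalize_to_spike(q), q)
})

test_that("normalization removes per-sample scale factors", {
  # scaling a whole column (spike included) moves the geometric-mean
  # reference by a global constant, so normalized matrices agree up to one
  # factor and every between-sample ratio is restored exactly
  q <- spiked_toy()
  scaled <- q
  scaled$s2 <- scaled$s2 * 3.7
  na <- normalize_to_spike(q)
  nb <- normalize_to_spike(scaled)
  ratio <- as.matrix(nb[, c("s1", "s2")]) / as.matrix(na[, c("s1", "s2")])
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  expect_equal(nb$s2 / nb$s1, na$s2 / na$s1)
})

test_that("the hand-computed two-sample ratio is recovered", {
  norm <- normalize_to_spike(spiked_toy())
  prot <- norm[norm$protein_id == "PROT1", ]
  # (40/200) / (10/100) = 2, independent of the geometric-mean reference
  expect_equal(prot$s2 / prot$s1, 2)
})

test_that("normalization is idempotent", {
  once <- normalize_to_spike(spiked_toy())
  twice <- normalize_to_spike(once)
  expect_equal(
    as.matrix(twice[, sample_columns(twice)]),
    as.matrix(once[, sample_columns(once)]),
    tolerance = 1e-12
  )
})

test_that("a missing or zero spike intensity is a normalization error", {
  q <- spiked_toy()
  q$s1[1] <- NA
  expect_error(normalize_to_spike(q), class = "pairedDEP_normalize")
  q$s1[1] <- 0
  expect_error(normalize_to_spike(q), class = "pairedDEP_normalize")
  expect_error(normalize_to_spike(spiked_toy(), spike_id = "ABSENT"),
               class = "pairedDEP_normalize")
})

test_that("technical replicates collapse to observed-only means", {
  d <- toy_design(groups = "LPS50", n_animals = 1, n_reps = 2)
  m <- matrix(c(10, 14, 3, 5,
                NA, 14, NA, NA,
                NA, NA, 1, 2),
              nrow = 3, byrow = TRUE,
              dimnames = list(NULL, d$sample_id))
  q <- toy_quant(m)
  col <- collapse_tech_reps(q, d)
  expect_identical(nrow(col$design), 2L)
  t0_col <- col$design$sample_id[col$design$timepoint == "T0"]
  t50_col <- col$design$sample_id[col$design$timepoint == "T50"]
  expect_equal(col$quant[[t0_col]], c(12, 14, NA))
  expect_equal(col$quant[[t50_col]], c(4, NA, 1.5))
})

test_that("quantifiability keeps proteins at the inclusive bounds", {
  q <- toy_quant(matrix(1, nrow = 4, ncol = 1,
                        dimnames = list(NULL, "s1")),
                 protein_ids = paste0("P", 1:4))
  q$n_unique_peptides <- c(1L, 2L, 5L, 5L)
  q$quality_score <- c(10, 6, 5.9, 6.1)
  res <- filter_quantifiable(q)
  expect_setequal(res$quant$protein_id, c("P2", "P4"))
  expect_setequal(res$report$removed_ids[[1]], c("P1", "P3"))
  # empty input passes through with a 0 -> 0 report
  empty <- filter_quantifiable(q[0, ])
  expect_identical(nrow(empty$quant), 0L)
  expect_identical(empty$report$n_before, 0L)
  expect_identical(empty$report$n_after, 0L)
})

test_that("missingness filter withdraws at three NA in any six-animal cell", {
  d <- toy_design(groups = c("CT50", "LPS50"), n_animals = 6)
  make_row <- function(na_cells) {
    v <- rep(10, nrow(d))
    names(v) <- d$sample_id
    v[na_cells] <- NA
    v
  }
  lps50_cols <- d$sample_id[d$group == "LPS50" & d$timepoint == "T50"]
  q <- toy_quant(rbind(
    make_row(character(0)),          # fully observed
    make_row(lps50_cols[1:3]),       # 3 NA in one cell: withdrawn
    make_row(c(d$sample_id[d$timepoint == "T0"][1:2], lps50_cols[1:2]))
  ), protein_ids = c("FULL", "BAD", "TWO_EACH"))
  res <- filter_missingness(q, d)
  expect_setequal(res$quant$protein_id, c("FULL", "TWO_EACH"))
  expect_identical(res$report$removed_ids[[1]], "BAD")
})

test_that("coverage filter keeps >= 15 and rejects invalid coverage", {
  q <- toy_quant(matrix(1, nrow = 3, ncol = 1,
                        dimnames = list(NULL, "s1")),
                 protein_ids = paste0("P", 1:3))
  q$coverage_pct <- c(14.9, 15.0, 80)
  res <- filter_coverage(q)
  expect_setequal(res$quant$protein_id, c("P2", "P3"))
  q$coverage_pct[1] <- 120
  expect_error(filter_coverage(q), class = "pairedDEP_format")
})

test_that("filters are pure row selections and chain without gaps", {
  cfg <- simulation_config(n_proteins = 80L, missing_rate = 0.25,
                           mnar_strength = 1.5, seed = 11L)
  ds <- generate_dataset(cfg)
  col <- collapse_tech_reps(normalize_to_spike(ds$quant), ds$design)
  f1 <- filter_quantifiable(col$quant)
  f2 <- filter_missingness(f1$quant, col$design)
  f3 <- filter_coverage(f2$quant)
  reports <- dplyr::bind_rows(f1$report, f2$report, f3$report)
  expect_true(check_filter_chain(reports))
  # retained rows are identical to their pre-filter values
  kept <- f3$quant
  orig <- col$quant[match(kept$protein_id, col$quant$protein_id), ]
  expect_equal(kept, orig)
  # a broken chain is detected
  reports$n_after[1] <- reports$n_after[1] - 1L
  expect_error(check_filter_chain(reports),
               class = "pairedDEP_filter_chain")
})
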