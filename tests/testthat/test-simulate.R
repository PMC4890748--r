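test_that("Haldane map function matches its closed form", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.1), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(haldane(0.1), 0.09063462, tolerance = 1e-6)
  expect_equal(haldane(Inf), 0.5)
  expect_error(haldane(-0.1), "non-negative")
})

test_that("planted bulk frequencies follow recessive-selection expectations", {
  g <- miniature_genome()
  b <- simulate_bulk_variants(g, seed = 42)
  tr <- b$truth$sites
  expect_equal(tr$expected_f[tr$is_causal], 1) # complete linkage at the lesion
  unlinked <- tr$chrom != b$truth$causal_chrom
  expect_true(all(tr$expected_f[unlinked] == 0.5)) # independent assortment
  linked <- !unlinked & !tr$is_causal
  expect_equal(
    tr$expected_f[linked],
    1 - haldane(abs(tr$pos[linked] - b$truth$causal_pos) / 1e6 * 0.04)
  )
})

test_that("mean realized bulk frequency matches 1 - c(d) within binomial error", {
  g <- miniature_genome(n_chrom = 2)
  f_at_d <- purrr::map_dfr(1:30, function(s) {
    b <- simulate_bulk_variants(
      g,
      n_sites = 40, n_monitor = 0,
      causal = list(chrom = "chr1", pos = 5e5), seed = 1000 + s
    )
    b$truth$sites[, c("d_morgan", "expected_f", "realized_f")]
  })
  agg <- f_at_d %>%
    dplyr::mutate(bin = cut(.data$expected_f, c(0, 0.6, 0.99, 1.001))) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(
      exp_f = mean(.data$expected_f), obs_f = mean(.data$realized_f),
      n = dplyr::n(), .groups = "drop"
    )
  # realized_f averages Binomial(100, f)/100 draws: 4 SE tolerance
  for (i in seq_len(nrow(agg))) {
    se <- sqrt(agg$exp_f[i] * (1 - agg$exp_f[i]) / (100 * agg$n[i]))
    expect_lt(abs(agg$obs_f[i] - agg$exp_f[i]), 4 * se + 1e-9)
  }
})

test_that("generators are pure functions of the seed", {
  g <- miniature_genome(n_chrom = 2, chrom_length = 1e5, peri_width = 2e4)
  f <- simulate_features(g, n = 60, seed = 5)
  expect_identical(
    simulate_bulk_variants(g, n_sites = 10, n_monitor = 10, seed = 7),
    simulate_bulk_variants(g, n_sites = 10, n_monitor = 10, seed = 7)
  )
  expect_identical(
    simulate_counts(f, n_up = 5, seed = 7),
    simulate_counts(f, n_up = 5, seed = 7)
  )
  expect_identical(
    simulate_bins(g, bin_size = 5e3, seed = 7),
    simulate_bins(g, bin_size = 5e3, seed = 7)
  )
  expect_identical(
    simulate_flow(n_nuclei = 2000, seed = 7),
    simulate_flow(n_nuclei = 2000, seed = 7)
  )
})

test_that("count simulation plants the requested fold changes", {
  g <- miniature_genome(n_chrom = 2, chrom_length = 2e5)
  f <- simulate_features(g, n = 200, seed = 3)
  cnt <- simulate_counts(f, n_up = 20, fc = 4, seed = 9)
  expect_equal(sum(cnt$truth$fc > 1), 20L)
  expect_true(all(cnt$truth$fc %in% c(1, 4)))
  # null model: with FC = 1 everywhere the group sums agree in expectation
  null <- simulate_counts(f, n_up = 0, seed = 9)
  tot <- null$counts %>%
    dplyr::left_join(null$samples, by = "sample") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(m = mean(.data$count), .groups = "drop")
  expect_lt(abs(log(tot$m[1] / tot$m[2])), 0.25)
  expect_error(simulate_counts(f, reps = 0), "at least 1")
})

test_that("bin simulation plants the pericentromeric gain", {
  g <- miniature_genome()
  bb <- simulate_bins(g, bin_size = 1e4, lambda = 200, gain = 2, seed = 21)
  peri <- bb$truth$pericentromeric
  expect_equal(sum(peri), 100L)
  arm_mean <- mean(bb$control$value[!peri][1:100])
  expect_lt(abs(arm_mean - 200) / 200, 0.05) # Poisson sampling check
  expect_lt(
    abs(mean(bb$mutant$value[peri]) / mean(bb$control$value[peri]) - 2), 0.15
  )
})

test_that("methylome simulation shifts levels inside planted DMRs and clips with warning", {
  g <- miniature_genome(n_chrom = 1, chrom_length = 2e5)
  m <- simulate_methylome(g, n_dmrs = 3, dmr_delta = -0.5, seed = 13)
  tr <- m$truth
  lev <- function(df, iv) {
    sel <- df$context == "CG" & df$chrom == iv$chrom &
      df$pos > iv$start & df$pos <= iv$end
    sum(df$meth_count[sel]) / sum(df$total_count[sel])
  }
  for (i in seq_len(nrow(tr))) {
    expect_lt(abs(lev(m$control, tr[i, ]) - 0.8), 0.12)
    expect_lt(abs(lev(m$mutant, tr[i, ]) - 0.3), 0.12)
  }
  expect_warning(
    simulate_methylome(g, n_dmrs = 1, dmr_delta = 0.5, seed = 13),
    "clipping"
  ) # 0.8 + 0.5 > 1
})

test_that("flow simulation builds doubling peaks and normalizes bad weights", {
  expect_warning(
    simulate_flow(weights = c(1, 1, 1, 1), n_nuclei = 500, seed = 2),
    "normalizing"
  )
  fl <- simulate_flow(n_nuclei = 30000, beta = 1, seed = 17)
  # beta = 1: the two histograms are draws from the same distribution
  ks <- suppressWarnings(stats::ks.test(
    rep((fl$control$lower + fl$control$upper) / 2, fl$control$count),
    rep((fl$mutant$lower + fl$mutant$upper) / 2, fl$mutant$count)
  ))
  expect_gt(ks$p.value, 0.001)
})
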