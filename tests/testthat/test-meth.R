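cyt <- function(chrom, pos, context, meth, total) {
  tibble::tibble(
    chrom = chrom, pos = pos, strand = "+", context = context,
    meth_count = meth, total_count = total, covered = total > 0
  )
}

test_that("context levels are coverage-weighted, not means of ratios", {
  r <- cyt("c1", c(1, 5), "CG", c(5, 15), c(10, 20))
  lv <- context_levels(r)
  expect_equal(lv$level, 20 / 30, tolerance = 1e-12)
  # weighting contrast: (1/1, 0/99) pools to 0.01 where a naive mean gives 0.5
  r2 <- cyt("c1", c(1, 5), "CG", c(1, 0), c(1, 99))
  expect_equal(context_levels(r2)$level, 0.01, tolerance = 1e-12)
  r3 <- cyt("c1", 1:3, "CHH", c(0, 0, 0), c(5, 5, 5))
  expect_equal(context_levels(r3)$level, 0)
  r4 <- cyt("c1", 1, "CHG", 0, 0)
  lv4 <- context_levels(r4)
  expect_true(is.na(lv4$level))
  expect_false(lv4$defined)
  # region restriction
  both <- dplyr::bind_rows(r, cyt("c1", 50, "CG", 0, 100))
  lv5 <- context_levels(both, regions = tibble::tibble(chrom = "c1", start = 0, end = 10))
  expect_equal(lv5$level, 20 / 30)
})

test_that("vectorized Fisher p matches fisher.test and brute enumeration", {
  withr::with_seed(21, {
    a <- rbinom(60, 30, 0.5)
    c <- rbinom(60, 30, runif(60))
    b <- 30 - a
    d <- 30 - c
  })
  mine <- fisher_2x2_p(a, b, c, d)
  for (i in seq_along(a)) {
    ft <- stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2, byrow = TRUE))
    expect_equal(mine[i], ft$p.value, tolerance = 1e-10)
    expect_equal(mine[i], fisher_oracle(a[i], b[i], c[i], d[i]), tolerance = 1e-12)
  }
  # degenerate margins give p = 1
  expect_equal(fisher_2x2_p(0, 0, 0, 0), 1)
  expect_equal(fisher_2x2_p(5, 0, 5, 0), 1)
  # the screened version only shortcuts tables that can never be rejected
  sc <- hetstab:::fisher_2x2_screened(a, b, c, d, screen = 0.1)
  exactish <- mine <= 0.1
  expect_equal(sc[exactish], mine[exactish])
  expect_true(all(sc[!exactish] > 0.1))
})

test_that("a saturated window is called as a hypo DMR with the enumerated p", {
  g <- genome_model(data.frame(chrom = "c1", length = 1000))
  ctrl <- cyt("c1", seq(10, 90, 20), "CG", rep(4, 5), rep(4, 5)) # 20/20 meth
  mut <- cyt("c1", seq(10, 90, 20), "CG", rep(0, 5), rep(4, 5)) # 0/20 meth
  dm <- call_dmrs(ctrl, mut, g, window = 100)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$direction, "hypo")
  expect_equal(dm$delta, -1)
  # minimum-likelihood two-sided p over the hypergeometric support:
  # both extreme tables have probability 1/C(40,20)
  expect_equal(dm$p_value, fisher_oracle(20, 0, 0, 20), tolerance = 1e-12)
  expect_equal(dm$p_value, 2 / choose(40, 20), tolerance = 1e-12)
})

test_that("identical inputs give zero DMRs and swapping inputs flips direction only", {
  g <- genome_model(data.frame(chrom = "c1", length = 20000))
  withr::with_seed(31, {
    pos <- sort(sample(1:20000, 1500))
    base <- cyt("c1", pos, "CG", rbinom(1500, 15, 0.8), 15)
    shifted <- base
    sel <- pos > 5000 & pos <= 5400
    shifted$meth_count[sel] <- rbinom(sum(sel), 15, 0.2)
  })
  expect_equal(nrow(call_dmrs(base, base, g)), 0L)
  fwd <- call_dmrs(base, shifted, g)
  rev <- call_dmrs(shifted, base, g)
  expect_gt(nrow(fwd), 0L)
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$end, rev$end)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$direction, ifelse(rev$direction == "hypo", "hyper", "hypo"))
  # both genomes must live on the genome model
  off <- dplyr::mutate(base, chrom = "cX")
  expect_error(call_dmrs(off, shifted, g), "absent from the genome model")
})

test_that("adjacent significant windows merge within the gap limit", {
  g <- genome_model(data.frame(chrom = "c1", length = 2000))
  pos <- c(seq(10, 90, 10), seq(110, 190, 10), seq(1010, 1090, 10))
  ctrl <- cyt("c1", pos, "CG", rep(10, length(pos)), 10)
  mut <- cyt("c1", pos, "CG", rep(0, length(pos)), 10)
  dm <- call_dmrs(ctrl, mut, g, window = 100, gap_max = 200)
  expect_equal(nrow(dm), 2L) # first two windows merge; the distant one stays
  expect_equal(dm$start, c(0, 1000))
  expect_equal(dm$end, c(200, 1100))
  expect_equal(dm$n_windows, c(2L, 1L))
})

test_that("methylation ratio tracks follow the closed form and masking rule", {
  g <- genome_model(data.frame(chrom = "c1", length = 300))
  pos <- seq(5, 95, 5) # 19 sites in bin 1; bin 2 and 3 empty
  ctrl <- cyt("c1", pos, "CG", rep(4, 19), 10) # level 0.4
  mut <- cyt("c1", pos, "CG", rep(8, 19), 10) # level 0.8
  tr <- meth_ratio_track(ctrl, mut, g, context = "CG", bin_size = 100, kappa = 0)
  expect_equal(tr$value[1], 1) # log2(0.8 / 0.4)
  expect_true(all(tr$masked[2:3]))
  tr0 <- meth_ratio_track(ctrl, ctrl, g, context = "CG", bin_size = 100, kappa = 0)
  expect_equal(tr0$value[1], 0)
  # insufficient sites -> masked
  trs <- meth_ratio_track(ctrl, mut, g, context = "CG", bin_size = 100, min_sites = 50)
  expect_true(all(trs$masked))
})
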