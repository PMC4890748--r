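test_that("binomial tail p-values match brute-force pmf summation", {
  for (eps in c(0.005, 0.01, 0.1)) {
    for (dp in c(1, 7, 30)) {
      sites <- tibble::tibble(
        chrom = "c1", pos = seq_len(dp + 1), ref = "G", alt = "A",
        depth = dp, alt_count = 0:dp,
        mismatch_fraction = (0:dp) / dp
      )
      res <- test_enrichment(sites, epsilon = eps)
      oracle <- vapply(0:dp, binom_tail_oracle, 0, n = dp, eps = eps)
      expect_equal(res$p_value, oracle, tolerance = 1e-12)
    }
  }
  # closed form: all reads alternate -> tail = eps^depth
  s <- variant_row("c1", 1, "G", "A", 20, 20)
  r <- test_enrichment(s, epsilon = 0.01)
  expect_equal(r$p_value, 1e-40, tolerance = 1e-6)
  expect_true(r$enriched)
  # no evidence: p = 1
  s0 <- variant_row("c1", 1, "G", "A", 10, 0)
  expect_equal(test_enrichment(s0)$p_value, 1)
  expect_false(test_enrichment(s0)$enriched)
})

test_that("BH q-values agree with an independent sort-and-cummin oracle", {
  withr::with_seed(8, {
    for (i in 1:5) {
      p <- runif(200)^2
      sites <- tibble::tibble(
        chrom = "c1", pos = seq_along(p), ref = "G", alt = "A",
        depth = 50, alt_count = stats::qbinom(p, 50, 0.005, lower.tail = FALSE),
        mismatch_fraction = 0.1
      )
      res <- test_enrichment(sites)
      expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
    }
  })
})

test_that("the EMS signature filter excludes non-canonical transitions", {
  sites <- dplyr::bind_rows(
    variant_row("c1", 1, "A", "G", 20, 20),
    variant_row("c1", 2, "G", "A", 20, 20),
    variant_row("c1", 3, "C", "T", 20, 20),
    variant_row("c1", 4, "G", "C", 20, 20)
  )
  r <- test_enrichment(sites)
  expect_equal(r$enriched, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(test_enrichment(sites, signature_filter = FALSE)$enriched, rep(TRUE, 4))
})

test_that("chromosome distribution normalizes against genome bp", {
  g <- miniature_genome()
  mk <- function(chroms) {
    tibble::tibble(
      chrom = chroms, pos = seq_along(chroms), ref = "G", alt = "A",
      depth = 10, alt_count = 10, mismatch_fraction = 1,
      p_value = 0, q_value = 0, ems_signature = TRUE, enriched = TRUE
    )
  }
  d <- chromosome_distribution(mk(rep(paste0("chr", 1:5), each = 4)), g)
  expect_equal(d$site_fraction, rep(0.2, 5))
  expect_equal(d$bp_fraction, rep(0.2, 5))
  expect_lt(attr(d, "chisq"), 1e-12)
  d1 <- chromosome_distribution(mk(rep("chr3", 7)), g)
  expect_equal(d1$site_fraction[d1$chrom == "chr3"], 1)
  expect_equal(sum(d1$site_fraction), 1)
  none <- mk("chr1")
  none$enriched <- FALSE
  expect_warning(d0 <- chromosome_distribution(none, g), "No enriched sites")
  expect_equal(nrow(d0), 0L)
})

test_that("frequency profile averages enriched sites per window and masks empties", {
  g <- genome_model(data.frame(chrom = "c1", length = 1000))
  enr <- tibble::tibble(
    chrom = "c1", pos = c(50, 60, 500), ref = "G", alt = "A",
    depth = 10, alt_count = c(4, 6, 10),
    mismatch_fraction = c(0.4, 0.6, 1),
    enriched = TRUE
  )
  pr <- frequency_profile(enr, g, window = 100, step = 100)
  expect_equal(pr$value[1], 0.5) # two sites averaged
  expect_equal(pr$value[5], 1) # singleton window
  expect_true(pr$masked[2]) # empty window
  expect_error(frequency_profile(enr, g, window = 10, step = 20), "must not exceed")
})

test_that("interval calling follows threshold, tie-break, and no-interval rules", {
  prof <- hetstab:::new_binned_track(tibble::tibble(
    chrom = "c1",
    start = seq(0, 900, 100), end = seq(100, 1000, 100),
    value = c(0.95, 0.96, 0.2, NA, 0.97, 0.99, 0.3, NA, 0.5, 0.6)
  ))
  iv <- call_interval(prof, tau = 0.9)
  # two runs of length 2; the right one has the higher mean
  expect_equal(iv$start, 400)
  expect_equal(iv$end, 600)
  expect_equal(iv$peak_pos, 550) # argmax window midpoint
  # masked windows do not break runs
  prof2 <- hetstab:::new_binned_track(tibble::tibble(
    chrom = "c1",
    start = seq(0, 400, 100), end = seq(100, 500, 100),
    value = c(0.95, NA, 0.96, NA, 0.97)
  ))
  iv2 <- call_interval(prof2, tau = 0.9)
  expect_equal(c(iv2$start, iv2$end), c(0, 500))
  expect_equal(iv2$n_windows, 3L)
  # all-flat profile yields no interval, not an error
  flat <- hetstab:::new_binned_track(tibble::tibble(
    chrom = "c1", start = seq(0, 400, 100), end = seq(100, 500, 100),
    value = rep(0.5, 5)
  ))
  expect_equal(nrow(call_interval(flat, tau = 0.9)), 0L)
  expect_error(call_interval(flat, tau = 0.4), "tau")
})

test_that("effect classification is codon- and strand-aware", {
  seqs <- toy_sequence()
  feats <- toy_features()
  classify1 <- function(pos, ref, alt) {
    classify_effects(
      tibble::tibble(chrom = "cT", pos = pos, ref = ref, alt = alt),
      feats, seqs
    )
  }
  # TGG -> TAG at CDS position 5 of G1
  expect_equal(classify1(15, "G", "A")$class, "stop_gain")
  expect_equal(classify1(15, "G", "A")$feature_id, "G1")
  # GGG -> GGA, third codon position: synonymous
  expect_equal(classify1(47, "G", "A")$class, "synonymous")
  # GGG -> AGG: missense
  expect_equal(classify1(45, "G", "A")$class, "missense")
  # 1 bp into the intron at the donor junction
  expect_equal(classify1(38, "T", "A")$class, "splice_site")
  # acceptor side, 2 bp from the junction
  expect_equal(classify1(43, "T", "A")$class, "splice_site")
  # intron interior
  expect_equal(classify1(40, "T", "A")$class, "intronic")
  # outside any feature
  expect_equal(classify1(25, "C", "T")$class, "intergenic")
  expect_true(is.na(classify1(25, "C", "T")$feature_id))
  # minus strand: genomic G>A reads as coding C>T, CGA -> TGA stop
  expect_equal(classify1(60, "G", "A")$class, "stop_gain")
  expect_equal(classify1(60, "G", "A")$feature_id, "G3")
  # reference mismatch is an error
  expect_error(classify1(15, "C", "T"), "disagrees with genome sequence")
})

test_that("intron retention ratio is coverage-weighted and flags undefined cases", {
  feats <- toy_features()
  g2 <- feats[feats$feature_id == "G2", ]
  cov <- tibble::tibble(pos = 1:70, depth = 0)
  cov$depth[31:36] <- 100
  cov$depth[45:50] <- 100
  cov$depth[37:44] <- 40
  r <- intron_retention_ratio(cov, g2, intron = 1)
  expect_equal(r$ratio, 0.4)
  cov0 <- dplyr::mutate(cov, depth = ifelse(.data$pos %in% 37:44, 0, .data$depth))
  expect_equal(intron_retention_ratio(cov0, g2)$ratio, 0)
  cov1 <- dplyr::mutate(cov, depth = ifelse(.data$pos %in% 37:44, 100, .data$depth))
  expect_equal(intron_retention_ratio(cov1, g2)$ratio, 1)
  covx <- dplyr::mutate(cov, depth = 0)
  expect_warning(rx <- intron_retention_ratio(covx, g2), "undefined")
  expect_true(is.na(rx$ratio))
  expect_false(rx$defined)
  expect_error(intron_retention_ratio(cov, g2, intron = 5), "no intron 5")
})

test_that("background subtraction removes shared sites only above the floor", {
  sel <- dplyr::bind_rows(
    variant_row("c1", 10, "G", "A", 30, 28),
    variant_row("c1", 20, "C", "T", 30, 27),
    variant_row("c2", 5, "G", "A", 30, 26)
  )
  bg <- dplyr::bind_rows(
    variant_row("c1", 10, "G", "A", 30, 15), # real background variant
    variant_row("c2", 5, "G", "A", 30, 1) # sequencing noise: kept
  )
  out <- subtract_background(sel, bg, min_fraction = 0.1)
  expect_equal(out$pos, c(20, 5))
})

test_that("interval recovery does not degrade with larger bulks", {
  g <- miniature_genome()
  rate_at_n <- vapply(c(10, 50), function(n) {
    mean(vapply(1:10, function(s) {
      b <- simulate_bulk_variants(g, bulk_n = n, n_monitor = 50, seed = 7000 + s)
      e <- test_enrichment(b$variants)
      iv <- call_interval(frequency_profile(e, g))
      nrow(iv) == 1L && iv$chrom == b$truth$causal_chrom &&
        iv$start <= b$truth$causal_pos - 1 && b$truth$causal_pos - 1 < iv$end
    }, TRUE))
  }, 0)
  expect_gte(rate_at_n[2], rate_at_n[1] - 0.1)
  expect_gte(rate_at_n[2], 0.9)
})
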