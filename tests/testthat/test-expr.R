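lens <- tibble::tibble(feature_id = c("f1", "f2"), length = c(2000, 500))

test_that("RPKM has its closed form and scaling law", {
  counts <- tibble::tibble(
    feature_id = c("f1", "f2"), sample = "s1", count = c(50, 0)
  )
  samples <- tibble::tibble(sample = "s1", group = "a", library_size = 1e6)
  r <- rpkm(counts, lens, samples)
  expect_equal(r$rpkm, c(25, 0)) # 50 / (2 kb * 1 M reads); zero count -> 0
  r2 <- rpkm(counts, lens, dplyr::mutate(samples, library_size = 2e6))
  expect_equal(r2$rpkm, r$rpkm / 2)
  expect_error(
    rpkm(counts, lens, dplyr::mutate(samples, library_size = 0)),
    "positive"
  )
})

make_de_input <- function(mat, groups = c("control", "control", "mutant", "mutant")) {
  samples <- tibble::tibble(
    sample = paste0("s", seq_along(groups)), group = groups,
    library_size = pmax(colSums(mat), 1) * 2
  )
  counts <- tidyr::expand_grid(
    feature_id = rownames(mat), sample = samples$sample
  ) %>%
    dplyr::mutate(count = as.vector(t(mat)))
  features <- tibble::tibble(feature_id = rownames(mat), length = 1000)
  list(counts = counts, samples = samples, features = features)
}

test_that("identical groups yield zero up-regulation calls", {
  withr::with_seed(4, {
    base <- matrix(rnbinom(400, mu = 50, size = 10), ncol = 2)
  })
  mat <- cbind(base, base) # mutant replicates duplicate the control ones
  rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  d <- make_de_input(mat)
  res <- call_upregulated(d$counts, d$samples, d$features)
  expect_equal(sum(res$called), 0L)
})

test_that("an all-or-nothing feature is called against any sane dispersion", {
  withr::with_seed(5, {
    mat <- matrix(rnbinom(4 * 300, mu = 100, size = 10), ncol = 4)
  })
  rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  mat[1, ] <- c(0, 0, 500, 480)
  d <- make_de_input(mat)
  res <- call_upregulated(d$counts, d$samples, d$features)
  r1 <- res[res$feature_id == "f001", ]
  expect_true(r1$called)
  expect_lt(r1$p_value, 1e-6)
  # all-zero features are skipped, not tested
  mat0 <- mat
  mat0[2, ] <- 0
  d0 <- make_de_input(mat0)
  res0 <- call_upregulated(d0$counts, d0$samples, d0$features)
  expect_false("f002" %in% res0$feature_id)
})

test_that("calls are invariant under replicate relabeling within groups", {
  withr::with_seed(6, {
    mat <- matrix(rnbinom(4 * 200, mu = 80, size = 10), ncol = 4)
    mat[1:10, 3:4] <- mat[1:10, 3:4] * 6
  })
  rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  d <- make_de_input(mat)
  res1 <- call_upregulated(d$counts, d$samples, d$features)
  swapped <- mat[, c(2, 1, 4, 3)]
  colnames(swapped) <- NULL
  d2 <- make_de_input(swapped)
  res2 <- call_upregulated(d2$counts, d2$samples, d2$features)
  expect_equal(res1$feature_id[res1$called], res2$feature_id[res2$called])
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
})

test_that("set overlap matches hypergeometric enumeration", {
  u <- paste0("f", 1:6)
  ov <- set_overlap(u[1:3], u[1:3], u)
  expect_equal(ov$p_value, 1 / choose(6, 3), tolerance = 1e-12) # = 0.05
  expect_equal(ov$both, 3)
  # disjoint sets covering the universe: maximal anti-overlap, p = 1
  expect_equal(set_overlap(u[1:3], u[4:6], u)$p_value, 1)
  # brute-force enumeration oracle over all possible draws of |B| features
  withr::with_seed(11, {
    for (i in 1:10) {
      n_u <- sample(6:12, 1)
      u2 <- paste0("g", seq_len(n_u))
      a <- sample(u2, sample(2:4, 1))
      b <- sample(u2, sample(2:5, 1))
      k_obs <- length(intersect(a, b))
      combos <- utils::combn(n_u, length(b))
      p_brute <- mean(apply(combos, 2, function(idx) {
        length(intersect(u2[idx], a)) >= k_obs
      }))
      expect_equal(set_overlap(a, b, u2)$p_value, p_brute, tolerance = 1e-10)
    }
  })
  expect_error(set_overlap("x", "y", character()), "non-empty")
  expect_error(set_overlap("zz", u[1], u), "subsets")
})

test_that("set summaries restrict to the set and match a sorting quantile oracle", {
  withr::with_seed(12, {
    mat <- matrix(rnbinom(4 * 50, mu = 60, size = 5), ncol = 4)
  })
  rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  d <- make_de_input(mat)
  set <- rownames(mat)[1:7]
  expect_warning(
    s <- set_summary(d$counts, d$features, d$samples, c(set, "nope")),
    "not in the count table"
  )
  expect_equal(dplyr::n_distinct(s$values$feature_id), 7L)
  # type-7 quantile oracle by direct sorted interpolation
  q_oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  v1 <- s$values$rpkm[s$values$sample == "s1"]
  row1 <- s$quartiles[s$quartiles$sample == "s1", ]
  expect_equal(row1$q25, q_oracle(v1, 0.25), tolerance = 1e-12)
  expect_equal(row1$q50, q_oracle(v1, 0.5), tolerance = 1e-12)
  expect_equal(row1$q75, q_oracle(v1, 0.75), tolerance = 1e-12)
  # constant matrix: all quartiles equal
  matc <- matrix(10, 5, 4)
  rownames(matc) <- paste0("k", 1:5)
  dc <- make_de_input(matc)
  sc <- set_summary(dc$counts, dc$features, dc$samples, paste0("k", 1:5))
  expect_true(all(sc$quartiles$q0 == sc$quartiles$q100))
})
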