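#' RPKM quantification
#'
#' Reads per kilobase of exonic feature length per million mapped reads:
#' `RPKM = count / (length_kb * library_size_millions)`.
#'
#' @param counts Long counts tibble (`feature_id`, `sample`, `count`).
#' @param features A [feature_model()] (or a tibble with `feature_id` and
#'   `length`) supplying exonic lengths in bp.
#' @param samples Samples tibble with `sample` and `library_size`.
#' @return The counts tibble with an added `rpkm` column.
#' @export
rpkm <- function(counts, features, samples) {
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  assert_columns(samples, c("sample", "library_size"), "samples")
  lens <- if ("length" %in% names(features)) {
    tibble::as_tibble(features)[, c("feature_id", "length")]
  } else {
    feature_lengths(features)
  }
  if (any(samples$library_size <= 0)) {
    stop_hetstab("Library sizes must be positive for RPKM.")
  }
  counts %>%
    dplyr::left_join(lens, by = "feature_id") %>%
    dplyr::left_join(samples[, c("sample", "library_size")], by = "sample") %>%
    dplyr::mutate(
      rpkm = .data$count / ((.data$length / 1e3) * (.data$library_size / 1e6))
    ) %>%
    dplyr::select(-"length", -"library_size")
}

# Solve trigamma(y) = x by Newton iteration (x > 0).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:30) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

# Median-of-ratios size factors (relative to the geometric-mean
# pseudo-reference, over features with no zero count).
size_factors <- function(wide_mat) {
  log_mat <- log(wide_mat)
  ref <- rowMeans(log_mat)
  keep <- is.finite(ref)
  if (!any(keep)) stop_hetstab("No feature has non-zero counts in every sample; size factors undefined.")
  apply(log_mat[keep, , drop = FALSE], 2, function(col) exp(stats::median(col - ref[keep])))
}

#' Call up-regulated features between two groups
#'
#' A one-sided (mutant above control) test for derepression on replicated
#' counts. Counts are normalized by median-of-ratios size factors; each
#' feature's dispersion is moment-estimated from within-group variability
#' and moderated toward the genome-wide median estimate (degrees-of-freedom
#' weighted, prior df 6), floored at `phi_min`. The test is a one-sided
#' Wald z on the log fold change of normalized group means (pseudo-count 1),
#' with the delta-method variance evaluated at the pooled null mean:
#' `Var(log mu_g) ~ [sum_j (mu0/s_j + phi mu0^2) / n_g^2] / (mu0 + 1)^2`.
#' BH correction is applied across tested features. A feature is called
#' up-regulated when `q <= alpha`, the LFC is at least `log2(fc_min)`, and
#' its mean mutant RPKM reaches `rpkm_floor`.
#'
#' @param counts Long counts tibble.
#' @param samples Samples tibble with `sample`, `group`, `library_size`.
#' @param features Feature model or length table (for the RPKM floor).
#' @param control,mutant Group labels in `samples$group`.
#' @param alpha BH threshold.
#' @param fc_min Minimum fold change for a call.
#' @param rpkm_floor Minimum mean mutant RPKM for a call.
#' @param phi_min Dispersion floor.
#' @return Tibble with one row per tested feature: `feature_id`,
#'   `base_mean`, `mean_control`, `mean_mutant`, `lfc`, `dispersion`,
#'   `p_value`, `q_value`, `mean_rpkm_mutant`, `called`. All-zero features
#'   are skipped.
#' @export
call_upregulated <- function(counts, samples, features,
                             control = "control", mutant = "mutant",
                             alpha = 0.05, fc_min = 2, rpkm_floor = 1,
                             phi_min = 0.01) {
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  assert_columns(samples, c("sample", "group", "library_size"), "samples")
  samples <- dplyr::filter(samples, .data$group %in% c(control, mutant))
  if (!all(c(control, mutant) %in% samples$group)) {
    stop_hetstab("Both group labels must be present in `samples`.")
  }
  counts <- dplyr::filter(counts, .data$sample %in% samples$sample)
  wide <- tidyr::pivot_wider(
    counts,
    id_cols = "feature_id", names_from = "sample", values_from = "count"
  )
  mat <- as.matrix(wide[, samples$sample, drop = FALSE])
  rownames(mat) <- wide$feature_id
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  is_a <- samples$group == control
  is_b <- samples$group == mutant
  n_a <- sum(is_a)
  n_b <- sum(is_b)
  mu_a <- rowMeans(norm[, is_a, drop = FALSE])
  mu_b <- rowMeans(norm[, is_b, drop = FALSE])
  tested <- mu_a + mu_b > 0
  # pooled within-group variance of normalized counts (shot noise included)
  dev_a <- norm[, is_a, drop = FALSE] - mu_a
  dev_b <- norm[, is_b, drop = FALSE] - mu_b
  df_w <- (n_a - 1) + (n_b - 1)
  if (df_w < 1) stop_hetstab("At least two replicates in one group are required.")
  var_w <- (rowSums(dev_a^2) + rowSums(dev_b^2)) / df_w
  mu_bar <- (n_a * mu_a + n_b * mu_b) / (n_a + n_b)
  shot <- mu_bar * mean(1 / sf)
  phi_hat <- ifelse(mu_bar > 0, (var_w - shot) / mu_bar^2, NA_real_)
  phi_med <- stats::median(phi_hat[tested & is.finite(phi_hat) & phi_hat > 0], na.rm = TRUE)
  if (!is.finite(phi_med)) phi_med <- phi_min
  # the median of a df_w-df moment estimate underestimates the centre of the
  # dispersion distribution; undo the chi-square median bias
  phi_med <- phi_med / (stats::qchisq(0.5, df_w) / df_w)
  # empirical-Bayes moderation strength: the spread of log dispersion
  # estimates in excess of the chi-square sampling noise determines the
  # prior df (none in excess -> shrink hard)
  lp <- log(phi_hat[tested & is.finite(phi_hat) & phi_hat > 0])
  excess <- max(stats::var(lp) - trigamma(df_w / 2), 0.02)
  prior_df <- min(max(2 * trigamma_inverse(excess), 4), 50)
  phi_shrunk <- (df_w * dplyr::coalesce(pmax(phi_hat, 0), phi_med) + prior_df * phi_med) /
    (df_w + prior_df)
  phi <- pmax(phi_shrunk, phi_min)
  # one-sided Wald z on the log fold change; delta-method variance at the
  # pooled null mean
  pc <- 1
  var_log_null <- vapply(seq_len(nrow(mat)), function(i) {
    m0 <- mu_bar[i]
    va <- sum(m0 / sf[is_a] + phi[i] * m0^2) / n_a^2
    vb <- sum(m0 / sf[is_b] + phi[i] * m0^2) / n_b^2
    (va + vb) / (m0 + pc)^2
  }, 0)
  t_log <- log((mu_b + pc) / (mu_a + pc))
  z <- ifelse(var_log_null > 0, t_log / sqrt(var_log_null), 0)
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[!tested] <- NA_real_
  # independent filtering on the base mean: choose the expression cutoff
  # that maximizes the number of BH rejections (the filter statistic is
  # independent of the test statistic under the null, so FDR control holds)
  q <- rep(NA_real_, length(p))
  thetas <- stats::quantile(mu_bar[tested], seq(0, 0.6, by = 0.1), names = FALSE)
  n_rej <- vapply(thetas, function(th) {
    sel <- tested & mu_bar >= th
    sum(stats::p.adjust(p[sel], method = "BH") <= alpha)
  }, 0L)
  theta <- thetas[which.max(n_rej)]
  keep_f <- tested & mu_bar >= theta
  q[keep_f] <- stats::p.adjust(p[keep_f], method = "BH")
  rp <- rpkm(counts, features, samples) %>%
    dplyr::left_join(samples[, c("sample", "group")], by = "sample") %>%
    dplyr::filter(.data$group == mutant) %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::summarise(mean_rpkm_mutant = mean(.data$rpkm), .groups = "drop")
  out <- tibble::tibble(
    feature_id = rownames(mat),
    base_mean = mu_bar,
    mean_control = mu_a,
    mean_mutant = mu_b,
    lfc = log2((mu_b + 1) / (mu_a + 1)),
    dispersion = phi,
    p_value = p,
    q_value = q
  ) %>%
    dplyr::left_join(rp, by = "feature_id") %>%
    dplyr::mutate(
      called = !is.na(.data$q_value) & .data$q_value <= alpha &
        .data$lfc >= log2(fc_min) & .data$mean_rpkm_mutant >= rpkm_floor
    ) %>%
    dplyr::filter(.data$base_mean > 0)
  log_info(
    "call_upregulated: %d/%d features called up-regulated (q <= %g, FC >= %g)",
    sum(out$called), nrow(out), alpha, fc_min
  )
  out
}

#' Fisher overlap test between two feature sets
#'
#' One-sided hypergeometric test for enrichment of the intersection of two
#' sets over a common universe (the classical Venn-overlap significance).
#'
#' @param set_a,set_b Character vectors of feature ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all eligible feature ids.
#' @return One-row tibble with the 2x2 contingency counts (`both`, `a_only`,
#'   `b_only`, `neither`) and the one-sided `p_value`.
#' @export
set_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_hetstab("The universe must be non-empty.")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop_hetstab("Both sets must be subsets of the universe.")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(
    k - 1, length(set_a), length(universe) - length(set_a), length(set_b),
    lower.tail = FALSE
  )
  tibble::tibble(
    both = k,
    a_only = length(set_a) - k,
    b_only = length(set_b) - k,
    neither = length(universe) - length(set_a) - length(set_b) + k,
    p_value = p
  )
}

#' Per-sample RPKM summary over a defined feature set
#'
#' Restricts the RPKM matrix to a defined set of features (e.g. the mutant
#' derepressed transposon set) and reports per-sample quartiles, the table
#' behind boxplot/heatmap summaries.
#'
#' @param counts Long counts tibble.
#' @param features Feature model or length table.
#' @param samples Samples tibble.
#' @param set Character vector of feature ids; unknown ids are dropped with
#'   a warning.
#' @return A list with `values` (long RPKM tibble restricted to the set) and
#'   `quartiles` (per-sample `q0`, `q25`, `q50`, `q75`, `q100`).
#' @export
set_summary <- function(counts, features, samples, set) {
  known <- unique(counts$feature_id)
  unknown <- setdiff(set, known)
  if (length(unknown) > 0L) {
    rlang::warn(sprintf(
      "%d feature id(s) in the set are not in the count table; skipping them.",
      length(unknown)
    ))
    set <- intersect(set, known)
  }
  values <- rpkm(counts, features, samples) %>%
    dplyr::filter(.data$feature_id %in% set)
  quart <- values %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::summarise(
      q0 = stats::quantile(.data$rpkm, 0, names = FALSE),
      q25 = stats::quantile(.data$rpkm, 0.25, names = FALSE),
      q50 = stats::quantile(.data$rpkm, 0.5, names = FALSE),
      q75 = stats::quantile(.data$rpkm, 0.75, names = FALSE),
      q100 = stats::quantile(.data$rpkm, 1, names = FALSE),
      .groups = "drop"
    )
  list(values = values, quartiles = quart)
}
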