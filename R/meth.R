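#' Two-sided Fisher exact p-values for 2x2 tables, vectorized
#'
#' Computes the two-sided Fisher exact p-value (sum of hypergeometric point
#' probabilities not exceeding that of the observed table, the convention
#' used by [stats::fisher.test()]) for vectors of tables
#' `rbind(c(a, b), c(c, d))`. Used to test thousands of methylation windows
#' without per-window calls to `fisher.test`.
#'
#' @param a,b,c,d Cell counts; `a`/`b` methylated and unmethylated reads in
#'   one sample, `c`/`d` in the other.
#' @return Numeric vector of p-values.
#' @export
fisher_2x2_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  m <- a + b # row 1 total (sample 1 reads)
  nn <- c + d # row 2 total
  k <- a + c # methylated column total
  p <- rep(1, n)
  todo <- which(m + nn > 0 & k > 0 & k < m + nn)
  if (length(todo) == 0L) {
    return(p)
  }
  p_obs <- stats::dhyper(a[todo], m[todo], nn[todo], k[todo])
  lo <- pmax(0, k[todo] - nn[todo])
  hi <- pmin(k[todo], m[todo])
  len <- hi - lo + 1
  # enumerate every table's hypergeometric support in one flat pass,
  # chunked to bound memory
  chunk_starts <- seq(1L, length(todo), by = 20000L)
  for (cs in chunk_starts) {
    ce <- min(cs + 20000L - 1L, length(todo))
    idx <- cs:ce
    g <- rep(seq_along(idx), len[idx])
    xs <- sequence(len[idx]) - 1L + rep(lo[idx], len[idx])
    gi <- todo[idx][g]
    probs <- stats::dhyper(xs, m[gi], nn[gi], k[gi])
    keep <- probs <= p_obs[idx][g] * (1 + 1e-7)
    sums <- rowsum(probs * keep, g)
    p[todo[idx]] <- pmin(as.numeric(sums), 1)
  }
  p
}

# Screened Fisher p for large batches: the smaller one-sided hypergeometric
# tail is a lower bound on the two-sided p, so tables whose bound already
# exceeds `screen` (>> the BH threshold) keep the bound -- they can never be
# rejected, and values above the threshold do not influence which smaller
# p-values BH rejects. Exact enumeration runs only on the candidates.
fisher_2x2_screened <- function(a, b, c, d, screen) {
  m <- a + b
  nn <- c + d
  k <- a + c
  left <- stats::phyper(a, m, nn, k)
  right <- stats::phyper(a - 1, m, nn, k, lower.tail = FALSE)
  lb <- pmin(left, right)
  p <- pmin(1, lb)
  cand <- lb <= screen
  if (any(cand)) {
    p[cand] <- fisher_2x2_p(a[cand], b[cand], c[cand], d[cand])
  }
  p
}

#' Genome-wide weighted methylation level per context
#'
#' The weighted level `sum(meth) / sum(total)` per sequence context, not the
#' mean of per-site ratios, so deeply covered cytosines contribute
#' proportionally to their evidence.
#'
#' @param records Cytosine record tibble (see [read_cytosine_report()]).
#' @param regions Optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open) restricting the computation.
#' @return Tibble with `context`, `meth`, `total`, `level` (`NA` with
#'   `defined = FALSE` where a context has no covered cytosine).
#' @export
context_levels <- function(records, regions = NULL) {
  assert_columns(records, c("chrom", "pos", "context", "meth_count", "total_count"), "records")
  if (!is.null(regions)) {
    keep <- rep(FALSE, nrow(records))
    for (i in seq_len(nrow(regions))) {
      keep <- keep | (records$chrom == regions$chrom[i] &
        (records$pos - 1) >= regions$start[i] &
        (records$pos - 1) < regions$end[i])
    }
    records <- records[keep, ]
  }
  records %>%
    dplyr::group_by(.data$context) %>%
    dplyr::summarise(
      meth = sum(.data$meth_count), total = sum(.data$total_count),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      level = ifelse(.data$total > 0, .data$meth / .data$total, NA_real_),
      defined = .data$total > 0
    )
}

#' Call differentially methylated regions between two cytosine reports
#'
#' The genome is cut into fixed non-overlapping windows per sequence
#' context. Within each window the methylated/unmethylated read counts of
#' cytosines with at least `cov_min` reads are pooled per sample and
#' compared by a two-sided Fisher exact test; BH correction is applied per
#' context. Windows pass when `q <= alpha`, the pooled level difference
#' `|delta| >= delta_min[context]`, and both samples have at least `n_min`
#' covered cytosines. Adjacent passing windows of the same context separated
#' by at most `gap_max` bp are merged; merged regions report pooled levels,
#' a Fisher p recomputed on the merged counts, and the smallest
#' constituent-window q.
#'
#' @param control,mutant Cytosine record tibbles on the same genome.
#' @param genome A [genome_model()] (used to verify both inputs share its
#'   chromosomes).
#' @param window Window width bp.
#' @param delta_min Named per-context minimum absolute level difference.
#' @param cov_min Minimum reads for a cytosine to count as covered.
#' @param n_min Minimum covered cytosines per sample per window.
#' @param alpha Per-context BH threshold.
#' @param gap_max Maximum gap bp between merged windows.
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `context`,
#'   `level_control`, `level_mutant`, `delta`, `p_value`, `q_value`,
#'   `direction` (`hyper`/`hypo`, mutant relative to control), `n_windows`.
#' @export
call_dmrs <- function(control, mutant, genome, window = 100,
                      delta_min = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                      cov_min = 4, n_min = 4, alpha = 0.01, gap_max = 200) {
  for (nm in c("control", "mutant")) {
    df <- get(nm)
    assert_columns(df, c("chrom", "pos", "context", "meth_count", "total_count"), nm)
    bad <- setdiff(unique(df$chrom), genome$chromosomes$chrom)
    if (length(bad) > 0L) {
      stop_hetstab(sprintf(
        "%s records on chromosome(s) absent from the genome model: %s.",
        nm, paste(bad, collapse = ", ")
      ))
    }
  }
  chrom_levels <- genome$chromosomes$chrom
  ctx_levels <- c("CG", "CHG", "CHH")
  n_win <- ceiling(max(genome$chromosomes$length) / window)
  # rowsum on a composite integer key: orders of magnitude faster than a
  # grouped summarise at ~10^6 cytosines
  pool <- function(df, label) {
    sel <- df$total_count >= cov_min
    meth <- df$meth_count[sel]
    total <- df$total_count[sel]
    win <- (df$pos[sel] - 1) %/% window
    key <- (match(df$chrom[sel], chrom_levels) - 1) * (3 * n_win) +
      (match(df$context[sel], ctx_levels) - 1) * n_win + win
    agg <- rowsum(cbind(meth, total - meth, 1), key, reorder = TRUE)
    ukey <- as.numeric(rownames(agg))
    out <- tibble::tibble(
      chrom = chrom_levels[ukey %/% (3 * n_win) + 1],
      context = ctx_levels[(ukey %% (3 * n_win)) %/% n_win + 1],
      win = ukey %% n_win,
      meth = agg[, 1L], unmeth = agg[, 2L], n_sites = agg[, 3L]
    )
    names(out)[4:6] <- paste0(c("meth", "unmeth", "n_sites"), "_", label)
    out
  }
  tab <- dplyr::inner_join(
    pool(control, "c"), pool(mutant, "m"),
    by = c("chrom", "context", "win")
  ) %>%
    dplyr::filter(.data$n_sites_c >= n_min, .data$n_sites_m >= n_min)
  if (nrow(tab) == 0L) {
    return(empty_dmrs())
  }
  tab <- tab %>%
    dplyr::mutate(
      level_c = .data$meth_c / (.data$meth_c + .data$unmeth_c),
      level_m = .data$meth_m / (.data$meth_m + .data$unmeth_m),
      delta = .data$level_m - .data$level_c,
      p_value = fisher_2x2_screened(
        .data$meth_c, .data$unmeth_c, .data$meth_m, .data$unmeth_m,
        screen = min(1, 10 * alpha)
      )
    ) %>%
    dplyr::group_by(.data$context) %>%
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH")) %>%
    dplyr::ungroup()
  hits <- tab %>%
    dplyr::filter(
      .data$q_value <= alpha,
      abs(.data$delta) >= unname(delta_min[.data$context])
    ) %>%
    dplyr::arrange(.data$context, .data$chrom, .data$win)
  if (nrow(hits) == 0L) {
    return(empty_dmrs())
  }
  hits <- hits %>%
    dplyr::mutate(start = .data$win * window, end = .data$win * window + window)
  grp <- hits %>%
    dplyr::group_by(.data$context, .data$chrom) %>%
    dplyr::mutate(
      new_block = c(TRUE, .data$start[-1L] - .data$end[-dplyr::n()] > gap_max),
      block = cumsum(.data$new_block)
    ) %>%
    dplyr::group_by(.data$context, .data$chrom, .data$block) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      meth_c = sum(.data$meth_c), unmeth_c = sum(.data$unmeth_c),
      meth_m = sum(.data$meth_m), unmeth_m = sum(.data$unmeth_m),
      q_value = min(.data$q_value), n_windows = dplyr::n(),
      .groups = "drop"
    )
  out <- grp %>%
    dplyr::mutate(
      level_control = .data$meth_c / (.data$meth_c + .data$unmeth_c),
      level_mutant = .data$meth_m / (.data$meth_m + .data$unmeth_m),
      delta = .data$level_mutant - .data$level_control,
      p_value = fisher_2x2_p(.data$meth_c, .data$unmeth_c, .data$meth_m, .data$unmeth_m),
      direction = ifelse(.data$delta > 0, "hyper", "hypo")
    ) %>%
    dplyr::arrange(
      match(.data$chrom, genome$chromosomes$chrom), .data$start, .data$context
    ) %>%
    dplyr::select(
      "chrom", "start", "end", "context", "level_control", "level_mutant",
      "delta", "p_value", "q_value", "direction", "n_windows"
    )
  log_info("call_dmrs: %d DMR(s) called", nrow(out))
  out
}

empty_dmrs <- function() {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    context = character(), level_control = numeric(), level_mutant = numeric(),
    delta = numeric(), p_value = numeric(), q_value = numeric(),
    direction = character(), n_windows = integer()
  )
}

#' Chromosomal log2 methylation-ratio track
#'
#' Pools per-bin weighted methylation levels per sample for one context and
#' reports `log2((level_mutant + kappa) / (level_control + kappa))`. Bins
#' where either sample has fewer than `min_sites` covered cytosines are
#' masked.
#'
#' @param control,mutant Cytosine record tibbles.
#' @param genome A [genome_model()].
#' @param context Sequence context to profile.
#' @param bin_size Bin width bp.
#' @param kappa Pseudo-level stabilizing the ratio.
#' @param min_sites Minimum covered cytosines per sample per bin.
#' @param cov_min Minimum reads for a cytosine to count as covered.
#' @return A binned track of log2 level ratios.
#' @export
meth_ratio_track <- function(control, mutant, genome, context = "CG",
                             bin_size = 1e5, kappa = 0.01, min_sites = 10,
                             cov_min = 1) {
  bins <- genome_bins(genome, bin_size)
  pool_bin <- function(df) {
    df %>%
      dplyr::filter(.data$context == !!context, .data$total_count >= cov_min) %>%
      dplyr::mutate(start = ((.data$pos - 1) %/% bin_size) * bin_size) %>%
      dplyr::group_by(.data$chrom, .data$start) %>%
      dplyr::summarise(
        meth = sum(.data$meth_count), total = sum(.data$total_count),
        n_sites = dplyr::n(), .groups = "drop"
      )
  }
  cc <- pool_bin(control)
  mm <- pool_bin(mutant)
  out <- bins %>%
    dplyr::left_join(cc, by = c("chrom", "start")) %>%
    dplyr::left_join(mm, by = c("chrom", "start"), suffix = c("_c", "_m")) %>%
    dplyr::mutate(
      masked = is.na(.data$n_sites_c) | is.na(.data$n_sites_m) |
        .data$n_sites_c < min_sites | .data$n_sites_m < min_sites,
      value = ifelse(
        .data$masked, NA_real_,
        log2((.data$meth_m / .data$total_m + kappa) / (.data$meth_c / .data$total_c + kappa))
      )
    ) %>%
    dplyr::select("chrom", "start", "end", "value", "masked")
  new_binned_track(out)
}
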