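#' Log2 read-ratio track between two binned count tracks
#'
#' Computes per-bin `log2((m_i/M + kappa) / (c_i/C + kappa))` where `m_i`,
#' `c_i` are mutant and control bin counts and `M`, `C` the library totals,
#' so the track is invariant under library-size rescaling. Bins whose
#' control count falls below `floor` are masked, mirroring the low-coverage
#' gaps left blank in chromosomal read-ratio views.
#'
#' @param control,mutant Binned count tracks on identical bin grids (as
#'   produced by [simulate_bins()] or read with [read_track()]).
#' @param kappa Pseudo-rate added to both normalized rates; default is a
#'   one-read pseudo-rate, `1 / min(M, C)`.
#' @param floor Minimum control bin count; bins below it are masked.
#' @return A binned track of log2 ratios (`masked` where low coverage).
#' @export
ratio_track <- function(control, mutant, kappa = NULL, floor = 10) {
  assert_columns(control, c("chrom", "start", "end", "value"), "control")
  assert_columns(mutant, c("chrom", "start", "end", "value"), "mutant")
  if (nrow(control) != nrow(mutant) ||
      !all(control$chrom == mutant$chrom) ||
      !all(control$start == mutant$start) ||
      !all(control$end == mutant$end)) {
    stop_hetstab("Control and mutant tracks must share an identical bin grid.")
  }
  C <- sum(control$value, na.rm = TRUE)
  M <- sum(mutant$value, na.rm = TRUE)
  if (C <= 0 || M <= 0) stop_hetstab("Both libraries must contain reads.")
  if (is.null(kappa)) kappa <- 1 / min(M, C)
  assert_scalar_number(kappa, "kappa", lower = 0)
  masked <- is.na(control$value) | is.na(mutant$value) | control$value < floor
  value <- log2((mutant$value / M + kappa) / (control$value / C + kappa))
  value[masked] <- NA_real_
  out <- tibble::tibble(
    chrom = control$chrom, start = control$start, end = control$end,
    value = value, masked = masked
  )
  log_info(
    "ratio_track: %d bins, %d masked (control < %g reads)",
    nrow(out), sum(masked), floor
  )
  new_binned_track(out)
}

#' Pericentromeric enrichment of a log2 ratio track
#'
#' The enrichment score is `S = mean(value | pericentromeric bins) -
#' mean(value | arm bins)` over unmasked bins; a planted copy gain `g`
#' restricted to the pericentromere yields `S ~ log2(g)`. Significance is a
#' one-sided permutation test: bin class labels are shuffled `n_perm` times
#' among unmasked bins and `p = (b + 1) / (n_perm + 1)` where `b` counts
#' permuted scores `>= S`.
#'
#' @param track A log2 [ratio_track()].
#' @param genome A [genome_model()] supplying the pericentromeric intervals;
#'   bins are classified by midpoint.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `enrichment_result` with fields `score`,
#'   `p_value`, `n_perm`, `n_peri`, `n_arm`.
#' @export
pericentromere_enrichment <- function(track, genome, n_perm = 1000, seed = 1L) {
  assert_columns(track, c("chrom", "start", "end", "value"), "track")
  assert_scalar_number(n_perm, "n_perm", lower = 1)
  if (nrow(genome$pericentromere) == 0L) {
    stop_hetstab("Genome model has no pericentromeric intervals; enrichment is undefined.",
      class = "hetstab_undefined"
    )
  }
  mid <- (track$start + track$end) / 2
  peri <- in_pericentromere(genome, track$chrom, mid)
  keep <- !is.na(track$value)
  if (!any(keep & peri)) {
    stop_hetstab("All pericentromeric bins are masked; enrichment is undefined.")
  }
  if (!any(keep & !peri)) {
    stop_hetstab("All arm bins are masked; enrichment is undefined.")
  }
  v <- track$value[keep]
  cls <- peri[keep]
  score <- mean(v[cls]) - mean(v[!cls])
  n_peri <- sum(cls)
  perm_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(v), n_peri)
      inn <- logical(length(v))
      inn[idx] <- TRUE
      mean(v[inn]) - mean(v[!inn])
    }, 0)
  })
  b <- sum(perm_scores >= score)
  structure(
    list(
      score = score,
      p_value = (b + 1) / (n_perm + 1),
      n_perm = n_perm,
      n_peri = n_peri,
      n_arm = sum(!cls),
      perm_scores = perm_scores
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> S = %.4f (pericentromere - arm, log2), p = %.4g (%d permutations; %d/%d bins)\n",
    x$score, x$p_value, x$n_perm, x$n_peri, x$n_arm
  ))
  invisible(x)
}

#' Export a chromosomal view of a track
#'
#' Writes the track as a TSV of `(chrom, start, end, value)` in genome
#' order, with masked bins emitted as `NA`, ready for plotting as a
#' chromosomal view.
#'
#' @param track A binned track.
#' @param path Output path.
#' @return Invisibly, the track.
#' @export
export_chromosome_view <- function(track, path) {
  write_track(track, path)
}
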