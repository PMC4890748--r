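#' Test variant sites for enrichment above sequencing error
#'
#' In a selected bulk, a real EMS lesion shows an alternate-read fraction
#' far above the sequencing error rate. Each site gets a one-sided binomial
#' tail p-value `P[X >= alt_count | depth, epsilon]`, Benjamini-Hochberg
#' correction across all tested sites, and an EMS-signature flag (ref>alt
#' is G>A or C>T, the transitions EMS chemistry produces). A site is called
#' enriched when `q <= alpha` and (if the signature filter is on) it carries
#' the EMS signature.
#'
#' @param sites Variant tibble as from [read_variants()].
#' @param epsilon Per-read sequencing error rate, in (0, 0.5).
#' @param alpha BH false-discovery-rate threshold.
#' @param signature_filter Require the canonical EMS transition signature.
#' @return The input tibble with added columns `p_value`, `q_value`,
#'   `ems_signature`, `enriched`.
#' @export
test_enrichment <- function(sites, epsilon = 0.005, alpha = 0.05,
                            signature_filter = TRUE) {
  assert_columns(sites, c("chrom", "pos", "ref", "alt", "depth", "alt_count"), "sites")
  assert_scalar_number(epsilon, "epsilon", lower = 1e-12, upper = 0.5 - 1e-12)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (any(sites$depth < 1)) stop_hetstab("All sites must have depth >= 1.")
  p <- stats::pbinom(sites$alt_count - 1, sites$depth, epsilon, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- (sites$ref == "G" & sites$alt == "A") | (sites$ref == "C" & sites$alt == "T")
  out <- sites %>%
    dplyr::mutate(
      p_value = p, q_value = q, ems_signature = sig,
      enriched = q <= alpha & (if (signature_filter) sig else TRUE)
    )
  log_info(
    "test_enrichment: %d/%d sites enriched at q <= %g (epsilon = %g)",
    sum(out$enriched), nrow(out), alpha, epsilon
  )
  out
}

#' Subtract background variants seen in an unselected pool
#'
#' Optional pre-filter for mapping: removes candidate sites that are also
#' present (at or above `min_fraction` mismatch) in an unselected sibling
#' pool, e.g. the phenotype-positive bulk of the same screen. Off by
#' default in the pipeline; apply it before [test_enrichment()] when a
#' background pool is available.
#'
#' @param sites Variant tibble of the selected bulk.
#' @param background Variant tibble of the unselected pool.
#' @param min_fraction Minimum background mismatch fraction for a site to be
#'   treated as background and removed.
#' @return `sites` without the background positions.
#' @export
subtract_background <- function(sites, background, min_fraction = 0.1) {
  assert_columns(sites, c("chrom", "pos"), "sites")
  assert_columns(background, c("chrom", "pos", "mismatch_fraction"), "background")
  bg <- background[!is.na(background$mismatch_fraction) &
    background$mismatch_fraction >= min_fraction, ]
  keep <- !paste(sites$chrom, sites$pos) %in% paste(bg$chrom, bg$pos)
  log_info("subtract_background: removed %d of %d sites", sum(!keep), nrow(sites))
  sites[keep, ]
}

#' Chromosome distribution of enriched variants
#'
#' A mapping diagnostic: linked mutations pile onto the causal chromosome,
#' so the fraction of enriched sites per chromosome is compared with the
#' fraction of genomic bp per chromosome. A chi-square-style statistic
#' `sum((obs - exp)^2 / exp)` (expected counts from bp fractions) is
#' reported as a descriptive value, not a test decision.
#'
#' @param enriched Output of [test_enrichment()]; only rows with
#'   `enriched == TRUE` are used.
#' @param genome A [genome_model()].
#' @return Tibble with `chrom`, `n_sites`, `site_fraction`, `bp_fraction`,
#'   plus attribute `chisq` carrying the diagnostic value. Zero enriched
#'   sites yield an empty tibble with a warning.
#' @export
chromosome_distribution <- function(enriched, genome) {
  assert_columns(enriched, c("chrom", "enriched"), "enriched")
  hits <- dplyr::filter(enriched, .data$enriched)
  if (nrow(hits) == 0L) {
    rlang::warn("No enriched sites; chromosome distribution is empty.")
    out <- tibble::tibble(
      chrom = character(), n_sites = integer(),
      site_fraction = numeric(), bp_fraction = numeric()
    )
    attr(out, "chisq") <- NA_real_
    return(out)
  }
  fr <- genome_fractions(genome)
  out <- fr %>%
    dplyr::left_join(
      dplyr::count(hits, .data$chrom, name = "n_sites"),
      by = "chrom"
    ) %>%
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      site_fraction = .data$n_sites / sum(.data$n_sites)
    ) %>%
    dplyr::select("chrom", "n_sites", "site_fraction", "bp_fraction")
  expected <- out$bp_fraction * sum(out$n_sites)
  attr(out, "chisq") <- sum((out$n_sites - expected)^2 / expected)
  out
}

#' Sliding-window allele-frequency profile of enriched variants
#'
#' Averages the mismatch fraction of enriched sites in sliding windows along
#' each chromosome. Windows containing no enriched site are masked: an empty
#' window carries no evidence about linkage.
#'
#' @param enriched Output of [test_enrichment()].
#' @param genome A [genome_model()].
#' @param window Window width bp.
#' @param step Step between window starts bp (`step <= window`).
#' @return A binned track (`chrom`, `start`, `end`, `value`, `masked`,
#'   `n_sites`); note that consecutive windows overlap when `step < window`.
#' @export
frequency_profile <- function(enriched, genome, window = 1e5, step = window / 5) {
  assert_columns(enriched, c("chrom", "pos", "mismatch_fraction", "enriched"), "enriched")
  assert_scalar_number(window, "window", lower = 1)
  assert_scalar_number(step, "step", lower = 1)
  if (step > window) stop_hetstab("`step` must not exceed `window`.")
  hits <- dplyr::filter(enriched, .data$enriched)
  wins <- purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(ci) {
    len <- genome$chromosomes$length[ci]
    starts <- seq(0, max(0, len - 1), by = step)
    tibble::tibble(
      chrom = genome$chromosomes$chrom[ci],
      start = starts, end = pmin(starts + window, len)
    )
  })
  stat <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    sel <- hits$chrom == wins$chrom[i] &
      (hits$pos - 1) >= wins$start[i] & (hits$pos - 1) < wins$end[i]
    tibble::tibble(
      value = if (any(sel)) mean(hits$mismatch_fraction[sel]) else NA_real_,
      n_sites = sum(sel)
    )
  })
  out <- dplyr::bind_cols(wins, stat)
  out$masked <- out$n_sites == 0L
  new_binned_track(out)
}

#' Call the candidate mapping interval from a frequency profile
#'
#' Scans the profile for runs of windows whose smoothed mismatch fraction
#' stays at or above `tau`. Runs are broken by windows that fall below the
#' threshold and by chromosome boundaries; masked (empty) windows are
#' skipped, since the absence of variants is not evidence against linkage.
#' The longest run wins, with ties broken by higher mean value, then by the
#' leftmost genomic position.
#'
#' @param profile Output of [frequency_profile()].
#' @param tau Frequency threshold in (0.5, 1].
#' @return A one-row tibble (`chrom`, `start`, `end`, `peak_pos`,
#'   `mean_mismatch`, `n_windows`) or a zero-row tibble when no window
#'   reaches `tau` ("no interval", not an error).
#' @export
call_interval <- function(profile, tau = 0.9) {
  assert_columns(profile, c("chrom", "start", "end", "value"), "profile")
  assert_scalar_number(tau, "tau", lower = 0.5 + 1e-12, upper = 1)
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    peak_pos = numeric(), mean_mismatch = numeric(), n_windows = integer()
  )
  obs <- profile %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::arrange(match(.data$chrom, unique(profile$chrom)), .data$start) %>%
    dplyr::mutate(pass = .data$value >= tau)
  if (nrow(obs) == 0L || !any(obs$pass)) {
    return(empty)
  }
  run_id <- cumsum(
    c(TRUE, obs$chrom[-1L] != obs$chrom[-nrow(obs)] | !obs$pass[-nrow(obs)])
  )
  runs <- obs %>%
    dplyr::mutate(run = run_id) %>%
    dplyr::filter(.data$pass) %>%
    dplyr::group_by(.data$run) %>%
    dplyr::summarise(
      chrom = .data$chrom[1L],
      peak_pos = (.data$start[which.max(.data$value)] + .data$end[which.max(.data$value)]) / 2,
      mean_mismatch = mean(.data$value),
      n_windows = dplyr::n(),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) %>%
    dplyr::arrange(
      dplyr::desc(.data$n_windows), dplyr::desc(.data$mean_mismatch),
      .data$chrom, .data$start
    )
  runs[1L, c("chrom", "start", "end", "peak_pos", "mean_mismatch", "n_windows")]
}

#' Classify the coding effect of single-nucleotide variants
#'
#' Assigns each variant one of `stop_gain`, `missense`, `synonymous`,
#' `splice_site`, `intronic`, `intergenic`. Codons are extracted
#' strand-aware from the spliced CDS of the overlapping feature; a variant
#' is `splice_site` when it lies in an intron within 2 bp of an exon-intron
#' junction. Positions without coding or intronic consequence (UTR exons,
#' non-coding TE bodies, and positions outside any feature) are reported as
#' `intergenic`.
#'
#' @param variants Variant tibble (`chrom`, `pos` 1-based, `ref`, `alt`).
#' @param features A [feature_model()].
#' @param sequence A `Biostrings::DNAStringSet` named by chromosome.
#' @return The variants tibble with added `feature_id` and `class` columns.
#' @export
classify_effects <- function(variants, features, sequence) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt"), "variants")
  spans <- tibble::tibble(
    feature_id = features$feature_id,
    chrom = features$chrom,
    start = vapply(features$exons, function(e) min(e$start), 0),
    end = vapply(features$exons, function(e) max(e$end), 0)
  )
  res <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    base <- as.character(Biostrings::subseq(sequence[[v$chrom]], v$pos, v$pos))
    if (base != v$ref) {
      stop_hetstab(sprintf(
        "Variant ref base %s at %s:%d disagrees with genome sequence (%s).",
        v$ref, v$chrom, as.integer(v$pos), base
      ))
    }
    p0 <- v$pos - 1 # 0-based
    hit <- which(spans$chrom == v$chrom & spans$start <= p0 & p0 < spans$end)
    if (length(hit) == 0L) {
      return(tibble::tibble(feature_id = NA_character_, class = "intergenic"))
    }
    f <- features[hit[1L], ]
    tibble::tibble(
      feature_id = f$feature_id,
      class = classify_one(p0, v$alt, f, sequence)
    )
  })
  dplyr::bind_cols(variants, res)
}

classify_one <- function(p0, alt, f, sequence) {
  ex <- f$exons[[1L]]
  cds <- f$cds[[1L]]
  in_exon <- any(ex$start <= p0 & p0 < ex$end)
  if (!in_exon) {
    # introns are the gaps between consecutive exons
    for (j in seq_len(nrow(ex) - 1L)) {
      i_start <- ex$end[j]
      i_end <- ex$start[j + 1L]
      if (p0 >= i_start && p0 < i_end) {
        near_junction <- (p0 - i_start < 2) || (i_end - p0 <= 2)
        return(if (near_junction) "splice_site" else "intronic")
      }
    }
    return("intergenic")
  }
  if (nrow(cds) == 0L || !any(cds$start <= p0 & p0 < cds$end)) {
    return("intergenic")
  }
  codon_effect(p0, alt, cds, f$strand, f$chrom, sequence)
}

codon_effect <- function(p0, alt, cds, strand, chrom, sequence) {
  widths <- cds$end - cds$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  k <- which(cds$start <= p0 & p0 < cds$end)
  spliced_pos <- offsets[k] + (p0 - cds$start[k]) # 0-based, genomic orientation
  cds_seq <- paste(vapply(seq_len(nrow(cds)), function(j) {
    as.character(Biostrings::subseq(sequence[[chrom]], cds$start[j] + 1, cds$end[j]))
  }, ""), collapse = "")
  total <- nchar(cds_seq)
  if (strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    spliced_pos <- total - 1 - spliced_pos
    alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  codon_idx <- spliced_pos %/% 3
  within <- spliced_pos %% 3
  ref_codon <- substr(cds_seq, codon_idx * 3 + 1, codon_idx * 3 + 3)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1, within + 1) <- alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (alt_aa == "*" && ref_aa != "*") {
    "stop_gain"
  } else if (alt_aa == ref_aa) {
    "synonymous"
  } else {
    "missense"
  }
}

#' Intron-retention ratio from per-base coverage
#'
#' Quantifies intron retention (e.g. caused by a splice-site lesion) as the
#' mean read coverage over an intron divided by the mean coverage over its
#' two flanking exons.
#'
#' @param coverage Tibble with `pos` (1-based) and `depth` over the locus;
#'   positions absent from the table count as zero coverage.
#' @param feature A single-row [feature_model()] slice.
#' @param intron Index of the intron (1 = between the first two exons).
#' @return One-row tibble with `intron_mean`, `exon_mean`, `ratio`, and
#'   `defined` (`FALSE` when the flanking exons have zero coverage, in which
#'   case `ratio` is `NA`).
#' @export
intron_retention_ratio <- function(coverage, feature, intron = 1L) {
  assert_columns(coverage, c("pos", "depth"), "coverage")
  ex <- feature$exons[[1L]]
  if (nrow(ex) < intron + 1L) {
    stop_hetstab(sprintf("Feature %s has no intron %d.", feature$feature_id, intron))
  }
  region_mean <- function(start, end) { # 0-based half-open
    width <- end - start
    sel <- (coverage$pos - 1) >= start & (coverage$pos - 1) < end
    sum(coverage$depth[sel]) / width
  }
  intron_mean <- region_mean(ex$end[intron], ex$start[intron + 1L])
  exon_mean <- (
    sum(coverage$depth[(coverage$pos - 1) >= ex$start[intron] & (coverage$pos - 1) < ex$end[intron]]) +
      sum(coverage$depth[(coverage$pos - 1) >= ex$start[intron + 1L] & (coverage$pos - 1) < ex$end[intron + 1L]])
  ) / ((ex$end[intron] - ex$start[intron]) + (ex$end[intron + 1L] - ex$start[intron + 1L]))
  defined <- exon_mean > 0
  if (!defined) {
    rlang::warn("Flanking exons have zero coverage; intron-retention ratio is undefined.")
  }
  tibble::tibble(
    intron_mean = intron_mean,
    exon_mean = exon_mean,
    ratio = if (defined) intron_mean / exon_mean else NA_real_,
    defined = defined
  )
}
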