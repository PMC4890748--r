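#' Haldane map function
#'
#' Converts a map distance in Morgans to a recombination fraction under the
#' Haldane (no-interference) model, `c(d) = (1 - exp(-2d)) / 2`.
#'
#' @param d Map distance in Morgans (vectorized, `d >= 0`).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(0)      # 0: complete linkage
#' haldane(0.1)    # ~0.0906
#' haldane(Inf)    # 0.5: free recombination
#' @export
haldane <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_hetstab("Map distance must be non-negative.")
  (1 - exp(-2 * d)) / 2
}

#' A miniature genome for desk-scale simulation
#'
#' Five chromosomes of 1 Mb each with one central 200 kb pericentromeric
#' interval per chromosome, mirroring the five-chromosome organisation of
#' the Arabidopsis genome at a size where whole-pipeline runs take seconds.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param peri_width Width of the central pericentromeric interval in bp.
#' @return A [genome_model()].
#' @export
miniature_genome <- function(n_chrom = 5, chrom_length = 1e6, peri_width = 2e5) {
  chroms <- tibble::tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = chrom_length
  )
  peri <- tibble::tibble(
    chrom = chroms$chrom,
    start = floor((chrom_length - peri_width) / 2),
    end = floor((chrom_length - peri_width) / 2) + peri_width
  )
  genome_model(chroms, peri)
}

#' Simulate a random reference sequence for a genome
#'
#' @param genome A [genome_model()].
#' @param seed Integer seed.
#' @param gc GC content of the random sequence.
#' @return A `Biostrings::DNAStringSet`, one entry per chromosome.
#' @export
simulate_sequence <- function(genome, seed = 1L, gc = 0.36) {
  stopifnot(inherits(genome, "genome_model"))
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(genome$chromosomes)), function(i) {
      len <- genome$chromosomes$length[i]
      paste(sample(
        c("A", "C", "G", "T"), len,
        replace = TRUE,
        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      ), collapse = "")
    }, "")
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genome$chromosomes$chrom
  out
}

#' Simulate an annotation of genes and transposable elements
#'
#' Features are placed non-overlapping along each chromosome with
#' exponential intergenic gaps. Genes receive 1-3 exons and a CDS (total
#' length a multiple of 3); transposable elements are single-exon,
#' non-coding. With the defaults the miniature genome holds ~3,000 features.
#'
#' @param genome A [genome_model()].
#' @param n Number of features to place.
#' @param te_fraction Fraction of features that are transposable elements.
#' @param seed Integer seed.
#' @return A [feature_model()].
#' @export
simulate_features <- function(genome, n = 3000, te_fraction = 0.4, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  total_bp <- sum(genome$chromosomes$length)
  withr::with_seed(seed, {
    # allocate features to chromosomes proportionally to length
    chrom_of <- sample(
      genome$chromosomes$chrom, n,
      replace = TRUE, prob = genome$chromosomes$length / total_bp
    )
    rows <- purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(ci) {
      chrom <- genome$chromosomes$chrom[ci]
      len <- genome$chromosomes$length[ci]
      k <- sum(chrom_of == chrom)
      if (k == 0L) {
        return(tibble::tibble())
      }
      widths <- pmax(150, round(stats::rlnorm(k, log(600), 0.5)))
      gap_mean <- max(50, (len - sum(widths)) / (k + 1))
      gaps <- pmax(20, round(stats::rexp(k, 1 / gap_mean)))
      starts <- cumsum(gaps) + cumsum(c(0, widths[-k]))
      keep <- starts + widths <= len
      is_te <- stats::runif(k) < te_fraction
      purrr::map_dfr(which(keep), function(j) {
        s <- starts[j]
        w <- widths[j]
        strand <- sample(c("+", "-"), 1L)
        if (is_te[j]) {
          ex <- tibble::tibble(start = s, end = s + w)
          cds <- tibble::tibble(start = numeric(), end = numeric())
        } else {
          n_ex <- sample(1:3, 1L)
          cuts <- sort(sample(seq(20, w - 20, by = 1), 2 * (n_ex - 1)))
          bounds <- matrix(c(0, cuts, w), ncol = 2, byrow = TRUE)
          ex <- tibble::tibble(start = s + bounds[, 1L], end = s + bounds[, 2L])
          # CDS: exons trimmed by a small UTR at each end, rounded to codons
          cds <- ex
          cds$start[1L] <- cds$start[1L] + min(10, cds$end[1L] - cds$start[1L] - 3)
          n_cds <- nrow(cds)
          cds$end[n_cds] <- cds$end[n_cds] - min(10, cds$end[n_cds] - cds$start[n_cds] - 3)
          excess <- sum(cds$end - cds$start) %% 3
          cds$end[n_cds] <- cds$end[n_cds] - excess
          cds <- cds[cds$end > cds$start, ]
        }
        tibble::tibble(
          chrom = chrom, strand = strand,
          class = ifelse(is_te[j], "TE", "gene"),
          exons = list(ex), cds = list(cds)
        )
      })
    })
  })
  rows$feature_id <- sprintf("F%05d", seq_len(nrow(rows)))
  feature_model(rows[, c("feature_id", "chrom", "strand", "class", "exons", "cds")])
}

#' Simulate pooled-bulk variant data from a recessive suppressor screen
#'
#' Models an F2-type bulk of plants selected for a recessive phenotype at a
#' single causal EMS lesion. Every chromosome of the bulk descends from an
#' independent gamete carrying the causal allele, so a planted EMS site at
#' map distance `d` Morgans from the causal site is co-inherited with
#' probability `1 - haldane(d)`; sites on other chromosomes segregate freely
#' at expected frequency 0.5. Read counts are binomial in the realized bulk
#' frequency; non-variant monitoring sites carry sequencing error only.
#' Planted variants are G>A / C>T, the canonical EMS transitions.
#'
#' @param genome A [genome_model()].
#' @param n_sites Number of planted EMS sites genome-wide.
#' @param bulk_n Number of plants in the selected bulk.
#' @param depth Mean sequencing depth per site (Poisson, floored at 1 read).
#' @param error Per-read sequencing error rate at monitoring sites.
#' @param r Recombination rate in Morgan/Mb (uniform along chromosomes).
#' @param n_monitor Number of non-variant monitoring sites.
#' @param causal Optional list `(chrom, pos)` fixing the causal site;
#'   by default one planted site is chosen uniformly at random.
#' @param selection If `FALSE`, no phenotypic selection is applied: every
#'   planted site (including the causal one) segregates at expected
#'   frequency 0.5. Used for mapping-specificity null simulations.
#' @param sequence Optional `DNAStringSet` reference; planted sites are then
#'   placed only on G/C bases so the written VCF is consistent with it.
#' @param seed Integer seed.
#' @return A list with `variants` (tibble as from [read_variants()]) and
#'   `truth` (list: `causal_chrom`, `causal_pos`, `r`, `bulk_n`, and a
#'   `sites` tibble with per-site map distance and expected frequency).
#' @export
simulate_bulk_variants <- function(genome, n_sites = 60, bulk_n = 50, depth = 30,
                                   error = 0.005, r = 0.04, n_monitor = 200,
                                   causal = NULL, selection = TRUE,
                                   sequence = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  assert_scalar_number(depth, "depth", lower = 1e-9)
  assert_scalar_number(error, "error", lower = 0, upper = 0.5)
  assert_scalar_number(bulk_n, "bulk_n", lower = 1)
  withr::with_seed(seed, {
    sites <- sample_positions(genome, n_sites, sequence, bases = c("G", "C"))
    if (is.null(causal)) {
      ci <- sample.int(n_sites, 1L)
    } else {
      ci <- which(sites$chrom == causal$chrom & sites$pos == causal$pos)
      if (length(ci) == 0L) {
        sites$chrom[1L] <- causal$chrom
        sites$pos[1L] <- causal$pos
        ci <- 1L
      }
    }
    causal_chrom <- sites$chrom[ci]
    causal_pos <- sites$pos[ci]
    d <- ifelse(
      sites$chrom == causal_chrom,
      abs(sites$pos - causal_pos) / 1e6 * r,
      Inf
    )
    f_exp <- if (selection) 1 - haldane(d) else rep(0.5, n_sites)
    # realized bulk frequency over 2n independently inherited chromosomes
    f_real <- stats::rbinom(n_sites, 2 * bulk_n, f_exp) / (2 * bulk_n)
    site_depth <- pmax(1L, stats::rpois(n_sites, depth))
    alt_reads <- stats::rbinom(n_sites, site_depth, f_real)
    ref_base <- if (is.null(sequence)) sample(c("G", "C"), n_sites, replace = TRUE) else sites$ref
    var_tbl <- tibble::tibble(
      chrom = sites$chrom, pos = sites$pos,
      ref = ref_base, alt = ifelse(ref_base == "G", "A", "T"),
      depth = as.numeric(site_depth), alt_count = as.numeric(alt_reads)
    )
    mon <- sample_positions(genome, n_monitor, sequence,
      bases = c("A", "C", "G", "T"),
      exclude = paste(sites$chrom, sites$pos)
    )
    mon_ref <- if (is.null(sequence)) sample(c("A", "C", "G", "T"), n_monitor, replace = TRUE) else mon$ref
    mon_alt <- vapply(mon_ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    mon_depth <- pmax(1L, stats::rpois(n_monitor, depth))
    mon_tbl <- tibble::tibble(
      chrom = mon$chrom, pos = mon$pos, ref = mon_ref, alt = unname(mon_alt),
      depth = as.numeric(mon_depth),
      alt_count = as.numeric(stats::rbinom(n_monitor, mon_depth, error))
    )
  })
  variants <- validate_variants(dplyr::bind_rows(var_tbl, mon_tbl), "simulated variants")
  truth <- list(
    causal_chrom = causal_chrom, causal_pos = causal_pos,
    r = r, bulk_n = bulk_n, selection = selection,
    sites = tibble::tibble(
      chrom = sites$chrom, pos = sites$pos, d_morgan = d,
      expected_f = f_exp, realized_f = f_real,
      is_causal = seq_len(n_sites) == ci
    )
  )
  list(variants = variants, truth = truth)
}

# Sample distinct 1-based genome positions; if a reference sequence is
# given, only positions whose base is in `bases` are eligible.
sample_positions <- function(genome, n, sequence = NULL, bases, exclude = character()) {
  total_bp <- sum(genome$chromosomes$length)
  offsets <- cumsum(c(0, genome$chromosomes$length[-nrow(genome$chromosomes)]))
  pick <- function(k) {
    lin <- sample.int(total_bp, min(k, total_bp))
    idx <- findInterval(lin - 1, offsets)
    tibble::tibble(
      chrom = genome$chromosomes$chrom[idx],
      pos = lin - offsets[idx] # 1-based within chromosome
    )
  }
  got <- tibble::tibble(chrom = character(), pos = numeric(), ref = character())
  tries <- 0L
  while (nrow(got) < n && tries < 50L) {
    cand <- pick(4L * n)
    cand <- cand[!paste(cand$chrom, cand$pos) %in% c(exclude, paste(got$chrom, got$pos)), ]
    if (!is.null(sequence)) {
      cand$ref <- vapply(seq_len(nrow(cand)), function(i) {
        as.character(Biostrings::subseq(sequence[[cand$chrom[i]]], cand$pos[i], cand$pos[i]))
      }, "")
      cand <- cand[cand$ref %in% bases, ]
    } else {
      cand$ref <- NA_character_
    }
    got <- dplyr::bind_rows(got, cand)
    got <- got[!duplicated(paste(got$chrom, got$pos)), ]
    tries <- tries + 1L
  }
  if (nrow(got) < n) {
    stop_hetstab("Could not place the requested number of variant positions.")
  }
  dplyr::arrange(got[seq_len(n), ], .data$chrom, .data$pos)
}

#' Simulate a replicated RNA-seq count table with planted up-regulation
#'
#' Baseline expression means are log-normal; counts are negative binomial
#' with gene-wise mean `s_j * mu_i * FC_i` (fold change applied in the
#' mutant group only) and common dispersion `dispersion`.
#'
#' @param features A [feature_model()] supplying feature ids and lengths.
#' @param n_up Number of planted up-regulated features.
#' @param fc Planted fold change (> 1) for up-regulated features.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param reps Replicates per group.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   means.
#' @param seed Integer seed.
#' @return List with `counts` (long tibble), `samples` (tibble with
#'   `sample`, `group`, `library_size`), and `truth` (tibble `feature_id`,
#'   `fc`).
#' @export
simulate_counts <- function(features, n_up = 100, fc = 4, dispersion = 0.1,
                            reps = 2, baseline_meanlog = log(100),
                            baseline_sdlog = 1.2, seed = 1L) {
  if (reps < 1) stop_hetstab("`reps` must be at least 1.")
  if (fc <= 1 && n_up > 0) stop_hetstab("Planted fold change must exceed 1.")
  assert_scalar_number(dispersion, "dispersion", lower = 1e-12)
  ids <- features$feature_id
  n <- length(ids)
  if (n_up > n) stop_hetstab("More planted features than features available.")
  samples <- tibble::tibble(
    sample = c(paste0("control_", seq_len(reps)), paste0("mutant_", seq_len(reps))),
    group = rep(c("control", "mutant"), each = reps)
  )
  withr::with_seed(seed, {
    mu <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    up <- sample.int(n, n_up)
    fc_i <- rep(1, n)
    fc_i[up] <- fc
    s_j <- stats::rlnorm(nrow(samples), 0, 0.1)
    counts <- purrr::map_dfr(seq_len(nrow(samples)), function(j) {
      m <- mu * s_j[j] * (if (samples$group[j] == "mutant") fc_i else rep(1, n))
      tibble::tibble(
        feature_id = ids, sample = samples$sample[j],
        count = stats::rnbinom(n, mu = m, size = 1 / dispersion)
      )
    })
  })
  totals <- counts %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  samples <- samples %>%
    dplyr::left_join(totals, by = "sample") %>%
    dplyr::mutate(library_size = ceiling(.data$total * 1.25)) %>%
    dplyr::select("sample", "group", "library_size")
  list(
    counts = counts, samples = samples,
    truth = tibble::tibble(feature_id = ids, fc = fc_i)
  )
}

#' Simulate binned read-depth tracks with a planted pericentromeric gain
#'
#' Control bins are Poisson with mean `lambda`; mutant bins are Poisson with
#' mean `lambda * gain` inside pericentromeric intervals and `lambda`
#' elsewhere.
#'
#' @param genome A [genome_model()].
#' @param bin_size Bin width bp.
#' @param lambda Mean reads per bin.
#' @param gain Planted copy-number gain factor (`>= 1`) over the
#'   pericentromere.
#' @param seed Integer seed.
#' @return List with `control` and `mutant` binned count tracks and `truth`.
#' @export
simulate_bins <- function(genome, bin_size = 1e4, lambda = 200, gain = 2, seed = 1L) {
  assert_scalar_number(lambda, "lambda", lower = 1e-9)
  assert_scalar_number(gain, "gain", lower = 1)
  bins <- genome_bins(genome, bin_size)
  mid <- (bins$start + bins$end) / 2
  peri <- in_pericentromere(genome, bins$chrom, mid)
  withr::with_seed(seed, {
    ctrl <- stats::rpois(nrow(bins), lambda)
    mut <- stats::rpois(nrow(bins), lambda * ifelse(peri, gain, 1))
  })
  list(
    control = new_binned_track(dplyr::mutate(bins, value = as.numeric(ctrl), masked = FALSE)),
    mutant = new_binned_track(dplyr::mutate(bins, value = as.numeric(mut), masked = FALSE)),
    truth = list(gain = gain, lambda = lambda, bin_size = bin_size, pericentromeric = peri)
  )
}

#' Simulate a pair of bisulfite cytosine reports with planted DMRs
#'
#' Cytosine positions are laid down per context with exponential spacing;
#' per-site coverage is Poisson and methylated counts are binomial in the
#' context base level. In the mutant file the base level is shifted by
#' `dmr_delta` inside the planted DMR intervals (for the DMR context only);
#' shifted levels outside `[0, 1]` are clipped with a warning.
#'
#' @param genome A [genome_model()].
#' @param base_levels Named vector of per-context methylation levels.
#' @param spacing Named vector of mean bp between consecutive cytosines of
#'   each context (both strands pooled; the defaults approximate motif
#'   densities at ~36% GC, with CHH thinned for desk scale).
#' @param coverage Mean per-site read coverage (Poisson).
#' @param n_dmrs Number of planted DMRs.
#' @param dmr_context Sequence context of the planted DMRs.
#' @param dmr_delta Methylation-level shift planted in the mutant (signed).
#' @param dmr_width Width of each planted DMR in bp.
#' @param seed Integer seed.
#' @return List with `control` and `mutant` cytosine record tibbles and a
#'   `truth` tibble of planted DMR intervals.
#' @export
simulate_methylome <- function(genome,
                               base_levels = c(CG = 0.8, CHG = 0.3, CHH = 0.1),
                               spacing = c(CG = 15, CHG = 20, CHH = 15),
                               coverage = 15, n_dmrs = 10, dmr_context = "CG",
                               dmr_delta = -0.5, dmr_width = 300, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  assert_scalar_number(coverage, "coverage", lower = 1e-9)
  withr::with_seed(seed, {
    sites <- purrr::map_dfr(names(base_levels), function(ctx) {
      purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(ci) {
        len <- genome$chromosomes$length[ci]
        n_exp <- ceiling(len / spacing[[ctx]] * 1.3) + 20L
        pos <- cumsum(pmax(1, round(stats::rexp(n_exp, 1 / spacing[[ctx]]))))
        pos <- pos[pos <= len]
        tibble::tibble(
          chrom = genome$chromosomes$chrom[ci],
          pos = pos, strand = "+", context = ctx
        )
      })
    })
    chrom_idx <- match(sites$chrom, genome$chromosomes$chrom)
    ord <- order(chrom_idx, sites$pos)
    sites <- sites[ord, ]
    chrom_idx <- chrom_idx[ord]
    # plant DMR intervals away from chromosome ends, non-overlapping
    dmrs <- plant_intervals(genome, n_dmrs, dmr_width)
    dmrs$context <- dmr_context
    dmrs$delta <- dmr_delta
    p0 <- unname(base_levels)[match(sites$context, names(base_levels))]
    dmr_chrom_idx <- match(dmrs$chrom, genome$chromosomes$chrom)
    ctx_idx <- which(sites$context == dmr_context)
    ctx_chrom <- chrom_idx[ctx_idx]
    ctx_pos <- sites$pos[ctx_idx]
    hit <- rep(FALSE, length(ctx_idx))
    for (i in seq_len(nrow(dmrs))) {
      hit <- hit | (ctx_chrom == dmr_chrom_idx[i] &
        ctx_pos > dmrs$start[i] & ctx_pos <= dmrs$end[i])
    }
    in_dmr <- rep(FALSE, nrow(sites))
    in_dmr[ctx_idx[hit]] <- TRUE
    p1 <- p0 + ifelse(in_dmr, dmr_delta, 0)
    if (any(p1 < 0 | p1 > 1)) {
      rlang::warn("Shifted methylation level outside [0, 1]; clipping.")
      p1 <- pmin(1, pmax(0, p1))
    }
    draw <- function(p) {
      cov <- stats::rpois(nrow(sites), coverage)
      meth <- stats::rbinom(nrow(sites), cov, p)
      tibble::tibble(
        chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
        context = sites$context,
        meth_count = as.numeric(meth),
        total_count = as.numeric(cov),
        covered = cov > 0
      )
    }
    control <- draw(p0)
    mutant <- draw(p1)
  })
  list(control = control, mutant = mutant, truth = tibble::as_tibble(dmrs))
}

plant_intervals <- function(genome, n, width, margin = 5e3) {
  placed <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  guard <- 0L
  while (nrow(placed) < n && guard < 1000L) {
    ci <- sample.int(nrow(genome$chromosomes), 1L)
    len <- genome$chromosomes$length[ci]
    s <- floor(stats::runif(1, margin, len - margin - width))
    cand <- tibble::tibble(chrom = genome$chromosomes$chrom[ci], start = s, end = s + width)
    clash <- placed$chrom == cand$chrom &
      placed$start < cand$end + width & cand$start < placed$end + width
    if (!any(clash)) placed <- dplyr::bind_rows(placed, cand)
    guard <- guard + 1L
  }
  if (nrow(placed) < n) stop_hetstab("Could not place non-overlapping DMR intervals.")
  dplyr::arrange(placed, .data$chrom, .data$start)
}

#' Simulate a pair of flow-cytometry ploidy histograms
#'
#' Nuclei intensities are drawn from a mixture of Gaussians centred at
#' doubling ploidy peaks `mu * 2^k`, `k = 0..K-1` (2C, 4C, 8C, 16C), each
#' with coefficient of variation `cv`. In the mutant histogram the standard
#' deviation of the highest peak (16C) is multiplied by `beta`, emulating
#' the peak broadening produced by heterochromatic over-replication.
#'
#' @param mu Base (2C) peak mean intensity, arbitrary units.
#' @param weights Mixture weights per peak (normalized with a warning if
#'   they do not sum to 1).
#' @param cv Per-peak coefficient of variation `sigma_k / (mu * 2^k)`.
#' @param beta Broadening factor (`>= 1`) applied to the top peak of the
#'   mutant sample.
#' @param n_nuclei Nuclei per sample.
#' @param bin_width Histogram bin width, same units as `mu`.
#' @param seed Integer seed.
#' @return List with `control` and `mutant` histogram tibbles and `truth`.
#' @export
simulate_flow <- function(mu = 50, weights = c(0.3, 0.3, 0.25, 0.15), cv = 0.05,
                          beta = 1.6, n_nuclei = 20000, bin_width = 1, seed = 1L) {
  assert_scalar_number(mu, "mu", lower = 1e-9)
  assert_scalar_number(beta, "beta", lower = 1)
  if (abs(sum(weights) - 1) > 1e-8) {
    rlang::warn("Mixture weights do not sum to 1; normalizing.")
    weights <- weights / sum(weights)
  }
  K <- length(weights)
  peak_means <- mu * 2^(seq_len(K) - 1)
  top <- max(peak_means) * (1 + 8 * cv * beta)
  edges <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  withr::with_seed(seed, {
    draw <- function(broaden) {
      k <- sample.int(K, n_nuclei, replace = TRUE, prob = weights)
      sd_k <- cv * peak_means * ifelse(seq_len(K) == K, broaden, 1)
      x <- stats::rnorm(n_nuclei, peak_means[k], sd_k[k])
      x <- x[x > 0 & x < max(edges)]
      cnt <- tabulate(findInterval(x, edges), nbins = length(edges) - 1L)
      tibble::tibble(
        lower = edges[-length(edges)], upper = edges[-1L],
        count = as.numeric(cnt)
      )
    }
    control <- draw(1)
    mutant <- draw(beta)
  })
  list(
    control = control, mutant = mutant,
    truth = list(mu = mu, weights = weights, cv = cv, beta = beta)
  )
}
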