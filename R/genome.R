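#' Construct a genome model
#'
#' A genome model is the shared coordinate frame for every track in the
#' package: an ordered set of chromosomes with lengths, plus the
#' pericentromeric heterochromatin intervals on which the over-replication
#' phenotype is read out. All intervals are 0-based half-open.
#'
#' @param chromosomes Data frame with columns `chrom` (character) and
#'   `length` (positive integer bp), in the desired chromosome order.
#' @param pericentromere Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). May have zero rows.
#' @return A `genome_model` object (list of two tibbles).
#' @examples
#' genome_model(
#'   data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 1e6)),
#'   data.frame(chrom = "chr1", start = 4e5, end = 6e5)
#' )
#' @export
genome_model <- function(chromosomes, pericentromere = NULL) {
  assert_columns(chromosomes, c("chrom", "length"), "chromosomes")
  chromosomes <- tibble::as_tibble(chromosomes)[, c("chrom", "length")]
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom)) {
    stop_hetstab("Duplicate chromosome names in genome model.")
  }
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0)) {
    stop_hetstab("All chromosome lengths must be positive.")
  }
  if (is.null(pericentromere) || nrow(pericentromere) == 0L) {
    pericentromere <- tibble::tibble(
      chrom = character(), start = numeric(), end = numeric()
    )
  } else {
    assert_columns(pericentromere, c("chrom", "start", "end"), "pericentromere")
    pericentromere <- tibble::as_tibble(pericentromere)[, c("chrom", "start", "end")]
    pericentromere$chrom <- as.character(pericentromere$chrom)
    pericentromere <- dplyr::arrange(
      pericentromere,
      match(.data$chrom, chromosomes$chrom), .data$start
    )
    bad_chrom <- setdiff(pericentromere$chrom, chromosomes$chrom)
    if (length(bad_chrom) > 0L) {
      stop_hetstab(sprintf(
        "Pericentromeric interval on unknown chromosome(s): %s.",
        paste(bad_chrom, collapse = ", ")
      ))
    }
    lens <- chromosomes$length[match(pericentromere$chrom, chromosomes$chrom)]
    if (any(pericentromere$start < 0) || any(pericentromere$end > lens) ||
        any(pericentromere$start >= pericentromere$end)) {
      stop_hetstab("Pericentromeric intervals must satisfy 0 <= start < end <= chromosome length.")
    }
    overlaps <- pericentromere %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::summarise(
        bad = dplyr::n() > 1L && any(.data$start[-1L] < .data$end[-dplyr::n()]),
        .groups = "drop"
      )
    if (any(overlaps$bad)) {
      stop_hetstab("Pericentromeric intervals overlap within a chromosome.")
    }
  }
  structure(
    list(chromosomes = chromosomes, pericentromere = pericentromere),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosome(s), %.3g Mb total, %d pericentromeric interval(s)\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, nrow(x$pericentromere)
  ))
  invisible(x)
}

#' Read a genome model from chromosome-sizes and pericentromere files
#'
#' @param sizes_path Two-column TSV (no header): chromosome name, length bp.
#' @param pericentromere_path Optional BED file (0-based half-open) of
#'   pericentromeric intervals; `NULL` or an empty file yields a model with
#'   zero intervals.
#' @return A [genome_model()].
#' @export
read_genome <- function(sizes_path, pericentromere_path = NULL) {
  sizes <- parse_tsv_checked(
    sizes_path, c("chrom", "length"),
    types = c("character", "numeric"), what = "chromosome sizes"
  )
  peri <- NULL
  if (!is.null(pericentromere_path)) {
    peri <- parse_tsv_checked(
      pericentromere_path, c("chrom", "start", "end"),
      types = c("character", "numeric", "numeric"), what = "pericentromere BED",
      allow_empty = TRUE
    )
  }
  g <- genome_model(sizes, peri)
  log_info(
    "read_genome: %d chromosomes, %d pericentromeric intervals from %s",
    nrow(g$chromosomes), nrow(g$pericentromere), sizes_path
  )
  g
}

#' Write a genome model to chromosome-sizes and pericentromere files
#'
#' @param genome A [genome_model()].
#' @param sizes_path,pericentromere_path Output paths.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, sizes_path, pericentromere_path) {
  stopifnot(inherits(genome, "genome_model"))
  readr::write_tsv(genome$chromosomes, sizes_path, col_names = FALSE)
  peri <- genome$pericentromere
  peri$start <- sprintf("%d", as.integer(peri$start))
  peri$end <- sprintf("%d", as.integer(peri$end))
  readr::write_tsv(peri, pericentromere_path, col_names = FALSE)
  invisible(genome)
}

# Headerless TSV parser with per-line diagnostics; used for the simple
# BED-like inputs where a malformed line must be reported by number.
parse_tsv_checked <- function(path, cols, types, what, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop_hetstab(sprintf("File not found: %s", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    if (allow_empty) {
      out <- lapply(seq_along(cols), function(i) vector(types[i], 0L))
      names(out) <- cols
      return(tibble::as_tibble(out))
    }
    stop_hetstab(sprintf("Empty %s file: %s", what, path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- which(vapply(fields, length, 1L) < length(cols))
  if (length(n_bad) > 0L) {
    stop_hetstab(sprintf(
      "Malformed %s line %d in %s: expected %d tab-separated fields.",
      what, n_bad[1L], path, length(cols)
    ))
  }
  out <- lapply(seq_along(cols), function(i) {
    raw <- vapply(fields, `[[`, "", i)
    if (types[i] == "numeric") {
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val)) {
        stop_hetstab(sprintf(
          "Malformed %s line %d in %s: field %d ('%s') is not numeric.",
          what, which(is.na(val))[1L], path, i, raw[which(is.na(val))[1L]]
        ))
      }
      val
    } else {
      raw
    }
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Tile a genome into fixed-width bins
#'
#' @param genome A [genome_model()].
#' @param bin_size Bin width in bp; the last bin of each chromosome is
#'   truncated at the chromosome end.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), in
#'   genome order.
#' @export
genome_bins <- function(genome, bin_size) {
  stopifnot(inherits(genome, "genome_model"))
  assert_scalar_number(bin_size, "bin_size", lower = 1)
  purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(
      chrom = genome$chromosomes$chrom[i],
      start = starts,
      end = pmin(starts + bin_size, len)
    )
  })
}

#' Classify genome positions as pericentromeric or arm
#'
#' @param genome A [genome_model()].
#' @param chrom,pos Parallel vectors of chromosome names and positions
#'   (0-based bp, e.g. bin midpoints).
#' @return Logical vector: `TRUE` where the position lies inside a
#'   pericentromeric interval.
#' @export
in_pericentromere <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "genome_model"))
  peri <- genome$pericentromere
  if (nrow(peri) == 0L) {
    return(rep(FALSE, length(chrom)))
  }
  out <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(peri))) {
    out <- out | (chrom == peri$chrom[i] & pos >= peri$start[i] & pos < peri$end[i])
  }
  out
}

#' Genome-fraction of each chromosome and of the pericentromere
#'
#' @param genome A [genome_model()].
#' @return Tibble with `chrom`, `length`, `bp_fraction`,
#'   `pericentromere_fraction` (fraction of the chromosome that is
#'   pericentromeric).
#' @export
genome_fractions <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  peri_bp <- genome$pericentromere %>%
    dplyr::mutate(width = .data$end - .data$start) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(peri_bp = sum(.data$width), .groups = "drop")
  genome$chromosomes %>%
    dplyr::left_join(peri_bp, by = "chrom") %>%
    dplyr::mutate(
      peri_bp = dplyr::coalesce(.data$peri_bp, 0),
      bp_fraction = .data$length / sum(.data$length),
      pericentromere_fraction = .data$peri_bp / .data$length
    ) %>%
    dplyr::select("chrom", "length", "bp_fraction", "pericentromere_fraction")
}
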