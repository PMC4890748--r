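#' Read variant sites from a minimal VCF or a tab-separated table
#'
#' Variant sites carry the per-site evidence used for bulked-segregant
#' mapping: read depth and alternate-read count in the selected pool, from
#' which the mismatch fraction (bulk allele frequency estimate) is computed.
#' VCF input must provide `DP` (depth) and `AD` (alternate reads) INFO keys;
#' TSV input must have columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#' `alt_count` with a header. Positions are 1-based on disk and kept 1-based
#' in the `pos` column (single positions, not intervals).
#'
#' @param path Input file; format detected from the first line.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `mismatch_fraction`, sorted by (chrom, pos).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) {
    stop_hetstab(sprintf("File not found: %s", path))
  }
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) == 1L && startsWith(first, "##")) {
    df <- parse_vcf_minimal(path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    assert_columns(df, c("chrom", "pos", "ref", "alt", "depth", "alt_count"), path)
  }
  validate_variants(df, path)
}

parse_vcf_minimal <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), depth = numeric(), alt_count = numeric()
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 8L)
  if (length(bad) > 0L) {
    stop_hetstab(sprintf(
      "Malformed VCF record line %d in %s: fewer than 8 fields.",
      which(!startsWith(lines, "#") & nzchar(lines))[bad[1L]], path
    ))
  }
  info <- vapply(fields, `[[`, "", 8L)
  get_info <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([0-9]+)"))[, 2L]
    if (anyNA(m)) {
      stop_hetstab(sprintf("VCF record missing INFO key %s in %s.", key, path))
    }
    as.numeric(m)
  }
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = as.numeric(vapply(fields, `[[`, "", 2L)),
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    depth = get_info("DP"),
    alt_count = get_info("AD")
  )
}

validate_variants <- function(df, what = "variants") {
  df <- tibble::as_tibble(df)
  if (nrow(df) > 0L) {
    if (any(df$alt_count > df$depth) || any(df$alt_count < 0) || any(df$depth < 0)) {
      stop_hetstab(sprintf("%s: alt_count must satisfy 0 <= alt_count <= depth.", what))
    }
    if (any(df$ref == df$alt)) {
      stop_hetstab(sprintf("%s: ref and alt base must differ.", what))
    }
    key <- paste(df$chrom, df$pos)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop_hetstab(sprintf("%s: duplicate variant position %s.", what, dup))
    }
  }
  df %>%
    dplyr::mutate(mismatch_fraction = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_)) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write variant sites as a minimal VCF
#'
#' @param variants Tibble as returned by [read_variants()].
#' @param path Output path.
#' @return Invisibly, `variants`.
#' @export
write_variants <- function(variants, path) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt", "depth", "alt_count"), "variants")
  variants <- dplyr::arrange(variants, .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate read count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AD=%d",
    variants$chrom, as.integer(variants$pos), variants$ref, variants$alt,
    as.integer(variants$depth), as.integer(variants$alt_count)
  )
  readr::write_lines(c(header, body), path)
  invisible(variants)
}

#' Read a cytosine methylation report
#'
#' Expects the Bismark-style cytosine report layout: chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context
#' (CG/CHG/CHH), trinucleotide. Zero-coverage cytosines are retained and
#' flagged by `covered = FALSE`.
#'
#' @param path Input TSV (no header).
#' @return Tibble with `chrom`, `pos`, `strand`, `context`, `meth_count`,
#'   `total_count`, `covered`, sorted by (chrom, pos).
#' @export
read_cytosine_report <- function(path) {
  df <- parse_tsv_checked(
    path,
    c("chrom", "pos", "strand", "meth_count", "unmeth_count", "context", "tri"),
    types = c("character", "numeric", "character", "numeric", "numeric", "character", "character"),
    what = "cytosine report"
  )
  bad <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(bad) > 0L) {
    stop_hetstab(sprintf(
      "Unknown context token '%s' at cytosine report line %d in %s.",
      df$context[bad[1L]], bad[1L], path
    ))
  }
  out <- df %>%
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos, strand = .data$strand,
      context = .data$context, meth_count = .data$meth_count,
      total_count = .data$meth_count + .data$unmeth_count,
      covered = .data$meth_count + .data$unmeth_count > 0
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  if (any(out$meth_count < 0) || any(out$meth_count > out$total_count)) {
    stop_hetstab(sprintf("Negative count in cytosine report %s.", path))
  }
  log_info("read_cytosine_report: %d records from %s", nrow(out), path)
  out
}

#' Write a cytosine methylation report
#'
#' @param records Tibble with `chrom`, `pos`, `strand`, `context`,
#'   `meth_count`, `total_count`.
#' @param path Output path.
#' @return Invisibly, `records`.
#' @export
write_cytosine_report <- function(records, path) {
  assert_columns(records, c("chrom", "pos", "strand", "context", "meth_count", "total_count"), "records")
  records <- dplyr::arrange(records, .data$chrom, .data$pos)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s",
    records$chrom, as.integer(records$pos), records$strand,
    as.integer(records$meth_count),
    as.integer(records$total_count - records$meth_count),
    records$context, records$context
  )
  readr::write_lines(lines, path)
  invisible(records)
}

#' Read / write a binned genome track
#'
#' Tracks are BED-graph-style TSVs with a header: `chrom`, `start`, `end`
#' (0-based half-open) and `value`, where masked bins (low coverage) are
#' written as `NA`.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `value`, `masked`.
#' @export
read_track <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), value = readr::col_double()
    ),
    progress = FALSE, na = "NA"
  )
  assert_columns(df, c("chrom", "start", "end", "value"), path)
  df$masked <- is.na(df$value)
  new_binned_track(df)
}

#' @rdname read_track
#' @param track A binned track tibble.
#' @export
write_track <- function(track, path) {
  assert_columns(track, c("chrom", "start", "end", "value"), "track")
  out <- tibble::tibble(
    chrom = track$chrom,
    start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    value = ifelse(
      is.na(track$value) | isTRUE_vec(track$masked),
      "NA", format(track$value, scientific = FALSE, trim = TRUE, digits = 10)
    )
  )
  readr::write_tsv(out, path)
  invisible(track)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) FALSE else !is.na(x) & x
}

new_binned_track <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"masked" %in% names(df)) df$masked <- is.na(df$value)
  df$value[df$masked] <- NA_real_
  class(df) <- c("binned_track", class(df))
  df
}

#' Read / write a feature count table
#'
#' Count tables are wide TSVs: a `feature_id` column plus one integer column
#' per sample. Library sizes (total mapped reads per sample) travel in a
#' companion samples TSV with columns `sample`, `group`, `library_size`.
#'
#' @param counts_path,samples_path File paths.
#' @return A list with `counts` (long tibble: `feature_id`, `sample`,
#'   `count`) and `samples` (tibble).
#' @export
read_counts <- function(counts_path, samples_path) {
  wide <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  assert_columns(wide, "feature_id", counts_path)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  assert_columns(samples, c("sample", "group", "library_size"), samples_path)
  counts <- tidyr::pivot_longer(
    wide, -"feature_id",
    names_to = "sample", values_to = "count"
  )
  if (any(counts$count < 0)) {
    stop_hetstab(sprintf("Negative count in %s.", counts_path))
  }
  missing <- setdiff(unique(counts$sample), samples$sample)
  if (length(missing) > 0L) {
    stop_hetstab(sprintf(
      "Sample column(s) %s missing from %s.",
      paste(missing, collapse = ", "), samples_path
    ))
  }
  assigned <- counts %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop") %>%
    dplyr::left_join(samples, by = "sample")
  if (any(assigned$library_size < assigned$total)) {
    stop_hetstab("Library size smaller than the column sum of assigned counts.")
  }
  list(counts = counts, samples = tibble::as_tibble(samples))
}

#' @rdname read_counts
#' @param counts Long counts tibble (`feature_id`, `sample`, `count`).
#' @param samples Samples tibble (`sample`, `group`, `library_size`).
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  wide <- tidyr::pivot_wider(
    counts,
    id_cols = "feature_id", names_from = "sample", values_from = "count"
  )
  readr::write_tsv(wide, counts_path)
  readr::write_tsv(samples, samples_path)
  invisible(counts)
}

#' Read / write a flow-cytometry intensity histogram
#'
#' Histograms are TSVs with columns `lower`, `upper` (bin edges, arbitrary
#' intensity units, strictly increasing) and `count` (nuclei per bin).
#'
#' @param path File path.
#' @return Tibble with `lower`, `upper`, `count`.
#' @export
read_histogram <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      lower = readr::col_double(), upper = readr::col_double(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  assert_columns(df, c("lower", "upper", "count"), path)
  validate_histogram(df)
}

validate_histogram <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$count < 0)) stop_hetstab("Histogram counts must be non-negative.")
  if (any(df$upper <= df$lower) || (nrow(df) > 1L && any(diff(df$lower) <= 0))) {
    stop_hetstab("Histogram bin edges must be strictly increasing.")
  }
  df
}

#' @rdname read_histogram
#' @param hist Histogram tibble.
#' @export
write_histogram <- function(hist, path) {
  assert_columns(hist, c("lower", "upper", "count"), "hist")
  readr::write_tsv(hist[, c("lower", "upper", "count")], path)
  invisible(hist)
}
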