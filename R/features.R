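#' Construct a feature model table
#'
#' Features are the annotation units of the expression and variant-effect
#' stages: protein-coding genes and transposable elements. Each row carries
#' its exon (and, for genes, CDS) intervals as nested tibbles in 0-based
#' half-open coordinates.
#'
#' @param df Data frame with columns `feature_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `class` (`"gene"` or `"TE"`), and list-columns `exons`
#'   and `cds`, each holding a tibble with `start`, `end` per feature
#'   (`cds` entries may be zero-row for non-coding features).
#' @return A validated `feature_model` tibble.
#' @export
feature_model <- function(df) {
  assert_columns(df, c("feature_id", "chrom", "strand", "class", "exons", "cds"), "features")
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$feature_id)) {
    stop_hetstab("Duplicate feature_id in feature model.")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop_hetstab("Feature strand must be '+' or '-'.")
  }
  if (!all(df$class %in% c("gene", "TE"))) {
    stop_hetstab("Feature class must be 'gene' or 'TE'.")
  }
  for (i in seq_len(nrow(df))) {
    ex <- normalize_intervals(df$exons[[i]], df$feature_id[i], "exons")
    cds <- normalize_intervals(df$cds[[i]], df$feature_id[i], "cds")
    if (nrow(cds) > 0L) {
      if (!intervals_contained(cds, ex)) {
        stop_hetstab(sprintf("CDS of %s not contained in its exons.", df$feature_id[i]))
      }
      if (sum(cds$end - cds$start) %% 3 != 0) {
        stop_hetstab(sprintf("CDS length of %s is not a multiple of 3.", df$feature_id[i]))
      }
    }
    df$exons[[i]] <- ex
    df$cds[[i]] <- cds
  }
  class(df) <- c("feature_model", class(df))
  df
}

normalize_intervals <- function(iv, id, what) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  assert_columns(iv, c("start", "end"), paste(id, what))
  iv <- dplyr::arrange(tibble::as_tibble(iv)[, c("start", "end")], .data$start)
  if (any(iv$end <= iv$start)) {
    stop_hetstab(sprintf("%s of %s has an empty or inverted interval.", what, id))
  }
  if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
    stop_hetstab(sprintf("%s of %s overlap.", what, id))
  }
  iv
}

# Every [start, end) of `inner` lies inside some interval of `outer`.
intervals_contained <- function(inner, outer) {
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer$start <= inner$start[i] & inner$end[i] <= outer$end)
  }, TRUE))
}

#' Exonic length of each feature
#'
#' @param features A [feature_model()].
#' @return Tibble with `feature_id` and `length` (summed exon bp).
#' @export
feature_lengths <- function(features) {
  tibble::tibble(
    feature_id = features$feature_id,
    length = vapply(features$exons, function(ex) sum(ex$end - ex$start), 0)
  )
}

#' Read a feature model from GFF3
#'
#' Genes are rows of type `gene` (with `exon`/`CDS` children, possibly via
#' an `mRNA` level); transposable elements are rows of type
#' `transposable_element`. For multi-isoform genes the isoform with the
#' longest total CDS is kept. GFF3 is 1-based inclusive on disk and
#' converted to 0-based half-open internally.
#'
#' @param path GFF3 file.
#' @return A [feature_model()].
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gr$Parent)) as.list(gr$Parent) else rep(list(character()), length(gr)),
      function(p) if (length(p) > 0L) p[[1L]] else NA_character_, ""
    )
  )
  tops <- df %>% dplyr::filter(.data$type %in% c("gene", "transposable_element"))
  mrna <- df %>% dplyr::filter(.data$type == "mRNA")
  parent_of_mrna <- stats::setNames(mrna$parent, mrna$id)
  kids <- df %>%
    dplyr::filter(.data$type %in% c("exon", "CDS")) %>%
    dplyr::mutate(
      feature = ifelse(.data$parent %in% names(parent_of_mrna),
        unname(parent_of_mrna[.data$parent]), .data$parent
      ),
      isoform = ifelse(.data$parent %in% names(parent_of_mrna), .data$parent, .data$feature)
    )
  rows <- purrr::map(seq_len(nrow(tops)), function(i) {
    fid <- tops$id[i]
    fk <- kids %>% dplyr::filter(.data$feature == fid)
    # multi-isoform: keep the isoform with the longest total CDS
    if (dplyr::n_distinct(fk$isoform) > 1L) {
      best <- fk %>%
        dplyr::group_by(.data$isoform) %>%
        dplyr::summarise(
          cds_len = sum((.data$end - .data$start)[.data$type == "CDS"]),
          .groups = "drop"
        ) %>%
        dplyr::arrange(dplyr::desc(.data$cds_len), .data$isoform) %>%
        dplyr::slice(1L)
      fk <- fk %>% dplyr::filter(.data$isoform == best$isoform)
    }
    ex <- fk %>% dplyr::filter(.data$type == "exon") %>% dplyr::select("start", "end")
    cds <- fk %>% dplyr::filter(.data$type == "CDS") %>% dplyr::select("start", "end")
    if (nrow(ex) == 0L) {
      ex <- tibble::tibble(start = tops$start[i], end = tops$end[i])
    }
    tibble::tibble(
      feature_id = fid, chrom = tops$chrom[i], strand = tops$strand[i],
      class = ifelse(tops$type[i] == "gene", "gene", "TE"),
      exons = list(ex), cds = list(cds)
    )
  })
  out <- feature_model(dplyr::bind_rows(rows))
  log_info("read_features: %d features from %s", nrow(out), path)
  out
}

#' Write a feature model as GFF3
#'
#' @param features A [feature_model()].
#' @param path Output path.
#' @return Invisibly, `features`.
#' @export
write_features <- function(features, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    ex <- f$exons[[1L]]
    cds <- f$cds[[1L]]
    type <- ifelse(f$class == "gene", "gene", "transposable_element")
    span <- c(min(ex$start), max(ex$end))
    lines <- c(lines, sprintf(
      "%s\thetstab\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      f$chrom, type, as.integer(span[1L] + 1), as.integer(span[2L]), f$strand, f$feature_id
    ))
    lines <- c(lines, sprintf(
      "%s\thetstab\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      f$chrom, as.integer(ex$start + 1), as.integer(ex$end), f$strand, f$feature_id
    ))
    if (nrow(cds) > 0L) {
      lines <- c(lines, sprintf(
        "%s\thetstab\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
        f$chrom, as.integer(cds$start + 1), as.integer(cds$end), f$strand, f$feature_id
      ))
    }
  }
  readr::write_lines(lines, path)
  invisible(features)
}
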