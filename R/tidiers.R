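#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ploidy mixture fit
#'
#' One row per ploidy peak with its mean, weight, standard deviation and
#' coefficient of variation.
#'
#' @param x A `ploidy_fit`.
#' @param ... Unused.
#' @return A tibble with `peak`, `k`, `mean`, `weight`, `sd`, `cv`.
#' @export
tidy.ploidy_fit <- function(x, ...) {
  tibble::tibble(
    peak = paste0(2^(0:(x$K - 1)) * 2, "C"),
    k = 0:(x$K - 1),
    mean = x$peak_means,
    weight = x$weights,
    sd = x$sigma,
    cv = x$cv
  )
}

#' @rdname tidy.ploidy_fit
#' @export
glance.ploidy_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, K = x$K, loglik = x$loglik,
    n_iter = x$n_iter, converged = x$converged, nobs = x$n
  )
}

#' Tidy a pericentromeric enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble with `score`, `p_value`, `n_perm`, `n_peri`,
#'   `n_arm`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    score = x$score, p_value = x$p_value, n_perm = x$n_perm,
    n_peri = x$n_peri, n_arm = x$n_arm
  )
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- tidy.enrichment_result
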