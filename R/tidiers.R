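#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OPLS-DA model
#'
#' One row per retained metabolite with its predictive weight, loading and
#' VIP score.
#'
#' @param x A fitted [fit_opls()] model.
#' @param ... Unused.
#' @return Tibble: metabolite_id, weight, loading, vip.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(
    metabolite_id = x$metabolite_id,
    weight = unname(x$weights),
    loading = unname(x$loadings),
    vip = unname(x$vip)
  )
}

#' One-row summary of an OPLS-DA model
#'
#' @param x A fitted [fit_opls()] model.
#' @param ... Unused.
#' @return Tibble: n_metabolites, n_samples, n_ortho, R2Y, Q2.
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(
    n_metabolites = length(x$weights),
    n_samples = length(x$scores),
    n_ortho = x$n_ortho,
    R2Y = x$R2Y,
    Q2 = x$Q2
  )
}

#' Tidy a Ks peak set
#'
#' One row per detected peak, tallest first.
#'
#' @param x A [ks_peaks()] result.
#' @param ... Unused.
#' @return Tibble: peak (rank), ks, height.
#' @export
tidy.ks_peaks <- function(x, ...) {
  dplyr::mutate(x$peaks, peak = dplyr::row_number(), .before = 1)
}

#' One-row summary of a Ks peak set
#'
#' @param x A [ks_peaks()] result.
#' @param ... Unused.
#' @return Tibble: n, n_peaks, mode, bw, method, low_confidence.
#' @export
glance.ks_peaks <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_peaks = nrow(x$peaks),
    mode = ks_mode(x),
    bw = x$bw,
    method = x$method,
    low_confidence = x$low_confidence
  )
}
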