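#' Refit a spectrum against a subset of catalog signatures
#'
#' Non-negative least-squares decomposition of an observed spectrum onto
#' the chosen signature columns. The headline summary is the fraction of
#' the observed mutation mass that the reconstruction accounts for,
#' together with the cosine similarity between observed and
#' reconstructed spectra.
#'
#' @param spectrum A `mut_spectrum` (counts or normalised counts).
#' @param catalog A [load_catalog()] catalog.
#' @param subset Character vector of signature names to fit; defaults to
#'   the whole catalog.
#' @return A `sig_refit` object with elements `contributions` (named,
#'   non-negative, on the scale of the spectrum), `reconstructed`
#'   (a `mut_spectrum`), `cosine_to_observed`, and `fraction_explained`
#'   (`sum(reconstructed) / sum(observed)`, clipped to `[0, 1]`; 0 for an
#'   all-zero spectrum by contract).
#' @export
#' @examples
#' cat <- load_catalog("bundled-proxy")
#' obs <- mut_spectrum(600 * cat[, "SBS17a-proxy"] + 400 * cat[, "SBS17b-proxy"])
#' refit_signatures(obs, cat, c("SBS17a-proxy", "SBS17b-proxy"))
refit_signatures <- function(spectrum, catalog, subset = NULL) {
  stopifnot(inherits(spectrum, "mut_spectrum"))
  m <- catalog_matrix(catalog)
  subset <- subset %||% colnames(m)
  if (length(subset) == 0) stopf("signature subset must be non-empty")
  missing <- setdiff(subset, colnames(m))
  if (length(missing)) stopf("signature(s) not in catalog: %s", paste(missing, collapse = ", "))
  A <- m[, subset, drop = FALSE]
  b <- spectrum_values(spectrum)

  if (sum(b) == 0) {
    contrib <- stats::setNames(rep(0, length(subset)), subset)
    recon <- mut_spectrum(rep(0, 96), source = attr(spectrum, "source"),
                          normalized = attr(spectrum, "normalized"))
    res <- list(contributions = contrib, reconstructed = recon,
                observed = spectrum, cosine_to_observed = NA_real_,
                fraction_explained = 0)
    return(structure(res, class = "sig_refit"))
  }

  fit <- pracma::lsqnonneg(A, b)
  contrib <- stats::setNames(pmax(fit$x, 0), subset)
  recon_values <- pmax(drop(A %*% contrib), 0)
  recon <- mut_spectrum(recon_values, source = attr(spectrum, "source"),
                        normalized = attr(spectrum, "normalized"))
  structure(list(
    contributions = contrib,
    reconstructed = recon,
    observed = spectrum,
    cosine_to_observed = cosine(b, recon_values),
    fraction_explained = min(max(sum(recon_values) / sum(b), 0), 1)
  ), class = "sig_refit")
}

#' @export
print.sig_refit <- function(x, ...) {
  cat("<sig_refit>\n contributions:\n")
  print(round(x$contributions, 3))
  cat(sprintf(" fraction_explained = %.3f, cosine = %.3f\n",
              x$fraction_explained, x$cosine_to_observed))
  invisible(x)
}

#' @describeIn refit_signatures One row per fitted signature with its
#'   contribution and share of the reconstruction.
#' @param x A `sig_refit`.
#' @param ... Unused.
#' @export
tidy.sig_refit <- function(x, ...) {
  total <- sum(x$contributions)
  tibble::tibble(
    signature = names(x$contributions),
    contribution = as.numeric(x$contributions),
    proportion = if (total > 0) as.numeric(x$contributions) / total else 0
  )
}

#' @describeIn refit_signatures One-row model summary.
#' @export
glance.sig_refit <- function(x, ...) {
  tibble::tibble(
    n_signatures = length(x$contributions),
    total_observed = sum(spectrum_values(x$observed)),
    total_reconstructed = sum(spectrum_values(x$reconstructed)),
    fraction_explained = x$fraction_explained,
    cosine_to_observed = x$cosine_to_observed
  )
}
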