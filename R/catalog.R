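#' Load a single-base-substitution signature catalog
#'
#' Reads a catalog in the conventional tab-separated layout (a `Type`
#' column of channel labels such as `"A[C>A]A"` plus one column per
#' signature), or returns the bundled proxy catalog when called with
#' `"bundled-proxy"`.
#'
#' The bundled proxies are constructed from the verbal channel
#' definitions of the signatures they stand in for, so no external
#' download is required:
#' * `SBS17a-proxy` — 0.90 probability on `C[T>C]T`, the remaining 0.10
#'   uniform over the other 95 channels.
#' * `SBS17b-proxy` — 0.225 on each of `A/C/G/T[T>G]T`, 0.10 uniform
#'   over the other 92 channels.
#' * `clocklike-proxy` — 0.225 on each of the four `N[C>T]G` channels
#'   (the deamination-type, age-associated contexts), 0.10 uniform
#'   elsewhere.
#' * `flat-proxy` — uniform over all 96 channels.
#'
#' These are deliberately simplified stand-ins, not the catalogued
#' signatures themselves; a real catalog file is accepted whenever the
#' user has one.
#'
#' @param path Path to a catalog TSV, or `"bundled-proxy"`.
#' @return A `sig_catalog`: a 96 x S probability matrix (each column
#'   sums to 1) with channel rownames.
#' @export
#' @examples
#' cat <- load_catalog("bundled-proxy")
#' colnames(cat)
load_catalog <- function(path = "bundled-proxy") {
  if (identical(path, "bundled-proxy")) return(proxy_catalog())
  if (inherits(path, "sig_catalog")) return(path)
  if (is.matrix(path)) {
    stopifnot(nrow(path) == 96)
    m <- path[sbs_channels(), , drop = FALSE]
    return(structure(sweep(m, 2, colSums(m), "/"),
                     class = c("sig_catalog", "matrix", "array")))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  type_col <- intersect(c("Type", "type", "channel", "Channel", "MutationType"), names(tab))
  if (length(type_col) == 0) stopf("catalog must have a 'Type' column of channel labels")
  labels <- as.character(tab[[type_col[1]]])
  if (nrow(tab) != 96) stopf("catalog must have 96 channel rows, got %d", nrow(tab))
  if (!setequal(labels, sbs_channels())) {
    stopf("unknown channel labels in catalog: %s",
          paste(utils::head(setdiff(labels, sbs_channels()), 3), collapse = ", "))
  }
  m <- as.matrix(tab[, setdiff(names(tab), type_col[1]), drop = FALSE])
  if (!is.numeric(m)) stopf("catalog signature columns must be numeric")
  if (any(m < 0)) stopf("catalog entries must be non-negative")
  rownames(m) <- labels
  m <- m[sbs_channels(), , drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  structure(m, class = c("sig_catalog", "matrix", "array"))
}

catalog_matrix <- function(catalog) {
  if (inherits(catalog, "sig_catalog")) return(unclass(catalog))
  stopifnot(is.matrix(catalog), nrow(catalog) == 96)
  catalog
}

# Point-mass-plus-flat construction used by all bundled proxies.
proxy_vector <- function(channels, mass_each) {
  ch <- sbs_channels()
  v <- rep((1 - mass_each * length(channels)) / (96 - length(channels)), 96)
  names(v) <- ch
  v[channels] <- mass_each
  v
}

proxy_catalog <- function() {
  ch <- sbs_channels()
  m <- cbind(
    `SBS17a-proxy` = proxy_vector("C[T>C]T", 0.90),
    `SBS17b-proxy` = proxy_vector(paste0(BASES, "[T>G]T"), 0.225),
    `clocklike-proxy` = proxy_vector(paste0(BASES, "[C>T]G"), 0.225),
    `flat-proxy` = rep(1 / 96, 96)
  )
  rownames(m) <- ch
  structure(m, class = c("sig_catalog", "matrix", "array"))
}
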