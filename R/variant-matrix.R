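#' Construct a site-by-cell variant matrix
#'
#' The central container of the filter cascade: one row per candidate
#' variant with its quality metadata and the set of supporting cells,
#' plus the full cell universe and an append-only filter history.
#'
#' @param variants Tibble with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `mq` (mapping quality, may be `NA`), optionally `vaf`, and
#'   `cells` (list-column of supporting cell barcodes).
#' @param cells Character vector of all cell barcodes (the matrix
#'   columns), including cells supporting no variant.
#' @param history Prior filter history (tibble `step, n_in, n_out`).
#' @return A `variant_matrix` object.
#' @export
variant_matrix <- function(variants, cells, history = NULL) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("contig", "pos", "ref", "alt", "mq", "cells") %in% names(variants)))
  if (!"vaf" %in% names(variants)) variants$vaf <- NA_real_
  key <- variant_key(variants$contig, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) stopf("duplicate variant keys: %s",
                                paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  if (any(variants$ref == variants$alt)) stopf("ref and alt alleles must differ")
  unknown <- setdiff(unlist(variants$cells), cells)
  if (length(unknown)) stopf("supporting cell(s) not in cell universe: %s",
                             paste(utils::head(unknown, 3), collapse = ", "))
  structure(list(
    variants = variants,
    cells = cells,
    history = history %||% tibble::tibble(step = character(), n_in = integer(),
                                          n_out = integer())
  ), class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d variants x %d cells\n",
              nrow(x$variants), length(x$cells)))
  if (nrow(x$history)) {
    cat("filter history:\n")
    print(as.data.frame(x$history), row.names = FALSE)
  }
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) c(nrow(x$variants), length(x$cells))

n_support <- function(vm) lengths(vm$variants$cells)

variant_keys <- function(vm) {
  variant_key(vm$variants$contig, vm$variants$pos, vm$variants$ref, vm$variants$alt)
}

# Record a cascade step and return the filtered object.
vm_step <- function(vm, step, keep) {
  out <- vm
  out$variants <- vm$variants[keep, , drop = FALSE]
  out$history <- dplyr::bind_rows(
    vm$history,
    tibble::tibble(step = step, n_in = nrow(vm$variants), n_out = sum(keep))
  )
  out
}

#' Tidy a variant matrix into long presence format
#'
#' @param x A `variant_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per (variant, supporting cell).
#' @export
tidy.variant_matrix <- function(x, ...) {
  v <- x$variants
  tibble::tibble(
    key = rep(variant_keys(x), lengths(v$cells)),
    contig = rep(v$contig, lengths(v$cells)),
    pos = rep(v$pos, lengths(v$cells)),
    ref = rep(v$ref, lengths(v$cells)),
    alt = rep(v$alt, lengths(v$cells)),
    cell = unlist(v$cells) %||% character(0)
  )
}

# Dense 0/1 presence matrix (variants x cells).
presence_matrix <- function(vm) {
  m <- matrix(0L, nrow(vm$variants), length(vm$cells),
              dimnames = list(variant_keys(vm), vm$cells))
  for (i in seq_len(nrow(vm$variants))) {
    m[i, vm$variants$cells[[i]]] <- 1L
  }
  m
}
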