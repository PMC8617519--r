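#' Construct a trinucleotide spectrum object
#'
#' A `mut_spectrum` is a named numeric vector over the 96 channels of
#' [sbs_channels()], with metadata on how (and whether) it was
#' depth-normalised. Most users obtain one from [build_spectrum()].
#'
#' @param values Numeric vector of length 96 (named or in channel order),
#'   all values non-negative.
#' @param source Label for the originating cell cluster or sample.
#' @param n_cells Number of cells behind the spectrum (used as the weight
#'   in [pooled_cs_baseline()]).
#' @param n_skipped Number of variants skipped during classification.
#' @param normalized Whether the values are on the common depth scale of
#'   [normalize_spectrum()].
#' @param reads_per_cell,covered_fraction Mean sequencing depth metadata
#'   recorded at normalisation time.
#' @return A `mut_spectrum` object.
#' @export
mut_spectrum <- function(values, source = NA_character_, n_cells = NA_integer_,
                         n_skipped = 0L, normalized = FALSE,
                         reads_per_cell = NA_real_, covered_fraction = NA_real_) {
  ch <- sbs_channels()
  if (length(values) != 96L) stopf("a trinucleotide spectrum has 96 channels, got %d", length(values))
  if (!is.null(names(values))) {
    if (!setequal(names(values), ch)) stopf("unknown channel labels in spectrum")
    values <- values[ch]
  } else {
    names(values) <- ch
  }
  if (any(values < 0)) stopf("spectrum values must be non-negative")
  structure(stats::setNames(as.numeric(values), ch),
            class = "mut_spectrum",
            source = source, n_cells = n_cells, n_skipped = n_skipped,
            normalized = normalized, reads_per_cell = reads_per_cell,
            covered_fraction = covered_fraction)
}

#' @export
print.mut_spectrum <- function(x, ...) {
  cat(sprintf("<mut_spectrum> source=%s total=%.4g normalized=%s n_cells=%s\n",
              attr(x, "source"), sum(x), attr(x, "normalized"),
              as.character(attr(x, "n_cells"))))
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("top channels:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

spectrum_values <- function(x) stats::setNames(as.numeric(x), sbs_channels())

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trinucleotide spectrum into a tibble
#'
#' @param x A `mut_spectrum`.
#' @param ... Unused.
#' @return A tibble with one row per channel: `channel`, `substitution`,
#'   `fivep`, `threep`, `value`.
#' @export
tidy.mut_spectrum <- function(x, ...) {
  ch <- sbs_channels()
  tibble::tibble(
    channel = ch,
    substitution = substr(ch, 3, 5),
    fivep = substr(ch, 1, 1),
    threep = substr(ch, 7, 7),
    value = as.numeric(x)
  )
}

#' Classify SNVs into the 96 trinucleotide channels
#'
#' Looks up the reference trinucleotide around each variant and collapses
#' purine-centred contexts to the pyrimidine strand, so e.g. a `G>A` call
#' with 5' flank `A` and 3' flank `T` lands in the same channel as the
#' `C>T` it represents on the opposite strand (`A[C>T]T`).
#'
#' @param variants A data frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, all single-base SNVs.
#' @param reference Named character vector of contig sequences (see
#'   [make_reference()] / [read_fasta()]).
#' @return The input tibble with a `channel` column added; variants whose
#'   context contains an ambiguous base get `NA` and a warning.
#' @export
#' @examples
#' ref <- c(chr1 = "AACTT")
#' classify_snv_context(
#'   tibble::tibble(contig = "chr1", pos = 3, ref = "C", alt = "T"), ref)
classify_snv_context <- function(variants, reference) {
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0) {
    variants$channel <- character(0)
    return(variants)
  }
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  bad <- !variants$contig %in% names(reference)
  if (any(bad)) stopf("variant contig(s) not in reference: %s",
                      paste(unique(variants$contig[bad]), collapse = ", "))
  seqs <- reference[variants$contig]
  lens <- nchar(seqs)
  if (any(variants$pos < 2 | variants$pos > lens - 1)) {
    stopf("variant position without both flanking bases (pos %s)",
          paste(utils::head(variants$pos[variants$pos < 2 | variants$pos > lens - 1], 3),
                collapse = ", "))
  }
  tri <- substr(seqs, variants$pos - 1L, variants$pos + 1L)
  centre <- substr(tri, 2, 2)
  mism <- centre != variants$ref
  if (any(mism)) {
    i <- which(mism)[1]
    stopf("reference mismatch at %s:%d (reference %s, variant ref %s)",
          variants$contig[i], variants$pos[i], centre[i], variants$ref[i])
  }
  ambig <- grepl("[^ACGT]", tri) | !variants$alt %in% BASES
  channel <- rep(NA_character_, nrow(variants))
  ok <- !ambig
  channel[ok] <- channel_from_context(tri[ok], variants$ref[ok], variants$alt[ok])
  if (any(ambig)) warnf("%d variant(s) skipped: ambiguous base in trinucleotide context", sum(ambig))
  variants$channel <- channel
  variants
}

#' Build a trinucleotide spectrum from a variant set
#'
#' @inheritParams classify_snv_context
#' @param source,n_cells Metadata stored on the spectrum.
#' @return A [mut_spectrum()] of raw channel counts; the channel total
#'   equals the number of classifiable variants, and the count of skipped
#'   (ambiguous-context) variants is kept in the `n_skipped` attribute.
#' @export
build_spectrum <- function(variants, reference, source = NA_character_,
                           n_cells = NA_integer_) {
  cls <- classify_snv_context(variants, reference)
  counts <- table(factor(cls$channel, levels = sbs_channels()))
  mut_spectrum(as.numeric(counts), source = source, n_cells = n_cells,
               n_skipped = sum(is.na(cls$channel)))
}

#' Normalise a spectrum to a common sequencing depth
#'
#' Rescales channel counts to the reference condition of 100,000 reads
#' per cell and 1% genome coverage per cell, as the product of two linear
#' factors: `100000 / mean reads per cell` and `0.01 / mean covered
#' fraction`. Both input means are recorded in the result's metadata.
#'
#' @param spectrum A `mut_spectrum` of raw counts.
#' @param reads_per_cell Per-cell read totals (vector or mean) of the
#'   cells behind the spectrum.
#' @param covered_fraction Per-cell covered genome fractions (vector or
#'   mean), in (0, 1].
#' @return A normalised `mut_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, reads_per_cell, covered_fraction) {
  stopifnot(inherits(spectrum, "mut_spectrum"))
  mr <- mean(reads_per_cell)
  mc <- mean(covered_fraction)
  if (!is.finite(mr) || mr <= 0) stopf("reads_per_cell must be positive")
  if (!is.finite(mc) || mc <= 0 || mc > 1) stopf("covered_fraction must be in (0, 1]")
  scale <- (1e5 / mr) * (0.01 / mc)
  mut_spectrum(spectrum_values(spectrum) * scale,
               source = attr(spectrum, "source"),
               n_cells = attr(spectrum, "n_cells"),
               n_skipped = attr(spectrum, "n_skipped"),
               normalized = TRUE, reads_per_cell = mr, covered_fraction = mc)
}

#' Subtract a stable-cluster baseline from a spectrum
#'
#' Channel-wise subtraction of the chromosomally stable (CS) baseline
#' from an unstable cluster's spectrum; negative channels are clipped to
#' zero. Both spectra must be on the same normalisation scale.
#'
#' @param spectrum,baseline `mut_spectrum` objects with matching
#'   `normalized` state.
#' @return A `mut_spectrum`, element-wise `max(spectrum - baseline, 0)`.
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "mut_spectrum"), inherits(baseline, "mut_spectrum"))
  if (!identical(attr(spectrum, "normalized"), attr(baseline, "normalized"))) {
    stopf("spectrum and baseline are on different normalization scales")
  }
  mut_spectrum(pmax(spectrum_values(spectrum) - spectrum_values(baseline), 0),
               source = attr(spectrum, "source"),
               n_cells = attr(spectrum, "n_cells"),
               n_skipped = attr(spectrum, "n_skipped"),
               normalized = attr(spectrum, "normalized"),
               reads_per_cell = attr(spectrum, "reads_per_cell"),
               covered_fraction = attr(spectrum, "covered_fraction"))
}

#' Pool CS spectra into a common baseline
#'
#' Cell-count-weighted mean of the normalised CS-cluster spectra from one
#' or more samples, for use as a common baseline subtracted from every
#' cluster.
#'
#' @param spectra List of normalised `mut_spectrum` objects from CS
#'   clusters.
#' @param n_cells Optional numeric weights; defaults to each spectrum's
#'   `n_cells` attribute.
#' @return A `mut_spectrum`.
#' @export
pooled_cs_baseline <- function(spectra, n_cells = NULL) {
  if (length(spectra) == 0) stopf("no CS spectra available for pooling")
  stopifnot(all(vapply(spectra, inherits, logical(1), "mut_spectrum")))
  if (!all(vapply(spectra, function(s) isTRUE(attr(s, "normalized")), logical(1)))) {
    stopf("all CS spectra must be normalized before pooling")
  }
  w <- n_cells %||% vapply(spectra, function(s) as.numeric(attr(s, "n_cells")), numeric(1))
  if (any(is.na(w) | w <= 0)) stopf("pooling weights (n_cells) must be positive")
  mat <- vapply(spectra, spectrum_values, numeric(96))
  mut_spectrum(drop(mat %*% (w / sum(w))), source = "pooled-CS",
               n_cells = as.integer(sum(w)), normalized = TRUE)
}

#' Cosine similarity of a spectrum to every catalog signature
#'
#' @param spectrum A non-zero `mut_spectrum`.
#' @param catalog A signature catalog from [load_catalog()].
#' @return A tibble with `signature` and `cosine`, in catalog order.
#' @export
cosine_similarity_profile <- function(spectrum, catalog) {
  stopifnot(inherits(spectrum, "mut_spectrum"))
  s <- spectrum_values(spectrum)
  if (sum(s) == 0) stopf("cosine similarity is undefined for an all-zero spectrum")
  m <- catalog_matrix(catalog)
  sims <- as.numeric(crossprod(m, s)) /
    (sqrt(sum(s^2)) * sqrt(colSums(m^2)))
  tibble::tibble(signature = colnames(m), cosine = unname(sims))
}

cosine <- function(a, b) {
  if (sum(a^2) == 0 || sum(b^2) == 0) return(NA_real_)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
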