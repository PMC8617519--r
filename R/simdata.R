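#' Specify a simulated clone
#'
#' @param name Clone label.
#' @param karyotype Data frame `(contig, start, end, copy_number)` with
#'   0-based half-open coordinates and integer copy number in `0:4`, or
#'   `NULL` for a diploid (all CN = 2) clone. Segments must tile each
#'   contig without overlap; this is checked by [sim_config()].
#' @param n_somatic Number of clonal somatic SNVs to simulate.
#' @param signature_mixture Named weights over catalog signatures,
#'   non-negative and summing to 1.
#' @return A `clone_spec` list.
#' @export
#' @examples
#' clone_spec("CS", n_somatic = 100,
#'            signature_mixture = c("clocklike-proxy" = 0.7, "flat-proxy" = 0.3))
clone_spec <- function(name, karyotype = NULL, n_somatic = 0,
                       signature_mixture = c("flat-proxy" = 1)) {
  stopifnot(is.character(name), length(name) == 1, is_count(n_somatic))
  w <- signature_mixture
  if (is.null(names(w)) || any(!nzchar(names(w)))) stopf("signature_mixture must be named")
  if (any(w < 0)) stopf("signature_mixture weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stopf("signature_mixture weights must sum to 1 (got %.12f)", sum(w))
  if (!is.null(karyotype)) {
    karyotype <- tibble::as_tibble(karyotype)
    stopifnot(all(c("contig", "start", "end", "copy_number") %in% names(karyotype)))
    if (!all(karyotype$copy_number %in% 0:4)) stopf("copy_number must be an integer in 0..4")
    if (any(karyotype$end <= karyotype$start)) stopf("karyotype segments must have end > start")
  }
  structure(list(name = name, karyotype = karyotype, n_somatic = as.integer(n_somatic),
                 signature_mixture = w),
            class = "clone_spec")
}

#' Configure a synthetic single-cell DNA dataset
#'
#' Bundles and validates every parameter of the generator: the synthetic
#' genome, the clonal structure, per-cell sequencing depth, and the
#' variant load. Defaults describe a small two-clone "patient" with one
#' near-diploid chromosomally stable (CS) clone and one unstable (CIN)
#' clone; per-cell genome coverage is drawn from 0.5-1%, the shallow
#' regime typical of plate-based single-cell DNA sequencing.
#'
#' @param seed Root RNG seed; every stage derives its own sub-stream
#'   from it.
#' @param n_contigs,contig_length,gc_fraction Synthetic genome shape.
#' @param bin_size Width (bp) of the count bins; a trailing partial bin
#'   is kept and weighted by its fractional width.
#' @param clones List of [clone_spec()] objects.
#' @param n_cells_per_clone Integer vector, one entry per clone.
#' @param mean_reads_per_cell Mean of the per-cell total-read
#'   distribution (lognormal, sdlog 0.25).
#' @param coverage_fraction_range Per-cell covered genome fraction is
#'   drawn uniformly from this interval.
#' @param n_germline Number of germline SNPs (carried by every cell).
#' @param overdispersion Negative-binomial size parameter for bin
#'   counts; `Inf` gives Poisson counts.
#' @param low_mq_fraction Fraction of emitted variants assigned a low
#'   mapping-quality score (below the default MQ filter), emulating
#'   poorly mapped sites.
#' @param catalog Signature catalog used to draw somatic channels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L,
                       contig_length = 2e6,
                       bin_size = 1e5,
                       gc_fraction = 0.4,
                       clones = list(clone_spec("CS")),
                       n_cells_per_clone = 50L,
                       mean_reads_per_cell = 1e5,
                       coverage_fraction_range = c(0.005, 0.01),
                       n_germline = 500L,
                       overdispersion = 10,
                       low_mq_fraction = 0.05,
                       catalog = "bundled-proxy") {
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
            is_count(n_contigs), n_contigs >= 1,
            contig_length > 0, bin_size > 0,
            gc_fraction > 0, gc_fraction < 1,
            mean_reads_per_cell > 0, is_count(n_germline),
            overdispersion > 0, low_mq_fraction >= 0, low_mq_fraction <= 1)
  if (contig_length < 10 * bin_size) {
    stopf("contig_length must be at least 10 * bin_size")
  }
  r <- coverage_fraction_range
  if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2]) {
    stopf("coverage_fraction_range must be within [0, 1] with low <= high")
  }
  if (!all(vapply(clones, inherits, logical(1), "clone_spec"))) {
    stopf("clones must be a list of clone_spec objects")
  }
  n_cells_per_clone <- as.integer(rep_len(n_cells_per_clone, length(clones)))
  if (any(n_cells_per_clone < 0)) stopf("n_cells_per_clone must be non-negative")

  contigs <- paste0("contig_", seq_len(n_contigs))
  clones <- lapply(clones, function(cl) {
    cl$karyotype <- expand_karyotype(cl$karyotype, contigs, contig_length, cl$name)
    cl
  })
  if (anyDuplicated(vapply(clones, `[[`, character(1), "name"))) {
    stopf("clone names must be unique")
  }
  cat_m <- load_catalog(catalog)
  for (cl in clones) {
    missing <- setdiff(names(cl$signature_mixture), colnames(cat_m))
    if (length(missing)) {
      stopf("clone '%s' mixture names not in catalog: %s", cl$name,
            paste(missing, collapse = ", "))
    }
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 bin_size = as.integer(bin_size), gc_fraction = gc_fraction,
                 clones = clones, n_cells_per_clone = n_cells_per_clone,
                 mean_reads_per_cell = mean_reads_per_cell,
                 coverage_fraction_range = r, n_germline = as.integer(n_germline),
                 overdispersion = overdispersion,
                 low_mq_fraction = low_mq_fraction, catalog = catalog,
                 contigs = contigs),
            class = "sim_config")
}

# Fill missing contigs with CN=2 and check that segments tile each contig.
expand_karyotype <- function(karyotype, contigs, contig_length, clone_name) {
  if (is.null(karyotype)) {
    return(tibble::tibble(contig = contigs, start = 0,
                          end = contig_length, copy_number = 2L))
  }
  bad <- setdiff(unique(karyotype$contig), contigs)
  if (length(bad)) stopf("clone '%s' karyotype names unknown contig(s): %s",
                         clone_name, paste(bad, collapse = ", "))
  parts <- lapply(contigs, function(ct) {
    seg <- karyotype[karyotype$contig == ct, , drop = FALSE]
    if (nrow(seg) == 0) {
      return(tibble::tibble(contig = ct, start = 0, end = contig_length,
                            copy_number = 2L))
    }
    seg <- seg[order(seg$start), , drop = FALSE]
    covered_ok <- seg$start[1] == 0 && seg$end[nrow(seg)] == contig_length &&
      (nrow(seg) == 1 || all(seg$end[-nrow(seg)] == seg$start[-1]))
    if (!covered_ok) {
      stopf("clone '%s' karyotype does not tile %s without gaps or overlaps",
            clone_name, ct)
    }
    seg
  })
  dplyr::bind_rows(parts)
}

#' The default two-clone study conditions
#'
#' One CS clone (diploid, 1,000 clonal somatic variants from the
#' clock-like and flat proxies) and one CIN clone (whole loss of one
#' contig, segmental gain on another, diploid elsewhere — segmental
#' aberrations on a majority-diploid background, as in dysplastic
#' biopsies; 2,000 clonal somatic variants drawn 45% SBS17a-proxy,
#' 45% SBS17b-proxy, 10% flat), 50 cells each, 100,000 mean reads per
#' cell and 0.5-1% per-cell genome coverage.
#'
#' @param seed Root RNG seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L) {
  L <- 2e6
  cin_kar <- tibble::tibble(
    contig = c("contig_1", "contig_3", "contig_3"),
    start = c(0, 0, L / 2),
    end = c(L, L / 2, L),
    copy_number = c(1L, 3L, 2L)
  )
  sim_config(
    seed = seed,
    clones = list(
      clone_spec("CS", n_somatic = 1000,
                 signature_mixture = c("clocklike-proxy" = 0.7, "flat-proxy" = 0.3)),
      clone_spec("CIN", karyotype = cin_kar, n_somatic = 2000,
                 signature_mixture = c("SBS17a-proxy" = 0.45,
                                       "SBS17b-proxy" = 0.45,
                                       "flat-proxy" = 0.10))
    ),
    n_cells_per_clone = c(50L, 50L)
  )
}

#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases at the requested GC content. Each contig is
#' resampled (from the same seeded stream) until every pyrimidine-centred
#' trinucleotide occurs at least once, so all 96 substitution channels
#' have eligible sites.
#'
#' @param seed RNG seed.
#' @param n_contigs,contig_length,gc_fraction Genome shape.
#' @return Named character vector of sequences (`contig_1`, ...), class
#'   `cinsig_reference`.
#' @export
make_reference <- function(seed, n_contigs, contig_length, gc_fraction = 0.4) {
  stopifnot(gc_fraction > 0, gc_fraction < 1, contig_length >= 100)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
            (1 - gc_fraction) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      repeat {
        codes <- sample.int(4L, contig_length, replace = TRUE, prob = prob) - 1L
        if (contig_length < 1e4 || all_pyr_trinucs_present(codes)) {
          return(intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L]))
        }
      }
    }, character(1))
    stats::setNames(seqs, paste0("contig_", seq_len(n_contigs)))
  })
}

# 32 pyrimidine-centred trinucleotide codes
pyr_trinuc_codes <- function() {
  g <- expand.grid(l = 0:3, c = c(1L, 3L), r = 0:3)
  sort(16L * g$l + 4L * g$c + g$r)
}

all_pyr_trinucs_present <- function(codes) {
  n <- length(codes)
  tri <- collapse_trinuc_code(codes[1:(n - 2L)], codes[2:(n - 1L)], codes[3:n])
  length(unique(tri)) == 32L
}

#' Bin grid over a reference genome
#'
#' @param reference A [make_reference()] genome (or any named character
#'   vector of sequences).
#' @param bin_size Bin width in bp. The trailing partial bin of each
#'   contig is kept with a proportional weight.
#' @return Tibble `(contig, start, end, weight)` with 0-based half-open
#'   coordinates, sorted by contig then start.
#' @export
bin_grid <- function(reference, bin_size) {
  parts <- lapply(names(reference), function(ct) {
    n <- nchar(reference[[ct]])
    starts <- seq(0, n - 1, by = bin_size)
    ends <- pmin(starts + bin_size, n)
    tibble::tibble(contig = ct, start = starts, end = ends,
                   weight = (ends - starts) / bin_size)
  })
  dplyr::bind_rows(parts)
}

# Cell roster shared by simulate_cells() and simulate_variants():
# barcodes, clone assignment, per-cell covered fraction, shuffled order.
cell_roster <- function(config) {
  with_seed(derive_seed(config$seed, 1), {
    clones <- vapply(config$clones, `[[`, character(1), "name")
    clone_of <- rep(clones, config$n_cells_per_clone)
    n <- length(clone_of)
    cells <- sprintf("cell_%04d", seq_len(n))
    covered <- stats::runif(n, config$coverage_fraction_range[1],
                            config$coverage_fraction_range[2])
    ord <- sample.int(n)
    tibble::tibble(cell = cells[ord], clone = clone_of[ord],
                   covered_fraction = covered[ord])
  })
}

# Per-bin expected copy number of a clone: overlap-weighted mean of the
# karyotype copy number over each bin.
karyotype_cn_by_bin <- function(karyotype, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    seg <- karyotype[karyotype$contig == grid$contig[i], , drop = FALSE]
    ov_start <- pmax(seg$start, grid$start[i])
    ov_end <- pmin(seg$end, grid$end[i])
    len <- pmax(ov_end - ov_start, 0)
    if (sum(len) < grid$end[i] - grid$start[i]) {
      stopf("karyotype does not cover bin %s:%d-%d", grid$contig[i],
            grid$start[i], grid$end[i])
    }
    sum(seg$copy_number * len) / sum(len)
  }, numeric(1))
}

#' Simulate per-cell binned read counts
#'
#' Each cell's total read count is lognormal around
#' `mean_reads_per_cell`; bin counts are negative-binomial with
#' expectation proportional to the clone's copy number times the bin
#' weight, and dispersion given by `overdispersion` (`Inf` = Poisson).
#'
#' @param config A [sim_config()].
#' @param reference The genome from [make_reference()] (matching
#'   `config`).
#' @return List with `counts` (tibble: `contig, start, end, weight` plus
#'   one integer column per cell, cells in shuffled order) and `truth`
#'   (tibble: `cell, clone, covered_fraction, total_reads`).
#' @export
simulate_cells <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  grid <- bin_grid(reference, config$bin_size)
  roster <- cell_roster(config)
  cn_by_clone <- lapply(config$clones, function(cl) karyotype_cn_by_bin(cl$karyotype, grid))
  names(cn_by_clone) <- vapply(config$clones, `[[`, character(1), "name")

  counts <- with_seed(derive_seed(config$seed, 2), {
    totals <- stats::rlnorm(nrow(roster),
                            meanlog = log(config$mean_reads_per_cell) - 0.25^2 / 2,
                            sdlog = 0.25)
    sapply(seq_len(nrow(roster)), function(i) {
      cn <- cn_by_clone[[roster$clone[i]]]
      mu <- totals[i] * (cn * grid$weight) / sum(cn * grid$weight)
      if (is.finite(config$overdispersion)) {
        stats::rnbinom(length(mu), mu = mu, size = config$overdispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
    })
  })
  if (nrow(roster) == 0) counts <- matrix(integer(0), nrow = nrow(grid), ncol = 0)
  colnames(counts) <- roster$cell
  out <- dplyr::bind_cols(grid, tibble::as_tibble(counts))
  truth <- dplyr::mutate(roster, total_reads = if (nrow(roster)) colSums(counts) else integer(0))
  list(counts = out, truth = truth)
}
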