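#' Normalise binned read counts to copy-number profiles
#'
#' Per cell, counts are first weight-adjusted (`count / weight`, so a
#' trailing partial bin is comparable to full bins), then divided by the
#' cell's median adjusted count and multiplied by 2. A diploid cell thus
#' centres at copy number 2.
#'
#' @param counts Tibble `(contig, start, end, weight, <cell columns>)`
#'   as produced by [simulate_cells()] / [read_counts_tsv()].
#' @return Tibble of the same shape holding normalised copy numbers.
#'   Cells with an all-zero median are rejected with an error naming
#'   them.
#' @export
#' @examples
#' grid <- tibble::tibble(contig = "c1", start = 0:3 * 10, end = 1:4 * 10,
#'                        weight = 1)
#' normalize_counts(dplyr::bind_cols(grid, tibble::tibble(cell1 = c(10, 10, 20, 10))))
normalize_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  meta <- intersect(c("contig", "start", "end", "weight"), names(counts))
  stopifnot(all(c("contig", "start", "end") %in% meta))
  if (!"weight" %in% meta) counts$weight <- 1
  cells <- setdiff(names(counts), c("contig", "start", "end", "weight"))
  out <- counts
  zero_med <- character(0)
  for (cell in cells) {
    adj <- counts[[cell]] / counts$weight
    med <- stats::median(adj)
    if (!is.finite(med) || med == 0) {
      zero_med <- c(zero_med, cell)
      next
    }
    out[[cell]] <- adj / med * 2
  }
  if (length(zero_med)) {
    stopf("zero median read count; cannot normalize cell(s): %s",
          paste(zero_med, collapse = ", "))
  }
  out
}

cn_matrix <- function(cn) {
  cells <- setdiff(names(cn), c("contig", "start", "end", "weight"))
  m <- t(as.matrix(cn[, cells, drop = FALSE]))
  rownames(m) <- cells
  m
}

#' Cluster cells on their copy-number profiles
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distance between profile vectors), cut at a user-chosen number of
#' clusters — the cluster count is a per-sample analyst decision, not
#' auto-selected. An average-silhouette suggestion over a small range of
#' k is printed as a message to aid that choice, but never applied.
#'
#' @param cn Normalised profile tibble from [normalize_counts()].
#' @param k Number of clusters.
#' @param suggest Print the silhouette suggestion (default off inside
#'   pipelines).
#' @return Tibble `(cell, cluster, is_cs)`; `is_cs` is `NA` until
#'   [label_cs_cluster()] runs. Cells are processed in lexicographic
#'   barcode order so ties break deterministically.
#' @export
cluster_cells <- function(cn, k, suggest = FALSE) {
  m <- cn_matrix(cn)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(m)) stopf("k (%d) exceeds the number of cells (%d)", k, nrow(m))
  if (nrow(m) == 1 || k == 1) {
    return(tibble::tibble(cell = rownames(m), cluster = "cluster_1", is_cs = NA))
  }
  d <- stats::dist(m)
  if (all(d == 0) && k > 1) {
    warnf("all profiles are identical; the %d clusters are degenerate", k)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # relabel by first appearance in barcode order
  lab <- match(raw, unique(raw))
  if (suggest && nrow(m) > 3) {
    ks <- 2:min(8, nrow(m) - 1)
    sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
    }, numeric(1))
    message(sprintf("silhouette suggests k = %d (mean widths: %s)",
                    ks[which.max(sil)],
                    paste(sprintf("k%d=%.2f", ks, sil), collapse = ", ")))
  }
  tibble::tibble(cell = rownames(m), cluster = paste0("cluster_", lab), is_cs = NA)
}

#' Mean copy-number profile of each cluster
#'
#' @param cn Normalised profile tibble.
#' @param assignment Tibble from [cluster_cells()].
#' @return Tibble in long-by-cluster form: `(cluster, contig, start,
#'   end, weight, value)`.
#' @export
cluster_mean_profiles <- function(cn, assignment) {
  bins <- cn[, c("contig", "start", "end", "weight")]
  parts <- lapply(unique(assignment$cluster), function(cl) {
    cells <- assignment$cell[assignment$cluster == cl]
    vals <- rowMeans(as.matrix(cn[, cells, drop = FALSE]))
    dplyr::bind_cols(tibble::tibble(cluster = cl), bins,
                     tibble::tibble(value = vals))
  })
  dplyr::bind_rows(parts)
}

#' Segment every cluster's mean profile
#'
#' @inheritParams cluster_mean_profiles
#' @inheritParams cbs_segment
#' @return Tibble `(cluster, contig, start, end, n_bins, weight,
#'   mean_cn)`.
#' @export
segment_clusters <- function(cn, assignment, alpha = 0.01, nperm = 1000,
                             min_width = 2, seed = NULL) {
  profiles <- cluster_mean_profiles(cn, assignment)
  parts <- lapply(unique(profiles$cluster), function(cl) {
    p <- profiles[profiles$cluster == cl, , drop = FALSE]
    segs <- cbs_segment(p[, c("contig", "start", "end", "weight", "value")],
                        alpha = alpha, nperm = nperm, min_width = min_width,
                        seed = seed)
    dplyr::bind_cols(tibble::tibble(cluster = cl), segs)
  })
  dplyr::bind_rows(parts)
}

#' Flag the chromosomally stable cluster
#'
#' Computes each cluster's aberrant genome fraction — the weighted
#' fraction of the binned genome lying in segments whose mean copy
#' number deviates from 2 by more than `cn_delta` — and flags the
#' cluster with the smallest fraction as chromosomally stable (CS),
#' provided that fraction is at most `cs_max_aberrant`. Ties go to the
#' cluster with more cells, then to the lexicographically smaller
#' label.
#'
#' @param segments Tibble from [segment_clusters()].
#' @param assignment Tibble from [cluster_cells()].
#' @param cn_delta Copy-number deviation from 2 that counts as aberrant.
#' @param cs_max_aberrant Maximum aberrant fraction for a CS call.
#' @return The assignment tibble with `is_cs` filled in (at most one
#'   cluster `TRUE`); if no cluster qualifies, all `FALSE` with a
#'   warning.
#' @export
label_cs_cluster <- function(segments, assignment, cn_delta = 0.5,
                             cs_max_aberrant = 0.05) {
  stats_tbl <- aberrant_fractions(segments, assignment, cn_delta)
  assignment$is_cs <- FALSE
  if (stats_tbl$aberrant_fraction[1] <= cs_max_aberrant) {
    assignment$is_cs <- assignment$cluster == stats_tbl$cluster[1]
  } else {
    warnf("no cluster qualifies as chromosomally stable (min aberrant fraction %.3f > %.3f)",
          stats_tbl$aberrant_fraction[1], cs_max_aberrant)
  }
  assignment
}

#' @rdname label_cs_cluster
#' @export
aberrant_fractions <- function(segments, assignment, cn_delta = 0.5) {
  counts <- dplyr::count(assignment, .data$cluster, name = "n_cells")
  per <- segments |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      aberrant_fraction = sum(.data$weight[abs(.data$mean_cn - 2) > cn_delta]) /
        sum(.data$weight),
      .groups = "drop") |>
    dplyr::left_join(counts, by = "cluster") |>
    dplyr::arrange(.data$aberrant_fraction, dplyr::desc(.data$n_cells),
                   .data$cluster)
  per
}

#' Call copy-number gained and lost regions
#'
#' Segments whose mean copy number is at least `2 + cn_delta` are gains,
#' at most `2 - cn_delta` losses; everything else is omitted. Adjacent
#' same-direction regions are merged per cluster and contig.
#'
#' @param segments Tibble from [segment_clusters()] (or [cbs_segment()]
#'   with a `cluster` column added).
#' @param cn_delta Copy-number threshold.
#' @return Tibble `(cluster, contig, start, end, direction)` with
#'   `direction` in `gain`/`loss`.
#' @export
call_cin_regions <- function(segments, cn_delta = 0.5) {
  if (!"cluster" %in% names(segments)) segments$cluster <- "cluster_1"
  reg <- segments |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$mean_cn >= 2 + cn_delta ~ "gain",
      .data$mean_cn <= 2 - cn_delta ~ "loss",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::arrange(.data$cluster, .data$contig, .data$start)
  merge_adjacent(reg[, c("cluster", "contig", "start", "end", "direction")])
}

# Merge touching/overlapping same-direction intervals within
# (cluster, contig, direction).
merge_adjacent <- function(reg) {
  if (nrow(reg) == 0) return(reg)
  reg <- dplyr::arrange(reg, .data$cluster, .data$contig, .data$direction,
                        .data$start)
  out <- reg[0, ]
  cur <- reg[1, ]
  for (i in seq_len(nrow(reg))[-1]) {
    r <- reg[i, ]
    same <- r$cluster == cur$cluster && r$contig == cur$contig &&
      r$direction == cur$direction && r$start <= cur$end
    if (same) {
      cur$end <- max(cur$end, r$end)
    } else {
      out <- dplyr::bind_rows(out, cur)
      cur <- r
    }
  }
  out <- dplyr::bind_rows(out, cur)
  dplyr::arrange(out, .data$cluster, .data$contig, .data$start)
}

#' Intersect CIN regions across samples
#'
#' Interval intersection of same-direction regions across two or more
#' region sets (e.g. the CIN clusters of two biopsies), yielding the
#' alterations they share. Commutative and associative in its inputs.
#'
#' @param region_sets List of region tibbles (each with `contig`,
#'   `start`, `end`, `direction`).
#' @return Tibble `(contig, start, end, direction)`.
#' @export
shared_cin_regions <- function(region_sets) {
  if (length(region_sets) < 2) stopf("need at least two region sets to intersect")
  canon <- function(r) {
    r <- tibble::as_tibble(r)[, c("contig", "start", "end", "direction")]
    r$cluster <- "all"
    merge_adjacent(r)[, c("contig", "start", "end", "direction")]
  }
  intersect_two <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(a[0, ])
    j <- dplyr::inner_join(a, b, by = c("contig", "direction"),
                           suffix = c("", ".y"), relationship = "many-to-many")
    j$start <- pmax(j$start, j$start.y)
    j$end <- pmin(j$end, j$end.y)
    canon(j[j$start < j$end, c("contig", "start", "end", "direction")])
  }
  Reduce(intersect_two, lapply(region_sets, canon))
}

#' Restrict a gene table to chromosomally stable regions
#'
#' Keeps genes whose interval overlaps no CIN region in any of the
#' provided sets (half-open overlap; a single base of overlap excludes
#' the gene). Genes on contigs absent from the bin grid are excluded
#' with a warning.
#'
#' @param genes Tibble `(gene, contig, start, end)`, 0-based half-open.
#' @param region_sets List of CIN region tibbles (or a single tibble).
#' @param grid Optional bin grid defining the known contigs.
#' @return The retained subset of `genes`.
#' @export
filter_genes_to_stable_regions <- function(genes, region_sets, grid = NULL) {
  genes <- tibble::as_tibble(genes)
  if (is.data.frame(region_sets)) region_sets <- list(region_sets)
  regions <- dplyr::bind_rows(lapply(region_sets, function(r) {
    tibble::as_tibble(r)[, c("contig", "start", "end")]
  }))
  keep <- rep(TRUE, nrow(genes))
  if (!is.null(grid)) {
    off <- !genes$contig %in% unique(grid$contig)
    if (any(off)) {
      warnf("%d gene(s) on contigs absent from the grid were excluded", sum(off))
      keep[off] <- FALSE
    }
  }
  if (nrow(regions)) {
    for (i in which(keep)) {
      hit <- regions$contig == genes$contig[i] &
        regions$start < genes$end[i] & genes$start[i] < regions$end
      if (any(hit)) keep[i] <- FALSE
    }
  }
  genes[keep, , drop = FALSE]
}
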