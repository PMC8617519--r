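# The somatic-variant filter cascade:
# MQ -> blacklist -> cross-patient sharing -> CS overlap -> Fisher enrichment.

#' Filter variants by mapping quality
#'
#' Retains variants with `MQ` strictly greater than the threshold (the
#' shallow single-cell mode uses 20; whole-genome mode uses 60).
#' Variants with a missing MQ cannot be qualified and are dropped, with
#' a warning carrying the count.
#'
#' @param vm A [variant_matrix()].
#' @param threshold Minimum (exclusive) mapping quality.
#' @return The filtered `variant_matrix`, history updated.
#' @export
filter_mq <- function(vm, threshold = 20) {
  stopifnot(inherits(vm, "variant_matrix"), threshold >= 0)
  missing <- is.na(vm$variants$mq)
  if (any(missing)) warnf("%d variant(s) without MQ dropped", sum(missing))
  vm_step(vm, sprintf("mq>%g", threshold), !missing & vm$variants$mq > threshold)
}

#' Filter variants by allele fraction (whole-genome mode)
#'
#' Retains variants with VAF strictly greater than the threshold,
#' excluding low-fraction calls such as culture-accumulated mutations.
#'
#' @param vm A [variant_matrix()] whose variants carry a `vaf` column.
#' @param threshold Minimum (exclusive) variant allele fraction.
#' @return The filtered `variant_matrix`.
#' @export
filter_vaf <- function(vm, threshold = 0.3) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (all(is.na(vm$variants$vaf))) {
    stopf("no VAF available: this filter applies to whole-genome (bulk) inputs only")
  }
  vm_step(vm, sprintf("vaf>%g", threshold),
          !is.na(vm$variants$vaf) & vm$variants$vaf > threshold)
}

#' Remove blacklisted (known germline) variants
#'
#' Exact-key matching on `(contig, pos, ref, alt)`: a different alt
#' allele at a blacklisted position is retained.
#'
#' @param vm A [variant_matrix()].
#' @param blacklist Tibble from [read_blacklist()] (or any data frame
#'   with `contig`, `pos`, `ref`, `alt`).
#' @return The filtered `variant_matrix`.
#' @export
remove_blacklisted <- function(vm, blacklist) {
  stopifnot(inherits(vm, "variant_matrix"))
  bl_keys <- variant_key(blacklist$contig, blacklist$pos, blacklist$ref, blacklist$alt)
  vm_step(vm, "blacklist", !variant_keys(vm) %in% bl_keys)
}

#' Remove variants shared by every patient
#'
#' A variant key observed (at least one supporting cell) in every
#' patient's matrix is treated as a residual germline or artefact and
#' removed from all matrices; keys observed in a strict subset are
#' retained.
#'
#' @param vms Named list of [variant_matrix()] objects, one per patient.
#' @return The list with ubiquitous keys removed from each matrix; with
#'   a single patient, the input is returned unchanged with a warning.
#' @export
remove_ubiquitous <- function(vms) {
  stopifnot(all(vapply(vms, inherits, logical(1), "variant_matrix")))
  if (length(vms) < 2) {
    warnf("cross-patient filter needs at least two patients; returning input unchanged")
    return(lapply(vms, function(vm) vm_step(vm, "ubiquitous", rep(TRUE, nrow(vm$variants)))))
  }
  observed <- lapply(vms, function(vm) variant_keys(vm)[n_support(vm) > 0])
  shared <- Reduce(intersect, observed)
  lapply(vms, function(vm) vm_step(vm, "ubiquitous", !variant_keys(vm) %in% shared))
}

#' Remove variants supported by the stable cluster
#'
#' Drops every variant with at least one supporting cell in the
#' chromosomally stable (CS) cluster, plus variants with no supporting
#' cell at all (unobserved rows carry no evidence).
#'
#' @param vm A [variant_matrix()].
#' @param assignment Cluster assignment with the CS flag set
#'   ([label_cs_cluster()]).
#' @return The filtered `variant_matrix`.
#' @export
remove_cs_supported <- function(vm, assignment) {
  stopifnot(inherits(vm, "variant_matrix"))
  cs_cells <- assignment$cell[assignment$is_cs %in% TRUE]
  if (length(cs_cells) == 0) {
    stopf("no chromosomally stable cluster is flagged; cannot apply the CS-overlap filter")
  }
  in_cs <- vapply(vm$variants$cells, function(x) any(x %in% cs_cells), logical(1))
  vm_step(vm, "cs_overlap", !in_cs & n_support(vm) > 0)
}

#' Per-cluster Fisher-exact enrichment of variants
#'
#' For every (variant, cluster) pair, builds the 2x2 table of supporting
#' vs non-supporting cells inside and outside the cluster and computes
#' the Fisher exact p-value — one-sided in the enrichment direction by
#' default, since the question is whether the variant concentrates in
#' the cluster. No multiple-testing correction is applied by default; a
#' Benjamini-Hochberg adjustment is available via `bh`.
#'
#' @param vm A [variant_matrix()].
#' @param assignment Cluster assignment tibble.
#' @param p_threshold Significance threshold on the (adjusted) p-value.
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @param bh Apply Benjamini-Hochberg adjustment across all tests.
#' @return Tibble with one row per (variant, cluster): the table counts
#'   `n_in_with`, `n_in_without`, `n_out_with`, `n_out_without`,
#'   `p_value`, and `enriched`.
#' @export
fisher_cluster_enrichment <- function(vm, assignment, p_threshold = 0.05,
                                      alternative = c("greater", "two.sided"),
                                      bh = FALSE) {
  stopifnot(inherits(vm, "variant_matrix"),
            p_threshold > 0, p_threshold < 1)
  alternative <- match.arg(alternative)
  clusters <- sort(unique(assignment$cluster))
  if (length(clusters) < 2) stopf("enrichment needs at least two clusters")
  sizes <- table(assignment$cluster)
  if (any(sizes == 0)) stopf("cluster with zero cells")
  n_total <- nrow(assignment)
  keys <- variant_keys(vm)

  rows <- lapply(clusters, function(cl) {
    cl_cells <- assignment$cell[assignment$cluster == cl]
    n_in <- length(cl_cells)
    a <- vapply(vm$variants$cells, function(x) sum(x %in% cl_cells), integer(1))
    k_tot <- n_support(vm)
    tibble::tibble(
      key = keys,
      contig = vm$variants$contig, pos = vm$variants$pos,
      ref = vm$variants$ref, alt = vm$variants$alt,
      cluster = cl,
      n_in_with = a, n_in_without = n_in - a,
      n_out_with = k_tot - a, n_out_without = (n_total - n_in) - (k_tot - a),
      p_value = fisher_p(a, k_tot, n_in, n_total, alternative)
    )
  })
  out <- dplyr::bind_rows(rows)
  p_eff <- if (bh) stats::p.adjust(out$p_value, method = "BH") else out$p_value
  out$p_adjusted <- if (bh) p_eff else NA_real_
  out$enriched <- p_eff < p_threshold
  out
}

# One-sided p: upper hypergeometric tail P(X >= a) with X the number of
# carrier cells falling in a cluster of size n_in out of n_total, given
# k_tot carriers overall. Two-sided delegates to fisher.test.
fisher_p <- function(a, k_tot, n_in, n_total, alternative) {
  if (alternative == "greater") {
    p <- stats::phyper(a - 1, k_tot, n_total - k_tot, n_in, lower.tail = FALSE)
    return(pmin(p, 1))
  }
  vapply(seq_along(a), function(i) {
    tab <- matrix(c(a[i], n_in - a[i], k_tot[i] - a[i],
                    (n_total - n_in) - (k_tot[i] - a[i])), 2)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
}

#' Export a cluster's enriched variants to VCF
#'
#' Minimal VCF v4.2 sorted by contig and position, with INFO fields
#' `CLUSTER`, `FISHER_P`, `CELLS_IN`, `CELLS_OUT` (and `MQ` when
#' available from the matrix).
#'
#' @param enrichment Tibble from [fisher_cluster_enrichment()].
#' @param cluster Cluster label to export.
#' @param path Output path.
#' @param vm Optional [variant_matrix()] supplying per-variant MQ.
#' @return The path, invisibly.
#' @export
export_enriched_vcf <- function(enrichment, cluster, path, vm = NULL) {
  e <- enrichment[enrichment$cluster == cluster & enrichment$enriched, , drop = FALSE]
  e <- e[order(e$contig, e$pos, e$ref, e$alt), , drop = FALSE]
  mq <- rep(NA_real_, nrow(e))
  if (!is.null(vm) && nrow(e)) {
    mq <- vm$variants$mq[match(e$key, variant_keys(vm))]
  }
  info <- sprintf("CLUSTER=%s;FISHER_P=%s;CELLS_IN=%d;CELLS_OUT=%d",
                  cluster, format(e$p_value, digits = 10, trim = TRUE),
                  e$n_in_with, e$n_out_with)
  info <- ifelse(is.na(mq), info, paste0(info, ";MQ=", format(mq, trim = TRUE)))
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=cinsig enriched variants, cluster %s", cluster),
    "##INFO=<ID=CLUSTER,Number=1,Type=String,Description=\"Enriched cluster\">",
    "##INFO=<ID=FISHER_P,Number=1,Type=Float,Description=\"Fisher exact p-value\">",
    "##INFO=<ID=CELLS_IN,Number=1,Type=Integer,Description=\"Supporting cells inside cluster\">",
    "##INFO=<ID=CELLS_OUT,Number=1,Type=Integer,Description=\"Supporting cells outside cluster\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    if (nrow(e)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                         e$contig, e$pos, e$ref, e$alt, info)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Attribute filtered variants to clusters
#'
#' Splits the post-cascade variant set into per-cluster sets for
#' spectrum building. With `method = "supported"` (default) a cluster
#' receives every variant with at least one supporting cell among its
#' cells — appropriate in the shallow-coverage regime where most
#' variants are seen in very few cells and the exact test has little
#' power. With `method = "enriched"` a cluster receives only its
#' Fisher-enriched variants.
#'
#' @param vm A [variant_matrix()].
#' @param assignment Cluster assignment tibble.
#' @param method Attribution rule (see above).
#' @param enrichment Required for `method = "enriched"`.
#' @return Named list (cluster label -> tibble of variants
#'   `(contig, pos, ref, alt, mq)`).
#' @export
cluster_variant_sets <- function(vm, assignment,
                                 method = c("supported", "enriched"),
                                 enrichment = NULL) {
  method <- match.arg(method)
  clusters <- sort(unique(assignment$cluster))
  out <- lapply(clusters, function(cl) {
    if (method == "supported") {
      cl_cells <- assignment$cell[assignment$cluster == cl]
      keep <- vapply(vm$variants$cells, function(x) any(x %in% cl_cells), logical(1))
      vm$variants[keep, c("contig", "pos", "ref", "alt", "mq")]
    } else {
      if (is.null(enrichment)) stopf("method='enriched' requires an enrichment table")
      keys <- enrichment$key[enrichment$cluster == cl & enrichment$enriched]
      vm$variants[variant_keys(vm) %in% keys, c("contig", "pos", "ref", "alt", "mq")]
    }
  })
  stats::setNames(out, clusters)
}
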