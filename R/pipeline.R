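# Pipeline orchestration: simulate -> run -> report.

sim_file_names <- c(reference = "reference.fa", counts = "counts.tsv",
                    vcf = "variants.vcf", presence = "presence.tsv",
                    blacklist = "blacklist.tsv", cell_qc = "cell_qc.tsv",
                    truth = "truth.json")

#' Write a complete synthetic dataset to disk
#'
#' Generates the reference genome, per-cell binned counts, variant calls
#' (minimal VCF plus site-by-cell presence TSV), the germline blacklist,
#' per-cell QC (realised reads and covered fraction, as a mapping
#' pipeline would report), and the ground-truth JSON. Deterministic per
#' config seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `truth` tables
#'   and the in-memory objects (`reference`, `counts`, `variants`).
#' @export
cmd_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory %s", outdir)

  reference <- make_reference(derive_seed(config$seed, 0), config$n_contigs,
                              config$contig_length, config$gc_fraction)
  cells <- simulate_cells(config, reference)
  vars <- simulate_variants(config, reference)

  paths <- stats::setNames(file.path(outdir, sim_file_names), names(sim_file_names))
  write_fasta(reference, paths[["reference"]])
  write_counts_tsv(cells$counts, paths[["counts"]])
  write_variant_matrix(vars$variants, vcf_path = paths[["vcf"]],
                       presence_path = paths[["presence"]])
  gl <- vars$truth[vars$truth$germline, c("contig", "pos", "ref", "alt")]
  readr::write_tsv(gl, paths[["blacklist"]], progress = FALSE)
  readr::write_tsv(cells$truth[, c("cell", "total_reads", "covered_fraction")],
                   paths[["cell_qc"]], progress = FALSE)
  truth <- list(
    seed = config$seed,
    cells = cells$truth,
    karyotypes = stats::setNames(
      lapply(config$clones, function(cl) cl$karyotype),
      vapply(config$clones, `[[`, character(1), "name")),
    n_somatic = stats::setNames(
      vapply(config$clones, `[[`, integer(1), "n_somatic"),
      vapply(config$clones, `[[`, character(1), "name")),
    n_germline = config$n_germline,
    variants = vars$truth
  )
  write_json(truth, paths[["truth"]])
  invisible(list(paths = as.list(paths), truth = truth, reference = reference,
                 counts = cells$counts, variants = vars$variants))
}

#' Run the full analysis pipeline on one sample
#'
#' Executes, in order: copy-number normalisation, hierarchical
#' clustering at the user-chosen `k`, per-cluster circular binary
#' segmentation, CS-cluster labelling and CIN-region calling; the
#' variant filter cascade (mapping quality, germline blacklist,
#' optional cross-patient sharing, CS overlap) and per-cluster
#' Fisher-exact enrichment with VCF export; and per-cluster
#' trinucleotide spectra, depth normalisation, CS-baseline subtraction,
#' cosine similarity profiles and the non-negative signature refit.
#'
#' @param data_dir Directory holding the sample files under the
#'   standard names written by [cmd_simulate()] (override individual
#'   files via `paths`).
#' @param outdir Where stage outputs and the report are written.
#' @param k Number of cell clusters (per-sample analyst choice).
#' @param cn_delta,cs_max_aberrant CS/CIN thresholds
#'   (see [label_cs_cluster()]).
#' @param mq_min Exclusive mapping-quality minimum.
#' @param p_threshold Fisher significance threshold.
#' @param subset Signature names refit against the spectra.
#' @param catalog Catalog path or `"bundled-proxy"`.
#' @param baseline `"per-sample"` (subtract this sample's CS spectrum),
#'   `"pooled"` (cell-count-weighted pool of the CS spectra in
#'   `cs_pool`), or `"none"`.
#' @param attribution How filtered variants are attributed to clusters
#'   for spectrum building (see [cluster_variant_sets()]).
#' @param alpha,nperm Segmentation parameters ([cbs_segment()]).
#' @param seed Seed for the segmentation permutation RNG.
#' @param cohort Optional named list of other patients'
#'   [variant_matrix()] objects for the cross-patient filter.
#' @param cs_pool Optional list of normalised CS spectra from other
#'   samples, pooled with this sample's for `baseline = "pooled"`.
#' @param paths Optional named list overriding individual input paths
#'   (`reference`, `counts`, `vcf`, `presence`, `blacklist`,
#'   `cell_qc`).
#' @return A `cinsig_report` (also persisted as JSON and Markdown in
#'   `outdir`).
#' @export
cmd_run <- function(data_dir, outdir = file.path(data_dir, "results"),
                    k = 2, cn_delta = 0.5, cs_max_aberrant = 0.05,
                    mq_min = 20, p_threshold = 0.05,
                    subset = c("SBS17a-proxy", "SBS17b-proxy"),
                    catalog = "bundled-proxy",
                    baseline = c("per-sample", "pooled", "none"),
                    attribution = c("supported", "enriched"),
                    alpha = 0.01, nperm = 1000, seed = 1,
                    cohort = NULL, cs_pool = NULL, paths = NULL) {
  baseline <- match.arg(baseline)
  attribution <- match.arg(attribution)
  p <- utils::modifyList(
    stats::setNames(as.list(file.path(data_dir, sim_file_names)),
                    names(sim_file_names)),
    paths %||% list())
  needed <- c("reference", "counts", "vcf", "presence", "blacklist", "cell_qc")
  missing <- needed[!vapply(p[needed], file.exists, logical(1))]
  if (length(missing)) {
    stopf("missing input file(s): %s",
          paste(sprintf("%s (%s)", missing, unlist(p[missing])), collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  reference <- read_fasta(p$reference)
  counts <- read_counts_tsv(p$counts)
  vm <- read_variant_matrix(p$presence, p$vcf)
  blacklist <- read_blacklist(p$blacklist)
  qc <- readr::read_tsv(p$cell_qc, show_col_types = FALSE, progress = FALSE)
  cat_m <- load_catalog(catalog)
  missing_sig <- setdiff(subset, colnames(cat_m))
  if (length(missing_sig)) stopf("subset signature(s) not in catalog: %s",
                                 paste(missing_sig, collapse = ", "))

  # --- copy number ---
  cn <- normalize_counts(counts)
  assignment <- cluster_cells(cn, k)
  segments <- segment_clusters(cn, assignment, alpha = alpha, nperm = nperm,
                               seed = derive_seed(seed, 20))
  assignment <- label_cs_cluster(segments, assignment, cn_delta, cs_max_aberrant)
  cin <- call_cin_regions(segments, cn_delta)

  # --- variant filter cascade ---
  vm1 <- filter_mq(vm, mq_min)
  vm2 <- remove_blacklisted(vm1, blacklist)
  vm3 <- if (!is.null(cohort)) {
    remove_ubiquitous(c(list(self = vm2), cohort))[["self"]]
  } else {
    vm_step(vm2, "ubiquitous(skipped)", rep(TRUE, nrow(vm2$variants)))
  }
  vm4 <- remove_cs_supported(vm3, assignment)
  enr <- fisher_cluster_enrichment(vm4, assignment, p_threshold)

  # --- spectra ---
  cluster_cells_of <- split(assignment$cell, assignment$cluster)
  qc_of <- function(cells) qc[match(cells, qc$cell), , drop = FALSE]
  cs_label <- assignment$cluster[assignment$is_cs][1]

  cs_cells <- cluster_cells_of[[cs_label]]
  cs_support <- vapply(vm3$variants$cells, function(x) any(x %in% cs_cells),
                       logical(1))
  cs_spec <- build_spectrum(vm3$variants[cs_support, ], reference,
                            source = cs_label, n_cells = length(cs_cells))
  cs_spec <- normalize_spectrum(cs_spec, qc_of(cs_cells)$total_reads,
                                qc_of(cs_cells)$covered_fraction)
  base_spec <- switch(baseline,
    "per-sample" = cs_spec,
    "pooled" = pooled_cs_baseline(c(list(cs_spec), cs_pool %||% list())),
    "none" = NULL)

  sets <- cluster_variant_sets(vm4, assignment, attribution, enrichment = enr)
  spectra <- list(); spectra_sub <- list()
  refit_rows <- list(); cosine_rows <- list()
  for (cl in names(cluster_cells_of)) {
    cells_cl <- cluster_cells_of[[cl]]
    vset <- if (identical(cl, cs_label)) {
      vm3$variants[cs_support, c("contig", "pos", "ref", "alt", "mq")]
    } else {
      sets[[cl]]
    }
    sp <- build_spectrum(vset, reference, source = cl,
                         n_cells = length(cells_cl))
    sp <- normalize_spectrum(sp, qc_of(cells_cl)$total_reads,
                             qc_of(cells_cl)$covered_fraction)
    spectra[[cl]] <- sp
    sub <- if (is.null(base_spec)) sp else subtract_baseline(sp, base_spec)
    spectra_sub[[cl]] <- sub
    if (sum(sub) > 0) {
      cosine_rows[[cl]] <- dplyr::mutate(cosine_similarity_profile(sub, cat_m),
                                         cluster = cl, .before = 1)
    }
    rf <- refit_signatures(sub, cat_m, subset)
    refit_rows[[cl]] <- dplyr::bind_cols(
      tibble::tibble(cluster = cl, n_variants = nrow(vset)),
      glance(rf))
  }
  refit_tbl <- dplyr::bind_rows(refit_rows)
  cosine_tbl <- dplyr::bind_rows(cosine_rows)

  # --- persist stage outputs ---
  write_counts_tsv(cn, file.path(outdir, "cn_matrix.tsv"))
  readr::write_tsv(assignment, file.path(outdir, "clusters.tsv"), progress = FALSE)
  for (cl in unique(segments$cluster)) {
    write_bed(segments[segments$cluster == cl, ],
              file.path(outdir, sprintf("segments_%s.bed", cl)))
  }
  if (nrow(cin)) {
    for (cl in unique(cin$cluster)) {
      write_bed(cin[cin$cluster == cl, ],
                file.path(outdir, sprintf("cin_%s.bed", cl)))
    }
  }
  write_variant_matrix(vm4, presence_path = file.path(outdir, "filtered_presence.tsv"))
  readr::write_tsv(enr, file.path(outdir, "fisher_tables.tsv"), progress = FALSE)
  for (cl in names(cluster_cells_of)) {
    export_enriched_vcf(enr, cl, file.path(outdir, sprintf("enriched_%s.vcf", cl)),
                        vm = vm4)
  }
  spec_tbl <- function(specs) {
    dplyr::bind_cols(tibble::tibble(channel = sbs_channels()),
                     tibble::as_tibble(lapply(specs, as.numeric)))
  }
  readr::write_tsv(spec_tbl(spectra), file.path(outdir, "spectra_raw.tsv"),
                   progress = FALSE)
  readr::write_tsv(spec_tbl(spectra_sub), file.path(outdir, "spectra_subtracted.tsv"),
                   progress = FALSE)
  readr::write_tsv(refit_tbl, file.path(outdir, "refit.tsv"), progress = FALSE)

  report <- structure(list(
    version = as.character(utils::packageVersion("cinsig")),
    params = list(k = k, cn_delta = cn_delta, cs_max_aberrant = cs_max_aberrant,
                  mq_min = mq_min, p_threshold = p_threshold, subset = subset,
                  catalog = if (is.character(catalog)) catalog else "user-matrix",
                  baseline = baseline, attribution = attribution,
                  alpha = alpha, nperm = nperm, seed = seed),
    attrition = vm4$history,
    clusters = dplyr::left_join(
      aberrant_fractions(segments, assignment, cn_delta),
      dplyr::distinct(assignment[, c("cluster", "is_cs")]), by = "cluster"),
    cs_cluster = cs_label,
    cin_regions = cin,
    cosine = cosine_tbl,
    refit = refit_tbl,
    spectra = spectra,
    spectra_subtracted = spectra_sub,
    outdir = outdir
  ), class = "cinsig_report")
  write_json(report_json(report), file.path(outdir, "report.json"))
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  report
}

report_json <- function(report) {
  r <- unclass(report)
  r$spectra <- lapply(r$spectra, as.numeric)
  r$spectra_subtracted <- lapply(r$spectra_subtracted, as.numeric)
  r
}

#' @export
print.cinsig_report <- function(x, ...) {
  cat("<cinsig_report>\n")
  cat("clusters:\n"); print(as.data.frame(x$clusters), row.names = FALSE)
  cat("filter attrition:\n"); print(as.data.frame(x$attrition), row.names = FALSE)
  cat("refit:\n")
  print(as.data.frame(x$refit[, c("cluster", "n_variants", "fraction_explained",
                                  "cosine_to_observed")]), row.names = FALSE)
  invisible(x)
}

render_report_md <- function(report) {
  cl <- report$clusters
  refit <- report$refit
  c(
    "# cinsig run report",
    "",
    sprintf("- package version: %s", report$version),
    sprintf("- parameters: %s",
            paste(sprintf("%s=%s", names(report$params),
                          vapply(report$params, function(v) paste(v, collapse = ","),
                                 character(1))),
                  collapse = "; ")),
    "",
    "## Clusters",
    "",
    "| cluster | cells | aberrant fraction | CS |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %.4f | %s |", cl$cluster, cl$n_cells,
            cl$aberrant_fraction, ifelse(cl$is_cs, "yes", "no")),
    "",
    "## Filter attrition",
    "",
    "| step | variants in | variants out |",
    "|---|---|---|",
    sprintf("| %s | %d | %d |", report$attrition$step, report$attrition$n_in,
            report$attrition$n_out),
    "",
    sprintf("## Signature refit (%s; baseline: %s)",
            paste(report$params$subset, collapse = " + "),
            report$params$baseline),
    "",
    "| cluster | variants | fraction explained | cosine |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %.4f | %.4f |", refit$cluster, refit$n_variants,
            refit$fraction_explained, refit$cosine_to_observed)
  )
}

#' Re-render the run report from persisted outputs
#'
#' Reads the persisted `report.json` and spectrum tables of a completed
#' [cmd_run()] and regenerates `report.md` without recomputing any
#' stage. Persisted spectra are validated (negative channel values are
#' rejected).
#'
#' @param outdir The `outdir` of a completed run.
#' @return The re-rendered `cinsig_report` (from persisted values).
#' @export
cmd_report <- function(outdir) {
  need <- file.path(outdir, c("report.json", "spectra_raw.tsv",
                              "spectra_subtracted.tsv", "refit.tsv"))
  for (f in need) if (!file.exists(f)) stopf("missing stage output: %s", f)
  raw <- jsonlite::read_json(file.path(outdir, "report.json"),
                             simplifyVector = TRUE)
  for (f in file.path(outdir, c("spectra_raw.tsv", "spectra_subtracted.tsv"))) {
    sp <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    vals <- as.matrix(sp[, setdiff(names(sp), "channel"), drop = FALSE])
    if (any(vals < 0)) stopf("negative spectrum value in %s", f)
    if (nrow(sp) != 96) stopf("spectrum table %s does not have 96 channels", f)
  }
  report <- structure(list(
    version = raw$version,
    params = raw$params,
    attrition = tibble::as_tibble(raw$attrition),
    clusters = tibble::as_tibble(raw$clusters),
    cs_cluster = raw$cs_cluster,
    cin_regions = tibble::as_tibble(raw$cin_regions),
    cosine = tibble::as_tibble(raw$cosine),
    refit = tibble::as_tibble(raw$refit),
    spectra = lapply(raw$spectra, function(v) mut_spectrum(unlist(v))),
    spectra_subtracted = lapply(raw$spectra_subtracted,
                                function(v) mut_spectrum(unlist(v))),
    outdir = outdir
  ), class = "cinsig_report")
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  report
}
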