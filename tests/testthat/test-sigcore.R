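test_that("SNV contexts classify with pyrimidine strand collapse", {
  ref <- c(chr1 = "AACTT", chr2 = "AAGTT", chr3 = "ACTTG")
  v <- tibble::tibble(contig = c("chr1", "chr2", "chr3"), pos = 3,
                      ref = c("C", "G", "T"), alt = c("T", "A", "G"))
  out <- classify_snv_context(v, ref)
  expect_equal(out$channel, c("A[C>T]T", "A[C>T]T", "C[T>G]T"))
})

test_that("reference mismatches error with the position; N contexts are skipped", {
  ref <- c(chr1 = "AACTT", chr2 = "ANCTG")
  bad <- tibble::tibble(contig = "chr1", pos = 3, ref = "G", alt = "A")
  expect_error(classify_snv_context(bad, ref), "chr1:3")
  ncase <- tibble::tibble(contig = "chr2", pos = 3, ref = "C", alt = "A")
  expect_warning(out <- classify_snv_context(ncase, ref), "ambiguous")
  expect_true(is.na(out$channel))
})

test_that("spectra conserve counts and are strand-collapse invariant", {
  ref <- make_reference(41, 1, 20000, 0.45)
  cfg <- sim_config(seed = 41, n_contigs = 1, contig_length = 20000,
                    bin_size = 2000,
                    clones = list(clone_spec("A", n_somatic = 400)),
                    n_cells_per_clone = 2, n_germline = 0)
  som <- simulate_variants(cfg, ref)$truth
  sp <- build_spectrum(som, ref)
  expect_equal(sum(sp), 400)
  expect_true(all(sp >= 0))

  # same variants re-expressed on the reverse-complemented genome
  L <- nchar(ref[[1]])
  ref_rc <- c(contig_1 = oracle_revcomp(ref[[1]]))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  som_rc <- dplyr::mutate(som, pos = L + 1 - pos,
                          ref = unname(comp[ref]), alt = unname(comp[alt]))
  sp_rc <- build_spectrum(som_rc, ref_rc)
  expect_equal(as.numeric(sp_rc), as.numeric(sp))

  # three identical variants -> 3 in one channel
  v3 <- tibble::tibble(contig = "chr1", pos = c(2, 2, 2), ref = "C", alt = "T")
  sp3 <- build_spectrum(v3, c(chr1 = "ACTAA"))
  expect_equal(sum(sp3), 3)
  expect_equal(unname(sp3["A[C>T]T"]), 3)

  empty <- build_spectrum(som[0, ], ref)
  expect_equal(sum(empty), 0)
})

test_that("depth normalisation applies the two linear factors", {
  sp <- mut_spectrum(stats::setNames(c(8, rep(0, 95)), sbs_channels()))
  out <- normalize_spectrum(sp, reads_per_cell = 2e5, covered_fraction = 0.02)
  expect_equal(unname(out[1]), 2)  # scale 0.5 * 0.5
  ident <- normalize_spectrum(sp, 1e5, 0.01)
  expect_equal(as.numeric(ident), as.numeric(sp))
  zero <- mut_spectrum(rep(0, 96))
  expect_equal(sum(normalize_spectrum(zero, 5e4, 0.005)), 0)
  expect_error(normalize_spectrum(sp, 1e5, 0), "covered_fraction")
})

test_that("baseline subtraction clips at zero and checks scales", {
  a <- mut_spectrum(c(5, 3, rep(1, 94)))
  b <- mut_spectrum(c(2, 4, rep(1, 94)))
  out <- subtract_baseline(a, b)
  expect_equal(as.numeric(out)[1:2], c(3, 0))
  expect_true(all(as.numeric(out) >= 0))
  expect_equal(sum(subtract_baseline(a, a)), 0)
  expect_equal(as.numeric(subtract_baseline(a, mut_spectrum(rep(0, 96)))),
               as.numeric(a))
  a_norm <- normalize_spectrum(a, 1e5, 0.01)
  expect_error(subtract_baseline(a_norm, b), "normalization")
})

test_that("the pooled CS baseline is the cell-count-weighted mean", {
  mk <- function(v1, v2, n) {
    normalize_spectrum(mut_spectrum(c(v1, v2, rep(0, 94)), n_cells = n), 1e5, 0.01)
  }
  s1 <- mk(2, 0, 10)
  s2 <- mk(0, 2, 30)
  pooled <- pooled_cs_baseline(list(s1, s2))
  expect_equal(as.numeric(pooled)[1:2], c(0.5, 1.5))
  expect_equal(as.numeric(pooled_cs_baseline(list(s1))), as.numeric(s1))
  expect_equal(as.numeric(pooled_cs_baseline(list(s2, s2))), as.numeric(s2))
  expect_error(pooled_cs_baseline(list()), "no CS spectra")
  raw <- mut_spectrum(rep(1, 96), n_cells = 5)
  expect_error(pooled_cs_baseline(list(raw)), "normalized")
})

test_that("cosine similarity is scale-invariant, detects orthogonality, errors on zero", {
  cat3 <- matrix(0, 96, 2, dimnames = list(sbs_channels(), c("sigA", "sigB")))
  cat3[1, "sigA"] <- 1
  cat3[c(1, 3), "sigB"] <- 0.5
  sp_vec <- rep(0, 96); sp_vec[c(1, 2)] <- 1
  sp <- mut_spectrum(sp_vec)
  prof <- cosine_similarity_profile(sp, cat3)
  expect_equal(prof$cosine[prof$signature == "sigB"], 0.5)  # 1/(sqrt2*sqrt2)
  prof10 <- cosine_similarity_profile(mut_spectrum(10 * sp_vec), cat3)
  expect_equal(prof$cosine, prof10$cosine)

  ortho <- rep(0, 96); ortho[5] <- 2
  expect_equal(cosine_similarity_profile(mut_spectrum(ortho), cat3)$cosine, c(0, 0))
  expect_error(cosine_similarity_profile(mut_spectrum(rep(0, 96)), cat3),
               "all-zero")
  # a spectrum equal to a scaled catalog signature has similarity 1
  cat_px <- load_catalog("bundled-proxy")
  sp17 <- mut_spectrum(500 * cat_px[, "SBS17a-proxy"])
  expect_equal(cosine_similarity_profile(sp17, cat_px)$cosine[1], 1)
})

test_that("the refit recovers exact non-negative combinations", {
  cat_px <- load_catalog("bundled-proxy")
  obs <- mut_spectrum(600 * cat_px[, "SBS17a-proxy"] + 400 * cat_px[, "SBS17b-proxy"])
  fit <- refit_signatures(obs, cat_px, c("SBS17a-proxy", "SBS17b-proxy"))
  expect_equal(unname(fit$contributions), c(600, 400), tolerance = 1e-6)
  expect_equal(fit$fraction_explained, 1, tolerance = 1e-6)
  expect_equal(fit$cosine_to_observed, 1, tolerance = 1e-9)
  expect_equal(as.numeric(fit$reconstructed), as.numeric(obs), tolerance = 1e-6)

  # orthogonal target: point-mass catalog cannot explain a disjoint spectrum
  pt <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "pt"))
  pt[1, 1] <- 1
  disjoint <- rep(0, 96); disjoint[50] <- 100
  fit0 <- refit_signatures(mut_spectrum(disjoint), load_catalog(pt), "pt")
  expect_equal(unname(fit0$contributions), 0)
  expect_equal(fit0$fraction_explained, 0)

  fitz <- refit_signatures(mut_spectrum(rep(0, 96)), cat_px, "SBS17a-proxy")
  expect_equal(fitz$fraction_explained, 0)

  td <- tidy(fit); gl <- glance(fit)
  expect_equal(td$proportion, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(gl$fraction_explained, 1, tolerance = 1e-6)
})

test_that("bundled proxy signatures are built as documented and catalogs validate", {
  cat_px <- load_catalog("bundled-proxy")
  expect_equal(colSums(cat_px), stats::setNames(rep(1, 4), colnames(cat_px)))
  a <- cat_px[, "SBS17a-proxy"]
  expect_equal(unname(a["C[T>C]T"]), 0.90)
  expect_equal(unname(a["A[C>A]A"]), 0.10 / 95)
  b <- cat_px[, "SBS17b-proxy"]
  expect_equal(unname(b[paste0(c("A", "C", "G", "T"), "[T>G]T")]), rep(0.225, 4))
  expect_equal(unname(b["A[C>A]A"]), 0.10 / 92)
  expect_equal(unname(cat_px[, "flat-proxy"]), rep(1 / 96, 96))
  ck <- cat_px[, "clocklike-proxy"]
  expect_equal(sum(ck[paste0(c("A", "C", "G", "T"), "[C>T]G")]), 0.9)

  # catalog file round trip and validation
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(Type = sbs_channels(),
                        S1 = as.numeric(cat_px[, 1]), S2 = as.numeric(cat_px[, 2]))
  readr::write_tsv(tab, f)
  back <- load_catalog(f)
  expect_equal(unname(back[, "S1"]), unname(cat_px[, 1]), tolerance = 1e-12)

  f95 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab[1:95, ], f95)
  expect_error(load_catalog(f95), "96")
  fneg <- withr::local_tempfile(fileext = ".tsv")
  tabn <- tab; tabn$S1[1] <- -0.1
  readr::write_tsv(tabn, fneg)
  expect_error(load_catalog(fneg), "non-negative")
  fbad <- withr::local_tempfile(fileext = ".tsv")
  tabb <- tab; tabb$Type[1] <- "X[C>A]A"
  readr::write_tsv(tabb, fbad)
  expect_error(load_catalog(fbad), "unknown channel")
})

test_that("INDELs classify into homopolymer and repeat channels", {
  ref <- c(c1 = "AACTTTTGAA", c2 = "TACGATTTTT", c3 = "GGATATATCC")
  cases <- tibble::tibble(
    contig = c("c1", "c2", "c3", "c2", "c1"),
    pos = c(4, 3, 8, 5, 2),
    type = c("ins", "del", "ins", "ins", "del"),
    seq = c("T", "C", "AT", "A", "A"))
  out <- classify_indel(cases, ref)
  expect_equal(out$channel, c(
    "ins_T_hp4",   # T inserted at a TTTT run
    "del_C_hp1",   # C deleted from ACG
    "ins_rep_3+",  # AT inserted after ATATAT (3 preceding copies)
    "ins_T_hp1",   # A collapses to T; no adjacent A run
    "del_T_hp2"))  # A (collapsed to T) deleted from an AA run

  expect_error(
    classify_indel(tibble::tibble(contig = "c1", pos = 4, type = "del", seq = "G"),
                   ref),
    "does not match")

  sp <- build_indel_spectrum(cases, ref)
  expect_equal(sum(sp), nrow(cases))
  expect_named(sp, indel_channels())
})
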