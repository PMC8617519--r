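test_that("reference generation is deterministic per seed and seed-sensitive", {
  r1 <- make_reference(1, n_contigs = 2, contig_length = 1e4, gc_fraction = 0.4)
  r2 <- make_reference(1, n_contigs = 2, contig_length = 1e4, gc_fraction = 0.4)
  r3 <- make_reference(2, n_contigs = 2, contig_length = 1e4, gc_fraction = 0.4)
  expect_identical(r1, r2)
  expect_false(identical(unname(r1), unname(r3)))
  expect_equal(unname(nchar(r1)), c(1e4, 1e4))
  expect_named(r1, c("contig_1", "contig_2"))
})

test_that("every pyrimidine-centred trinucleotide occurs in each contig", {
  ref <- make_reference(7, n_contigs = 2, contig_length = 12000, gc_fraction = 0.3)
  for (s in ref) {
    # oracle: enumerate all windows, collapse purine centres by hand
    tri <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    centre <- substr(tri, 2, 2)
    collapsed <- ifelse(centre %in% c("A", "G"),
                        vapply(tri, oracle_revcomp, character(1)), tri)
    expect_length(unique(collapsed), 32)
  }
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(coverage_fraction_range = c(0.5, 0.1)), "low <= high")
  expect_error(sim_config(coverage_fraction_range = c(-0.1, 0.5)), "within")
  expect_error(sim_config(contig_length = 5e4, bin_size = 1e4), "10 \\* bin_size")
  gap <- tibble::tibble(contig = "contig_1", start = 0, end = 1e6, copy_number = 1L)
  expect_error(
    sim_config(clones = list(clone_spec("bad", karyotype = gap, n_somatic = 0))),
    "tile")
  expect_error(clone_spec("x", signature_mixture = c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(clone_spec("x", signature_mixture = c(a = -0.5, b = 1.5)),
               "non-negative")
})

test_that("bin counts follow the clone karyotype in expectation", {
  kar <- tibble::tibble(contig = c("contig_1", "contig_2"),
                        start = 0, end = 3e5, copy_number = c(4L, 2L))
  cfg <- sim_config(seed = 11, n_contigs = 2, contig_length = 3e5, bin_size = 2e4,
                    clones = list(clone_spec("G", karyotype = kar)),
                    n_cells_per_clone = 50, mean_reads_per_cell = 2e4,
                    overdispersion = 10)
  ref <- make_reference(11, 2, 3e5, 0.4)
  sim <- simulate_cells(cfg, ref)
  cells <- sim$truth$cell
  m <- as.matrix(sim$counts[, cells])
  cn4 <- sim$counts$contig == "contig_1"
  ratio <- mean(m[cn4, ]) / mean(m[!cn4, ])
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
  # uniform diploid clone: every bin expectation equal
  cfg2 <- sim_config(seed = 12, n_contigs = 1, contig_length = 3e5, bin_size = 2e4,
                     clones = list(clone_spec("D")), n_cells_per_clone = 60,
                     mean_reads_per_cell = 15 * 1000, overdispersion = 1e4)
  sim2 <- simulate_cells(cfg2, make_reference(12, 1, 3e5, 0.4))
  bin_means <- rowMeans(as.matrix(sim2$counts[, sim2$truth$cell]))
  expect_true(all(abs(bin_means - 1000) / 1000 < 0.15))
})

test_that("a clone with zero cells yields no columns and no error", {
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 2e5, bin_size = 2e4,
                    clones = list(clone_spec("A"), clone_spec("B")),
                    n_cells_per_clone = c(0L, 5L), n_germline = 10)
  ref <- make_reference(5, 1, 2e5, 0.4)
  sim <- simulate_cells(cfg, ref)
  expect_equal(nrow(sim$truth), 5)
  expect_setequal(unique(sim$truth$clone), "B")
})

test_that("degenerate point-mass mixture puts every somatic variant in its channel", {
  point <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "pointA"))
  point["C[T>C]T", 1] <- 1
  cfg <- sim_config(seed = 3, n_contigs = 1, contig_length = 2e5, bin_size = 2e4,
                    clones = list(clone_spec("P", n_somatic = 50,
                                             signature_mixture = c(pointA = 1))),
                    n_cells_per_clone = 4, n_germline = 0,
                    catalog = load_catalog(point))
  ref <- make_reference(3, 1, 2e5, 0.4)
  vars <- simulate_variants(cfg, ref)
  som <- vars$truth[!vars$truth$germline, ]
  expect_equal(nrow(som), 50)
  expect_true(all(som$channel == "C[T>C]T"))
  # placements really carry the context on the reference
  cls <- classify_snv_context(som, ref)
  expect_true(all(cls$channel == "C[T>C]T"))
})

test_that("full coverage means every clone cell observes every clone variant", {
  cfg <- sim_config(seed = 8, n_contigs = 1, contig_length = 2e5, bin_size = 2e4,
                    clones = list(clone_spec("A", n_somatic = 30)),
                    n_cells_per_clone = 6, coverage_fraction_range = c(1, 1),
                    n_germline = 5)
  ref <- make_reference(8, 1, 2e5, 0.4)
  vars <- simulate_variants(cfg, ref)
  expect_true(all(lengths(vars$variants$variants$cells) == 6))
})

test_that("sparse coverage observation matches the Bernoulli expectation", {
  cfg <- sim_config(seed = 9, n_contigs = 2, contig_length = 1e6, bin_size = 5e4,
                    clones = list(clone_spec("A", n_somatic = 500)),
                    n_cells_per_clone = 100,
                    coverage_fraction_range = c(0.01, 0.01), n_germline = 0)
  ref <- make_reference(9, 2, 1e6, 0.4)
  vars <- simulate_variants(cfg, ref)
  obs <- lengths(vars$variants$variants$cells)
  # each variant observed Binomial(100, 0.01): mean 1, SE of the mean over
  # 500 variants = sqrt(100 * 0.01 * 0.99 / 500)
  se <- sqrt(100 * 0.01 * 0.99 / 500)
  expect_lt(abs(mean(obs) - 1), 3 * se)
})

test_that("truth conserves counts and germline variants are carried by all clones", {
  cfg <- small_sim_config(seed = 21)
  ref <- make_reference(21, 2, 3e5, 0.4)
  vars <- simulate_variants(cfg, ref)
  tt <- vars$truth
  expect_equal(sum(!tt$germline), 150 + 300)
  expect_equal(sum(tt$germline), 80)
  expect_equal(anyDuplicated(tt$key), 0)
  # a germline variant can be observed in cells of both clones
  roster_clones <- c("CS", "CIN")
  gl_keys <- tt$key[tt$germline]
  vm <- vars$variants
  gl_cells <- unlist(vm$variants$cells[match(gl_keys, paste(vm$variants$contig,
                                                            vm$variants$pos,
                                                            vm$variants$ref,
                                                            vm$variants$alt,
                                                            sep = ":"))])
  expect_gt(length(gl_cells), 0)
})

test_that("simulated channel frequencies recover the requested mixture", {
  cfg <- sim_config(seed = 13, n_contigs = 2, contig_length = 1e6, bin_size = 5e4,
                    clones = list(clone_spec("mix", n_somatic = 6000,
                      signature_mixture = c("SBS17a-proxy" = 0.45,
                                            "SBS17b-proxy" = 0.45,
                                            "flat-proxy" = 0.10))),
                    n_cells_per_clone = 2, n_germline = 0)
  ref <- make_reference(13, 2, 1e6, 0.4)
  vars <- simulate_variants(cfg, ref)
  som <- vars$truth[!vars$truth$germline, ]
  emp <- as.numeric(table(factor(som$channel, levels = sbs_channels()))) / nrow(som)
  cat_m <- load_catalog("bundled-proxy")
  target <- as.numeric(cat_m[, c("SBS17a-proxy", "SBS17b-proxy", "flat-proxy")] %*%
                         c(0.45, 0.45, 0.10))
  expect_lte(sum(abs(emp - target)), 0.08)
})

test_that("identical configs reproduce byte-identical datasets", {
  cfg <- sim_config(seed = 77, n_contigs = 1, contig_length = 1.2e5, bin_size = 1e4,
                    clones = list(clone_spec("A", n_somatic = 40)),
                    n_cells_per_clone = 5, n_germline = 10)
  d1 <- file.path(tempdir(), "simrep1")
  d2 <- file.path(tempdir(), "simrep2")
  cmd_simulate(cfg, d1)
  cmd_simulate(cfg, d2)
  for (f in c("reference.fa", "counts.tsv", "variants.vcf", "presence.tsv",
              "blacklist.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
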