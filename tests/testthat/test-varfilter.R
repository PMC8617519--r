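cells6 <- paste0("cell_", 1:6)

test_that("the MQ filter is strictly greater-than and drops unqualifiable variants", {
  vm <- toy_vm(list("cell_1", "cell_2", "cell_3"), cells6,
               mq = c(20, 21, NA))
  expect_warning(out <- filter_mq(vm, 20), "without MQ")
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$mq, 21)
  expect_equal(out$history$step, "mq>20")

  empty <- toy_vm(list(), cells6)
  expect_equal(nrow(filter_mq(empty, 20)$variants), 0)
})

test_that("the VAF filter is strict and refuses VAF-less input", {
  vm <- toy_vm(list("cell_1", "cell_1", "cell_1"), cells6,
               vaf = c(0.5, 0.3, 0.0))
  out <- filter_vaf(vm, 0.3)
  expect_equal(out$variants$vaf, 0.5)
  no_vaf <- toy_vm(list("cell_1"), cells6)
  expect_error(filter_vaf(no_vaf, 0.3), "whole-genome")
})

test_that("blacklist removal is allele-exact", {
  vm <- toy_vm(list("cell_1", "cell_2"), cells6, pos = c(100, 100))
  # rows: 100 C>T and 100 T>G (from toy_vm allele cycling)
  bl <- tibble::tibble(contig = "contig_1", pos = 100, ref = "C", alt = "T")
  out <- remove_blacklisted(vm, bl)
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$ref, "T")
  # empty blacklist is the identity
  out2 <- remove_blacklisted(vm, bl[0, ])
  expect_equal(nrow(out2$variants), 2)
})

test_that("malformed blacklist files are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt", "c1\t100\tC\tT", "c1\tbroken"), f)
  expect_error(read_blacklist(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tr\ta"), f2)
  expect_error(read_blacklist(f2), "header")
})

test_that("variants observed in every patient are removed everywhere", {
  mk <- function(supports) toy_vm(supports, cells6, pos = c(100, 200, 300))
  p1 <- mk(list("cell_1", "cell_2", "cell_3"))
  p2 <- mk(list("cell_1", "cell_2", character(0)))
  p3 <- mk(list("cell_1", character(0), "cell_3"))
  out <- remove_ubiquitous(list(a = p1, b = p2, c = p3))
  # pos 100 observed in 3/3 -> gone from all; pos 200 in 2/3 -> retained
  expect_false(100 %in% out$a$variants$pos)
  expect_false(100 %in% out$b$variants$pos)
  expect_true(200 %in% out$a$variants$pos)
  expect_true(300 %in% out$a$variants$pos)
  expect_warning(remove_ubiquitous(list(a = p1)), "two patients")
})

test_that("CS-supported and unobserved variants are removed", {
  asg <- tibble::tibble(cell = cells6,
                        cluster = rep(c("cluster_1", "cluster_2"), each = 3),
                        is_cs = rep(c(TRUE, FALSE), each = 3))
  vm <- toy_vm(list(c("cell_1", "cell_4", "cell_5"),  # 1 CS + 2 CIN cells
                    c("cell_4", "cell_5"),            # CIN only
                    character(0)),                    # unobserved
               cells6)
  out <- remove_cs_supported(vm, asg)
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$cells[[1]], c("cell_4", "cell_5"))
  asg_none <- dplyr::mutate(asg, is_cs = FALSE)
  expect_error(remove_cs_supported(vm, asg_none), "no chromosomally stable")
})

test_that("one-sided Fisher p-values match exhaustive hypergeometric enumeration", {
  asg <- tibble::tibble(cell = paste0("cell_", 1:20),
                        cluster = rep(c("cluster_1", "cluster_2"), each = 10),
                        is_cs = NA)
  # [[8,2],[1,9]]: 8 of 10 in-cluster cells carry, 1 of 10 outside
  vm <- toy_vm(list(paste0("cell_", c(1:8, 11)),
                    paste0("cell_", c(1:5, 11:15)),   # 5 vs 5: no signal
                    character(0)),
               paste0("cell_", 1:20))
  enr <- fisher_cluster_enrichment(vm, asg, p_threshold = 0.05)
  e1 <- enr[enr$cluster == "cluster_1", ]
  expect_equal(e1$p_value[1], oracle_fisher_greater(8, 2, 1, 9), tolerance = 1e-12)
  expect_true(e1$enriched[1])
  expect_equal(e1$p_value[2], oracle_fisher_greater(5, 5, 5, 5), tolerance = 1e-12)
  expect_false(e1$enriched[2])
  # unobserved variant: p = 1
  expect_equal(e1$p_value[3], 1)
  expect_false(e1$enriched[3])
})

test_that("one-sided p agrees with fisher.test on random tables", {
  set.seed(7)
  asg <- tibble::tibble(cell = paste0("cell_", 1:12),
                        cluster = rep(c("cluster_1", "cluster_2"), each = 6),
                        is_cs = NA)
  for (r in 1:25) {
    supp <- sample(paste0("cell_", 1:12), sample(0:12, 1))
    vm <- toy_vm(list(supp), paste0("cell_", 1:12))
    enr <- fisher_cluster_enrichment(vm, asg)
    a <- sum(supp %in% paste0("cell_", 1:6))
    ft <- stats::fisher.test(matrix(c(a, 6 - a, length(supp) - a,
                                      6 - (length(supp) - a)), 2),
                             alternative = "greater")
    expect_equal(enr$p_value[enr$cluster == "cluster_1"], ft$p.value,
                 tolerance = 1e-12)
  }
})

test_that("raising the p threshold never shrinks an enriched set", {
  set.seed(8)
  asg <- tibble::tibble(cell = paste0("cell_", 1:16),
                        cluster = rep(c("cluster_1", "cluster_2"), each = 8),
                        is_cs = NA)
  supports <- lapply(1:30, function(i) sample(paste0("cell_", 1:16), sample(0:16, 1)))
  vm <- toy_vm(supports, paste0("cell_", 1:16),
               pos = seq(100, by = 10, length.out = 30))
  prev <- NULL
  for (th in c(0.01, 0.05, 0.2, 0.5)) {
    enr <- fisher_cluster_enrichment(vm, asg, p_threshold = th)
    cur <- enr$key[enr$enriched]
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("filters are idempotent and history is append-only", {
  vm <- toy_vm(list("cell_1", "cell_2", "cell_3"), cells6, mq = c(10, 30, 50))
  once <- filter_mq(vm, 20)
  twice <- filter_mq(once, 20)
  expect_equal(twice$variants, once$variants)
  expect_equal(nrow(twice$history), 2)
  bl <- tibble::tibble(contig = "contig_1", pos = 110, ref = "T", alt = "G")
  b1 <- remove_blacklisted(once, bl)
  expect_equal(remove_blacklisted(b1, bl)$variants, b1$variants)
})

test_that("enriched variants export to a valid, ordered, re-parsable VCF", {
  asg <- tibble::tibble(cell = paste0("cell_", 1:10),
                        cluster = rep(c("cluster_1", "cluster_2"), each = 5),
                        is_cs = NA)
  vm <- toy_vm(list(paste0("cell_", 1:5), paste0("cell_", 1:5), "cell_6"),
               paste0("cell_", 1:10), pos = c(500, 120, 300))
  enr <- fisher_cluster_enrichment(vm, asg, p_threshold = 0.05)
  f <- withr::local_tempfile(fileext = ".vcf")
  export_enriched_vcf(enr, "cluster_1", f, vm = vm)
  parsed <- read_minimal_vcf(f)
  expect_equal(parsed$pos, c(120, 500))  # sorted
  keys_in <- enr$key[enr$cluster == "cluster_1" & enr$enriched]
  expect_setequal(paste(parsed$contig, parsed$pos, parsed$ref, parsed$alt, sep = ":"),
                  keys_in)
  expect_true(all(grepl("CLUSTER=cluster_1", parsed$info)))
  expect_true(all(grepl("FISHER_P=", parsed$info)))

  # independent parser agrees on the exported records
  v_ext <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(vcfR::getPOS(v_ext), parsed$pos)
  expect_equal(vcfR::getREF(v_ext), parsed$ref)
  expect_equal(vcfR::getALT(v_ext), parsed$alt)

  # empty export: header-only but valid
  f2 <- withr::local_tempfile(fileext = ".vcf")
  export_enriched_vcf(enr, "cluster_2", f2, vm = vm)
  parsed2 <- read_minimal_vcf(f2)
  expect_equal(nrow(parsed2), 0)
  expect_true(any(startsWith(readLines(f2), "##fileformat=VCFv4.2")))
})
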