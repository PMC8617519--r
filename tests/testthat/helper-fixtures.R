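# Shared fixtures and independent oracles, built in code at test time.

# Adjusted Rand index between two labellings (independent implementation
# from the contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Reverse complement without package code (oracle for strand collapse).
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive one-sided Fisher p: sum of hypergeometric point masses
# P(X >= a) computed from binomial coefficients directly.
oracle_fisher_greater <- function(a, b, c, d) {
  # table [[a, b], [c, d]]: a carriers in cluster, cluster size a+b,
  # carriers total a+c, N = a+b+c+d
  K <- a + c
  n_in <- a + b
  N <- a + b + c + d
  xs <- max(0, K + n_in - N):min(K, n_in)
  p_point <- choose(K, xs) * choose(N - K, n_in - xs) / choose(N, n_in)
  sum(p_point[xs >= a])
}

# Brute-force arc search: double loop over (i, j], pooled-sd t statistic.
oracle_best_arc <- function(x, min_width = 2) {
  n <- length(x)
  best <- NULL
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      m <- j - i
      if (m < min_width || n - m < min_width) next
      inside <- x[(i + 1):j]
      outside <- x[-((i + 1):j)]
      sse <- sum((inside - mean(inside))^2) + sum((outside - mean(outside))^2)
      sd2 <- sse / max(n - 2, 1)
      se <- sqrt(sd2 * (1 / m + 1 / (n - m)))
      stat <- if (se == 0) {
        if (abs(mean(inside) - mean(outside)) > 0) Inf else 0
      } else {
        abs(mean(inside) - mean(outside)) / se
      }
      if (is.null(best) || stat > best$stat) best <- list(i = i, j = j, stat = stat)
    }
  }
  best
}

# A tiny two-clone config for pipeline-level tests: small genome, low
# count noise, generous per-cell coverage so per-cluster variant sets
# are non-trivial at 12 cells per clone.
small_sim_config <- function(seed = 4242) {
  kar <- tibble::tibble(contig = "contig_1", start = c(0, 2e5),
                        end = c(2e5, 3e5), copy_number = c(1L, 2L))
  sim_config(
    seed = seed, n_contigs = 2, contig_length = 3e5, bin_size = 2e4,
    clones = list(
      clone_spec("CS", n_somatic = 150,
                 signature_mixture = c("clocklike-proxy" = 0.7, "flat-proxy" = 0.3)),
      clone_spec("CIN", karyotype = kar, n_somatic = 300,
                 signature_mixture = c("SBS17a-proxy" = 0.45, "SBS17b-proxy" = 0.45,
                                       "flat-proxy" = 0.10))
    ),
    n_cells_per_clone = c(12L, 12L),
    mean_reads_per_cell = 2e4,
    coverage_fraction_range = c(0.05, 0.1),
    n_germline = 80,
    overdispersion = 50
  )
}

# Toy variant matrix: explicit supports over a named cell universe.
toy_vm <- function(supports, cells, mq = NULL, vaf = NULL, pos = NULL) {
  n <- length(supports)
  v <- tibble::tibble(
    contig = "contig_1",
    pos = pos %||% seq(100, by = 10, length.out = n),
    ref = rep(c("C", "T"), length.out = n),
    alt = rep(c("T", "G"), length.out = n),
    mq = mq %||% rep(60, n),
    cells = supports
  )
  if (!is.null(vaf)) v$vaf <- vaf
  variant_matrix(v, cells = cells)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# One cached default-conditions dataset + pipeline run, shared by the
# acceptance suite (simulated fresh per session, never stored on disk).
.accept_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.accept_cache$res)) return(.accept_cache$res)
  dir <- file.path(tempdir(), "cinsig-acceptance")
  sim <- cmd_simulate(default_sim_config(seed = 101), dir)
  report <- cmd_run(dir, k = 2, seed = 101)
  .accept_cache$res <- list(dir = dir, sim = sim, report = report)
  .accept_cache$res
}
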