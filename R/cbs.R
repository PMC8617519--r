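# Circular binary segmentation of copy-number profiles.

# All arc statistics for one contig profile. Arcs are (i, j],
# 0 <= i < j <= n; the t-like statistic contrasts bins inside the arc
# against all bins outside. Returns the maximising arc and its |T|,
# or NULL if no arc satisfies the width constraint.
arc_max <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(NULL)
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  jm <- matrix(0:n, n + 1, n + 1, byrow = TRUE)
  im <- matrix(0:n, n + 1, n + 1)
  m <- jm - im
  valid <- m >= min_width & (n - m) >= min_width
  if (!any(valid)) return(NULL)

  sum_in <- matrix(S[jm + 1], n + 1) - matrix(S[im + 1], n + 1)
  ss_in <- matrix(S2[jm + 1], n + 1) - matrix(S2[im + 1], n + 1)
  m_out <- n - m
  sum_out <- S[n + 1] - sum_in
  ss_out <- S2[n + 1] - ss_in

  mean_in <- sum_in / m
  mean_out <- sum_out / m_out
  sse <- pmax(ss_in - sum_in^2 / m, 0) + pmax(ss_out - sum_out^2 / m_out, 0)
  sd2 <- sse / pmax(n - 2, 1)
  se <- suppressWarnings(sqrt(sd2 * (1 / m + 1 / m_out)))
  diff <- mean_in - mean_out
  tt <- abs(diff) / se
  zero_se <- valid & !is.na(se) & se == 0
  tt[zero_se] <- ifelse(abs(diff)[zero_se] > 0, Inf, 0)
  tt[!valid | is.na(tt)] <- -Inf

  k <- which.max(tt)  # column-major: deterministic tie-break
  list(i = im[k], j = jm[k], stat = tt[k])
}

# Max arc statistic only (used on permuted profiles).
arc_max_stat <- function(x, min_width) {
  b <- arc_max(x, min_width)
  if (is.null(b)) -Inf else b$stat
}

#' Best segmentation arc of a single profile
#'
#' The maximising arc `(i, j]` of the circular-binary-segmentation
#' statistic on one vector of bin values, before any significance
#' testing — exposed so the arc search can be inspected and checked
#' against exhaustive enumeration.
#'
#' @param x Numeric vector of bin values (one contig).
#' @param min_width Minimum bins inside and outside the arc.
#' @return A one-row tibble `(i, j, stat)` (`i`/`j` are 0-based arc
#'   bounds; bins `i+1 .. j` lie inside), or `NULL` when no arc
#'   satisfies the width constraint.
#' @export
cbs_best_arc <- function(x, min_width = 2) {
  b <- arc_max(as.numeric(x), min_width)
  if (is.null(b)) return(NULL)
  tibble::tibble(i = b$i, j = b$j, stat = b$stat)
}

# Recursive CBS on one contig. Returns integer breakpoints (bin indices
# after which a new segment starts, excluding 0 and n).
cbs_breakpoints <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  best <- arc_max(x, min_width)
  if (is.null(best) || best$stat <= 0) return(integer(0))
  exceed <- 0L
  thr <- best$stat * (1 + 1e-9) + 1e-12  # ulp guard: ties are not exceedances
  for (b in seq_len(nperm)) {
    if (arc_max_stat(sample(x), min_width) > thr) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (nperm + 1)
  if (p >= alpha) return(integer(0))
  cuts <- setdiff(c(best$i, best$j), c(0L, n))
  bounds <- c(0L, sort(cuts), n)
  out <- cuts
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    out <- c(out, lo + cbs_breakpoints(x[(lo + 1):hi], alpha, nperm, min_width))
  }
  sort(unique(out))
}

#' Segment a copy-number profile by circular binary segmentation
#'
#' Recursive change-point search: on each contig, the arc `(i, j]`
#' maximising a two-sample t-like statistic between bins inside and
#' outside the arc is tested by a permutation test; if significant, the
#' profile is split there and the search recurses on each piece.
#' Significance counts permutations whose maximal statistic strictly
#' exceeds the observed one, so that re-creations of the observed
#' partition itself do not mask a split on short contigs.
#'
#' @param profile Either a tibble `(contig, start, end, weight, value)`
#'   (one row per bin, as produced by [cluster_mean_profiles()]) or a
#'   plain numeric vector (treated as one contig of unit bins).
#' @param alpha Permutation p-value threshold for accepting a split.
#' @param nperm Number of permutations.
#' @param min_width Minimum segment width in bins.
#' @param seed Optional seed for the permutation RNG (scoped to this
#'   call).
#' @return Tibble `(contig, start, end, n_bins, weight, mean_cn)`;
#'   segments tile the binned genome.
#' @export
#' @examples
#' cbs_segment(c(2, 2, 2, 4, 4, 4) + rnorm(6, sd = 0.01), nperm = 200)
cbs_segment <- function(profile, alpha = 0.01, nperm = 1000, min_width = 2,
                        seed = NULL) {
  if (is.numeric(profile)) {
    profile <- tibble::tibble(contig = "contig_1",
                              start = seq_along(profile) - 1,
                              end = seq_along(profile),
                              weight = 1, value = as.numeric(profile))
  }
  stopifnot(all(c("contig", "start", "end", "value") %in% names(profile)))
  if (!"weight" %in% names(profile)) profile$weight <- 1
  with_seed(seed, {
    parts <- lapply(unique(profile$contig), function(ct) {
      p <- profile[profile$contig == ct, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      bp <- cbs_breakpoints(p$value, alpha, nperm, min_width)
      bounds <- c(0L, bp, nrow(p))
      segs <- lapply(seq_len(length(bounds) - 1), function(k) {
        idx <- (bounds[k] + 1):bounds[k + 1]
        tibble::tibble(contig = ct, start = p$start[idx[1]],
                       end = p$end[idx[length(idx)]],
                       n_bins = length(idx), weight = sum(p$weight[idx]),
                       mean_cn = mean(p$value[idx]))
      })
      dplyr::bind_rows(segs)
    })
    dplyr::bind_rows(parts)
  })
}
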