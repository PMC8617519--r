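# Site indexing and variant simulation.

# For each contig, the collapsed trinucleotide code of every internal
# position (2 .. n-1), as an integer vector; NA where the triplet holds
# a non-ACGT base.
contig_trinuc_codes <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], BASES) - 1L
  n <- length(codes)
  collapse_trinuc_code(codes[1:(n - 2L)], codes[2:(n - 1L)], codes[3:n])
}

# Eligible-site index: list keyed by collapsed trinucleotide code
# ("t0".."t63"), each a tibble (contig, pos) of 1-based positions.
build_site_index <- function(reference) {
  per_contig <- lapply(names(reference), function(ct) {
    tri <- contig_trinuc_codes(reference[[ct]])
    pos <- which(!is.na(tri)) + 1L
    tibble::tibble(contig = ct, pos = pos, code = tri[pos - 1L])
  })
  all <- dplyr::bind_rows(per_contig)
  split(all[c("contig", "pos")], paste0("t", all$code))
}

#' Simulate germline and clonal somatic variants
#'
#' Somatic variants are drawn channel-first: each clone's 96-channel
#' probability vector (its signature mixture times the catalog) feeds a
#' multinomial over channels, and each drawn channel is placed uniformly
#' on an unused reference site with the matching pyrimidine-collapsed
#' trinucleotide. Germline SNPs are placed uniformly and carried by all
#' cells. A cell observes a variant carried by its clone with
#' probability equal to its covered genome fraction.
#'
#' @param config A [sim_config()].
#' @param reference The matching [make_reference()] genome.
#' @return List with `variants` (a [variant_matrix()]) and `truth`
#'   (tibble: `key, contig, pos, ref, alt, clone, channel, germline`;
#'   every emitted variant appears exactly once).
#' @export
simulate_variants <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  roster <- cell_roster(config)
  cat_m <- catalog_matrix(load_catalog(config$catalog))
  ch_tab <- channel_table()

  with_seed(derive_seed(config$seed, 3), {
    index <- build_site_index(reference)
    used <- lapply(reference, function(s) logical(nchar(s)))

    draw_sites <- function(code, n, channel) {
      key <- paste0("t", code)
      sites <- index[[key]]
      if (!is.null(sites) && nrow(sites)) {
        avail <- rep(TRUE, nrow(sites))
        for (ct in unique(sites$contig)) {
          ii <- sites$contig == ct
          avail[ii] <- !used[[ct]][sites$pos[ii]]
        }
        sites <- sites[avail, , drop = FALSE]
      }
      if (is.null(sites) || nrow(sites) < n) {
        stopf("not enough eligible reference sites for channel %s (need %d, have %d)",
              channel, n, if (is.null(sites)) 0L else nrow(sites))
      }
      take <- sites[sample.int(nrow(sites), n), , drop = FALSE]
      for (i in seq_len(n)) used[[take$contig[i]]][take$pos[i]] <<- TRUE
      take
    }

    rows <- list()
    for (cl in config$clones) {
      p <- drop(cat_m[, names(cl$signature_mixture), drop = FALSE] %*%
                  cl$signature_mixture)
      n_by_channel <- drop(stats::rmultinom(1, cl$n_somatic, p))
      for (j in which(n_by_channel > 0)) {
        sites <- draw_sites(ch_tab$trinuc_code[j], n_by_channel[j], ch_tab$channel[j])
        base <- substr(reference[sites$contig], sites$pos, sites$pos)
        pyr <- base == ch_tab$ref[j]
        rows[[length(rows) + 1]] <- tibble::tibble(
          contig = sites$contig, pos = sites$pos,
          ref = base,
          alt = ifelse(pyr, ch_tab$alt[j], complement_base(ch_tab$alt[j])),
          clone = cl$name, channel = ch_tab$channel[j], germline = FALSE
        )
      }
    }

    # germline SNPs: uniform over unused internal positions
    if (config$n_germline > 0) {
      g <- list()
      n_done <- 0L
      lens <- nchar(reference)
      while (n_done < config$n_germline) {
        ct <- sample(names(reference), 1, prob = lens)
        p <- sample.int(lens[[ct]] - 2L, 1) + 1L
        if (used[[ct]][p]) next
        base <- substr(reference[[ct]], p, p)
        if (!base %in% BASES) next
        used[[ct]][p] <- TRUE
        alt <- sample(setdiff(BASES, base), 1)
        n_done <- n_done + 1L
        g[[n_done]] <- tibble::tibble(contig = ct, pos = p, ref = base, alt = alt,
                                      clone = NA_character_, channel = NA_character_,
                                      germline = TRUE)
      }
      rows <- c(rows, g)
    }

    truth <- dplyr::bind_rows(rows)
    truth <- truth[order(truth$contig, truth$pos), , drop = FALSE]
    truth$key <- variant_key(truth$contig, truth$pos, truth$ref, truth$alt)

    # mapping quality: mostly well-mapped, a configurable low-MQ tail
    nv <- nrow(truth)
    low <- stats::runif(nv) < config$low_mq_fraction
    mq <- ifelse(low, stats::runif(nv, 0, 20), stats::runif(nv, 30, 60))

    # per-cell Bernoulli observation at the cell's covered fraction
    supports <- vector("list", nv)
    for (i in seq_len(nv)) supports[[i]] <- character(0)
    clone_names <- c(vapply(config$clones, `[[`, character(1), "name"))
    for (cl_name in clone_names) {
      cells_cl <- roster[roster$clone == cl_name, , drop = FALSE]
      vi <- which(truth$germline | truth$clone == cl_name)
      if (!nrow(cells_cl) || !length(vi)) next
      obs <- matrix(stats::rbinom(length(vi) * nrow(cells_cl), 1,
                                  rep(cells_cl$covered_fraction, each = length(vi))),
                    nrow = length(vi))
      hit <- which(obs == 1, arr.ind = TRUE)
      if (nrow(hit)) {
        by_var <- split(cells_cl$cell[hit[, 2]], hit[, 1])
        for (k in names(by_var)) {
          i <- vi[as.integer(k)]
          supports[[i]] <- c(supports[[i]], by_var[[k]])
        }
      }
    }
    supports <- lapply(supports, function(x) sort(unique(x)))

    vm <- variant_matrix(
      tibble::tibble(contig = truth$contig, pos = truth$pos, ref = truth$ref,
                     alt = truth$alt, mq = round(mq, 1), cells = supports),
      cells = sort(roster$cell)
    )
    list(variants = vm,
         truth = truth[, c("key", "contig", "pos", "ref", "alt",
                           "clone", "channel", "germline")])
  })
}
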