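# File formats: FASTA via Biostrings, tables via readr, minimal VCF.

#' Read / write reference genomes
#'
#' Thin wrappers around Biostrings FASTA I/O returning the plain named
#' character representation used throughout the package.
#'
#' @param reference Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(reference)))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read / write bin-count and copy-number matrices
#'
#' Tab-separated with a three-column bin header (`contig`, `start`,
#' `end`) plus `weight`, then one column per cell.
#'
#' @param counts Tibble as produced by [simulate_cells()].
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a variant matrix as minimal VCF plus presence TSV
#'
#' The VCF (v4.2) carries `CHROM, POS, ID, REF, ALT, QUAL, FILTER` and
#' an `INFO` `MQ=` field; the presence TSV has one row per variant
#' (keyed `contig:pos:ref:alt`) and one 0/1 column per cell barcode.
#'
#' @param vm A [variant_matrix()].
#' @param vcf_path,presence_path Output paths (either may be `NULL` to
#'   skip that file).
#' @export
write_variant_matrix <- function(vm, vcf_path = NULL, presence_path = NULL) {
  v <- vm$variants
  ord <- order(v$contig, v$pos, v$ref, v$alt)
  v <- v[ord, , drop = FALSE]
  if (!is.null(vcf_path)) {
    info <- sprintf("MQ=%s", format(v$mq, trim = TRUE))
    has_vaf <- !all(is.na(v$vaf))
    if (has_vaf) info <- paste0(info, ";VAF=", format(v$vaf, trim = TRUE))
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
      if (has_vaf) "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", v$contig, v$pos, v$ref, v$alt, info)
    )
    writeLines(lines, vcf_path)
  }
  if (!is.null(presence_path)) {
    m <- presence_matrix(vm)[ord, , drop = FALSE]
    tab <- dplyr::bind_cols(tibble::tibble(key = rownames(m)), tibble::as_tibble(m))
    readr::write_tsv(tab, presence_path, progress = FALSE)
  }
  invisible(vm)
}

#' Read a variant matrix from a presence TSV (plus optional VCF metadata)
#'
#' @param presence_path Presence TSV written by [write_variant_matrix()].
#' @param vcf_path Optional minimal VCF supplying `MQ` (and `VAF`)
#'   per-variant metadata.
#' @return A [variant_matrix()].
#' @export
read_variant_matrix <- function(presence_path, vcf_path = NULL) {
  tab <- readr::read_tsv(presence_path, show_col_types = FALSE, progress = FALSE)
  key_parts <- strsplit(tab$key, ":", fixed = TRUE)
  cells_cols <- setdiff(names(tab), "key")
  m <- as.matrix(tab[, cells_cols, drop = FALSE])
  supports <- lapply(seq_len(nrow(m)), function(i) cells_cols[m[i, ] == 1])
  v <- tibble::tibble(
    contig = vapply(key_parts, `[`, character(1), 1),
    pos = as.integer(vapply(key_parts, `[`, character(1), 2)),
    ref = vapply(key_parts, `[`, character(1), 3),
    alt = vapply(key_parts, `[`, character(1), 4),
    mq = NA_real_,
    cells = supports
  )
  if (!is.null(vcf_path)) {
    meta <- read_minimal_vcf(vcf_path)
    idx <- match(variant_key(v$contig, v$pos, v$ref, v$alt),
                 variant_key(meta$contig, meta$pos, meta$ref, meta$alt))
    v$mq <- meta$mq[idx]
    if ("vaf" %in% names(meta)) v$vaf <- meta$vaf[idx]
  }
  variant_matrix(v, cells = cells_cols)
}

#' Read a minimal VCF into a tibble
#'
#' Parses the site fields and the `MQ`/`VAF` INFO keys of VCFs written
#' by this package (and any VCF restricted to those fields).
#'
#' @param path VCF path.
#' @return Tibble `(contig, pos, ref, alt, mq[, vaf][, info])`.
#' @export
read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(), mq = numeric()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8)
  if (length(bad)) stopf("malformed VCF record at line %d of %s",
                         which(!startsWith(lines, "#"))[bad[1]], path)
  info <- vapply(parts, `[`, character(1), 8)
  grab <- function(field) {
    m <- regmatches(info, regexpr(paste0("(?<=^|;)", field, "=[^;]+"), info, perl = TRUE))
    out <- rep(NA_real_, length(info))
    hit <- grepl(paste0("(^|;)", field, "="), info)
    out[hit] <- as.numeric(sub(paste0(field, "="), "", m))
    out
  }
  tibble::tibble(
    contig = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 4),
    alt = vapply(parts, `[`, character(1), 5),
    mq = grab("MQ"),
    vaf = grab("VAF"),
    info = info
  )
}

#' Read a germline blacklist
#'
#' Accepts either a tab-separated table with columns `contig`, `pos`,
#' `ref`, `alt` (header required) or a VCF; keys are allele-exact.
#'
#' @param path Blacklist path (`.vcf` handled as VCF, anything else as
#'   TSV).
#' @return Tibble `(contig, pos, ref, alt)`.
#' @export
read_blacklist <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    v <- read_minimal_vcf(path)
    return(v[c("contig", "pos", "ref", "alt")])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4)
  if (length(bad)) stopf("malformed blacklist line %d in %s", bad[1], path)
  header <- parts[[1]]
  if (!identical(tolower(header[1:4]), c("contig", "pos", "ref", "alt"))) {
    stopf("blacklist TSV must have header 'contig\tpos\tref\talt'")
  }
  body <- parts[-1]
  pos <- suppressWarnings(as.integer(vapply(body, `[`, character(1), 2)))
  if (anyNA(pos) && length(body)) stopf("malformed blacklist line %d in %s",
                                        which(is.na(pos))[1] + 1L, path)
  tibble::tibble(
    contig = vapply(body, `[`, character(1), 1),
    pos = pos,
    ref = vapply(body, `[`, character(1), 3),
    alt = vapply(body, `[`, character(1), 4)
  )
}

#' Write cluster segments or CIN regions as BED
#'
#' BED (0-based half-open) with `name` = cluster label and `score` =
#' mean copy number (segments) or the direction (CIN regions).
#'
#' @param segments Tibble with `cluster`, `contig`, `start`, `end` and
#'   either `mean_cn` or `direction`.
#' @param path Output path.
#' @export
write_bed <- function(segments, path) {
  score <- if ("mean_cn" %in% names(segments)) {
    sprintf("%.4f", segments$mean_cn)
  } else if ("direction" %in% names(segments)) {
    as.character(segments$direction)
  } else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", segments$contig,
                   as.integer(segments$start), as.integer(segments$end),
                   segments$cluster, score)
  writeLines(lines, path)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
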