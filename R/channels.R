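#' The 96 trinucleotide substitution channels
#'
#' Channel labels for the pyrimidine-centred single-base-substitution
#' spectrum, in the conventional catalog order: the six substitution
#' classes `C>A, C>G, C>T, T>A, T>C, T>G`, each expanded over the 16
#' flanking-base pairs with the 5' flank cycling slowest
#' (`A[C>A]A, A[C>A]C, ..., T[T>G]T`).
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (l in bases) {
      for (r in bases) {
        out <- c(out, paste0(l, "[", s, "]", r))
      }
    }
  }
  out
}

# base <-> integer code 0..3 (A C G T); complement is 3 - code
BASES <- c("A", "C", "G", "T")

encode_base <- function(chr) {
  code <- match(chr, BASES) - 1L
  code  # NA for N / other
}

complement_base <- function(chr) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(m[chr])
}

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(complement_base(ch)), collapse = "")
  }, character(1))
}

is_pyrimidine <- function(chr) chr %in% c("C", "T")

# Collapsed trinucleotide code for vectors of (l, c, r) codes in 0..3:
# if the centre is a purine the whole triplet is reverse-complemented,
# so the returned code always has a pyrimidine centre. Returns 0..63.
collapse_trinuc_code <- function(l, c, r) {
  pur <- c == 0L | c == 2L
  lc <- ifelse(pur, 3L - r, l)
  cc <- ifelse(pur, 3L - c, c)
  rc <- ifelse(pur, 3L - l, r)
  16L * lc + 4L * cc + rc
}

# Map a collapsed trinucleotide code (pyrimidine centre) back to its label.
trinuc_code_to_label <- function(code) {
  l <- BASES[code %/% 16L + 1L]
  c <- BASES[(code %/% 4L) %% 4L + 1L]
  r <- BASES[code %% 4L + 1L]
  paste0(l, c, r)
}

# Collapsed trinucleotide code (0..63) for every channel, plus the
# pyrimidine ref and alt base of each channel.
channel_table <- function() {
  ch <- sbs_channels()
  l <- substr(ch, 1, 1)
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  r <- substr(ch, 7, 7)
  code <- 16L * encode_base(l) + 4L * encode_base(ref) + encode_base(r)
  tibble::tibble(channel = ch, fivep = l, ref = ref, alt = alt, threep = r,
                 trinuc_code = code)
}

# Channel label from (possibly purine-centred) trinucleotide + ref + alt.
channel_from_context <- function(trinuc, ref, alt) {
  pur <- !is_pyrimidine(ref)
  trinuc[pur] <- revcomp(trinuc[pur])
  ref[pur] <- complement_base(ref[pur])
  alt[pur] <- complement_base(alt[pur])
  paste0(substr(trinuc, 1, 1), "[", ref, ">", alt, "]", substr(trinuc, 3, 3))
}
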