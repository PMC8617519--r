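#' INDEL context channels
#'
#' Channel labels for the compact insertion/deletion spectrum: 1-bp
#' deletions and insertions of C or T (purine events collapsed to their
#' pyrimidine complement) binned by the homopolymer run length at the
#' event site (1, 2, 3, 4, 5+), multi-base insertions landing after
#' copies of themselves binned by the preceding repeat count (1, 2, 3+),
#' and two catch-all channels.
#'
#' @return Character vector of the 25 channel labels.
#' @export
indel_channels <- function() {
  hp <- c("1", "2", "3", "4", "5+")
  c(paste0("del_C_hp", hp), paste0("del_T_hp", hp),
    paste0("ins_C_hp", hp), paste0("ins_T_hp", hp),
    paste0("ins_rep_", c("1", "2", "3+")),
    "other_del", "other_ins")
}

# Run length of base `b` in `seq` containing position `pos` (1-based).
homopolymer_run <- function(seq, pos, b) {
  n <- nchar(seq)
  if (substr(seq, pos, pos) != b) return(0L)
  left <- pos
  while (left > 1 && substr(seq, left - 1L, left - 1L) == b) left <- left - 1L
  right <- pos
  while (right < n && substr(seq, right + 1L, right + 1L) == b) right <- right + 1L
  right - left + 1L
}

classify_one_indel <- function(contig, pos, type, seq_event, refseq) {
  n <- nchar(refseq)
  len <- nchar(seq_event)
  pyr <- c(A = "T", G = "C", C = "C", T = "T")

  if (type == "del") {
    observed <- substr(refseq, pos, pos + len - 1L)
    if (observed != seq_event) {
      stopf("deleted sequence %s does not match reference %s at %s:%d",
            seq_event, observed, contig, pos)
    }
    if (len == 1L && seq_event %in% names(pyr)) {
      run <- homopolymer_run(refseq, pos, seq_event)
      bin <- if (run >= 5) "5+" else as.character(run)
      return(paste0("del_", pyr[[seq_event]], "_hp", bin))
    }
    return("other_del")
  }

  if (type == "ins") {
    if (len == 1L && seq_event %in% names(pyr)) {
      # anchored to the base immediately 3' of the insertion point
      anchor <- min(pos + 1L, n)
      run <- homopolymer_run(refseq, anchor, seq_event)
      if (run == 0L && pos >= 1L) run <- homopolymer_run(refseq, pos, seq_event)
      bin <- if (run >= 5) "5+" else as.character(max(run, 1L))
      return(paste0("ins_", pyr[[seq_event]], "_hp", bin))
    }
    if (len >= 2L) {
      # count copies of the inserted unit immediately 5' of the insertion point
      copies <- 0L
      at <- pos
      while (at - len + 1L >= 1L &&
             substr(refseq, at - len + 1L, at) == seq_event) {
        copies <- copies + 1L
        at <- at - len
      }
      if (copies >= 1L) {
        bin <- if (copies >= 3) "3+" else as.character(copies)
        return(paste0("ins_rep_", bin))
      }
    }
    return("other_ins")
  }
  stopf("indel type must be 'ins' or 'del', got '%s'", type)
}

#' Classify insertions and deletions into context channels
#'
#' 1-bp events are collapsed to the pyrimidine base (A to T, G to C) and
#' binned by the homopolymer run length of the event base adjacent to
#' the event site in the reference; insertions are anchored to the base
#' immediately 3' of the insertion point. Insertions of two or more
#' bases are checked for a tandem-repeat context (copies of the inserted
#' unit immediately upstream). Everything else falls into the catch-all
#' channels.
#'
#' @param indels A data frame with `contig`, `pos` (1-based; for
#'   insertions the base after which the sequence is inserted), `type`
#'   (`"ins"` or `"del"`), and `seq` (inserted or deleted bases).
#' @param reference Named character vector of contig sequences.
#' @return The input tibble with a `channel` column added.
#' @export
classify_indel <- function(indels, reference) {
  indels <- tibble::as_tibble(indels)
  stopifnot(all(c("contig", "pos", "type", "seq") %in% names(indels)))
  bad <- !indels$contig %in% names(reference)
  if (any(bad)) stopf("indel contig(s) not in reference: %s",
                      paste(unique(indels$contig[bad]), collapse = ", "))
  indels$channel <- purrr::pmap_chr(
    list(indels$contig, indels$pos, indels$type, indels$seq),
    function(contig, pos, type, seq_event) {
      classify_one_indel(contig, pos, type, toupper(seq_event), reference[[contig]])
    })
  indels
}

#' Build an INDEL context spectrum
#'
#' @inheritParams classify_indel
#' @return Named numeric vector over [indel_channels()] (class
#'   `indel_spectrum`); every classified event lands in exactly one
#'   channel.
#' @export
build_indel_spectrum <- function(indels, reference) {
  cls <- classify_indel(indels, reference)
  counts <- table(factor(cls$channel, levels = indel_channels()))
  structure(stats::setNames(as.numeric(counts), indel_channels()),
            class = "indel_spectrum")
}
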