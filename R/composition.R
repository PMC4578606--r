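# Per-position nucleotide composition of TSS-anchored windows and
# dinucleotide analysis around the initiator.

#' Per-position base composition of aligned TSS-anchored sequences
#'
#' Column-wise proportions of A, C, G and T across a set of equal-length,
#' TSS-aligned sequences. Position labels skip 0 (-up..-1, +1..+down; +1 is
#' the TSS base). N (or any ambiguity code) is excluded from both the
#' numerator and the denominator, so each position with at least one
#' counted base sums to 1.
#'
#' @param sequences `DNAStringSet` (or character vector) of equal-length
#'   sequences in transcript orientation.
#' @param window Integer pair `c(up, down)`; `up + down` must equal the
#'   sequence length. Default `c(200, 100)`.
#' @return `data.frame` with columns `position`, `A`, `C`, `G`, `T`.
#' @export
composition_profile <- function(sequences, window = c(200L, 100L)) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  wlen <- unique(width(sequences))
  if (length(wlen) != 1L) stop("sequences must all have the same length")
  if (wlen != sum(window)) {
    stop("window (", window[1L], " + ", window[2L],
         ") does not match sequence length ", wlen)
  }
  cm <- consensusMatrix(sequences, baseOnly = TRUE)
  acgt <- cm[DNA_BASES, , drop = FALSE]
  denom <- colSums(acgt)
  freq <- t(acgt) / ifelse(denom == 0, NA_real_, denom)
  out <- data.frame(position = .label_positions(window[1L], window[2L]),
                    freq)
  rownames(out) <- NULL
  out
}

#' Dinucleotide frequencies at the initiator
#'
#' Proportions of the 16 dinucleotides read at a pair of TSS-relative
#' positions (default -1/+1, the two bases flanking the transcription
#' start). Pairs containing an ambiguous base are excluded from the
#' denominator; the returned table sums to 1.
#'
#' @param sequences `DNAStringSet` of equal-length TSS-aligned sequences.
#' @param positions Integer pair of TSS-relative labels (no 0); default
#'   `c(-1, 1)`.
#' @param window Integer pair `c(up, down)` describing the sequence span;
#'   default `c(50, 50)` for 100-nt core promoters.
#' @return Named numeric vector of length 16 (AA, AC, ..., TT).
#' @export
initiator_dinucleotide <- function(sequences, positions = c(-1L, 1L),
                                   window = c(50L, 50L)) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  stopifnot(length(positions) == 2L, all(positions != 0L))
  cols <- .label_to_col(as.integer(positions), window[1L])
  if (any(cols < 1L) || any(cols > unique(width(sequences))[1L])) {
    stop("positions fall outside the sequence window")
  }
  b1 <- as.character(subseq(sequences, start = cols[1L], width = 1L))
  b2 <- as.character(subseq(sequences, start = cols[2L], width = 1L))
  keep <- b1 %in% DNA_BASES & b2 %in% DNA_BASES
  dinucs <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, times = 4L))
  counts <- table(factor(paste0(b1[keep], b2[keep]), levels = dinucs))
  if (sum(counts) == 0L) stop("no unambiguous dinucleotides at the requested positions")
  out <- as.numeric(counts) / sum(counts)
  names(out) <- dinucs
  out
}
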