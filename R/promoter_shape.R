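# Promoter shape: dominant TSS, individual peakedness score Sg = m/(n*w),
# three-way shape classification, and core promoter extraction.

.hist_list <- function(clusters) {
  h <- mcols(clusters)$tss_hist
  if (is.null(h)) stop("clusters carry no tss_hist metadata; run merge_reads()")
  as.list(h)
}

#' Dominant TSS of each tag cluster
#'
#' The genomic position with the highest 5'-end read count. Ties are broken
#' toward the most upstream position in transcript orientation: the
#' smallest coordinate on `+`, the largest on `-`.
#'
#' @param clusters A `GRanges` of tag clusters from [merge_reads()].
#' @return Integer vector of genomic TSS positions, one per cluster.
#' @export
dominant_tss <- function(clusters) {
  hists <- .hist_list(clusters)
  st <- as.character(strand(clusters))
  vapply(seq_along(hists), function(i) {
    h <- hists[[i]]
    if (length(h) == 0L) stop("cluster ", i, " has an empty TSS histogram")
    pos <- as.integer(names(h))
    best <- pos[h == max(h)]
    if (st[i] == "-") max(best) else min(best)
  }, integer(1))
}

#' Individual peakedness score of tag clusters
#'
#' For a cluster g, the peakedness is \eqn{S_g = m / (n w)} where `m` is
#' the tag count at the dominant (modal) TSS position, `n` the total tag
#' count and `w` the width of the TSS distribution. A cluster whose reads
#' all start at a single position has \eqn{S_g = 1}, the maximum; Sg
#' decreases as initiation spreads out.
#'
#' @param clusters Tag clusters from [merge_reads()].
#' @param width_mode `"tss"` (default) measures `w` as the span of distinct
#'   read 5'-end positions, `max - min + 1`, so single-TSS clusters reach
#'   Sg = 1 regardless of read length. `"interval"` uses the merged cluster
#'   interval width instead, for comparison.
#' @return A `data.frame` with columns `m`, `n`, `w`, `sg`, `n_positions`.
#' @examples
#' reads <- GenomicRanges::GRanges("s", IRanges::IRanges(rep(500, 150), width = 30),
#'                                 strand = "+")
#' peakedness(merge_reads(reads))$sg  # 1
#' @export
peakedness <- function(clusters, width_mode = c("tss", "interval")) {
  width_mode <- match.arg(width_mode)
  hists <- .hist_list(clusters)
  m <- vapply(hists, function(h) as.integer(max(h)), integer(1))
  n <- vapply(hists, function(h) as.integer(sum(h)), integer(1))
  n_positions <- lengths(hists)
  w <- if (width_mode == "interval") width(clusters) else
    vapply(hists, function(h) {
      pos <- as.integer(names(h))
      diff(range(pos)) + 1L
    }, integer(1))
  data.frame(m = m, n = n, w = as.integer(w), sg = m / (n * as.numeric(w)),
             n_positions = as.integer(n_positions))
}

#' Classify promoter shape
#'
#' A cluster with 10 or fewer distinct TSS positions is `narrow`. Broader
#' clusters are `broad_with_peak` when the modal position carries at least
#' 50 % of the total tag count, and `broad_without_peak` otherwise.
#'
#' @param shape Output of [peakedness()] (needs `m`, `n`, `n_positions`).
#' @param narrow_max Maximum distinct TSS positions for a narrow promoter
#'   (default 10).
#' @param peak_fraction Minimal modal fraction defining a dominant peak
#'   (default 0.5).
#' @return Factor with levels `narrow`, `broad_with_peak`,
#'   `broad_without_peak`.
#' @export
classify_shape <- function(shape, narrow_max = 10L, peak_fraction = 0.5) {
  stopifnot(all(c("m", "n", "n_positions") %in% names(shape)))
  cls <- ifelse(shape$n_positions <= narrow_max, "narrow",
                ifelse(shape$m >= peak_fraction * shape$n,
                       "broad_with_peak", "broad_without_peak"))
  factor(cls, levels = c("narrow", "broad_with_peak", "broad_without_peak"))
}

#' Peakedness and shape class in one table
#'
#' @inheritParams peakedness
#' @inheritParams classify_shape
#' @return [peakedness()] columns plus `shape_class`.
#' @export
promoter_shapes <- function(clusters, width_mode = c("tss", "interval"),
                            narrow_max = 10L, peak_fraction = 0.5) {
  s <- peakedness(clusters, width_mode)
  s$shape_class <- classify_shape(s, narrow_max, peak_fraction)
  s
}

#' Select the representative tag cluster of a gene
#'
#' When several five_prime clusters compete for one gene, the cluster with
#' the most tags wins; ties go to the most upstream cluster in transcript
#' orientation.
#'
#' @param candidates A `GRanges` of clusters, all assigned to one gene.
#' @return A single-cluster `GRanges`.
#' @export
select_gene_cluster <- function(candidates) {
  candidates[.select_gene_cluster_idx(candidates)]
}

# Index of the winning cluster (max tags, ties to the upstream cluster).
.select_gene_cluster_idx <- function(candidates) {
  stopifnot(methods::is(candidates, "GRanges"))
  if (length(candidates) == 0L) stop("no candidate clusters supplied")
  counts <- mcols(candidates)$tag_count
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    st <- as.character(strand(candidates))[best[1L]]
    best <- if (st == "-") best[which.max(end(candidates)[best])]
            else best[which.min(start(candidates)[best])]
  }
  best[1L]
}

# Extract a TSS-anchored window (-up..-1, +1..+down in transcript
# orientation, no position 0) as a character string, N-padding beyond the
# scaffold ends.
.tss_window_seq <- function(genome, scaffold, tss, strand, up, down,
                            warn = TRUE) {
  if (!scaffold %in% names(genome)) {
    stop("scaffold '", scaffold, "' not present in the genome")
  }
  chr <- genome[[scaffold]]
  len <- length(chr)
  gstart <- if (strand == "+") tss - up else tss - down + 1L
  gend <- if (strand == "+") tss + down - 1L else tss + up
  left_pad <- max(0L, 1L - gstart)
  right_pad <- max(0L, gend - len)
  if ((left_pad > 0L || right_pad > 0L) && warn) {
    warning("TSS window at ", scaffold, ":", tss,
            " extends past a scaffold end; padding with N")
  }
  s <- as.character(subseq(chr, start = max(1L, gstart), end = min(len, gend)))
  s <- paste0(strrep("N", left_pad), s, strrep("N", right_pad))
  if (strand == "-") {
    s <- as.character(reverseComplement(DNAStringSet(s))[[1L]])
  }
  s
}

#' Extract core promoter sequences around dominant TSSs
#'
#' Each core promoter is the 100-nt window -50..-1, +1..+50 around the TSS
#' in transcript orientation (there is no position 0; the base at +1 is the
#' TSS base). Windows reaching past a scaffold end are N-padded with a
#' warning. A promoter whose genomic window intersects any transposon
#' interval by >= 1 bp is flagged `transposon_overlap` and should be
#' excluded from motif annotation.
#'
#' @param genome Named `DNAStringSet` (or FASTA path).
#' @param tss_table `data.frame` with columns `gene_id`, `scaffold`, `tss`,
#'   `strand` (and optionally `shape_class`, `sg`).
#' @param transposons Optional `GRanges` of repeat/transposon intervals.
#' @param flank Half-window in bp (default 50 giving 100-nt promoters).
#' @return A `DNAStringSet` named by `gene_id`, with metadata columns
#'   `gene_id`, `scaffold`, `tss`, `strand`, `transposon_overlap` (plus any
#'   `shape_class`/`sg` passed through).
#' @export
extract_core_promoters <- function(genome, tss_table, transposons = NULL,
                                   flank = 50L) {
  genome <- .as_genome(genome)
  stopifnot(all(c("gene_id", "scaffold", "tss", "strand") %in%
                  names(tss_table)))
  .check_strand(tss_table$strand)
  n <- nrow(tss_table)
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- .tss_window_seq(genome, tss_table$scaffold[i],
                               as.integer(tss_table$tss[i]),
                               tss_table$strand[i], up = flank, down = flank)
  }
  windows <- GRanges(tss_table$scaffold,
                     IRanges(start = ifelse(tss_table$strand == "+",
                                            tss_table$tss - flank,
                                            tss_table$tss - flank + 1L),
                             width = 2L * flank))
  overlap <- rep(FALSE, n)
  if (!is.null(transposons) && length(transposons) > 0L) {
    overlap <- overlapsAny(windows, transposons, ignore.strand = TRUE)
  }
  out <- DNAStringSet(seqs)
  names(out) <- tss_table$gene_id
  md <- tss_table[, intersect(c("gene_id", "scaffold", "tss", "strand",
                                "shape_class", "sg"), names(tss_table)),
                  drop = FALSE]
  md$transposon_overlap <- overlap
  mcols(out) <- S4Vectors::DataFrame(md)
  out
}

#' @rdname extract_core_promoters
#' @param scaffold,tss,strand Location of a single TSS.
#' @param gene_id Identifier attached to the single promoter.
#' @export
extract_core_promoter <- function(genome, scaffold, tss, strand,
                                  transposons = NULL, gene_id = "promoter",
                                  flank = 50L) {
  extract_core_promoters(genome,
                         data.frame(gene_id = gene_id, scaffold = scaffold,
                                    tss = tss, strand = strand,
                                    stringsAsFactors = FALSE),
                         transposons = transposons, flank = flank)
}

#' TSS-anchored windows for composition profiling
#'
#' Like [extract_core_promoters()] but with an asymmetric window (default
#' -200..+100) used for nucleotide composition profiles.
#'
#' @inheritParams extract_core_promoters
#' @param up,down Bases upstream / downstream of the TSS (no position 0).
#' @export
extract_tss_windows <- function(genome, tss_table, up = 200L, down = 100L) {
  genome <- .as_genome(genome)
  .check_strand(tss_table$strand)
  seqs <- vapply(seq_len(nrow(tss_table)), function(i) {
    .tss_window_seq(genome, tss_table$scaffold[i],
                    as.integer(tss_table$tss[i]), tss_table$strand[i],
                    up = up, down = down)
  }, character(1))
  out <- DNAStringSet(seqs)
  names(out) <- tss_table$gene_id
  out
}
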