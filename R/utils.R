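# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user analyses.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# TSS-relative coordinates skip 0: labels run -up..-1, +1..+down.
.label_positions <- function(up, down) {
  c(seq.int(-up, -1L), seq.int(1L, down))
}

# Column index of label `p` in a sequence spanning -up..+down.
.label_to_col <- function(p, up) {
  ifelse(p < 0L, p + up + 1L, p + up)
}

# Genomic coordinate (1-based) of TSS-relative label `p`; +1 is the TSS base.
# All arguments recycle to the longest length.
.label_to_genomic <- function(tss, strand, p) {
  n <- max(length(tss), length(strand), length(p))
  tss <- rep_len(tss, n); strand <- rep_len(strand, n); p <- rep_len(p, n)
  ifelse(strand == "+",
         ifelse(p < 0L, tss + p, tss + p - 1L),
         ifelse(p < 0L, tss - p, tss - p + 1L))
}

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every interval (strand '*' is not allowed)")
  }
  invisible(strand)
}

# Coerce a genome argument (DNAStringSet or FASTA path) to a named DNAStringSet.
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a named DNAStringSet or the path to a FASTA file")
  }
  if (is.null(names(genome))) stop("genome sequences must be named")
  genome
}

.canonical_motifs <- c("BREu", "BREd", "TATA", "INR", "MTE", "DPE")

# Uniform draw from an integer range c(low, high); safe when low == high
# (base sample() would otherwise treat the scalar as 1:n).
.sample_range <- function(r, n = 1L) {
  if (r[1L] == r[2L]) rep(r[1L], n) else
    sample(seq.int(r[1L], r[2L]), n, replace = TRUE)
}
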