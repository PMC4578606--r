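# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Stranded reads from 5'-end positions (1-based), mirroring real tag data.
make_reads <- function(pos5, strand = "+", scaffold = "scf", width = 30L) {
  strand <- rep_len(strand, length(pos5))
  starts <- ifelse(strand == "+", pos5, pos5 - width + 1L)
  GRanges(scaffold, IRanges(start = starts, width = width), strand = strand)
}

# One tag cluster built honestly through merge_reads from a histogram
# specification: named counts, names = genomic 5'-end positions.
make_cluster <- function(hist, strand = "+", scaffold = "scf",
                         width = 30L) {
  pos <- rep(as.integer(names(hist)), times = as.integer(hist))
  merge_reads(make_reads(pos, strand, scaffold, width))
}

# Independent connected-components oracle for read merging: igraph
# components over the pairwise same-strand/scaffold >=1 bp overlap graph.
oracle_clusters <- function(reads) {
  n <- length(reads)
  if (n == 0L) return(integer(0))
  s <- start(reads); e <- end(reads)
  key <- paste(as.character(seqnames(reads)), as.character(strand(reads)))
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    key[i] == key[j] & s[i] <= e[j] & s[j] <= e[i]
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Canonical membership signature (sorted partition) for comparing two
# clusterings independent of cluster numbering.
partition_signature <- function(membership) {
  unname(sort(vapply(split(seq_along(membership), membership),
                     paste, character(1), collapse = ",")))
}

# Membership implied by merge_reads: which cluster interval contains each
# read (same strand).
merge_membership <- function(reads, clusters) {
  hits <- findOverlaps(reads, clusters, ignore.strand = FALSE)
  m <- integer(length(reads))
  m[queryHits(hits)] <- subjectHits(hits)
  m
}

# Brute-force PWM p-value oracle: enumerate all 4^L words, score each with
# the same discretized (1e-3-bit grid) per-column log-odds scores, and
# accumulate P(score >= s) under the background.
brute_force_pvalue <- function(pfm, background, int_score,
                               pseudocount = 0.8, grid = 1e-3) {
  L <- ncol(pfm)
  probs <- sweep(pfm + pseudocount, 2L, colSums(pfm + pseudocount), "/")
  K <- round(log2(probs / background) / grid)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(words))
  wp <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    scores <- scores + K[cbind(words[, j], j)]
    wp <- wp * background[words[, j]]
  }
  vapply(int_score, function(s) sum(wp[scores >= s]), numeric(1))
}

# Toy two-exon gene model in GFF3-style GRanges form.
toy_gene_model <- function(scaffold = "scf", start = 2000L, end = 6000L,
                           strand = "+", utr_len = 200L, gene_id = "g1",
                           scaffold_length = 20000L) {
  e1 <- 800L
  if (strand == "+") {
    utr <- c(start, start + utr_len - 1L)
    cds1 <- c(start + utr_len, start + utr_len + e1 - 1L)
    cds2 <- c(end - 1000L, end)
  } else {
    utr <- c(end - utr_len + 1L, end)
    cds1 <- c(end - utr_len - e1 + 1L, end - utr_len)
    cds2 <- c(start, start + 1000L)
  }
  si <- GenomeInfoDb::Seqinfo(scaffold, scaffold_length)
  gr <- GRanges(scaffold,
                IRanges(c(start, start, utr[1], cds1[1], cds2[1]),
                        c(end, end, utr[2], cds1[2], cds2[2])),
                strand = strand, seqinfo = si)
  mcols(gr)$type <- c("gene", "mRNA", "five_prime_UTR", "CDS", "CDS")
  mcols(gr)$ID <- c(gene_id, paste0(gene_id, ".t"), paste0(gene_id, ".u"),
                    paste0(gene_id, ".c1"), paste0(gene_id, ".c2"))
  mcols(gr)$Parent <- IRanges::CharacterList(
    list(character(0), gene_id, paste0(gene_id, ".t"),
         paste0(gene_id, ".t"), paste0(gene_id, ".t")))
  gr
}

# A small fast config for simulation-backed tests.
small_config <- function(n_genes = 30L, ...) {
  sim_config(n_scaffolds = 4L, scaffold_length = 60000L,
             n_genes = n_genes, ...)
}
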