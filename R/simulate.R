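# Synthetic-data generator: AT-rich scaffolds carrying gene models with
# 5'UTRs, planted core-promoter motif consensi, transposon intervals,
# shaped TSS-seq read distributions and a sparse skewed GO map. Fully
# deterministic given the config seed, so every downstream stage can be
# validated against the recorded ground truth.

# Consensus strings planted at the motifs' functional windows. These are
# deliberately strong words (one per motif) rather than paper-specific
# matrices; the planted start positions sit at the center of each window.
.plant_consensus <- c(TATA = "TATAAA", INR = "TCAGTT", DPE = "AGACGT",
                      MTE = "CGAACGGA", BREu = "GGGCGCC", BREd = "GTTTGTT")
.plant_starts <- c(BREu = -38L, TATA = -30L, BREd = -23L, INR = -2L,
                   MTE = 19L, DPE = 28L)

#' Configuration for the synthetic TSS-seq study
#'
#' Defaults describe the emulated study conditions: AT-rich (70 %) insect
#' scaffolds, 150 genes with 50-300 bp 5'UTRs, a promoter shape mixture of
#' 5 % narrow / 23 % broad-with-peak / 72 % broad-without-peak, roughly 200
#' mapped 36-nt 5'-end reads per gene, and per-motif planting rates
#' matching the observed occurrence of the six canonical motifs
#' (BREu 0.21, BREd 0.29, TATA 0.32, INR 0.34, MTE 0.33, DPE 0.30).
#'
#' @param n_scaffolds,scaffold_length Number and length (bp) of scaffolds;
#'   the last scaffold is kept gene-less when `n_scaffolds >= 2`.
#' @param n_genes Number of simulated genes.
#' @param gene_length_range,utr_length_range Integer pairs (bp).
#' @param at_fraction Background A+T proportion, in `[0, 1]`.
#' @param shape_mix Probabilities of (narrow, broad_with_peak,
#'   broad_without_peak); must sum to 1.
#' @param reads_per_gene_range Integer pair: reads drawn per gene.
#' @param read_length Read (tag) length in bp.
#' @param motif_plant_rates Named probabilities of planting each motif
#'   consensus in a gene's promoter.
#' @param transposon_density Fraction of the genome covered by transposon
#'   intervals (placed clear of promoter windows).
#' @param background_read_rate Scattered background reads per kb of genome.
#' @param n_go_terms Number of GO terms in the simulated vocabulary.
#' @param go_skew Zipf exponent of the term frequency distribution; larger
#'   values concentrate annotations on the first terms.
#' @param go_annotation_rate Fraction of genes receiving 1-3 GO terms.
#' @param seed Integer seed; fully determines every generated byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 10L, scaffold_length = 120000L,
                       n_genes = 150L,
                       gene_length_range = c(2000L, 5000L),
                       utr_length_range = c(50L, 300L),
                       at_fraction = 0.70,
                       shape_mix = c(narrow = 0.05, broad_with_peak = 0.23,
                                     broad_without_peak = 0.72),
                       reads_per_gene_range = c(150L, 250L),
                       read_length = 36L,
                       motif_plant_rates = c(BREu = 0.21, BREd = 0.29,
                                             TATA = 0.32, INR = 0.34,
                                             MTE = 0.33, DPE = 0.30),
                       transposon_density = 0.02,
                       background_read_rate = 0.05,
                       n_go_terms = 25L, go_skew = 1.0,
                       go_annotation_rate = 0.25, seed = 1L) {
  cfg <- list(n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              utr_length_range = as.integer(utr_length_range),
              at_fraction = at_fraction,
              shape_mix = shape_mix,
              reads_per_gene_range = as.integer(reads_per_gene_range),
              read_length = as.integer(read_length),
              motif_plant_rates = motif_plant_rates,
              transposon_density = transposon_density,
              background_read_rate = background_read_rate,
              n_go_terms = as.integer(n_go_terms),
              go_skew = go_skew,
              go_annotation_rate = go_annotation_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_scaffolds >= 1L, cfg$scaffold_length >= 1000L,
            cfg$n_genes >= 0L)
  if (abs(sum(cfg$shape_mix) - 1) > 1e-8) stop("shape_mix must sum to 1")
  if (length(cfg$shape_mix) != 3L) stop("shape_mix needs three components")
  for (r in list(cfg$gene_length_range, cfg$utr_length_range,
                 cfg$reads_per_gene_range)) {
    if (length(r) != 2L || r[1L] > r[2L]) stop("ranges must satisfy low <= high")
  }
  if (cfg$at_fraction < 0 || cfg$at_fraction > 1) {
    stop("at_fraction must lie in [0, 1]")
  }
  if (!all(names(cfg$motif_plant_rates) %in% .canonical_motifs)) {
    stop("motif_plant_rates names must be canonical motifs")
  }
  if (any(cfg$motif_plant_rates < 0 | cfg$motif_plant_rates > 1)) {
    stop("motif_plant_rates must be probabilities")
  }
  class(cfg) <- "sim_config"
  cfg
}

# L consecutive TSS-relative labels starting at s, skipping position 0.
.labels_from <- function(s, L) {
  cand <- seq.int(s, s + L)
  cand <- cand[cand != 0L]
  cand[seq_len(L)]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# Write `word` (read in transcript orientation from label `s`) into the
# scaffold character vector around a TSS.
.plant_word <- function(chars, tss, strand, s, word) {
  bases <- strsplit(word, "")[[1L]]
  pos <- .label_to_genomic(tss, strand, .labels_from(s, length(bases)))
  if (strand == "-") bases <- unname(.complement[bases])
  chars[pos] <- bases
  chars
}

#' Generate a synthetic genome with gene models, transposons and truth
#'
#' Produces scaffolds with the configured background composition, places
#' non-overlapping genes (each with a 5'UTR and two CDS exons) on all but
#' the last scaffold, plants motif consensi at their functional windows
#' around each TSS according to `motif_plant_rates`, and lays transposon
#' intervals in intergenic space. The truth table records each gene's TSS,
#' its assigned shape archetype and the set of planted motifs.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `genes` (GFF3-style
#'   `GRanges`: gene / mRNA / five_prime_UTR / CDS), `transposons`
#'   (`GRanges`), `truth` (`data.frame`: `gene_id`, `scaffold`, `strand`,
#'   `true_tss`, `true_shape`, `planted_motifs`), and the `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .generate_genome_impl(config))
}

.generate_genome_impl <- function(config) {
  scf_names <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  p_at <- config$at_fraction
  base_probs <- c(A = p_at / 2, C = (1 - p_at) / 2,
                  G = (1 - p_at) / 2, T = p_at / 2)
  chars <- lapply(scf_names, function(nm) {
    sample(names(base_probs), config$scaffold_length, replace = TRUE,
           prob = base_probs)
  })
  names(chars) <- scf_names

  gene_scaffolds <- if (config$n_scaffolds >= 2L)
    scf_names[-config$n_scaffolds] else scf_names
  margin <- 400L
  cursors <- setNames(rep(margin, length(gene_scaffolds)), gene_scaffolds)
  scf_i <- 1L

  n <- config$n_genes
  truth <- data.frame(gene_id = character(n), scaffold = character(n),
                      strand = character(n), true_tss = integer(n),
                      true_shape = character(n),
                      planted_motifs = character(n),
                      stringsAsFactors = FALSE)
  gff_rows <- list()
  shapes <- names(config$shape_mix)
  if (is.null(shapes)) shapes <- c("narrow", "broad_with_peak",
                                   "broad_without_peak")
  gene_shapes <- if (n > 0L)
    sample(shapes, n, replace = TRUE, prob = config$shape_mix) else character(0)

  for (g in seq_len(n)) {
    len <- .sample_range(config$gene_length_range)
    gap <- sample(500:1500, 1L)
    placed <- FALSE
    while (!placed) {
      if (scf_i > length(gene_scaffolds)) {
        stop("gene placement impossible: requested gene density exceeds ",
             "scaffold capacity")
      }
      scf <- gene_scaffolds[scf_i]
      start <- cursors[[scf]] + gap
      end <- start + len - 1L
      if (end > config$scaffold_length - margin) {
        scf_i <- scf_i + 1L
      } else {
        cursors[[scf]] <- end
        placed <- TRUE
      }
    }
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("gene_%04d", g)
    tss <- if (strand == "+") start else end
    u <- .sample_range(config$utr_length_range)
    coding <- len - u
    intron <- max(60L, as.integer(round(0.1 * coding)))
    e1 <- as.integer(round(0.4 * (coding - intron)))
    e2 <- coding - intron - e1
    stopifnot(e1 > 0L, e2 > 0L)
    if (strand == "+") {
      utr <- c(start, start + u - 1L)
      cds1 <- c(start + u, start + u + e1 - 1L)
      cds2 <- c(end - e2 + 1L, end)
    } else {
      utr <- c(end - u + 1L, end)
      cds1 <- c(end - u - e1 + 1L, end - u)
      cds2 <- c(start, start + e2 - 1L)
    }
    planted <- character(0)
    for (m in names(config$motif_plant_rates)) {
      if (runif(1L) < config$motif_plant_rates[[m]]) {
        chars[[scf]] <- .plant_word(chars[[scf]], tss, strand,
                                    .plant_starts[[m]], .plant_consensus[[m]])
        planted <- c(planted, m)
      }
    }
    truth[g, ] <- list(gene_id, scf, strand, tss, gene_shapes[g],
                       paste(planted, collapse = ","))
    mrna_id <- paste0(gene_id, ".t1")
    gff_rows[[g]] <- data.frame(
      scaffold = scf,
      start = c(start, start, utr[1L], cds1[1L], cds2[1L]),
      end = c(end, end, utr[2L], cds1[2L], cds2[2L]),
      strand = strand,
      type = c("gene", "mRNA", "five_prime_UTR", "CDS", "CDS"),
      ID = c(gene_id, mrna_id, paste0(mrna_id, ".utr5"),
             paste0(mrna_id, ".cds1"), paste0(mrna_id, ".cds2")),
      Parent = c(NA, gene_id, mrna_id, mrna_id, mrna_id),
      phase = c(NA, NA, NA, 0L, (3L - e1 %% 3L) %% 3L),
      stringsAsFactors = FALSE)
  }

  gff <- if (n > 0L) do.call(rbind, gff_rows) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               strand = character(0), type = character(0), ID = character(0),
               Parent = character(0), phase = integer(0))
  seqinfo <- Seqinfo(scf_names, rep(config$scaffold_length,
                                    config$n_scaffolds))
  genes <- GRanges(factor(gff$scaffold, scf_names),
                   IRanges(gff$start, gff$end), strand = gff$strand,
                   seqinfo = seqinfo)
  mcols(genes)$type <- gff$type
  mcols(genes)$ID <- gff$ID
  mcols(genes)$Parent <- CharacterList(
    lapply(gff$Parent, function(p) if (is.na(p)) character(0) else p))
  mcols(genes)$phase <- as.integer(gff$phase)

  transposons <- .place_transposons(config, truth, scf_names, seqinfo)
  genome <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- scf_names
  list(genome = genome, genes = genes, transposons = transposons,
       truth = truth, config = config)
}

# Transposon intervals in intergenic space, kept >= 500 bp away from every
# TSS so promoter windows stay repeat-free by construction.
.place_transposons <- function(config, truth, scf_names, seqinfo) {
  target <- config$transposon_density * config$n_scaffolds *
    config$scaffold_length
  placed <- 0
  rows <- list()
  tries <- 0L
  while (placed < target && tries < 10000L) {
    tries <- tries + 1L
    scf <- sample(scf_names, 1L)
    len <- sample(200:2000, 1L)
    start <- sample.int(config$scaffold_length - len, 1L)
    end <- start + len - 1L
    tss_here <- truth$true_tss[truth$scaffold == scf]
    if (length(tss_here) > 0L &&
        any(tss_here >= start - 500L & tss_here <= end + 500L)) next
    rows[[length(rows) + 1L]] <- c(scf, start, end)
    placed <- placed + len
  }
  if (length(rows) == 0L) {
    return(GRanges(seqinfo = seqinfo))
  }
  m <- do.call(rbind, rows)
  GRanges(factor(m[, 1L], scf_names),
          IRanges(as.integer(m[, 2L]), as.integer(m[, 3L])), strand = "+",
          seqinfo = seqinfo)
}

# Shape-specific TSS offset distributions (in transcript orientation).
.draw_offsets <- function(shape, n) {
  if (shape == "narrow") {
    # point mass + geometric tail truncated to <= 10 distinct positions
    k <- sample(3:9, 1L)
    probs <- 0.55 * 0.45^(0:(k - 1L))
    return(sample(0:(k - 1L), n, replace = TRUE, prob = probs))
  }
  win <- sample(60:150, 1L)
  sdv <- win / 6
  clip <- function(x) pmin(pmax(x, -win %/% 2L), win %/% 2L)
  if (shape == "broad_with_peak") {
    for (try in 1:50) {
      f <- runif(1L, 0.55, 0.70)
      n_spike <- as.integer(ceiling(f * n))
      rest <- clip(as.integer(round(rnorm(n - n_spike, 0, sdv))))
      offs <- c(rep(0L, n_spike), rest)
      tab <- table(offs)
      if (length(tab) >= 11L && max(tab) >= 0.5 * n) return(offs)
    }
    # deterministic fallback for very small n
    rest <- rep(c(-6:-1, 1:6), length.out = max(0L, n - n_spike))
    return(c(rep(0L, n_spike), rest))
  }
  # broad_without_peak
  for (try in 1:50) {
    offs <- clip(as.integer(round(rnorm(n, 0, sdv))))
    tab <- table(offs)
    if (length(tab) >= 11L && max(tab) < 0.5 * n) return(offs)
  }
  rep(seq(-15L, 15L)[seq(-15L, 15L) != 0L], length.out = n)
}

#' Generate mapped TSS-seq read intervals
#'
#' Draws each gene's read 5'-end positions from its shape archetype --
#' narrow: a point mass with a geometric tail over at most 10 positions;
#' broad with peak: a discretized Gaussian plus a modal spike carrying at
#' least half the reads; broad without peak: a discretized Gaussian with
#' modal fraction below one half -- and emits `read_length` intervals
#' oriented with the gene strand, plus a low rate of scattered background
#' reads.
#'
#' @param truth Truth table from [generate_genome()].
#' @param config The same [sim_config()].
#' @return A stranded `GRanges` of read intervals (BED6-exportable).
#' @export
generate_tss_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0L) stop("truth table is empty; no genes to simulate")
  .with_seed(config$seed + 1L, {
    scf <- character(0); pos5 <- integer(0); st <- character(0)
    for (g in seq_len(nrow(truth))) {
      n <- .sample_range(config$reads_per_gene_range)
      offs <- .draw_offsets(truth$true_shape[g], n)
      p <- if (truth$strand[g] == "+") truth$true_tss[g] + offs
           else truth$true_tss[g] - offs
      scf <- c(scf, rep(truth$scaffold[g], n))
      pos5 <- c(pos5, p)
      st <- c(st, rep(truth$strand[g], n))
    }
    n_bg <- as.integer(round(config$background_read_rate *
                               config$n_scaffolds *
                               config$scaffold_length / 1000))
    if (n_bg > 0L) {
      scf_names <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
      scf <- c(scf, sample(scf_names, n_bg, replace = TRUE))
      pos5 <- c(pos5, sample.int(config$scaffold_length, n_bg,
                                 replace = TRUE))
      st <- c(st, sample(c("+", "-"), n_bg, replace = TRUE))
    }
    rl <- config$read_length
    pos5 <- pmin(pmax(pos5, rl), config$scaffold_length - rl)
    starts <- ifelse(st == "+", pos5, pos5 - rl + 1L)
    seqinfo <- Seqinfo(sprintf("scaffold_%02d", seq_len(config$n_scaffolds)),
                       rep(config$scaffold_length, config$n_scaffolds))
    GRanges(factor(scf, seqlevels(seqinfo)),
            IRanges(start = starts, width = rl), strand = st,
            seqinfo = seqinfo)
  })
}

#' Generate a sparse, skewed gene-to-GO map
#'
#' A fraction of genes receives 1-3 terms drawn from a Zipf-weighted
#' vocabulary, so a few terms are common and many are rare — the regime the
#' percentile-based over-representation rule is designed for.
#'
#' @inheritParams generate_tss_reads
#' @return `data.frame` with columns `gene_id`, `go_term`.
#' @export
generate_go_annotations <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), config$n_go_terms >= 1L)
  .with_seed(config$seed + 2L, {
    terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    weights <- seq_len(config$n_go_terms)^(-config$go_skew)
    rows <- list()
    for (g in seq_len(nrow(truth))) {
      if (runif(1L) >= config$go_annotation_rate) next
      k <- min(sample(1:3, 1L), config$n_go_terms)
      picked <- sample(terms, k, prob = weights)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = truth$gene_id[g], go_term = picked,
                   stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
      return(data.frame(gene_id = character(0), go_term = character(0)))
    }
    do.call(rbind, rows)
  })
}

#' Write a simulated study to standard flat formats
#'
#' Emits `scaffolds.fa`, `genes.gff3`, `transposons.bed`, `reads.bed`,
#' `truth.tsv` and `go.tsv` under `dir`. Output is byte-deterministic for
#' a fixed [sim_config()].
#'
#' @param sim Output of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @param reads Optional `GRanges` from [generate_tss_reads()].
#' @param go Optional `data.frame` from [generate_go_annotations()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, reads = NULL, go = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "scaffolds.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             transposons = file.path(dir, "transposons.bed"),
             truth = file.path(dir, "truth.tsv"))
  writeXStringSet(sim$genome, paths[["fasta"]])
  rtracklayer::export(sim$genes, paths[["gff3"]], format = "gff3")
  rtracklayer::export(sim$transposons, paths[["transposons"]],
                      format = "BED")
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(reads)) {
    paths[["reads"]] <- file.path(dir, "reads.bed")
    rtracklayer::export(reads, paths[["reads"]], format = "BED")
  }
  if (!is.null(go)) {
    paths[["go"]] <- file.path(dir, "go.tsv")
    write.table(go, paths[["go"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
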