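# End-to-end driver: reads -> clusters -> shapes -> promoters ->
# composition -> motifs -> statistics.

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_genome()],
#' [generate_tss_reads()] and [generate_go_annotations()] under one
#' config.
#'
#' @param config A [sim_config()].
#' @return List with `sim` (genome/genes/transposons/truth), `reads`, `go`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- generate_genome(config)
  reads <- generate_tss_reads(sim$truth, config)
  go <- generate_go_annotations(sim$truth, config)
  list(sim = sim, reads = reads, go = go)
}

#' Run the full core promoter architecture pipeline
#'
#' Chains tag clustering, tag-count filtering, positional classification,
#' per-gene cluster selection, dominant-TSS and peakedness computation,
#' core promoter extraction with transposon exclusion, composition
#' profiling, window-restricted motif annotation, shuffled-background
#' binomial enrichment, motif co-occurrence, the TATA partition table and
#' GO over-representation.
#'
#' @param reads Stranded `GRanges` of mapped read intervals.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param genes GFF3 `GRanges` of gene models.
#' @param transposons Optional `GRanges` of repeat intervals.
#' @param go_map Optional `data.frame` (`gene_id`, `go_term`).
#' @param models Motif models (default the bundled synthetic PFMs).
#' @param min_tags Tag-count threshold for clusters (default 100).
#' @param utr_upstream Upstream allowance for five_prime classification.
#' @param p_threshold PWM scan p-value threshold (default 1e-2).
#' @param shuffle_seed Seed for the shuffled random promoter set.
#' @param merge_gap See [merge_reads()].
#' @return List with elements `clusters`, `annotations`, `tss_table`,
#'   `promoters`, `composition`, `initiator`, `profiles`, `null_profiles`,
#'   `enrichment`, `cooccurrence2`, `cooccurrence3`, `tata_table`, `go`.
#' @export
run_promoter_pipeline <- function(reads, genome, genes, transposons = NULL,
                                  go_map = NULL, models = promarch_motifs(),
                                  min_tags = 100L, utr_upstream = 300L,
                                  p_threshold = 1e-2, shuffle_seed = 1L,
                                  merge_gap = -1L) {
  genome <- .as_genome(genome)
  clusters <- filter_clusters(merge_reads(reads, merge_gap), min_tags)
  scaffold_lengths <- setNames(width(genome), names(genome))
  ann <- annotate_clusters(clusters, genes, utr_upstream = utr_upstream,
                           scaffold_lengths = scaffold_lengths)

  fp <- which(ann$category == "five_prime")
  sel_idx <- integer(0)
  if (length(fp) > 0L) {
    sel_idx <- vapply(split(fp, ann$gene_id[fp]), function(idx) {
      idx[.select_gene_cluster_idx(clusters[idx])]
    }, integer(1))
  }
  selected <- clusters[sel_idx]
  shapes <- if (length(selected)) promoter_shapes(selected) else
    data.frame(m = integer(0), n = integer(0), w = integer(0),
               sg = numeric(0), n_positions = integer(0),
               shape_class = factor(character(0)))
  tss_table <- data.frame(
    gene_id = ann$gene_id[sel_idx],
    scaffold = as.character(seqnames(selected)),
    tss = if (length(selected)) dominant_tss(selected) else integer(0),
    strand = as.character(strand(selected)),
    shape_class = shapes$shape_class,
    sg = shapes$sg,
    stringsAsFactors = FALSE)

  promoters <- extract_core_promoters(genome, tss_table, transposons)
  keep <- !mcols(promoters)$transposon_overlap
  wide <- extract_tss_windows(genome, tss_table[keep, , drop = FALSE])
  composition <- if (length(wide)) composition_profile(wide) else NULL
  initiator <- if (length(wide))
    initiator_dinucleotide(wide, window = c(200L, 100L)) else NULL

  profiles <- motif_profiles(promoters, models, p_threshold = p_threshold)
  true_promoters <- promoters[keep]
  shuffled <- shuffle_promoters(true_promoters, seed = shuffle_seed)
  null_profiles <- motif_profiles(shuffled, models,
                                  background = profiles$background,
                                  p_threshold = p_threshold)

  enrichment <- NULL
  if (nrow(profiles$profiles) > 0L) {
    motif_names <- vapply(models, `[[`, character(1), "name")
    cls <- unique(profiles$profiles$shape_class)
    enr <- list()
    for (cl in cls) {
      tr <- profiles$profiles[profiles$profiles$shape_class == cl, ]
      rd <- null_profiles$profiles[null_profiles$profiles$shape_class == cl, ]
      for (m in motif_names) {
        enr[[length(enr) + 1L]] <- binomial_enrichment(
          sum(tr[[m]]), sum(rd[[m]]), nrow(tr), motif = m, shape_class = cl)
      }
    }
    enrichment <- do.call(rbind, enr)
  }

  cooc2 <- cooc3 <- tata <- NULL
  if (nrow(profiles$profiles) > 0L) {
    cooc2 <- cooccurrence(profiles$profiles, 2L)
    cooc3 <- cooccurrence(profiles$profiles, 3L)
    tata <- tata_partition_table(profiles$profiles)
  }

  go <- NULL
  if (!is.null(go_map) && nrow(tss_table) > 0L) {
    class_map <- tss_table[, c("gene_id", "shape_class")]
    go <- go_overrepresentation(go_map, class_map)
  }

  list(clusters = clusters, annotations = ann, tss_table = tss_table,
       promoters = promoters, composition = composition,
       initiator = initiator, profiles = profiles,
       null_profiles = null_profiles, enrichment = enrichment,
       cooccurrence2 = cooc2, cooccurrence3 = cooc3, tata_table = tata,
       go = go)
}
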