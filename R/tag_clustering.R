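# Tag clustering: merging mapped 5'-end read intervals into strand-aware
# clusters, tag-count filtering, and positional classification of clusters
# against gene models.

#' Read mapped TSS-seq read intervals from a BED6 file
#'
#' Thin wrapper around [rtracklayer::import()] that enforces the fields the
#' clustering step needs: every interval must carry an explicit strand.
#' Coordinates follow the BED dialect (0-based half-open on disk) and are
#' converted to the 1-based closed convention of [GenomicRanges::GRanges].
#'
#' @param path Path to a BED file (6 or more columns).
#' @return A `GRanges` of read intervals, one per mapped read.
#' @export
read_tss_reads <- function(path) {
  reads <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  st <- as.character(strand(reads))
  if (any(st == "*")) {
    bad <- which(st == "*")
    stop("BED line(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " lack a strand; TSS-seq reads must be stranded")
  }
  reads
}

#' Merge overlapping reads into tag clusters
#'
#' Two reads belong to the same tag cluster iff they are connected by a
#' chain of pairwise same-scaffold, same-strand overlaps of at least one
#' base. Each cluster records its tag count and the histogram of read
#' 5'-end positions (the interval start on `+`, the interval end on `-`),
#' which downstream shape statistics operate on.
#'
#' @param reads A `GRanges` of stranded read intervals (see
#'   [read_tss_reads()]).
#' @param merge_gap Maximum gap (bp) between intervals that are still
#'   merged. The default `-1` requires a true overlap of >= 1 shared base;
#'   `merge_gap = 1` reproduces `bedtools merge -d 1` semantics, which also
#'   joins intervals separated by a single base.
#' @return A `GRanges` of clusters with metadata columns `tag_count`
#'   (integer) and `tss_hist` (an [IRanges::IntegerList] of per-position
#'   5'-end counts, names = genomic positions).
#' @examples
#' reads <- GenomicRanges::GRanges("scf1",
#'   IRanges::IRanges(c(100, 129, 200), width = 31), strand = "+")
#' merge_reads(reads)
#' @export
merge_reads <- function(reads, merge_gap = -1L) {
  stopifnot(methods::is(reads, "GRanges"))
  if (length(reads) == 0L) {
    out <- GRanges()
    mcols(out)$tag_count <- integer(0)
    mcols(out)$tss_hist <- IntegerList()
    return(out)
  }
  .check_strand(as.character(strand(reads)))
  # reduce() merges ranges whose gap is < min.gapwidth; merge_gap = -1
  # (true overlap only) maps to min.gapwidth = 0.
  clusters <- GenomicRanges::reduce(reads, min.gapwidth = merge_gap + 1L,
                                    ignore.strand = FALSE)
  hits <- findOverlaps(reads, clusters, ignore.strand = FALSE)
  if (length(hits) != length(reads)) {
    stop("internal error: reads not uniquely assigned to clusters")
  }
  assign <- integer(length(reads))
  assign[queryHits(hits)] <- subjectHits(hits)
  five_prime <- start(GenomicRanges::resize(reads, width = 1L, fix = "start"))
  hist_list <- lapply(split(five_prime, factor(assign, seq_along(clusters))),
                      function(p) {
                        tab <- table(p)
                        pos <- as.integer(names(tab))
                        o <- order(pos)
                        setNames(as.integer(tab)[o], pos[o])
                      })
  mcols(clusters)$tag_count <- as.integer(lengths(
    split(five_prime, factor(assign, seq_along(clusters)))))
  mcols(clusters)$tss_hist <- IntegerList(hist_list)
  unname(clusters)
}

#' Filter tag clusters by tag count
#'
#' Retains clusters supported by at least `min_tags` reads — the evidence
#' threshold that separates strong transcriptional signal from scattered
#' background tags.
#'
#' @param clusters Output of [merge_reads()].
#' @param min_tags Minimum tag count (default 100).
#' @return The qualifying clusters, input order preserved.
#' @export
filter_clusters <- function(clusters, min_tags = 100L) {
  stopifnot(methods::is(clusters, "GRanges"))
  if (!is.numeric(min_tags) || length(min_tags) != 1L || min_tags < 1) {
    stop("min_tags must be a single count >= 1")
  }
  clusters[mcols(clusters)$tag_count >= min_tags]
}

#' Median gene length of an annotation
#'
#' The median of `gene_end - gene_start + 1` over gene features; used as
#' the default periphery margin when classifying clusters near scaffold
#' ends. An even number of genes yields the mean of the two middle values.
#'
#' @param genes A `GRanges` of gene models (a GFF3 import); if a `type`
#'   column is present only `type == "gene"` rows are used.
#' @return Median gene length in bp.
#' @export
median_gene_length <- function(genes) {
  genes <- .gene_rows(genes)
  if (length(genes) == 0L) stop("annotation contains no gene features")
  stats::median(width(genes))
}

.gene_rows <- function(genes) {
  stopifnot(methods::is(genes, "GRanges"))
  if (!is.null(mcols(genes)$type)) {
    genes <- genes[as.character(mcols(genes)$type) == "gene"]
  }
  genes
}

# Resolve gene/five_prime_UTR/CDS features from a GFF3 GRanges, following
# Parent chains of depth <= 2 (CDS -> mRNA -> gene).
.gene_features <- function(gff) {
  stopifnot(methods::is(gff, "GRanges"))
  type <- as.character(mcols(gff)$type)
  if (is.null(type)) stop("gene models must carry a 'type' column (GFF3 import)")
  ids <- as.character(mcols(gff)$ID)
  parents <- mcols(gff)$Parent
  parent1 <- if (is.null(parents)) rep(NA_character_, length(gff)) else
    vapply(as.list(parents), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  gene_of <- setNames(ids[type == "gene"], ids[type == "gene"])
  resolve <- function(id) {
    for (i in 1:3) {
      if (is.na(id)) return(NA_character_)
      if (id %in% names(gene_of)) return(gene_of[[id]])
      j <- match(id, ids)
      if (is.na(j)) return(NA_character_)
      id <- parent1[j]
    }
    NA_character_
  }
  feat_gene <- vapply(ifelse(type == "gene", ids, parent1), resolve, character(1))
  genes <- gff[type == "gene"]
  mcols(genes)$gene_id <- ids[type == "gene"]
  utr5 <- gff[type == "five_prime_UTR"]
  mcols(utr5)$gene_id <- feat_gene[type == "five_prime_UTR"]
  cds <- gff[type == "CDS"]
  mcols(cds)$gene_id <- feat_gene[type == "CDS"]
  # first coding exon in transcript orientation
  cds1 <- GRanges()
  if (length(cds) > 0L) {
    key <- mcols(cds)$gene_id
    pick <- tapply(seq_along(cds), key, function(i) {
      if (as.character(strand(cds))[i[1L]] == "+") i[which.min(start(cds)[i])]
      else i[which.max(end(cds)[i])]
    })
    cds1 <- cds[unlist(pick)]
  }
  list(genes = genes, utr5 = utr5, cds1 = cds1)
}

#' Classify tag clusters by position relative to gene models
#'
#' Assigns each cluster one of five categories, in decreasing precedence:
#' \describe{
#'   \item{five_prime}{overlaps a gene's first coding exon or 5'UTR, or
#'     lies within `utr_upstream` bases upstream (transcript orientation)
#'     of the 5'UTR start — or of the first coding exon when the 5'UTR is
#'     absent or 10 bp or shorter. These are the promoter-bearing clusters.}
#'   \item{other_genic}{overlaps any other part of a same-strand gene.}
#'   \item{geneless_scaffold}{its scaffold carries no gene feature.}
#'   \item{periphery}{within `periphery_margin` of a scaffold end, so a
#'     flanking gene may simply be missing from the fragmented assembly.}
#'   \item{intergenic}{anything else.}
#' }
#' All gene-relative tests are same-strand.
#'
#' @param clusters Output of [merge_reads()]/[filter_clusters()].
#' @param genes GFF3 `GRanges` with gene / five_prime_UTR / CDS features.
#' @param utr_upstream Upstream allowance in bp (default 300, a typical
#'   mean 5'UTR length).
#' @param periphery_margin Distance (bp) from a scaffold end within which
#'   an unassigned cluster is called periphery; defaults to
#'   [median_gene_length()] of `genes`.
#' @param scaffold_lengths Named integer vector of scaffold lengths; taken
#'   from `seqlengths(clusters)` when omitted. Required for the periphery
#'   rule; a cluster on a scaffold absent from it is an error.
#' @return A `data.frame` with one row per cluster: `scaffold`, `strand`,
#'   `start`, `end`, `tag_count`, `category`, `gene_id`.
#' @export
annotate_clusters <- function(clusters, genes, utr_upstream = 300L,
                              periphery_margin = NULL,
                              scaffold_lengths = NULL) {
  stopifnot(methods::is(clusters, "GRanges"))
  feats <- .gene_features(genes)
  if (is.null(periphery_margin)) {
    periphery_margin <- if (length(feats$genes)) median_gene_length(feats$genes)
                        else 0
  }
  if (is.null(scaffold_lengths)) {
    sl <- seqlengths(clusters)
    scaffold_lengths <- sl[!is.na(sl)]
  }
  missing_scf <- setdiff(as.character(seqnames(clusters)), names(scaffold_lengths))
  if (length(missing_scf) > 0L) {
    stop("cluster scaffold(s) absent from the genome index: ",
         paste(unique(missing_scf), collapse = ", "))
  }

  # 5' zone per gene: union of 5'UTR, first CDS and the upstream allowance
  zones <- GRanges()
  if (length(feats$genes) > 0L) {
    zone_list <- lapply(mcols(feats$genes)$gene_id, function(g) {
      utr <- feats$utr5[mcols(feats$utr5)$gene_id == g]
      cds1 <- feats$cds1[mcols(feats$cds1)$gene_id == g]
      anchor <- if (length(utr) > 0L && sum(width(utr)) > 10L) utr else cds1
      parts <- c(granges(utr), granges(cds1))
      if (length(anchor) > 0L) {
        a <- GenomicRanges::reduce(granges(anchor))
        a <- if (as.character(strand(a))[1L] == "+") a[which.min(start(a))]
             else a[which.max(end(a))]
        parts <- c(parts, GenomicRanges::flank(a, utr_upstream, start = TRUE))
      }
      z <- GenomicRanges::reduce(parts)
      z <- restrict(z, start = 1L)
      mcols(z)$gene_id <- rep(g, length(z))
      z
    })
    zones <- do.call(c, zone_list)
  }

  n <- length(clusters)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)

  # harmonize sequence levels so overlap queries do not warn when clusters
  # and annotation cover disjoint scaffold sets
  lv <- union(seqlevels(clusters), seqlevels(feats$genes))
  suppressWarnings({
    seqlevels(clusters) <- lv
    seqlevels(feats$genes) <- lv
    if (length(zones)) seqlevels(zones) <- lv
  })

  genic_hits <- findOverlaps(clusters, feats$genes, ignore.strand = FALSE)
  fp_hits <- if (length(zones)) findOverlaps(clusters, zones,
                                             ignore.strand = FALSE)
             else Hits()

  if (length(genic_hits) > 0L) {
    first <- !duplicated(queryHits(genic_hits))
    category[queryHits(genic_hits)[first]] <- "other_genic"
    gene_id[queryHits(genic_hits)[first]] <-
      mcols(feats$genes)$gene_id[subjectHits(genic_hits)[first]]
  }
  if (length(fp_hits) > 0L) {
    # widest overlap decides the gene when zones of neighbours touch
    ov <- width(pintersect(ranges(clusters)[queryHits(fp_hits)],
                           ranges(zones)[subjectHits(fp_hits)],
                           resolve.empty = "max.start"))
    o <- order(queryHits(fp_hits), -ov)
    first <- !duplicated(queryHits(fp_hits)[o])
    qi <- queryHits(fp_hits)[o][first]
    category[qi] <- "five_prime"
    gene_id[qi] <- mcols(zones)$gene_id[subjectHits(fp_hits)[o][first]]
  }

  gene_scaffolds <- unique(as.character(seqnames(feats$genes)))
  unassigned <- category == "intergenic"
  scf <- as.character(seqnames(clusters))
  geneless <- unassigned & !(scf %in% gene_scaffolds)
  category[geneless] <- "geneless_scaffold"
  unassigned <- category == "intergenic"
  if (any(unassigned)) {
    len <- scaffold_lengths[scf[unassigned]]
    near_end <- start(clusters)[unassigned] <= periphery_margin |
      (len - end(clusters)[unassigned]) < periphery_margin
    category[which(unassigned)[near_end]] <- "periphery"
  }

  data.frame(
    scaffold = scf,
    strand = as.character(strand(clusters)),
    start = start(clusters),
    end = end(clusters),
    tag_count = mcols(clusters)$tag_count,
    category = factor(category, levels = c("five_prime", "other_genic",
                                           "intergenic", "geneless_scaffold",
                                           "periphery")),
    gene_id = gene_id,
    stringsAsFactors = FALSE
  )
}
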