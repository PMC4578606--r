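test_that("overlapping reads merge into clusters; abutting reads do not", {
  # [100,130), [129,160), [200,230) in BED terms: first two share base 129
  reads <- GRanges("scf", IRanges(start = c(100L, 129L, 200L),
                                  end = c(129L, 159L, 229L)), strand = "+")
  cl <- merge_reads(reads)
  expect_equal(length(cl), 2L)
  expect_equal(start(cl), c(100L, 200L))
  expect_equal(end(cl), c(159L, 229L))
  expect_equal(mcols(cl)$tag_count, c(2L, 1L))

  # zero shared bases -> two clusters under the default true-overlap rule
  abutting <- GRanges("scf", IRanges(start = c(100L, 130L),
                                     end = c(129L, 159L)), strand = "+")
  expect_equal(length(merge_reads(abutting)), 2L)
  # bedtools -d 1 semantics join them
  expect_equal(length(merge_reads(abutting, merge_gap = 1L)), 1L)

  expect_equal(length(merge_reads(GRanges())), 0L)
})

test_that("clusters are strand- and scaffold-separated and histograms track 5' ends", {
  reads <- suppressWarnings(
    c(make_reads(c(500L, 500L, 510L), "+"),
      make_reads(c(505L, 505L), "-"),
      make_reads(510L, "+", scaffold = "scf2")))
  cl <- merge_reads(reads)
  expect_equal(length(cl), 3L)
  plus <- cl[strand(cl) == "+" & seqnames(cl) == "scf"]
  h <- as.list(mcols(plus)$tss_hist)[[1L]]
  expect_equal(h, setNames(c(2L, 1L), c(500L, 510L)))
  minus <- cl[strand(cl) == "-"]
  hm <- as.list(mcols(minus)$tss_hist)[[1L]]
  # on the minus strand the 5' end is the interval end
  expect_equal(hm, setNames(2L, 505L))
})

test_that("merging matches a brute-force connected-components oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(1:60, 1L)
    reads <- GRanges(sample(c("s1", "s2"), n, replace = TRUE),
                     IRanges(start = sample.int(400L, n, replace = TRUE),
                             width = sample(10:40, n, replace = TRUE)),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    cl <- merge_reads(reads)
    expect_equal(partition_signature(merge_membership(reads, cl)),
                 partition_signature(oracle_clusters(reads)))
    # partition invariant: tag counts sum to the read count, clusters
    # never overlap within a strand
    expect_equal(sum(mcols(cl)$tag_count), n)
    expect_true(isDisjoint(cl))
  }
})

test_that("tag-count filtering applies the threshold and is monotone", {
  pos <- c(rep(1000L, 40L), rep(3000L, 100L), rep(5000L, 350L))
  cl <- merge_reads(make_reads(pos))
  expect_equal(mcols(filter_clusters(cl))$tag_count, c(100L, 350L))
  expect_equal(length(filter_clusters(cl, 1L)), length(cl))
  expect_error(filter_clusters(cl, 0L), "min_tags")
  sizes <- vapply(c(1L, 50L, 100L, 200L, 400L),
                  function(t) length(filter_clusters(cl, t)), integer(1))
  expect_true(all(diff(sizes) <= 0L))
  # boundary: 99 drops, 100 stays
  cl99 <- merge_reads(make_reads(rep(700L, 99L)))
  expect_equal(length(filter_clusters(cl99)), 0L)
})

test_that("median gene length follows the even/odd median definition", {
  g <- function(lens) {
    gr <- GRanges("s", IRanges(start = cumsum(rep(10000L, length(lens))),
                               width = lens))
    mcols(gr)$type <- "gene"
    gr
  }
  expect_equal(median_gene_length(g(1000L)), 1000)
  expect_equal(median_gene_length(g(c(1000L, 2000L, 4000L))), 2000)
  expect_equal(median_gene_length(g(c(1000L, 3000L))), 2000)
  empty <- GRanges()
  mcols(empty)$type <- character(0)
  expect_error(median_gene_length(empty), "no gene")
})

test_that("cluster positional classification follows the precedence rules", {
  genes <- toy_gene_model(start = 2000L, end = 6000L, strand = "+",
                          utr_len = 200L)
  sl <- c(scf = 20000L, bare = 20000L)
  classify <- function(cl) {
    annotate_clusters(cl, genes, scaffold_lengths = sl)$category
  }
  # 250 bp upstream of the 5'UTR start, same strand -> five_prime
  up <- merge_reads(make_reads(rep(1750L, 5L)))
  expect_equal(as.character(classify(up)), "five_prime")
  # inside the 5'UTR itself
  expect_equal(as.character(classify(merge_reads(make_reads(rep(2100L, 5L))))),
               "five_prime")
  # wholly inside the intron between the two CDS exons -> other_genic
  intron <- merge_reads(make_reads(rep(4000L, 5L)))
  expect_equal(as.character(classify(intron)), "other_genic")
  # same location, opposite strand: not assignable to the gene; the gene
  # spans most of the scaffold so the margin rule kicks in
  anti <- merge_reads(make_reads(rep(4000L, 5L), strand = "-"))
  expect_true(as.character(classify(anti)) %in% c("periphery", "intergenic"))
  # scaffold with no gene features
  bare <- merge_reads(make_reads(rep(4000L, 5L), scaffold = "bare"))
  expect_equal(as.character(classify(bare)), "geneless_scaffold")
  # far from genes and far from scaffold ends -> intergenic
  mid <- merge_reads(make_reads(rep(12000L, 5L)))
  expect_equal(
    as.character(annotate_clusters(mid, genes, periphery_margin = 2000L,
                                   scaffold_lengths = sl)$category),
    "intergenic")
  # near the scaffold end -> periphery
  edge <- merge_reads(make_reads(rep(19500L, 5L)))
  expect_equal(
    as.character(annotate_clusters(edge, genes, periphery_margin = 2000L,
                                   scaffold_lengths = sl)$category),
    "periphery")
  # unknown scaffold -> lookup error
  stray <- merge_reads(make_reads(rep(100L, 5L), scaffold = "nope"))
  expect_error(annotate_clusters(stray, genes, scaffold_lengths = sl),
               "absent")
})

test_that("five_prime outranks other_genic and short UTRs fall back to CDS1", {
  genes <- toy_gene_model(start = 2000L, end = 6000L, strand = "+",
                          utr_len = 200L)
  sl <- c(scf = 20000L)
  # span from upstream into the first CDS: overlaps both zone and body
  span <- merge_reads(make_reads(seq(2150L, 2350L, by = 10L)))
  ann <- annotate_clusters(span, genes, scaffold_lengths = sl)
  expect_equal(as.character(ann$category), "five_prime")
  expect_equal(ann$gene_id, "g1")

  # UTR of <= 10 bp: upstream window anchors on the first coding exon
  short <- toy_gene_model(start = 2000L, end = 6000L, strand = "+",
                          utr_len = 8L)
  up <- merge_reads(make_reads(rep(1900L, 5L)))
  expect_equal(
    as.character(annotate_clusters(up, short, scaffold_lengths = sl)$category),
    "five_prime")
})

test_that("minus-strand genes classify upstream clusters in transcript orientation", {
  genes <- toy_gene_model(start = 2000L, end = 6000L, strand = "-",
                          utr_len = 200L)
  sl <- c(scf = 20000L)
  # upstream of a minus-strand gene means higher coordinates
  up <- merge_reads(make_reads(rep(6250L, 5L), strand = "-"))
  expect_equal(
    as.character(annotate_clusters(up, genes, scaffold_lengths = sl)$category),
    "five_prime")
})
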