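# Enrichment statistics: shuffled null promoters, exact binomial
# real-vs-random motif enrichment, motif co-occurrence with confidence
# interval flags, TATA partition table, and percentile-rule GO
# over-representation.

#' Shuffle promoter sequences to build a random promoter set
#'
#' Each sequence is independently permuted (a uniform random permutation of
#' its own bases), so the random set preserves the exact per-sequence
#' nucleotide counts of the true core promoters while destroying positional
#' motifs — preferable to coding or intergenic background sequence, which
#' carries its own composition bias.
#'
#' @param promoters `DNAStringSet` or character vector.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return `DNAStringSet` of shuffled sequences (names and metadata
#'   columns preserved).
#' @export
shuffle_promoters <- function(promoters, seed = 1L) {
  chr <- as.character(promoters)
  if (length(chr) == 0L) stop("no sequences to shuffle")
  shuffled <- .with_seed(seed, {
    vapply(chr, function(s) {
      paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  out <- DNAStringSet(shuffled)
  names(out) <- names(promoters)
  if (methods::is(promoters, "DNAStringSet")) mcols(out) <- mcols(promoters)
  out
}

#' Exact binomial enrichment of motif counts, real vs random
#'
#' Tests whether the number of true promoters carrying a motif exceeds the
#' number observed in the matched shuffled (random) promoter set. The
#' random count defines the null proportion with a continuity pseudocount,
#' `p_hat = (random_count + 0.5) / (n + 1)`, and the one-sided p-value is
#' the exact binomial upper tail `P(X >= true_count)` for
#' `X ~ Binomial(n, p_hat)`.
#'
#' @param true_count,random_count Promoters with the motif in the true and
#'   shuffled sets (vectors allowed).
#' @param n Number of promoters scanned in each set.
#' @param motif,shape_class Optional labels carried into the result.
#' @return `data.frame` with `motif`, `shape_class`, `true_count`,
#'   `random_count`, `n_promoters`, `p_value`.
#' @export
binomial_enrichment <- function(true_count, random_count, n,
                                motif = NA_character_,
                                shape_class = NA_character_) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(true_count < 0 | true_count > n) ||
      any(random_count < 0 | random_count > n)) {
    stop("counts must lie in [0, n]")
  }
  p_hat <- (random_count + 0.5) / (n + 1)
  p <- pbinom(true_count - 1, n, p_hat, lower.tail = FALSE)
  data.frame(motif = motif, shape_class = shape_class,
             true_count = true_count, random_count = random_count,
             n_promoters = n, p_value = p)
}

#' Two- and three-way motif co-occurrence with CI flags
#'
#' For every pair (`k = 2`; 15 combinations over six motifs) or triple
#' (`k = 3`; 20 combinations) and every promoter shape class, compares the
#' observed percent of promoters carrying all motifs of the set with the
#' percent expected under independence (the product of the class-specific
#' marginal frequencies). A 95 % interval around the expected proportion
#' `e`, scaled by the class sample size `N`, flags combinations whose
#' observed value falls above (`over`) or below (`under`) the band.
#'
#' Three interval constructions are available. The default,
#' `"independence"`, is a delta-method band for the difference between the
#' observed proportion and the plug-in independence expectation: under
#' independence `Var(obs - e) = (e (1 - e) - e^2 sum_i (1 - p_i)/p_i) / N`
#' (the covariance between the observed count and the estimated marginals
#' is subtracted), so flags fire at the nominal two-sided rate. `"wald"`
#' is the simpler band `e +/- z * sqrt(e (1 - e) / N)`, which ignores that
#' covariance and is therefore conservative (it under-fires under
#' independence). `"exact"` uses binomial quantiles of `Binomial(N, e)`.
#'
#' @param profiles The `profiles` data.frame from [motif_profiles()]
#'   (logical motif columns plus `shape_class`).
#' @param k Combination size, 2 or 3.
#' @param motifs Motif column names (default the six canonical motifs
#'   present in `profiles`).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"independence"` (default), `"wald"` or `"exact"`.
#' @return `data.frame` with `combination`, `shape_class`, `n`,
#'   `observed_pct`, `expected_pct`, `lower_pct`, `upper_pct`, `flag`.
#' @export
cooccurrence <- function(profiles, k = 2L, motifs = NULL,
                         conf_level = 0.95,
                         ci_method = c("independence", "wald", "exact")) {
  ci_method <- match.arg(ci_method)
  stopifnot(k %in% c(2L, 3L))
  if (is.null(motifs)) motifs <- intersect(.canonical_motifs, names(profiles))
  if (length(motifs) < k) stop("need at least k motif columns")
  classes <- unique(as.character(profiles$shape_class))
  combos <- combn(motifs, k, simplify = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (cl in classes) {
    sub <- profiles[profiles$shape_class == cl, , drop = FALSE]
    N <- nrow(sub)
    if (N == 0L) {
      warning("shape class '", cl, "' has no promoters; omitted")
      next
    }
    marg <- vapply(motifs, function(m) mean(sub[[m]]), numeric(1))
    for (cb in combos) {
      obs <- mean(Reduce(`&`, lapply(cb, function(m) sub[[m]])))
      e <- prod(marg[cb])
      if (ci_method == "independence") {
        p_i <- marg[cb]
        v <- if (e <= 0 || any(p_i <= 0)) 0 else
          max(0, e * (1 - e) - e^2 * sum((1 - p_i) / p_i)) / N
        half <- z * sqrt(v)
        lower <- max(0, e - half); upper <- min(1, e + half)
      } else if (ci_method == "wald") {
        half <- z * sqrt(e * (1 - e) / N)
        lower <- max(0, e - half); upper <- min(1, e + half)
      } else {
        lower <- qbinom((1 - conf_level) / 2, N, e) / N
        upper <- qbinom(1 - (1 - conf_level) / 2, N, e) / N
      }
      flag <- if (obs > upper) "over" else if (obs < lower) "under" else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste(cb, collapse = "-"), shape_class = cl, n = N,
        observed_pct = 100 * obs, expected_pct = 100 * e,
        lower_pct = 100 * lower, upper_pct = 100 * upper, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Motif occurrence in TATA-containing vs TATA-less promoters
#'
#' Percent occurrence of each motif in the two TATA partitions; by
#' construction the TATA row of the TATA-less column is 0.
#'
#' @param profiles `profiles` data.frame from [motif_profiles()].
#' @param motifs Motif column names (default canonical motifs present).
#' @return `data.frame` with `motif`, `pct_tata_containing`,
#'   `pct_tata_less`, `n_tata_containing`, `n_tata_less`.
#' @export
tata_partition_table <- function(profiles, motifs = NULL) {
  if (nrow(profiles) == 0L) stop("no promoter profiles supplied")
  if (is.null(motifs)) motifs <- intersect(.canonical_motifs, names(profiles))
  has <- profiles$tata_status == "TATA_containing"
  if (!any(has)) warning("no TATA-containing promoters")
  if (all(has)) warning("no TATA-less promoters")
  pct <- function(idx) {
    if (!any(idx)) return(rep(NA_real_, length(motifs)))
    vapply(motifs, function(m) 100 * mean(profiles[[m]][idx]), numeric(1))
  }
  data.frame(motif = motifs,
             pct_tata_containing = pct(has),
             pct_tata_less = pct(!has),
             n_tata_containing = sum(has), n_tata_less = sum(!has),
             row.names = NULL)
}

#' GO term over-representation by the 75th-percentile rule
#'
#' Within each promoter shape class, GO annotation counts are summed per
#' term and a term is reported as over-represented when its count reaches
#' the nearest-rank 75th percentile of the class's term-count distribution
#' (the value at rank `ceiling(0.75 * n_terms)` of the sorted counts).
#'
#' @param go_map `data.frame` with columns `gene_id`, `go_term` (one row
#'   per annotation).
#' @param class_map `data.frame` with columns `gene_id`, `shape_class`.
#' @param prob Percentile as a probability (default 0.75).
#' @return `data.frame` with `shape_class`, `go_term`, `count`,
#'   `threshold`, over-represented terms only.
#' @export
go_overrepresentation <- function(go_map, class_map, prob = 0.75) {
  stopifnot(all(c("gene_id", "go_term") %in% names(go_map)),
            all(c("gene_id", "shape_class") %in% names(class_map)))
  merged <- merge(go_map, class_map, by = "gene_id")
  classes <- unique(as.character(class_map$shape_class))
  rows <- list()
  for (cl in classes) {
    sub <- merged[merged$shape_class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("shape class '", cl, "' has no annotated genes; omitted")
      next
    }
    counts <- sort(table(sub$go_term), decreasing = TRUE)
    thr <- .nearest_rank(as.integer(counts), prob)
    keep <- counts >= thr
    rows[[length(rows) + 1L]] <- data.frame(
      shape_class = cl, go_term = names(counts)[keep],
      count = as.integer(counts[keep]), threshold = thr,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(shape_class = character(0), go_term = character(0),
                      count = integer(0), threshold = integer(0)))
  }
  do.call(rbind, rows)
}

# Nearest-rank percentile: value at rank ceiling(prob * n) of the sorted
# (ascending) vector.
.nearest_rank <- function(x, prob) {
  s <- sort(x)
  s[max(1L, ceiling(prob * length(s)))]
}
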