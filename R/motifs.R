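# Core promoter motif annotation: JASPAR PFM parsing, input-estimated
# background, PWM log-odds scanning with exact score-distribution p-values
# (dynamic-programming convolution of per-column score distributions), and
# window-restricted hit filtering.

#' Default functional genomic windows of the canonical core motifs
#'
#' TSS-relative intervals (+1 = TSS base, no position 0) inside which each
#' canonical motif is biologically functional. Hits starting outside the
#' window (after the +/- elasticity allowance) are discarded. These are the
#' canonical literature placements and are fully configurable.
#'
#' @return Named list of integer pairs `c(start, end)`.
#' @export
default_motif_windows <- function() {
  list(BREu = c(-38L, -32L), TATA = c(-31L, -24L), BREd = c(-23L, -17L),
       INR = c(-2L, 4L), MTE = c(18L, 27L), DPE = c(28L, 32L))
}

#' Construct a motif model
#'
#' @param name Motif name (e.g. `"TATA"`).
#' @param pfm 4 x L base-count matrix with rownames A, C, G, T; counts must
#'   be non-negative with a positive total in every column.
#' @param window Integer pair: TSS-relative functional window of the motif
#'   start position.
#' @param elasticity Allowed slack (bp) on each side of the window
#'   (default 5).
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, pfm, window, elasticity = 5L) {
  pfm <- as.matrix(pfm)
  if (is.null(rownames(pfm))) rownames(pfm) <- DNA_BASES
  pfm <- pfm[DNA_BASES, , drop = FALSE]
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(pfm) <= 0)) stop("every PFM column needs a positive total count")
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be an increasing integer pair")
  }
  structure(list(name = name, pfm = pfm, window = window,
                 elasticity = as.integer(elasticity)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model ", x$name, ": length ", ncol(x$pfm),
      ", window [", x$window[1L], ", ", x$window[2L], "] +/- ",
      x$elasticity, " bp\n", sep = "")
  invisible(x)
}

#' Read position frequency matrices in JASPAR PFM format
#'
#' Parses the JASPAR flat text format: a `>identifier name` header followed
#' by four rows of counts, either bracketed (`A [ 3 10 ... ]`) or plain.
#' Functional windows are attached from `windows` by motif name; matrices
#' whose name has no configured window get an `NA` window and must be
#' assigned one before scanning.
#'
#' @param path PFM file (may contain several matrices).
#' @param windows Named list of windows as in [default_motif_windows()].
#' @param elasticity Window slack in bp (default 5).
#' @return Named list of [motif_model()] objects (empty, with a warning,
#'   for an empty file).
#' @export
read_jaspar <- function(path, windows = default_motif_windows(),
                        elasticity = 5L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty PFM file: ", path)
    return(list())
  }
  headers <- grep("^>", lines)
  if (length(headers) == 0L) headers <- integer(0)
  blocks <- if (length(headers)) {
    Map(function(s, e) lines[s:e], headers,
        c(headers[-1L] - 1L, length(lines)))
  } else list(c(">motif", lines))
  models <- lapply(blocks, function(bl) {
    header <- sub("^>", "", bl[1L])
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rows <- bl[-1L]
    if (length(rows) != 4L) {
      stop("PFM block '", name, "' must have exactly 4 count rows, found ",
           length(rows))
    }
    parsed <- lapply(rows, function(r) {
      lab <- sub("^\\s*([ACGTacgt])[\\s\\[:].*$", "\\1", r, perl = TRUE)
      if (!toupper(lab) %in% DNA_BASES) lab <- NA_character_
      nums <- gsub("[^0-9eE+.-]", " ", sub("^\\s*[ACGTacgt]?", "", r))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (anyNA(vals)) stop("unparseable counts in PFM row: ", r)
      list(label = toupper(lab), counts = vals)
    })
    lens <- vapply(parsed, function(p) length(p$counts), integer(1))
    if (length(unique(lens)) != 1L) {
      stop("PFM '", name, "': rows have differing lengths (",
           paste(lens, collapse = ", "), ")")
    }
    m <- do.call(rbind, lapply(parsed, `[[`, "counts"))
    labs <- vapply(parsed, `[[`, character(1), "label")
    rownames(m) <- if (anyNA(labs)) DNA_BASES else labs
    if (any(m < 0)) stop("PFM '", name, "' contains negative counts")
    win <- windows[[name]]
    if (is.null(win)) win <- c(NA_integer_, NA_integer_)
    structure(list(name = name, pfm = m[DNA_BASES, , drop = FALSE],
                   window = as.integer(win),
                   elasticity = as.integer(elasticity)),
              class = "motif_model")
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  models
}

#' Write motif models in JASPAR PFM format
#'
#' @param models List of [motif_model()] objects.
#' @param path Output file.
#' @export
write_jaspar <- function(models, path) {
  if (methods::is(models, "motif_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(paste0(">", m$name, " ", m$name), con)
    for (b in DNA_BASES) {
      writeLines(paste0(b, " [ ", paste(m$pfm[b, ], collapse = " "), " ]"),
                 con)
    }
  }
  invisible(path)
}

#' Bundled synthetic PFMs for the six canonical core motifs
#'
#' Loads the consensus-derived count matrices shipped with the package
#' (files `inst/extdata/pfm/synthetic_*.pfm`). These are synthetic stand-in
#' matrices built from the canonical consensus of each motif, not
#' database-curated PFMs; substitute curated matrices via [read_jaspar()]
#' for real analyses.
#'
#' @inheritParams read_jaspar
#' @return Named list of [motif_model()] objects, one per canonical motif.
#' @export
promarch_motifs <- function(windows = default_motif_windows(),
                            elasticity = 5L) {
  dir <- system.file("extdata", "pfm", package = "promarch")
  files <- list.files(dir, pattern = "\\.pfm$", full.names = TRUE)
  models <- list()
  for (f in files) models <- c(models, read_jaspar(f, windows, elasticity))
  models[intersect(.canonical_motifs, names(models))]
}

#' Mononucleotide background model estimated from input sequences
#'
#' Base frequencies over all promoter bases (ambiguous bases excluded).
#' Zero frequencies are floored at 1e-4 and the vector renormalized, so
#' log-odds scores stay finite even for degenerate inputs.
#'
#' @param promoters `DNAStringSet` or character vector.
#' @param floor Minimum frequency after flooring (default 1e-4).
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @export
background_model <- function(promoters, floor = 1e-4) {
  if (is.character(promoters)) promoters <- DNAStringSet(promoters)
  if (length(promoters) == 0L) stop("no sequences supplied")
  counts <- colSums(letterFrequency(promoters, DNA_BASES))
  if (sum(counts) == 0) stop("sequences contain no unambiguous bases")
  p <- counts / sum(counts)
  p <- pmax(p, floor)
  p <- p / sum(p)
  setNames(as.numeric(p), DNA_BASES)
}

# Discretized log-odds score matrix: integer units of `grid` bits.
# Pseudocount is added per cell before column normalization.
.pwm_int_scores <- function(pfm, background, pseudocount = 0.8,
                            grid = 1e-3) {
  probs <- sweep(pfm + pseudocount, 2L, colSums(pfm + pseudocount), "/")
  s <- log2(probs / background[DNA_BASES])
  round(s / grid)
}

# Exact distribution of the total discretized score under the background:
# successive convolution of the per-column 4-point score distributions.
# Returns the upper-tail function as a step lookup.
.score_distribution <- function(K, background) {
  L <- ncol(K)
  offset <- 0L            # integer score corresponding to dist index 1
  dist <- 1
  for (j in seq_len(L)) {
    kj <- K[, j]
    lo <- min(kj); hi <- max(kj)
    new_len <- length(dist) + (hi - lo)
    nd <- numeric(new_len)
    for (b in seq_len(4L)) {
      sh <- kj[b] - lo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + background[b] * dist
    }
    dist <- nd
    offset <- offset + lo
  }
  tail_p <- rev(cumsum(rev(dist)))    # P(total >= offset + i - 1)
  list(offset = offset, tail_p = tail_p,
       max_int = offset + length(dist) - 1L)
}

# P(total integer score >= s) under the background.
.score_pvalue <- function(sd, s) {
  i <- s - sd$offset + 1L
  n <- length(sd$tail_p)
  out <- numeric(length(s))
  out[i <= 1L] <- 1
  inside <- i >= 1L & i <= n
  out[inside] <- sd$tail_p[i[inside]]
  out[i > n] <- 0
  pmin(pmax(out, 0), 1)
}

#' Scan a core promoter with one motif model
#'
#' Computes the PWM log-odds score at every start position of the promoter
#' (pseudocount added per PFM cell before column normalization; scores
#' discretized to a 1e-3-bit grid), assigns each score an exact p-value --
#' the probability of an equal-or-better score under the mononucleotide
#' background, obtained by dynamic-programming convolution of the
#' per-column score distributions -- and retains hits with
#' `p_value <= p_threshold` whose start position lies inside the motif's
#' functional window extended by its elasticity. Promoters containing
#' ambiguous bases are skipped with a warning.
#'
#' @param promoter A single sequence (character, `DNAString`, or a
#'   length-1 `DNAStringSet`) in transcript orientation, spanning
#'   `-window[1]..+window[2]` around the TSS.
#' @param model A [motif_model()].
#' @param background Background base frequencies (see [background_model()]).
#' @param p_threshold Per-position p-value threshold (default 1e-2).
#' @param pseudocount PFM smoothing added to every cell (default 0.8).
#' @param grid Score discretization in bits (default 1e-3).
#' @param window Integer pair `c(up, down)` describing the promoter span
#'   (default `c(50, 50)`).
#' @param apply_window If `FALSE`, report all significant hits without the
#'   functional-window restriction.
#' @return `data.frame` with columns `motif`, `start` (TSS-relative label
#'   of the match start), `score` (bits, on the discretized grid),
#'   `p_value`.
#' @export
scan_promoter <- function(promoter, model, background,
                          p_threshold = 1e-2, pseudocount = 0.8,
                          grid = 1e-3, window = c(50L, 50L),
                          apply_window = TRUE) {
  if (methods::is(promoter, "DNAStringSet")) promoter <- promoter[[1L]]
  seq <- toupper(as.character(promoter))
  L <- ncol(model$pfm)
  empty <- data.frame(motif = character(0), start = integer(0),
                      score = numeric(0), p_value = numeric(0))
  if (nchar(seq) < L) {
    warning("promoter shorter than motif ", model$name, "; no hits")
    return(empty)
  }
  bases <- strsplit(seq, "")[[1L]]
  if (any(!bases %in% DNA_BASES)) {
    warning("promoter contains ambiguous bases; skipped by the PWM scanner")
    return(empty)
  }
  K <- .pwm_int_scores(model$pfm, background, pseudocount, grid)
  sd <- .score_distribution(K, background)
  code <- match(bases, DNA_BASES)
  n_pos <- length(bases) - L + 1L
  ints <- vapply(seq_len(n_pos), function(i) {
    sum(K[cbind(code[i:(i + L - 1L)], seq_len(L))])
  }, numeric(1))
  pvals <- .score_pvalue(sd, ints)
  labels <- .label_positions(window[1L], window[2L])[seq_len(n_pos)]
  keep <- pvals <= p_threshold
  if (apply_window) {
    if (anyNA(model$window)) {
      stop("motif ", model$name, " has no functional window configured")
    }
    lo <- model$window[1L] - model$elasticity
    hi <- model$window[2L] + model$elasticity
    keep <- keep & labels >= lo & labels <= hi
  }
  data.frame(motif = rep(model$name, sum(keep)), start = labels[keep],
             score = ints[keep] * grid, p_value = pvals[keep])
}

#' Motif presence profiles and occurrence tables
#'
#' Scans every (non-transposon) promoter with every motif model and
#' collapses multiple hits of a motif to a presence/absence flag. The
#' summary reports percent occurrence per motif overall, per shape class,
#' and split by TATA status, plus the fraction of promoters with no
#' canonical motif at all.
#'
#' @param promoters `DNAStringSet` from [extract_core_promoters()]; the
#'   metadata columns `shape_class` and `transposon_overlap` are used when
#'   present (flagged promoters are excluded).
#' @param models Named list of [motif_model()] objects.
#' @param background Background base frequencies; estimated from the
#'   scanned promoters when `NULL`.
#' @inheritParams scan_promoter
#' @return List with elements `profiles` (`data.frame`: `promoter_id`,
#'   `shape_class`, one logical column per motif, `tata_status`,
#'   `any_motif`), `occurrence` (`data.frame` of percent occurrence per
#'   motif x class), `pct_any_motif`, and `background`.
#' @export
motif_profiles <- function(promoters, models, background = NULL,
                           p_threshold = 1e-2, pseudocount = 0.8,
                           grid = 1e-3, window = c(50L, 50L)) {
  stopifnot(length(models) > 0L)
  md <- mcols(promoters)
  if (!is.null(md$transposon_overlap)) {
    promoters <- promoters[!md$transposon_overlap]
    md <- mcols(promoters)
  }
  motif_names <- vapply(models, `[[`, character(1), "name")
  shape <- if (!is.null(md$shape_class)) as.character(md$shape_class)
           else rep("all", length(promoters))
  ids <- if (!is.null(names(promoters))) names(promoters)
         else paste0("promoter_", seq_along(promoters))
  if (length(promoters) == 0L) {
    prof <- data.frame(promoter_id = character(0),
                       shape_class = character(0))
    for (m in motif_names) prof[[m]] <- logical(0)
    prof$tata_status <- character(0)
    prof$any_motif <- logical(0)
    return(list(profiles = prof,
                occurrence = data.frame(motif = character(0),
                                        shape_class = character(0),
                                        n = integer(0), pct = numeric(0)),
                pct_any_motif = NA_real_, background = background))
  }
  if (is.null(background)) background <- background_model(promoters)

  presence <- matrix(FALSE, length(promoters), length(models),
                     dimnames = list(ids, motif_names))
  for (j in seq_along(models)) {
    K <- .pwm_int_scores(models[[j]]$pfm, background, pseudocount, grid)
    sdist <- .score_distribution(K, background)
    Lm <- ncol(K)
    lo <- models[[j]]$window[1L] - models[[j]]$elasticity
    hi <- models[[j]]$window[2L] + models[[j]]$elasticity
    labels <- .label_positions(window[1L], window[2L])
    for (i in seq_along(promoters)) {
      seq <- as.character(promoters[[i]])
      bases <- strsplit(seq, "")[[1L]]
      code <- match(bases, DNA_BASES)
      if (anyNA(code)) next   # ambiguous promoter: no calls
      n_pos <- length(bases) - Lm + 1L
      if (n_pos < 1L) next
      found <- FALSE
      for (s in seq_len(n_pos)) {
        if (labels[s] < lo || labels[s] > hi) next
        int <- sum(K[cbind(code[s:(s + Lm - 1L)], seq_len(Lm))])
        if (.score_pvalue(sdist, int) <= p_threshold) { found <- TRUE; break }
      }
      presence[i, j] <- found
    }
  }

  tata <- if ("TATA" %in% motif_names) presence[, "TATA"] else
    rep(FALSE, nrow(presence))
  prof <- data.frame(promoter_id = ids, shape_class = shape,
                     stringsAsFactors = FALSE)
  for (m in motif_names) prof[[m]] <- unname(presence[, m])
  prof$tata_status <- ifelse(tata, "TATA_containing", "TATA_less")
  prof$any_motif <- rowSums(presence) > 0L

  classes <- setdiff(unique(shape), "all")
  occ <- do.call(rbind, lapply(c("all", classes), function(cl) {
    idx <- if (cl == "all") rep(TRUE, nrow(prof)) else shape == cl
    data.frame(motif = motif_names, shape_class = cl, n = sum(idx),
               pct = 100 * colMeans(presence[idx, , drop = FALSE]),
               row.names = NULL)
  }))
  list(profiles = prof, occurrence = occ,
       pct_any_motif = 100 * mean(prof$any_motif), background = background)
}
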