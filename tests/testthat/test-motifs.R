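test_that("JASPAR PFM parsing, validation and round-trip", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TOY",
               "A [ 90  1  1 90 90  1 ]",
               "C [  3  2 90  3  3  2 ]",
               "G [  2 90  3  2  2  4 ]",
               "T [  2  4  3  2  2 90 ]"), f)
  models <- read_jaspar(f, windows = list(TOY = c(-10L, 5L)))
  expect_equal(length(models), 1L)
  expect_equal(ncol(models$TOY$pfm), 6L)
  expect_equal(unname(colSums(models$TOY$pfm)), rep(97, 6L))
  expect_equal(models$TOY$window, c(-10L, 5L))

  empty <- withr::local_tempfile(fileext = ".pfm")
  writeLines(character(0), empty)
  expect_warning(out <- read_jaspar(empty), "empty")
  expect_equal(length(out), 0L)

  bad <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">X X", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), bad)
  expect_error(read_jaspar(bad), "differing lengths")

  rt <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar(models, rt)
  back <- read_jaspar(rt, windows = list(TOY = c(-10L, 5L)))
  expect_equal(back$TOY$pfm, models$TOY$pfm)
})

test_that("bundled motif set covers the six canonical motifs with windows", {
  models <- promarch_motifs()
  expect_setequal(names(models),
                  c("BREu", "BREd", "TATA", "INR", "MTE", "DPE"))
  for (m in models) {
    expect_false(anyNA(m$window))
    expect_equal(m$elasticity, 5L)
  }
})

test_that("background model estimates floored, normalized base frequencies", {
  allA <- background_model(DNAStringSet(strrep("A", 200L)))
  expect_equal(sum(allA), 1)
  expect_true(all(allA[c("C", "G", "T")] > 0))
  expect_gt(allA[["A"]], 0.999)

  at <- background_model(DNAStringSet(strrep("AT", 100L)))
  expect_equal(unname(at[["A"]]), unname(at[["T"]]))
  expect_lt(abs(at[["A"]] - 0.5), 1e-3)

  set.seed(5)
  unif <- DNAStringSet(vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
          collapse = "")
  }, character(1)))
  expect_true(all(abs(background_model(unif) - 0.25) < 0.01))
  expect_error(background_model(DNAStringSet("NNNN")), "no unambiguous")
})

test_that("perfect-consensus score matches the closed form under uniform background", {
  models <- promarch_motifs()
  bg <- setNames(rep(0.25, 4L), c("A", "C", "G", "T"))
  tata <- models$TATA
  probs <- sweep(tata$pfm + 0.8, 2L, colSums(tata$pfm + 0.8), "/")
  expected <- sum(log2(apply(probs, 2L, max) / 0.25))
  promoter <- paste0(strrep("A", 20L), "TATAAA", strrep("A", 74L))
  hits <- scan_promoter(promoter, tata, bg, apply_window = FALSE)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$start, -30L)  # column 21 is label -30
  # grid rounding: up to 5e-4 bits per column
  expect_lt(abs(best$score - expected), 6 * 5e-4 + 1e-9)
})

test_that("DP p-values equal brute-force enumeration over all words", {
  set.seed(7)
  backgrounds <- list(uniform = rep(0.25, 4L),
                      at_rich = c(0.35, 0.15, 0.15, 0.35))
  for (bg in backgrounds) {
    names(bg) <- c("A", "C", "G", "T")
    for (L in c(3L, 5L, 6L)) {
      pfm <- matrix(sample(0:50, 4L * L, replace = TRUE), 4L,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pfm[1L, colSums(pfm) == 0] <- 1L
      K <- promarch:::.pwm_int_scores(pfm, bg)
      sd <- promarch:::.score_distribution(K, bg)
      probe <- unique(c(sd$offset, sd$max_int,
                        sample(seq(sd$offset, sd$max_int), 20L)))
      dp <- promarch:::.score_pvalue(sd, probe)
      bf <- brute_force_pvalue(pfm, bg, probe)
      expect_lt(max(abs(dp - bf)), 1e-9)
    }
  }
})

test_that("p-values are monotone non-increasing in score", {
  bg <- setNames(c(0.3, 0.2, 0.2, 0.3), c("A", "C", "G", "T"))
  K <- promarch:::.pwm_int_scores(promarch_motifs()$INR$pfm, bg)
  sd <- promarch:::.score_distribution(K, bg)
  s <- seq(sd$offset, sd$max_int, length.out = 200L)
  p <- promarch:::.score_pvalue(sd, round(s))
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("window filter is a pure restriction with +/-5 elasticity", {
  models <- promarch_motifs()
  bg <- setNames(c(0.35, 0.15, 0.15, 0.35), c("A", "C", "G", "T"))
  # consensus planted at window start: retained
  inside <- paste0(strrep("A", 20L), "TATAAA", strrep("A", 74L))  # -30
  hit_in <- scan_promoter(inside, models$TATA, bg)
  expect_gte(nrow(hit_in), 1L)
  # consensus 6 bp beyond the window end (-24): start -18, elasticity 5
  beyond <- paste0(strrep("A", 32L), "TATAAA", strrep("A", 62L))  # -18
  expect_equal(nrow(scan_promoter(beyond, models$TATA, bg)), 0L)
  expect_gte(nrow(scan_promoter(beyond, models$TATA, bg,
                                apply_window = FALSE)), 1L)
  # filtered hits are a subset of unfiltered hits
  set.seed(13)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 100L, replace = TRUE,
                      prob = c(.35, .15, .15, .35)), collapse = "")
    for (m in models) {
      filt <- scan_promoter(s, m, bg)
      all_hits <- scan_promoter(s, m, bg, apply_window = FALSE)
      expect_true(all(filt$start %in% all_hits$start))
      expect_true(all(filt$p_value <= 1e-2))
    }
  }
})

test_that("degenerate promoters are handled with warnings", {
  models <- promarch_motifs()
  bg <- setNames(rep(0.25, 4L), c("A", "C", "G", "T"))
  expect_warning(h <- scan_promoter(strrep("A", 4L), models$MTE, bg),
                 "shorter")
  expect_equal(nrow(h), 0L)
  expect_warning(h2 <- scan_promoter(paste0(strrep("A", 50L), "N",
                                            strrep("A", 49L)),
                                     models$TATA, bg), "ambiguous")
  expect_equal(nrow(h2), 0L)
})

test_that("profiles record planted motifs and TATA status", {
  cfg <- small_config(motif_plant_rates = c(TATA = 1.0), seed = 31L)
  sim <- generate_genome(cfg)
  tm <- sim$truth
  promo <- extract_core_promoters(sim$genome,
                                  data.frame(gene_id = tm$gene_id,
                                             scaffold = tm$scaffold,
                                             tss = tm$true_tss,
                                             strand = tm$strand))
  out <- motif_profiles(promo, promarch_motifs())
  expect_true(all(out$profiles$TATA))
  expect_true(all(out$profiles$tata_status == "TATA_containing"))
  occ <- out$occurrence
  expect_equal(occ$pct[occ$motif == "TATA" & occ$shape_class == "all"], 100)
  # empty promoter set yields an empty table
  empty <- motif_profiles(promo[0], promarch_motifs())
  expect_equal(nrow(empty$profiles), 0L)
})
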