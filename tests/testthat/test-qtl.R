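# small deterministic map fixture: 3 markers on one chromosome
fixture_map <- function(geno) {
  build_map(geno, rep("Chr1", ncol(geno)),
            c(1e5, 1e6, 1.9e6), cross_chrom_alpha = 1e-4)
}

test_that("recombination fractions use the selfed-RIL correction", {
  g <- rep(c(0, 1), 50)
  expect_equal(estimate_rf(g, g), list(R = 0, r = 0))
  g2 <- g; g2[1:20] <- 1 - g2[1:20]
  rf <- estimate_rf(g, g2)
  expect_equal(rf$R, 0.2)
  expect_equal(rf$r, 0.125)
  g3 <- g; g3[1:50] <- 1 - g3[1:50]
  expect_equal(estimate_rf(g, g3)$r, 0.5)  # capped at unlinked
  expect_error(estimate_rf(c(NA, NA), c(0, 1)), "no lines")
})

test_that("the Haldane map function round trips", {
  for (r in c(0.01, 0.1, 0.25, 0.4, 0.49)) {
    expect_equal(haldane_r(haldane_cm(r)), r, tolerance = 1e-12)
  }
  expect_equal(haldane_cm(0.125), -50 * log(0.75))
})

test_that("map construction spaces markers by Haldane distance", {
  set.seed(19)
  n <- 200L
  g1 <- sample(0:1, n, TRUE)
  flip <- function(g, k) {
    idx <- sample(n, k)
    g[idx] <- 1 - g[idx]
    g
  }
  geno <- cbind(m1 = g1, m2 = flip(g1, 40), m3 = flip(flip(g1, 40), 40))
  # m2 differs from m1 in ~40/200 = 0.2 of lines
  mp <- fixture_map(geno)
  r12 <- estimate_rf(geno[, 1], geno[, 2])$r
  expect_equal(mp$map$cM[2] - mp$map$cM[1], -50 * log(1 - 2 * r12))
  expect_equal(mp$map$cM[1], 0)
  expect_true(all(diff(mp$map$cM) > 0))
})

test_that("cross-chromosome correlated markers are rejected", {
  set.seed(23)
  n <- 80L
  honest <- replicate(6, sample(0:1, n, TRUE))
  colnames(honest) <- paste0("m", 1:6)
  chrom <- rep(c("Chr1", "Chr2"), each = 3)
  bp <- rep(c(1e5, 1e6, 1.9e6), 2)
  mp <- build_map(honest, chrom, bp)
  expect_length(mp$rejected, 0L)
  # duplicate a Chr1 marker onto Chr2: the copy is rejected, not the original
  dup <- cbind(honest, m7 = honest[, 1])
  mp2 <- build_map(dup, c(chrom, "Chr2"), c(bp, 1.5e6))
  expect_equal(mp2$rejected, "m7")
  expect_true("m1" %in% mp2$map$marker_id)
})

test_that("genotype probabilities interpolate the flanking markers", {
  # at a typed marker the probability is the observed state
  expect_equal(genotype_prob(c(0, 1, 0), c(0, 10, 20), c(0, 10, 20)),
               c(0, 1, 0))
  # midpoint between discordant flanks is exactly 1/2
  expect_equal(genotype_prob(c(0, 1), c(0, 10), 5), 0.5)
  # midpoint between concordant ddm1 flanks 10 cM apart is > 0.9
  expect_gt(genotype_prob(c(1, 1), c(0, 10), 5), 0.9)
  # NA markers are skipped in favour of informative flanks
  expect_equal(genotype_prob(c(1, NA, 1), c(0, 5, 10), 5),
               genotype_prob(c(1, 1), c(0, 10), 5))
  expect_equal(genotype_prob(c(NA, NA), c(0, 10), 5), 0.5)
  # probabilities stay in [0, 1] across random configurations
  set.seed(3)
  for (i in 1:20) {
    st <- sample(c(0, 1, NA), 8, TRUE)
    p <- genotype_prob(st, sort(runif(8, 0, 80)), seq(0, 80, by = 2))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("the scan LOD equals a direct least-squares computation", {
  geno <- cbind(
    m1 = c(0, 0, 0, 0, 1, 1, 1, 1),
    m2 = c(0, 0, 1, 0, 1, 1, 0, 1),
    m3 = c(0, 1, 1, 0, 1, 0, 0, 1))
  y <- c(0.12, 0.25, 0.92, 0.31, 1.08, 0.80, 0.41, 1.19)
  mp <- fixture_map(geno)
  curve <- hk_scan(mp, y, trait = "fixture")
  for (m in colnames(geno)) {
    cm <- mp$map$cM[mp$map$marker_id == m]
    at <- which(curve$grid$cM == cm & curve$grid$chrom == "Chr1")
    g <- geno[, m]
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(residuals(lm(y ~ g))^2)
    expect_equal(curve$lod[at], (8 / 2) * log10(rss0 / rss1),
                 tolerance = 1e-8)
  }
})

test_that("a noiseless marker phenotype maxes out at that marker", {
  set.seed(29)
  geno <- replicate(3, sample(0:1, 40, TRUE))
  colnames(geno) <- paste0("m", 1:3)
  mp <- fixture_map(geno)
  curve <- hk_scan(mp, geno[, "m2"], trait = "perfect")
  at <- which(curve$grid$cM == mp$map$cM[mp$map$marker_id == "m2"])
  expect_equal(curve$lod[at], 50)  # capped
  expect_equal(curve$lod[at], max(curve$lod))
  expect_warning(flat <- hk_scan(mp, rep(1, 40)), "constant phenotype")
  expect_true(all(flat$lod == 0))
})

test_that("permutation thresholds are seeded and respect alpha bounds", {
  set.seed(37)
  geno <- replicate(4, sample(0:1, 60, TRUE))
  colnames(geno) <- paste0("m", 1:4)
  mp <- build_map(geno, rep("Chr1", 4), c(1e5, 8e5, 1.4e6, 1.9e6))
  y <- rnorm(60)
  t1 <- suppressWarnings(permutation_threshold(mp, y, n_perm = 60, seed = 5))
  t2 <- suppressWarnings(permutation_threshold(mp, y, n_perm = 60, seed = 5))
  expect_identical(t1, t2)
  t3 <- suppressWarnings(permutation_threshold(mp, y, n_perm = 60, seed = 6))
  expect_false(identical(t1, t3))
  tmin <- suppressWarnings(
    permutation_threshold(mp, y, n_perm = 60, alpha = 1, seed = 5))
  expect_lte(tmin, t1)
  expect_warning(permutation_threshold(mp, y, n_perm = 50, seed = 5),
                 "unstable")
  # a null trait's threshold lands in the usual LOD band
  expect_gt(t1, 1)
  expect_lt(t1, 5)
})

test_that("peaks are classified cis/trans and by compartment", {
  grid <- data.frame(
    chrom = rep(c("Chr1", "Chr4"), each = 50),
    cM = rep(seq(0, 49), 2),
    bp = rep(seq(1e4, by = 4e4, length.out = 50), 2))
  lod <- c(dnorm(seq(-3, 3, length.out = 50)) * 20,
           dnorm(seq(-3, 3, length.out = 50)) * 12)
  curve <- list(trait = "g1", grid = grid, lod = lod)
  gene <- GRanges("Chr1", IRanges(9e5, 9.5e5))
  het <- GRanges("Chr4", IRanges(8e5, 1.2e6))
  hits <- find_peaks_and_classify(curve, threshold = 3, gene_locus = gene,
                                  het_intervals = het)
  expect_equal(nrow(hits), 2L)
  h1 <- hits[hits$chrom == "Chr1", ]
  expect_equal(h1$relation, "cis")
  expect_equal(h1$compartment, "euchromatin")
  h4 <- hits[hits$chrom == "Chr4", ]
  expect_equal(h4$relation, "trans")
  expect_equal(h4$compartment, "heterochromatin")
  expect_true(all(hits$support_start_bp <= hits$bp &
                    hits$bp <= hits$support_end_bp))
  # sub-threshold curves yield no hits
  none <- find_peaks_and_classify(
    list(trait = "g1", grid = grid, lod = rep(1, 100)), threshold = 3)
  expect_equal(nrow(none), 0L)
})

test_that("scanning all genes aggregates hits consistently", {
  set.seed(41)
  n <- 80L
  geno <- replicate(6, sample(0:1, n, TRUE))
  colnames(geno) <- paste0("m", 1:6)
  mp <- build_map(geno, rep(c("Chr1", "Chr2"), each = 3),
                  rep(c(1e5, 1e6, 1.9e6), 2))
  phen <- cbind(
    gA = geno[, "m2"] + rnorm(n, 0, 0.3),   # QTL at m2 on Chr1
    gB = geno[, "m5"] + rnorm(n, 0, 0.3),   # QTL at m5 on Chr2
    gC = rnorm(n))                          # no QTL
  loci <- GRanges(c("Chr1", "Chr1", "Chr2"),
                  IRanges(c(5e5, 1.8e6, 1e4), width = 1e4))
  mcols(loci)$gene_id <- colnames(phen)
  res <- scan_all_genes(mp, phen, threshold = 3, gene_loci = loci)
  expect_true(all(c("gA", "gB") %in% res$hits$trait))
  expect_equal(res$n_genes_with_qtl, length(unique(res$hits$trait)))
  expect_equal(sum(res$hits_per_gene * as.integer(names(res$hits_per_gene))),
               nrow(res$hits))
  a_hit <- res$hits[res$hits$trait == "gA", ][1, ]
  expect_equal(a_hit$chrom, "Chr1")
})
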