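make_pair <- function(deltas, base = 0.2, cov = 10L, context = "CAG",
                      gene_start = 1000L) {
  n <- length(deltas)
  pos <- seq(gene_start + 10L, by = 10L, length.out = n)
  ctrl <- cytosine_sites("Chr1", pos, "+", context,
                         as.integer(round(base * cov)), cov)
  samp <- cytosine_sites("Chr1", pos, "+", context,
                         as.integer(round((base + deltas) * cov)), cov)
  list(sample = samp, control = ctrl)
}

test_that("gain calls require three sites and a 10% mean increase", {
  gene <- make_gene(start = 1000L, end = 1999L)
  five <- make_pair(rep(0.2, 5))
  g <- call_gene_gain(gene, five$sample, five$control, "CHG")
  expect_true(g$is_gain)
  expect_equal(g$delta, 0.2)
  expect_equal(g$n_sites, 5L)
  # two sites, however strong, are below the site floor
  two <- make_pair(rep(0.5, 2))
  expect_false(call_gene_gain(gene, two$sample, two$control, "CHG")$is_gain)
  # ten sites averaging +0.08 are below the delta floor
  ten <- make_pair(rep(0.1, 10), cov = 50L)
  g08 <- call_gene_gain(gene,
                        cytosine_sites("Chr1", seq(1010L, by = 10L,
                                                   length.out = 10L),
                                       "+", "CAG", 14L, 50L),
                        ten$control, "CHG")
  expect_equal(g08$delta, 0.08)
  expect_false(g08$is_gain)
})

test_that("gain calling needs coverage in both samples and is symmetric", {
  gene <- make_gene(start = 1000L, end = 1999L)
  pr <- make_pair(rep(0.3, 6))
  # drop coverage below min_cov in the control for half the sites
  ctrl <- copy(pr$control)
  ctrl$total_reads[1:3] <- 2L
  ctrl$mc_reads[1:3] <- 0L
  g <- call_gene_gain(gene, pr$sample, ctrl, "CHG", min_cov = 3L)
  expect_equal(g$n_sites, 3L)
  # swapping sample and control negates delta
  fwd <- call_gene_gain(gene, pr$sample, pr$control, "CHG")
  rev <- call_gene_gain(gene, pr$control, pr$sample, "CHG")
  expect_equal(rev$delta, -fwd$delta)
  # self-comparison yields no gain
  self <- call_gene_gain(gene, pr$control, pr$control, "CHG")
  expect_equal(self$delta, 0)
  expect_false(self$is_gain)
})

test_that("one-sided Fisher matches enumeration and closed cases", {
  expect_equal(fisher_enrichment_one_sided(0, 10, 5, 5)$p, 1)
  expect_equal(fisher_enrichment_one_sided(1, 1, 1, 1)$p, 5 / 6)
  expect_equal(fisher_enrichment_one_sided(1, 1, 1, 1)$odds_ratio, 1)
  expect_equal(fisher_enrichment_one_sided(5, 0, 0, 5)$odds_ratio, Inf)
  expect_error(fisher_enrichment_one_sided(0, 0, 0, 0), "all-zero")
  # exhaustive check against table enumeration for small margins
  for (r1 in 0:6) for (r2 in 0:6) for (a in 0:r1) for (cc in 0:r2) {
    if (r1 + r2 == 0) next
    b <- r1 - a; d <- r2 - cc
    expect_equal(fisher_enrichment_one_sided(a, b, cc, d)$p,
                 brute_fisher_one_sided(a, b, cc, d), tolerance = 1e-12)
  }
  # larger random tables, margins up to 30
  set.seed(7)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(10:30, 1), runif(4, 0.05, 1)))
    expect_equal(do.call(fisher_enrichment_one_sided, as.list(cells))$p,
                 do.call(brute_fisher_one_sided, as.list(cells)),
                 tolerance = 1e-10)
    # agreement with the standard exact test implementation
    expect_equal(do.call(fisher_enrichment_one_sided, as.list(cells))$p,
                 fisher.test(matrix(cells, 2, byrow = TRUE),
                             alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("class enrichment flags the planted class only", {
  classes <- data.frame(
    gene_id = sprintf("g%03d", 1:300),
    class = rep(c("gbM", "UM", "teM"), each = 100))
  gains <- data.frame(gene_id = classes$gene_id,
                      is_gain = c(rep(TRUE, 40), rep(FALSE, 60),
                                  rep(FALSE, 200)))
  enr <- class_enrichment(gains, classes)
  expect_lt(enr$p[enr$class == "gbM"], 1e-10)
  expect_gte(enr$p[enr$class == "UM"], 0.5)
  expect_equal(enr$prop_gain[enr$class == "gbM"], 0.4)
  # single-class universe is skipped with a warning
  expect_warning(
    empty <- class_enrichment(gains[1:100, ], classes[1:100, ]),
    "single class")
  expect_equal(nrow(empty), 0L)
})

test_that("uniform random gains leave no class enriched", {
  set.seed(9)
  classes <- data.frame(gene_id = sprintf("g%03d", 1:600),
                        class = rep(c("gbM", "UM", "teM"), each = 200))
  hits <- 0L
  for (i in 1:20) {
    gains <- data.frame(gene_id = classes$gene_id,
                        is_gain = runif(600) < 0.1)
    enr <- class_enrichment(gains, classes)
    hits <- hits + sum(bh_adjust(enr$p) < 0.05)
  }
  expect_lte(hits, 3L)
})

test_that("delta-index correlation flags linear association only", {
  h <- seq(0.1, 0.9, length.out = 20)
  lin <- delta_index_correlation(0.3 * h, h)
  expect_equal(lin$r, 1)
  expect_true(lin$flagged)
  flat <- delta_index_correlation(rep(0.2, 20), h)
  expect_true(is.na(flat$r))
  expect_false(flat$flagged)
  expect_false(delta_index_correlation(c(0.1, 0.2), h[1:2])$flagged)
  # planted slope 0.3 with sd 0.05 noise over 150 lines is detected
  set.seed(13)
  power <- mean(vapply(1:40, function(i) {
    hh <- runif(150, 0, 1)
    d <- 0.3 * hh + rnorm(150, 0, 0.05)
    delta_index_correlation(d, hh)$flagged
  }, TRUE))
  expect_gte(power, 0.95)
})

test_that("the gain matrix recovers planted gains and its own sums", {
  sim <- small_sim()
  ids <- rownames(sim$truth$genotypes)[1:3]
  lns <- simulate_line_sites(sim, ids)
  gm <- gain_matrix(sim$genes, lns, sim$parents$WT, context = "CHG")
  for (ln in ids) {
    called <- gm$calls[line_id == ln & is_gain == TRUE, gene_id]
    planted <- names(which(sim$truth$gains[ln, ]))
    expect_gte(length(intersect(called, planted)),
               0.9 * length(planted))
    # summary count equals the column-wise sum of gain flags
    expect_equal(gm$summary[line_id == ln, n_gain], length(called))
  }
  # control against itself yields no gains anywhere
  self <- gain_matrix(sim$genes, list(ctrl = sim$parents$WT),
                      sim$parents$WT, context = "CHG")
  expect_equal(self$summary$n_gain, 0L)
  # a line without a methylome is dropped with a warning
  expect_warning(
    gm2 <- gain_matrix(sim$genes, c(lns[1], list(bad = lns[[1]][0])),
                       sim$parents$WT),
    "no methylome")
  expect_equal(unique(gm2$calls$line_id), ids[1])
})
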