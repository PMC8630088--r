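small_cfg <- function(...) {
  sim_config(n_genes = c(gbM = 20L, teM = 8L, UM = 20L), n_lines = 8L,
             n_markers = 12L, n_chromosomes = 2L, het_sites_per_chrom = 60L,
             control_sites = 200L, ...)
}

test_that("identical configurations reproduce identical experiments", {
  s1 <- simulate_epiril_experiment(small_cfg(seed = 101L))
  s2 <- simulate_epiril_experiment(small_cfg(seed = 101L))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$template, s2$template)
  expect_identical(s1$parents, s2$parents)
  expect_identical(s1$contacts, s2$contacts)
  expect_identical(simulate_line_sites(s1, "L003"),
                   simulate_line_sites(s2, "L003"))
  s3 <- simulate_epiril_experiment(small_cfg(seed = 102L))
  expect_false(identical(s1$truth$genotypes, s3$truth$genotypes))
})

test_that("the annotation honours gene counts and placement rules", {
  sim <- simulate_epiril_experiment(small_cfg(seed = 103L))
  expect_equal(as.integer(table(sim$truth$gene_class)[c("gbM", "teM", "UM")]),
               c(20L, 8L, 20L))
  # genes stay clear of heterochromatin and of each other
  expect_length(findOverlaps(sim$genes, sim$het), 0L)
  expect_equal(length(findOverlaps(sim$genes, sim$genes)), length(sim$genes))
  # markers are intergenic
  expect_length(findOverlaps(sim$markers, sim$genes), 0L)
  # zero heterochromatin fraction keeps every gene euchromatic
  s0 <- simulate_epiril_experiment(small_cfg(seed = 104L, het_fraction = 0))
  expect_length(s0$het, 0L)
  expect_length(s0$peaks, 0L)
})

test_that("marker alleles segregate close to 50/50 across many lines", {
  set.seed(105)
  cfg <- small_cfg(n_lines = 500L)
  ann <- simulate_annotation(cfg)
  pop <- simulate_population(cfg, ann)
  freq <- colMeans(pop$genotypes)
  se <- sqrt(0.25 / 500)
  expect_true(all(abs(freq - 0.5) < 4 * se))
  expect_equal(pop$h_true, rowMeans(pop$genotypes))
})

test_that("adjacent-marker discordance grows with separation", {
  set.seed(106)
  cfg <- small_cfg(n_lines = 500L)
  ann <- simulate_annotation(cfg)
  pop <- simulate_population(cfg, ann)
  g <- pop$genotypes
  chroms <- as.character(seqnames(ann$markers))
  disc <- function(lag) {
    mean(vapply(which(chroms[-seq_len(lag)] ==
                        chroms[seq_len(length(chroms) - lag)]),
                function(i) mean(g[, i] != g[, i + lag]), 0))
  }
  expect_lt(disc(1L), disc(3L))
})

test_that("zero crossovers give single-parent chromosomes", {
  cfg <- small_cfg(seed = 107L, crossovers_per_chrom = 0)
  sim <- simulate_epiril_experiment(cfg)
  chroms <- as.character(seqnames(sim$markers))
  for (ln in rownames(sim$truth$genotypes)) {
    for (chr in unique(chroms)) {
      expect_length(unique(sim$truth$genotypes[ln, chroms == chr]), 1L)
    }
  }
})

test_that("read emission follows the configured depth and rates", {
  # zero depth: everything uncovered
  s0 <- simulate_epiril_experiment(small_cfg(seed = 108L, depth = 0))
  expect_true(all(s0$parents$WT$total_reads == 0L))
  # saturated rates without non-conversion: mc equals total
  sat <- small_cfg(seed = 109L, nonconversion = 0,
                   rates = list(gbM = c(CG = 1, CHG = 1, CHH = 1),
                                teM = c(CG = 1, CHG = 1, CHH = 1),
                                UM = c(CG = 1, CHG = 1, CHH = 1),
                                het = c(CG = 1, CHG = 1, CHH = 1)))
  ssat <- simulate_epiril_experiment(sat)
  wt <- ssat$parents$WT
  genic <- wt[wt$chrom != "ChrC"]
  expect_true(all(genic$mc_reads == genic$total_reads))
  # the control contig recovers the configured non-conversion rate
  sim <- simulate_epiril_experiment(small_cfg(seed = 110L,
                                              control_sites = 2000L))
  est <- estimate_nonconversion(sim$parents$WT, "ChrC")$rate
  n_reads <- sum(sim$parents$WT[chrom == "ChrC", total_reads])
  expect_lt(abs(est - 0.005), 4 * sqrt(0.005 * 0.995 / n_reads))
})

test_that("planted gains follow the hypomethylation index and QTL allele", {
  sim <- simulate_epiril_experiment(small_cfg(seed = 111L, n_lines = 150L))
  counts <- rowSums(sim$truth$gains)
  h <- sim$truth$h_true
  # the generator's central premise: more hypomethylated lines gain more
  expect_gt(cor(counts, h), 0.3)
  qm <- sim$truth$qtl_markers
  carrier <- sim$truth$genotypes[, qm] == 1
  expect_gt(mean(counts[carrier]), mean(counts[!carrier]))
  # gains concentrate in gbM genes
  per_gene <- colSums(sim$truth$gains)
  cls <- sim$truth$gene_class[colnames(sim$truth$gains)]
  expect_gt(mean(per_gene[cls == "gbM"]), 10 * mean(per_gene[cls == "UM"]))
  expect_true(all(per_gene[cls == "teM"] == 0))
})

test_that("a null gain model is flat in the index", {
  set.seed(112)
  cfg <- small_cfg(n_lines = 150L, gain_slope = 0, qtl_effect = 0,
                   gain_base = -2)
  ann <- simulate_annotation(cfg)
  pop <- simulate_population(cfg, ann)
  pg <- plant_gains(cfg, ann, pop)
  expect_lt(abs(cor(rowSums(pg$gains), pop$h_true)), 0.3)
})

test_that("contact simulation responds to the enrichment multiplier", {
  set.seed(113)
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  flags <- setNames(rep(c(TRUE, FALSE), length.out = length(ann$genes)),
                    S4Vectors::mcols(ann$genes)$gene_id)
  # multiplier 1: flagged and unflagged draw from the same distribution
  hic1 <- simulate_contacts(sim_config(contact_multiplier = 1), ann, flags)
  s1 <- summarize_gene_contacts(hic1$contacts, hic1$peaks, ann$genes)
  expect_lt(abs(mean(s1$n_contacts[flags]) - mean(s1$n_contacts[!flags])),
            0.5)
  # zero background: no contacts at all
  hic0 <- simulate_contacts(sim_config(contact_background = 0), ann, flags)
  expect_equal(nrow(hic0$contacts), 0L)
  # emitted q-values sit below the significance threshold
  expect_true(all(hic1$contacts$q_value < sim_config()$contact_q))
})
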