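#' Configuration for the synthetic epiRIL experiment generator
#'
#' Returns the default simulation configuration, optionally overridden by
#' named arguments. The defaults describe a desk-scale caricature of a
#' ddm1-derived epiRIL methylome panel: five 2-Mb chromosomes with a central
#' pericentromeric heterochromatin block, 600 genes (250 gbM, 100 teM,
#' 250 UM) on the euchromatic arms, 100 quasi-evenly spaced DMR markers,
#' 150 lines, 20x read depth and a 0.5% bisulfite non-conversion rate.
#' Wild-type per-context methylation rates are gbM 0.8/0.02/0.02, teM
#' 0.9/0.7/0.15, UM 0.005 everywhere and heterochromatic intergenic
#' 0.9/0.7/0.2 (CG/CHG/CHH); the ddm1 parent attenuates heterochromatic
#' (marker and intergenic) rates by x0.1. Ectopic gains are planted in gbM
#' genes with logistic probability in the line's hypomethylation index and
#' its genotype at a designated pericentromeric trans-QTL marker, raising
#' CHG/CWA site rates by 0.25; UM genes gain at 2% of the gbM probability.
#' Flagged genes receive Hi-C contacts with H3K9me2 peaks at twice the
#' background Poisson rate.
#'
#' @param ... named overrides of any default.
#' @return a named list (`sim_config`).
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes = 5L,
    chrom_length = 2e6,
    n_genes = c(gbM = 250L, teM = 100L, UM = 250L),
    het_fraction = 0.2,
    rates = list(
      gbM = c(CG = 0.8, CHG = 0.02, CHH = 0.02),
      teM = c(CG = 0.9, CHG = 0.7, CHH = 0.15),
      UM = c(CG = 0.005, CHG = 0.005, CHH = 0.005),
      het = c(CG = 0.9, CHG = 0.7, CHH = 0.2)
    ),
    ddm1_attenuation = 0.1,
    n_markers = 100L,
    marker_width = 500L,
    sites_per_marker = 20L,
    het_sites_per_chrom = 300L,
    n_lines = 150L,
    crossovers_per_chrom = 2,
    depth = 20,
    nonconversion = 0.005,
    control_contig = "ChrC",
    control_sites = 1000L,
    cg_dyads_per_gene = 15L,
    chg_per_gene = 30L,
    chh_per_gene = 40L,
    cwa_fraction = 0.5,
    gain_base = -2.5,
    gain_slope = 2.5,
    qtl_effect = 2,
    qtl_markers = NULL,       # default: marker nearest chr1 het centre
    gain_delta = 0.25,
    um_gain_fraction = 0.02,
    gene_length_meanlog = log(2000),
    gene_length_sdlog = 0.35,
    gbm_length_factor = 1.4,  # gbM genes drawn longer on average
    contact_background = 1,
    contact_multiplier = 2,
    contact_bin = 2000L,
    contact_q = 1e-6
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Simulate the genome annotation: genes, heterochromatin and DMR markers
#'
#' Genes are placed without overlap, uniformly on the euchromatic arms,
#' with log-normal lengths (gbM genes longer on average); each gene's CDS
#' is its full span. A central pericentromeric heterochromatin block covers
#' `het_fraction` of every chromosome. Markers are spaced quasi-evenly
#' along each chromosome.
#'
#' @param cfg a [sim_config()] list. Callers wanting determinism should
#'   `set.seed()` first (the top-level [simulate_epiril_experiment()] does).
#' @return list with `genes` (`GRanges`: `gene_id`, `class`, `cds`), `het`
#'   (`GRanges`), `markers` (`GRanges` with `name`), `chrom_lengths`.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  chroms <- paste0("Chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms)

  het_half <- cfg$het_fraction / 2
  if (cfg$het_fraction > 0) {
    het <- GRanges(chroms,
                   IRanges(round(cfg$chrom_length * (0.5 - het_half)) + 1L,
                           round(cfg$chrom_length * (0.5 + het_half))))
  } else {
    het <- GRanges()
  }

  classes <- rep(names(cfg$n_genes), cfg$n_genes)
  classes <- sample(classes)
  n_total <- length(classes)
  gene_chrom <- sample(chroms, n_total, replace = TRUE)
  g_start <- integer(n_total); g_end <- integer(n_total)
  occ_s <- lapply(setNames(chroms, chroms), function(x) numeric(0))
  occ_e <- occ_s
  if (length(het)) {
    het_start <- setNames(start(het), chroms)
    het_end <- setNames(end(het), chroms)
  } else {
    het_start <- setNames(rep(cfg$chrom_length + 1, length(chroms)), chroms)
    het_end <- setNames(rep(cfg$chrom_length, length(chroms)), chroms)
  }
  for (i in seq_len(n_total)) {
    meanlog <- cfg$gene_length_meanlog +
      if (classes[i] == "gbM") log(cfg$gbm_length_factor) else 0
    ok <- FALSE
    for (attempt in 1:200) {
      len <- max(200L, round(rlnorm(1, meanlog, cfg$gene_length_sdlog)))
      chr <- gene_chrom[i]
      arm <- if (runif(1) < 0.5) c(1, het_start[[chr]] - 1) else
        c(het_end[[chr]] + 1, cfg$chrom_length)
      if (arm[2] - arm[1] < len + 2) next
      s <- floor(runif(1, arm[1], arm[2] - len))
      e <- s + len - 1
      if (!any(s <= occ_e[[chr]] & e >= occ_s[[chr]])) {
        g_start[i] <- s; g_end[i] <- e
        occ_s[[chr]] <- c(occ_s[[chr]], s)
        occ_e[[chr]] <- c(occ_e[[chr]], e)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place gene ", i, "; reduce n_genes")
  }
  g_strand <- sample(c("+", "-"), n_total, replace = TRUE)
  ord <- order(gene_chrom, g_start)
  genes <- GRanges(gene_chrom[ord], IRanges(g_start[ord], g_end[ord]),
                   strand = g_strand[ord])
  classes <- classes[ord]
  mcols(genes)$gene_id <- sprintf("G%04d", seq_len(n_total))
  mcols(genes)$class <- classes
  flat_cds <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                      strand = strand(genes))
  mcols(genes)$cds <- GenomicRanges::split(flat_cds, seq_len(n_total))

  # markers sit in intergenic space: a marker interval overlapping a gene
  # would mix genic cytosines into the DMR level
  per_chrom <- cfg$n_markers %/% cfg$n_chromosomes
  extra <- cfg$n_markers - per_chrom * cfg$n_chromosomes
  mw <- cfg$marker_width
  mk_chrom <- character(0); mk_start <- numeric(0)
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    n_m <- per_chrom + (ci <= extra)
    targets <- round(seq(cfg$chrom_length * 0.03, cfg$chrom_length * 0.97,
                         length.out = n_m))
    placed_s <- numeric(0)
    for (tc in targets) {
      window <- cfg$chrom_length * 0.005
      for (attempt in 1:100) {
        s <- round(tc + runif(1, -window, window)) - mw %/% 2L
        s <- min(max(s, 1), cfg$chrom_length - mw)
        e <- s + mw - 1L
        clash <- any(s <= occ_e[[chr]] & e >= occ_s[[chr]]) ||
          any(s <= placed_s + mw - 1L & e >= placed_s)
        if (!clash) break
        window <- window * 1.5
      }
      placed_s <- c(placed_s, s)
    }
    mk_chrom <- c(mk_chrom, rep(chr, n_m))
    mk_start <- c(mk_start, sort(placed_s))
  }
  markers <- GRanges(mk_chrom, IRanges(mk_start, width = mw))
  mcols(markers)$name <- sprintf("DMR%03d", seq_along(markers))

  list(genes = genes, het = het, markers = markers,
       chrom_lengths = chrom_lengths)
}

#' Simulate an epiRIL population of parental mosaics
#'
#' Per line and chromosome, crossover positions are drawn as a Poisson
#' process (`crossovers_per_chrom` expected) and the leftmost parent is
#' chosen fairly, giving the expected 50/50 parental contribution. Marker
#' genotypes are the mosaic parent at the marker midpoint (0 = wild type,
#' 1 = ddm1); the true hypomethylation index is the ddm1 fraction over
#' markers.
#'
#' @param cfg a [sim_config()] list.
#' @param annotation from [simulate_annotation()].
#' @return list with `genotypes` (lines x markers 0/1 matrix), `h_true`,
#'   `mosaic` (data.table: `line_id`, `chrom`, `start`, `end`, `parent`).
#' @export
simulate_population <- function(cfg, annotation) {
  chroms <- names(annotation$chrom_lengths)
  line_ids <- sprintf("L%03d", seq_len(cfg$n_lines))
  mk <- annotation$markers
  mk_mid <- floor((start(mk) + end(mk)) / 2)
  mk_chrom <- as.character(seqnames(mk))
  geno <- matrix(NA_integer_, cfg$n_lines, length(mk),
                 dimnames = list(line_ids, mcols(mk)$name))
  mosaic <- list()
  for (li in seq_len(cfg$n_lines)) {
    for (chr in chroms) {
      len <- annotation$chrom_lengths[[chr]]
      n_xo <- rpois(1, cfg$crossovers_per_chrom)
      bp <- sort(runif(n_xo, 1, len))
      first <- sample(0:1, 1L)
      seg_start <- c(1, floor(bp) + 1)
      seg_end <- c(floor(bp), len)
      parent <- (first + seq_len(n_xo + 1L) - 1L) %% 2L
      mosaic[[length(mosaic) + 1L]] <- data.table(
        line_id = line_ids[li], chrom = chr, start = seg_start,
        end = seg_end, parent = parent)
      in_chr <- which(mk_chrom == chr)
      seg_of <- findInterval(mk_mid[in_chr], seg_start)
      geno[li, in_chr] <- parent[seg_of]
    }
  }
  list(genotypes = geno, h_true = rowMeans(geno),
       mosaic = rbindlist(mosaic))
}

#' Plant ectopic methylation gains in the simulated population
#'
#' Per line, each gbM gene gains with probability
#' `plogis(gain_base + gain_slope * h + qtl_effect * g_qtl)` where `h` is
#' the line's true hypomethylation index and `g_qtl` its ddm1-allele count
#' at the designated pericentromeric trans-QTL marker(s); UM genes gain at
#' `um_gain_fraction` of that probability. A gained gene's CHG and CWA site
#' rates are raised by `gain_delta` when its methylome is emitted.
#'
#' @param cfg a [sim_config()] list.
#' @param annotation from [simulate_annotation()].
#' @param population from [simulate_population()].
#' @return list with `gains` (lines x genes logical matrix) and
#'   `qtl_markers` (character ids used).
#' @export
plant_gains <- function(cfg, annotation, population) {
  qtl <- cfg$qtl_markers
  if (is.null(qtl)) {
    mk <- annotation$markers
    chr1 <- names(annotation$chrom_lengths)[1L]
    het1 <- annotation$het[as.character(seqnames(annotation$het)) == chr1]
    centre <- if (length(het1)) floor((start(het1) + end(het1)) / 2) else
      floor(annotation$chrom_lengths[[chr1]] / 2)
    on1 <- which(as.character(seqnames(mk)) == chr1)
    mid <- floor((start(mk[on1]) + end(mk[on1])) / 2)
    qtl <- mcols(mk)$name[on1[which.min(abs(mid - centre))]]
  }
  g_qtl <- population$genotypes[, qtl, drop = FALSE]
  g_qtl <- rowSums(g_qtl) / ncol(g_qtl)
  eta <- cfg$gain_base + cfg$gain_slope * population$h_true +
    cfg$qtl_effect * g_qtl
  p_gbm <- plogis(eta)
  classes <- mcols(annotation$genes)$class
  gene_ids <- mcols(annotation$genes)$gene_id
  n_lines <- nrow(population$genotypes)
  gains <- matrix(FALSE, n_lines, length(gene_ids),
                  dimnames = list(rownames(population$genotypes), gene_ids))
  for (li in seq_len(n_lines)) {
    p <- ifelse(classes == "gbM", p_gbm[li],
                ifelse(classes == "UM", p_gbm[li] * cfg$um_gain_fraction, 0))
    gains[li, ] <- runif(length(p)) < p
  }
  list(gains = gains, qtl_markers = qtl)
}

# fixed cytosine template: every simulated cytosine with its wild-type and
# ddm1 parental rates. Gene CG sites come as symmetric dyads so the
# symmetric-mCG filter is exercised. DMR marker sites are CG/CHG dominated
# (2:1), matching the methylated-region character of ultra-stable DMRs.
build_site_template <- function(cfg, annotation) {
  genes <- annotation$genes
  classes <- mcols(genes)$class
  gene_ids <- mcols(genes)$gene_id
  n_g <- length(genes)
  n_cg <- cfg$cg_dyads_per_gene
  n_chg <- cfg$chg_per_gene
  n_chh <- cfg$chh_per_gene
  n_cwa <- round(n_chh * cfg$cwa_fraction)
  per_gene <- 2L * n_cg + n_chg + n_chh

  pos <- integer(n_g * per_gene)
  stn <- character(n_g * per_gene)
  for (i in seq_len(n_g)) {
    gs <- start(genes)[i]
    len <- width(genes)[i]
    p_cg <- sort(sample.int(len - 1L, n_cg)) + gs - 1L
    p_chg <- sample.int(len, n_chg) + gs - 1L
    p_chh <- sample.int(len, n_chh) + gs - 1L
    off <- (i - 1L) * per_gene
    pos[off + seq_len(per_gene)] <- c(p_cg, p_cg + 1L, p_chg, p_chh)
    stn[off + seq_len(per_gene)] <- c(
      rep("+", n_cg), rep("-", n_cg),
      sample(c("+", "-"), n_chg + n_chh, replace = TRUE))
  }
  tri_one <- c(rep("CGA", n_cg), rep("CGA", n_cg), rep("CAG", n_chg),
               rep("CAA", n_cwa), rep("CCT", n_chh - n_cwa))
  ctx_one <- c(rep("CG", 2L * n_cg), rep("CHG", n_chg), rep("CHH", n_chh))
  gene_sites <- data.table(
    chrom = rep(as.character(seqnames(genes)), each = per_gene),
    pos = pos, strand = stn,
    tri_context = rep(tri_one, n_g),
    wt_rate = unlist(lapply(classes, function(cl) cfg$rates[[cl]][
      c(rep("CG", 2L * n_cg), rep("CHG", n_chg), rep("CHH", n_chh))]),
      use.names = FALSE),
    region = rep(gene_ids, each = per_gene))
  gene_sites[, ddm1_rate := wt_rate]

  mk <- annotation$markers
  n_m <- cfg$sites_per_marker
  tri_m <- rep(c("CGA", "CGA", "CAG"), length.out = n_m)
  mk_pos <- unlist(lapply(seq_along(mk), function(i) {
    sort(sample.int(width(mk)[i], n_m)) + start(mk)[i] - 1L
  }), use.names = FALSE)
  marker_sites <- data.table(
    chrom = rep(as.character(seqnames(mk)), each = n_m),
    pos = mk_pos, strand = "+",
    tri_context = rep(tri_m, length(mk)),
    wt_rate = rep(unname(cfg$rates$het[context_class(tri_m)]), length(mk)),
    region = rep(paste0("marker:", mcols(mk)$name), each = n_m))
  marker_sites[, ddm1_rate := wt_rate * cfg$ddm1_attenuation]

  het <- annotation$het
  if (length(het)) {
    n_h <- cfg$het_sites_per_chrom
    tri_h <- rep(c("CGA", "CAG", "CAA"), length.out = n_h)
    het_pos <- unlist(lapply(seq_along(het), function(i) {
      sort(sample.int(width(het)[i], n_h)) + start(het)[i] - 1L
    }), use.names = FALSE)
    het_sites <- data.table(
      chrom = rep(as.character(seqnames(het)), each = n_h),
      pos = het_pos, strand = "+",
      tri_context = rep(tri_h, length(het)),
      wt_rate = rep(unname(cfg$rates$het[context_class(tri_h)]), length(het)),
      region = "het")
    het_sites[, ddm1_rate := wt_rate * cfg$ddm1_attenuation]
  } else {
    het_sites <- NULL
  }

  ctrl <- data.table(
    chrom = cfg$control_contig,
    pos = sort(sample.int(150000L, cfg$control_sites)),
    strand = "+",
    tri_context = rep(c("CGA", "CAG", "CTT"), length.out = cfg$control_sites),
    wt_rate = 0, region = "control")
  ctrl[, ddm1_rate := 0]

  template <- rbindlist(Filter(Negate(is.null),
                               list(gene_sites, marker_sites, het_sites, ctrl)))
  template[, context := context_class(tri_context)]
  template[]
}

# sample read counts for one methylome given per-site rates
sample_reads <- function(template, rates, cfg) {
  total <- rpois(nrow(template), cfg$depth)
  nc <- cfg$nonconversion
  p_obs <- rates * (1 - nc) + (1 - rates) * nc
  mc <- rbinom(nrow(template), total, p_obs)
  cytosine_sites(template$chrom, template$pos, template$strand,
                 template$tri_context, mc, total)
}

#' Simulate a complete epiRIL methylome experiment with ground truth
#'
#' Drives [simulate_annotation()], [simulate_population()] and
#' [plant_gains()] under the configured seed, emits the two parental
#' methylomes, and simulates the Hi-C contact list. Per-line methylomes are
#' emitted on demand by [simulate_line_sites()] (each line has its own
#' stored seed, so any subset is reproducible). Identical configurations
#' yield identical output.
#'
#' @param cfg a [sim_config()] list.
#' @return a `sim` list: `cfg`, `annotation` fields (`genes`, `het`,
#'   `markers`, `chrom_lengths`), `template` (cytosine template with
#'   parental rates), `parents` (list of WT and ddm1 site tables), `truth`
#'   (`genotypes`, `h_true`, `mosaic`, `gains`, `qtl_markers`,
#'   `gene_class`, `contact_flags`), `contacts`, `peaks`, `line_seeds`.
#' @export
simulate_epiril_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  annotation <- simulate_annotation(cfg)
  population <- simulate_population(cfg, annotation)
  planted <- plant_gains(cfg, annotation, population)
  template <- build_site_template(cfg, annotation)

  line_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_lines + 2L)
  set.seed(line_seeds[cfg$n_lines + 1L])
  wt <- sample_reads(template, template$wt_rate, cfg)
  set.seed(line_seeds[cfg$n_lines + 2L])
  ddm1 <- sample_reads(template, template$ddm1_rate, cfg)

  set.seed(cfg$seed + 1L)
  flags <- mcols(annotation$genes)$class == "gbM" & colSums(planted$gains) > 0L
  names(flags) <- mcols(annotation$genes)$gene_id
  hic <- simulate_contacts(cfg, annotation, flags)

  truth <- list(
    genotypes = population$genotypes,
    h_true = population$h_true,
    mosaic = population$mosaic,
    gains = planted$gains,
    qtl_markers = planted$qtl_markers,
    gene_class = setNames(mcols(annotation$genes)$class,
                          mcols(annotation$genes)$gene_id),
    contact_flags = flags
  )
  c(list(cfg = cfg, template = template,
         parents = list(WT = wt, ddm1 = ddm1),
         contacts = hic$contacts, peaks = hic$peaks,
         line_seeds = line_seeds, truth = truth),
    annotation)
}

#' Emit per-line methylomes from a simulated experiment
#'
#' For each requested line the per-site methylation rate is assembled from
#' the parental mosaic (marker and heterochromatin sites take the rate of
#' the inherited parent; gene sites keep their class rate, raised by
#' `gain_delta` on CHG/CWA sites of genes planted as gains in that line)
#' and reads are drawn as `total ~ Poisson(depth)`,
#' `mc ~ Binomial(total, rate (1 - nc) + (1 - rate) nc)`.
#'
#' @param sim object from [simulate_epiril_experiment()].
#' @param line_ids line ids (default all).
#' @return named list of cytosine site tables.
#' @export
simulate_line_sites <- function(sim, line_ids = rownames(sim$truth$genotypes)) {
  cfg <- sim$cfg
  all_ids <- rownames(sim$truth$genotypes)
  template <- sim$template
  out <- list()
  for (ln in line_ids) {
    li <- match(ln, all_ids)
    if (is.na(li)) stop("unknown line id '", ln, "'")
    rate <- template$wt_rate
    # parental mosaic decides marker/heterochromatin rates
    seg <- sim$truth$mosaic[line_id == ln]
    inherit <- template$region %chin% "het" |
      startsWith(template$region, "marker:")
    for (chr in unique(seg$chrom)) {
      rows <- which(inherit & template$chrom == chr)
      if (!length(rows)) next
      s <- seg[chrom == chr][order(start)]
      par <- s$parent[findInterval(template$pos[rows], s$start)]
      ddm <- rows[par == 1L]
      rate[ddm] <- template$ddm1_rate[ddm]
    }
    gained <- names(which(sim$truth$gains[li, ]))
    if (length(gained)) {
      hit <- template$region %chin% gained &
        (template$context == "CHG" | is_cwa(template$tri_context))
      rate[hit] <- pmin(rate[hit] + cfg$gain_delta, 1)
    }
    set.seed(sim$line_seeds[li])
    out[[ln]] <- sample_reads(template, rate, cfg)
  }
  out
}

#' Simulate significant Hi-C contacts between genes and H3K9me2 peaks
#'
#' Peaks are the 2-kb bins tiling the heterochromatin blocks. Each gene
#' receives `Poisson(background * multiplier^flag)` contacts; every contact
#' joins the 2-kb bin containing the gene midpoint to a uniformly chosen
#' peak bin and carries a q-value below the significance threshold.
#'
#' @param cfg a [sim_config()] list.
#' @param annotation from [simulate_annotation()] (fields `genes`, `het`).
#' @param flags named logical over genes: contact-enriched or not.
#' @return list with `contacts` (data.frame in the [read_contacts()]
#'   layout) and `peaks` (`GRanges`).
#' @export
simulate_contacts <- function(cfg, annotation, flags) {
  bin <- cfg$contact_bin
  peak_list <- lapply(seq_along(annotation$het), function(i) {
    hr <- annotation$het[i]
    starts <- seq(start(hr), end(hr) - bin + 1L, by = bin)
    GRanges(seqnames(hr), IRanges(starts, starts + bin - 1L))
  })
  peaks <- if (length(peak_list)) suppressWarnings(do.call(c, peak_list)) else
    GRanges()
  genes <- annotation$genes
  rows <- list()
  if (length(peaks)) for (i in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[i]
    lambda <- cfg$contact_background *
      cfg$contact_multiplier^as.numeric(isTRUE(flags[[gid]]))
    n <- rpois(1, lambda)
    if (n == 0L) next
    mid <- floor((start(genes[i]) + end(genes[i])) / 2)
    a_start <- (mid %/% bin) * bin + 1L
    pk <- sample(length(peaks), n, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom1 = as.character(seqnames(genes[i])), start1 = a_start,
      end1 = a_start + bin - 1L,
      chrom2 = as.character(seqnames(peaks[pk])), start2 = start(peaks[pk]),
      end2 = end(peaks[pk]),
      q_value = runif(n, 0, cfg$contact_q), stringsAsFactors = FALSE)
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
               chrom2 = character(), start2 = numeric(), end2 = numeric(),
               q_value = numeric())
  list(contacts = contacts, peaks = peaks)
}
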