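#' Haldane map function and its inverse
#'
#' `haldane_cm()` converts a recombination fraction to map distance,
#' `d = -50 ln(1 - 2r)` centiMorgan; `haldane_r()` inverts it.
#'
#' @param r recombination fraction in `[0, 0.5)`.
#' @param d map distance in cM.
#' @return distance in cM, or recombination fraction.
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_cm
#' @export
haldane_r <- function(d) (1 - exp(-d / 50)) / 2

#' Recombination fraction between two markers in selfed RILs
#'
#' `R` is the observed discordance fraction over lines typed at both
#' markers. In recombinant inbred lines by selfing the map expansion
#' inflates observed discordance, so the meiotic recombination fraction is
#' recovered as `r = R / (2 (1 - R))`, capped at 0.5.
#'
#' @param g1,g2 genotype vectors over lines, coded 0/1 with `NA` allowed.
#' @return list with `R` (observed discordance) and `r` (meiotic fraction).
#' @export
estimate_rf <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no lines typed at both markers")
  R <- mean(g1[ok] != g2[ok])
  r <- min(R / (2 * (1 - R)), 0.5)
  list(R = R, r = r)
}

#' Build a genetic map from binary DMR-marker genotypes
#'
#' Markers are screened greedily in input order: a marker is rejected when
#' its one-sided Fisher association (same-allele concordance, odds ratio
#' > 1) with any already-accepted marker on a different chromosome has
#' `p < cross_chrom_alpha` — cross-chromosome correlated markers cannot be
#' genuine segregating loci. Retained markers are ordered by physical
#' position within each chromosome and given cumulative Haldane map
#' positions from adjacent-marker recombination fractions (the first marker
#' of each chromosome sits at 0 cM). Adjacent fractions are capped at 0.49
#' before conversion so distances stay finite.
#'
#' @param geno lines x markers matrix coded 0 (wild type) / 1 (ddm1) with
#'   `NA` allowed; column names are marker ids.
#' @param marker_chrom,marker_bp chromosome and physical position per
#'   marker (parallel to columns of `geno`).
#' @param cross_chrom_alpha rejection threshold (default 1e-4).
#' @return list with `map` (data.frame: `marker_id`, `chrom`, `bp`, `cM`),
#'   `rejected` (character marker ids) and `geno` (the genotype matrix
#'   restricted to retained markers, ordered as the map).
#' @export
build_map <- function(geno, marker_chrom, marker_bp, cross_chrom_alpha = 1e-4) {
  stopifnot(ncol(geno) == length(marker_chrom),
            ncol(geno) == length(marker_bp))
  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(geno)))
  accepted <- integer(0)
  rejected <- character(0)
  for (j in seq_len(ncol(geno))) {
    other <- accepted[marker_chrom[accepted] != marker_chrom[j]]
    drop <- FALSE
    for (k in other) {
      ok <- !is.na(geno[, j]) & !is.na(geno[, k])
      a <- sum(geno[ok, j] == 1 & geno[ok, k] == 1)
      b <- sum(geno[ok, j] == 1 & geno[ok, k] == 0)
      cc <- sum(geno[ok, j] == 0 & geno[ok, k] == 1)
      dd <- sum(geno[ok, j] == 0 & geno[ok, k] == 0)
      if (a + b + cc + dd == 0) next
      if (fisher_enrichment_one_sided(a, b, cc, dd)$p < cross_chrom_alpha) {
        drop <- TRUE
        break
      }
    }
    if (drop) rejected <- c(rejected, ids[j]) else accepted <- c(accepted, j)
  }
  ord <- accepted[order(marker_chrom[accepted], marker_bp[accepted])]
  cm <- numeric(length(ord))
  chroms <- marker_chrom[ord]
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    if (length(idx) < 2L) {
      warning("chromosome ", chr, " retains < 2 markers; excluded from scans")
      next
    }
    for (i in idx[-1L]) {
      r <- min(estimate_rf(geno[, ord[i - 1L]], geno[, ord[i]])$r, 0.49)
      cm[i] <- cm[i - 1L] + haldane_cm(r)
    }
  }
  map <- data.frame(marker_id = ids[ord], chrom = chroms,
                    bp = marker_bp[ord], cM = cm, stringsAsFactors = FALSE)
  list(map = map, rejected = rejected,
       geno = geno[, ord, drop = FALSE])
}

# discordance probability between two loci d cM apart in selfed RILs
ril_discordance <- function(d) {
  r <- haldane_r(d)
  2 * r / (1 + 2 * r)
}

#' Conditional probability of the ddm1 allele at a map position
#'
#' Markov interpolation between the nearest informative flanking markers:
#' with flanking states `sL`, `sR` at distances `dL`, `dR` (cM), the
#' conditional probability of carrying the ddm1 allele is
#' `t(sL,1;dL) t(1,sR;dR)` normalised over the two genotype paths, where
#' `t(a,b;d)` is the selfed-RIL transition probability from the Haldane
#' recombination fraction at distance `d`. With a single informative flank
#' the two-point conditional is used; with none the prior 0.5.
#'
#' @param states marker states on one chromosome for one line (0/1/`NA`).
#' @param marker_cm marker map positions (cM), sorted ascending.
#' @param grid_cm positions to evaluate.
#' @return numeric vector of `P(ddm1)` over `grid_cm`.
#' @export
genotype_prob <- function(states, marker_cm, grid_cm) {
  info <- which(!is.na(states))
  if (length(info) == 0L) return(rep(0.5, length(grid_cm)))
  icm <- marker_cm[info]
  ist <- as.numeric(states[info])
  n_i <- length(icm)
  trans <- function(a, b, d) {
    R <- ril_discordance(d)
    ifelse(a == b, 1 - R, R)
  }
  li <- findInterval(grid_cm, icm)
  res <- numeric(length(grid_cm))
  interior <- li >= 1L & li < n_i
  if (any(interior)) {
    g <- grid_cm[interior]
    sL <- ist[li[interior]]; sR <- ist[li[interior] + 1L]
    dL <- g - icm[li[interior]]; dR <- icm[li[interior] + 1L] - g
    # condition on both flanks and normalise over the two genotype paths;
    # at dL = 0 this collapses to the typed state, so markers on the grid
    # need no special case
    num1 <- trans(sL, 1, dL) * trans(1, sR, dR)
    num0 <- trans(sL, 0, dL) * trans(0, sR, dR)
    res[interior] <- num1 / (num1 + num0)
  }
  left <- li == 0L
  if (any(left)) {
    res[left] <- trans(1, ist[1L], icm[1L] - grid_cm[left])
  }
  right <- li == n_i
  if (any(right)) {
    res[right] <- trans(ist[n_i], 1, grid_cm[right] - icm[n_i])
  }
  res
}

# evaluation grid: regular step per chromosome, augmented with the marker
# positions themselves; bp by linear interpolation of the marker bp ~ cM
scan_grid <- function(map, step_cm = 1) {
  out <- list()
  for (chr in unique(map$chrom)) {
    m <- map[map$chrom == chr, ]
    if (nrow(m) < 2L) next
    cm <- sort(unique(c(seq(0, max(m$cM), by = step_cm), m$cM)))
    bp <- stats::approx(m$cM, m$bp, xout = cm, rule = 2, ties = "ordered")$y
    out[[chr]] <- data.frame(chrom = chr, cM = cm, bp = round(bp))
  }
  do.call(rbind, out)
}

# lines x grid matrix of P(ddm1)
genotype_prob_matrix <- function(map, geno, grid) {
  P <- matrix(NA_real_, nrow(geno), nrow(grid))
  for (chr in unique(grid$chrom)) {
    gi <- which(grid$chrom == chr)
    mi <- which(map$chrom == chr)
    g_sub <- geno[, map$marker_id[mi], drop = FALSE]
    for (ln in seq_len(nrow(geno))) {
      P[ln, gi] <- genotype_prob(g_sub[ln, ], map$cM[mi], grid$cM[gi])
    }
  }
  P
}

# LOD profile by Haley-Knott regression of y on P(ddm1), correlation form:
# RSS1 = RSS0 (1 - cor^2) for simple linear regression
hk_lod <- function(y, P, cap = 50) {
  n <- length(y)
  sdp <- apply(P, 2L, stats::sd)
  lod <- numeric(ncol(P))
  ok <- sdp > 0
  if (any(ok)) {
    r2 <- as.vector(cor(y, P[, ok, drop = FALSE]))^2
    l <- -(n / 2) * log10(pmax(1 - r2, 0))
    l[!is.finite(l)] <- cap
    lod[ok] <- pmin(l, cap)
  }
  lod
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each grid position the phenotype is regressed on the conditional
#' probability of the ddm1 allele; `LOD = (n/2) log10(RSS0 / RSS1)`, capped
#' at `cap` when the residual sum of squares vanishes.
#'
#' @param map_obj list from [build_map()].
#' @param phenotype numeric vector over lines (`NA` lines dropped).
#' @param step_cm grid step in cM (default 1); marker positions are always
#'   included in the grid.
#' @param cap LOD cap (default 50).
#' @param trait trait label carried in the result.
#' @return list (`LODCurve`) with `trait`, `grid` (chrom, cM, bp), `lod`
#'   and `threshold` (`NA` until set).
#' @export
hk_scan <- function(map_obj, phenotype, step_cm = 1, cap = 50,
                    trait = "trait") {
  stopifnot(length(phenotype) == nrow(map_obj$geno))
  grid <- scan_grid(map_obj$map, step_cm)
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  if (length(y) == 0L || stats::sd(y) == 0) {
    warning("constant phenotype for trait '", trait, "'; LOD curve is zero")
    return(list(trait = trait, grid = grid,
                lod = numeric(nrow(grid)), threshold = NA_real_))
  }
  P <- genotype_prob_matrix(map_obj$map, map_obj$geno[ok, , drop = FALSE], grid)
  list(trait = trait, grid = grid, lod = hk_lod(y, P, cap),
       threshold = NA_real_)
}

#' Genome-wide permutation threshold for the scan
#'
#' The `(1 - alpha)` quantile of the genome-wide maximum LOD over
#' `n_perm` phenotype permutations; deterministic given `seed`.
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed RNG seed.
#' @return LOD threshold.
#' @export
permutation_threshold <- function(map_obj, phenotype, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L, step_cm = 1,
                                  cap = 50) {
  if (n_perm < 100L) warning("n_perm < 100 gives an unstable threshold")
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  grid <- scan_grid(map_obj$map, step_cm)
  P <- genotype_prob_matrix(map_obj$map, map_obj$geno[ok, , drop = FALSE], grid)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(i) {
    max(hk_lod(sample(y), P, cap))
  }, 0)
  unname(quantile(maxima, 1 - alpha, type = 7))
}

#' Find significant peaks on a LOD curve and classify them
#'
#' Peaks are local maxima at or above `threshold`; two candidate maxima on
#' the same chromosome belong to the same peak unless the curve dips at
#' least 1.5 LOD below the lower of the two between them. The support
#' interval extends from the peak until the curve drops 1.5 LOD below it.
#' A hit is `cis` when its peak lies within `cis_window_bp` of the gene's
#' span on the same chromosome, `trans` otherwise; the compartment is
#' `heterochromatin` when the peak position falls in `het_intervals`.
#'
#' @param curve LOD curve from [hk_scan()].
#' @param threshold significance threshold (e.g. from
#'   [permutation_threshold()], or the fixed LOD-3 convention).
#' @param gene_locus single-range `GRanges` of the phenotype's gene, or
#'   `NULL` for global traits (relation is then `NA`).
#' @param het_intervals heterochromatin `GRanges` (may be `NULL`).
#' @param cis_window_bp cis window (default 1e6).
#' @return data.frame of hits: `trait`, `chrom`, `cM`, `bp`, `lod`,
#'   `support_start_bp`, `support_end_bp`, `relation`, `compartment`.
#' @export
find_peaks_and_classify <- function(curve, threshold, gene_locus = NULL,
                                    het_intervals = NULL,
                                    cis_window_bp = 1e6) {
  grid <- curve$grid
  lod <- curve$lod
  hits <- list()
  for (chr in unique(grid$chrom)) {
    gi <- which(grid$chrom == chr)
    l <- lod[gi]
    n <- length(gi)
    is_max <- l >= c(-Inf, l[-n]) & l >= c(l[-1L], -Inf) & l >= threshold
    cand <- which(is_max)
    if (length(cand) == 0L) next
    cand <- cand[order(l[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in cand) {
      sep <- TRUE
      for (k in kept) {
        valley <- min(l[seq(min(i, k), max(i, k))])
        if (valley > min(l[i], l[k]) - 1.5) {
          sep <- FALSE
          break
        }
      }
      if (sep) kept <- c(kept, i)
    }
    for (i in kept) {
      lo <- i
      while (lo > 1L && l[lo - 1L] > l[i] - 1.5) lo <- lo - 1L
      hi <- i
      while (hi < n && l[hi + 1L] > l[i] - 1.5) hi <- hi + 1L
      peak_bp <- grid$bp[gi[i]]
      relation <- NA_character_
      if (!is.null(gene_locus)) {
        same <- as.character(seqnames(gene_locus)) == chr
        dist <- if (same) {
          max(0, max(start(gene_locus) - peak_bp, peak_bp - end(gene_locus)))
        } else Inf
        relation <- if (dist <= cis_window_bp) "cis" else "trans"
      }
      compartment <- "euchromatin"
      if (!is.null(het_intervals)) {
        pt <- GRanges(chr, IRanges(peak_bp, peak_bp))
        if (length(quiet_overlaps(pt, het_intervals))) compartment <- "heterochromatin"
      }
      hits[[length(hits) + 1L]] <- data.frame(
        trait = curve$trait, chrom = chr, cM = grid$cM[gi[i]], bp = peak_bp,
        lod = l[i], support_start_bp = grid$bp[gi[lo]],
        support_end_bp = grid$bp[gi[hi]], relation = relation,
        compartment = compartment, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(trait = character(), chrom = character(),
                      cM = numeric(), bp = numeric(), lod = numeric(),
                      support_start_bp = numeric(),
                      support_end_bp = numeric(), relation = character(),
                      compartment = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Scan every gene's methylation phenotype for QTL
#'
#' One Haley-Knott scan per gene at a shared significance threshold, with
#' the aggregation tables used to summarise a methylation-QTL experiment:
#' number of genes with at least one QTL, hits per compartment, and the
#' hits-per-gene histogram. Genes with constant phenotypes are skipped.
#'
#' @param map_obj list from [build_map()].
#' @param phenotypes lines x genes numeric matrix (column names are gene
#'   ids).
#' @param threshold shared LOD threshold.
#' @param gene_loci `GRanges` with `gene_id` metadata locating each
#'   phenotype's gene.
#' @param het_intervals heterochromatin `GRanges` (or `NULL`).
#' @param step_cm grid step (default 1).
#' @param cis_window_bp cis window (default 1e6).
#' @return list with `hits` (data.frame over all genes), `n_genes_with_qtl`,
#'   `hits_per_compartment` and `hits_per_gene` (table).
#' @export
scan_all_genes <- function(map_obj, phenotypes, threshold, gene_loci,
                           het_intervals = NULL, step_cm = 1,
                           cis_window_bp = 1e6) {
  grid <- scan_grid(map_obj$map, step_cm)
  P <- genotype_prob_matrix(map_obj$map, map_obj$geno, grid)
  all_hits <- list()
  for (g in colnames(phenotypes)) {
    y <- phenotypes[, g]
    ok <- !is.na(y)
    if (sum(ok) < 2L || stats::sd(y[ok]) == 0) next
    lod <- hk_lod(y[ok], P[ok, , drop = FALSE])
    curve <- list(trait = g, grid = grid, lod = lod, threshold = threshold)
    locus <- gene_loci[mcols(gene_loci)$gene_id == g]
    if (length(locus) == 0L) locus <- NULL
    h <- find_peaks_and_classify(curve, threshold, locus, het_intervals,
                                 cis_window_bp)
    if (nrow(h)) all_hits[[g]] <- h
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    find_peaks_and_classify(list(trait = "none",
                                 grid = grid[0, ], lod = numeric(0)), Inf)
  rownames(hits) <- NULL
  list(hits = hits,
       n_genes_with_qtl = length(unique(hits$trait)),
       hits_per_compartment = table(hits$compartment),
       hits_per_gene = table(table(hits$trait)))
}
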