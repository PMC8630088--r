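# assign a gene id to every in-context covered site falling in a gene span
# (full span: intronic gains count); returns sites with a gene_id column,
# duplicated where spans overlap
sites_in_genes <- function(sites, genes, context, min_cov) {
  sel <- filter_context(sites, context)
  sel <- sel[total_reads >= min_cov]
  if (nrow(sel) == 0L) {
    return(cbind(sel, data.table(gene_id = character(0))))
  }
  gr <- GRanges(sel$chrom, IRanges(sel$pos, sel$pos))
  ov <- findOverlaps(gr, genes)
  out <- sel[queryHits(ov)]
  out[, gene_id := mcols(genes)$gene_id[subjectHits(ov)]]
  out
}

#' Call an ectopic methylation gain for one gene in one line
#'
#' Usable sites are in-context cytosines in the gene body (full gene span)
#' covered by at least `min_cov` reads in both the sample and the control.
#' `delta` is the mean over usable sites of the per-site level difference
#' (sample minus control); a gain requires at least `min_sites` usable sites
#' and `delta >= min_delta` (the "minimum of three sites with an average 10%
#' higher methylation" rule).
#'
#' @param gene single-gene `GRanges`.
#' @param sample_sites,control_sites cytosine site tables.
#' @param context `"CHG"`, `"CWA"` or `"CHH_nonCWA"`.
#' @param min_sites site floor (default 3).
#' @param min_delta mean level increase required (default 0.1).
#' @param min_cov per-sample coverage floor per site (default 3).
#' @return list with `gene_id`, `context`, `n_sites`, `delta` (`NA` when no
#'   usable site) and `is_gain`.
#' @export
call_gene_gain <- function(gene, sample_sites, control_sites, context,
                           min_sites = 3L, min_delta = 0.1, min_cov = 3L) {
  calls <- gain_calls(gene, sample_sites, control_sites, context,
                      min_sites, min_delta, min_cov)
  idx <- match(mcols(gene)$gene_id, calls$gene_id)
  list(gene_id = mcols(gene)$gene_id, context = context,
       n_sites = calls$n_sites[idx], delta = calls$delta[idx],
       is_gain = calls$is_gain[idx])
}

# vectorised gain calling over a gene set; one row per gene
gain_calls <- function(genes, sample_sites, control_sites, context,
                       min_sites = 3L, min_delta = 0.1, min_cov = 3L) {
  samp <- sites_in_genes(sample_sites, genes, context, min_cov)
  ctrl <- sites_in_genes(control_sites, genes, context, min_cov)
  merged <- merge(
    samp[, .(gene_id, chrom, pos, strand,
             s_level = mc_reads / total_reads)],
    ctrl[, .(gene_id, chrom, pos, strand,
             c_level = mc_reads / total_reads)],
    by = c("gene_id", "chrom", "pos", "strand")
  )
  agg <- merged[, .(n_sites = .N, delta = mean(s_level - c_level)),
                by = gene_id]
  out <- data.table(gene_id = mcols(genes)$gene_id, context = context)
  out <- merge(out, agg, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(n_sites), n_sites := 0L]
  out[, is_gain := n_sites >= min_sites & !is.na(delta) & delta >= min_delta]
  out[]
}

#' Gain matrix and per-line methylation phenotypes across an epiRIL panel
#'
#' Calls [call_gene_gain()] for every gene in every line against a common
#' control methylome and summarises each line with the three QTL phenotypes:
#' the number of gaining genes (`n_gain`), the mean genic in-context
#' weighted level (`mean_genic_level`), and the genome-wide weighted level
#' (`global_level`).
#'
#' @param genes gene `GRanges`.
#' @param line_sites named list of cytosine site tables, one per line.
#' @param control_sites control (wild-type parent) site table.
#' @param context gain context (default `"CHG"`).
#' @param min_sites,min_delta,min_cov see [call_gene_gain()].
#' @return list with `calls` (per line x gene: `n_sites`, `delta`,
#'   `is_gain`) and `summary` (per line phenotypes).
#' @export
gain_matrix <- function(genes, line_sites, control_sites, context = "CHG",
                        min_sites = 3L, min_delta = 0.1, min_cov = 3L) {
  stopifnot(!is.null(names(line_sites)))
  all_calls <- list()
  summaries <- list()
  for (ln in names(line_sites)) {
    sites <- line_sites[[ln]]
    if (is.null(sites) || nrow(sites) == 0L) {
      warning("line ", ln, " has no methylome; excluded")
      next
    }
    calls <- gain_calls(genes, sites, control_sites, context,
                        min_sites, min_delta, min_cov)
    calls[, line_id := ln]
    all_calls[[ln]] <- calls

    genic <- sites_in_genes(sites, genes, context, 1L)
    genic_levels <- genic[, .(level = sum(mc_reads) / sum(total_reads)),
                          by = gene_id]
    ctx_all <- filter_context(sites, context)[total_reads >= 1L]
    summaries[[ln]] <- data.table(
      line_id = ln,
      n_gain = sum(calls$is_gain),
      mean_genic_level = mean(genic_levels$level),
      global_level = if (nrow(ctx_all)) sum(ctx_all$mc_reads) / sum(ctx_all$total_reads) else NA_real_
    )
  }
  list(calls = rbindlist(all_calls), summary = rbindlist(summaries))
}

#' One-sided Fisher exact test for enrichment (odds ratio > 1)
#'
#' Exact hypergeometric upper tail over 2x2 tables with the observed margins
#' and first cell at least `a`; the odds ratio is `ad/bc` (infinite when
#' `bc = 0`).
#'
#' @param a,b,c,d cell counts of the table `[[a, b], [c, d]]`.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_enrichment_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("all-zero contingency table")
  p <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  list(odds_ratio = or, p = p)
}

#' Enrichment of methylation gains by gene class
#'
#' For each class present in the gene universe, a one-sided Fisher test on
#' the 2x2 table (gaining vs not) x (class vs rest) over all analysed genes.
#'
#' @param gains data.frame with columns `gene_id` and `is_gain` (one row per
#'   gene).
#' @param classes data.frame with columns `gene_id` and `class`.
#' @return data.frame per class: `n`, `n_gain`, `prop_gain`, `odds_ratio`,
#'   `p`.
#' @export
class_enrichment <- function(gains, classes) {
  dt <- merge(as.data.table(gains)[, .(gene_id, is_gain)],
              as.data.table(classes)[, .(gene_id, class)], by = "gene_id")
  cls <- sort(unique(dt$class))
  if (length(cls) < 2L) {
    warning("gene universe contains a single class; enrichment skipped")
    return(data.frame(class = character(), n = integer(), n_gain = integer(),
                      prop_gain = numeric(), odds_ratio = numeric(),
                      p = numeric()))
  }
  rows <- lapply(cls, function(x) {
    a <- sum(dt$is_gain & dt$class == x)
    b <- sum(dt$is_gain & dt$class != x)
    cc <- sum(!dt$is_gain & dt$class == x)
    dd <- sum(!dt$is_gain & dt$class != x)
    ft <- fisher_enrichment_one_sided(a, b, cc, dd)
    data.frame(class = x, n = a + cc, n_gain = a,
               prop_gain = if (a + cc > 0) a / (a + cc) else NA_real_,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  do.call(rbind, rows)
}

#' Correlation of a gene's methylation change with the hypomethylation index
#'
#' Pearson correlation, across the lines of one parental stratum, between
#' the gene's per-line mean level difference (`delta`) and the line's
#' hypomethylation index `h`. Genes with `|r| > cutoff` are flagged as
#' index-associated. Undefined (zero variance or fewer than 3 lines)
#' correlations are not flagged.
#'
#' @param delta numeric per-line level differences for the gene.
#' @param h per-line hypomethylation indices, parallel to `delta`.
#' @param cutoff `|r|` threshold (default 0.35).
#' @return list with `r`, `n_lines` and `flagged`.
#' @export
delta_index_correlation <- function(delta, h, cutoff = 0.35) {
  ok <- !is.na(delta) & !is.na(h)
  delta <- delta[ok]; h <- h[ok]
  n <- length(delta)
  if (n < 3L || stats::sd(delta) == 0 || stats::sd(h) == 0) {
    return(list(r = NA_real_, n_lines = n, flagged = FALSE))
  }
  r <- cor(delta, h)
  list(r = r, n_lines = n, flagged = is.finite(r) && abs(r) > cutoff)
}
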