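#' Estimate the bisulfite non-conversion rate from an unmethylated control
#'
#' Chloroplast DNA is fully unmethylated, so any apparently methylated reads
#' on the control contig measure the fraction of unconverted cytosines. The
#' estimate is the weighted rate: total methylated reads over total reads on
#' the control contig.
#'
#' @param sites cytosine site table.
#' @param control_contig contig name of the unmethylated control (e.g.
#'   `"ChrC"`).
#' @return list with `rate` (in `[0,1]`) and `control_contig`.
#' @export
estimate_nonconversion <- function(sites, control_contig) {
  ctrl <- sites[chrom == control_contig & total_reads > 0L]
  if (nrow(ctrl) == 0L) {
    stop("no covered sites on control contig '", control_contig, "'")
  }
  list(rate = sum(ctrl$mc_reads) / sum(ctrl$total_reads),
       control_contig = control_contig)
}

#' Call per-site methylation with a binomial test
#'
#' Sites with coverage below `min_cov` are left uncalled. For each tested
#' site, the one-sided binomial p-value `P(X >= mc | n = total, p = rate)`
#' asks whether the methylated read count exceeds what bisulfite
#' non-conversion alone would produce; p-values are Benjamini-Hochberg
#' adjusted across all tested sites and a site is called methylated when its
#' q-value falls below `fdr`.
#'
#' @param sites cytosine site table.
#' @param rate non-conversion rate in `[0,1)`, or the list returned by
#'   [estimate_nonconversion()].
#' @param min_cov minimum read coverage for a site to be tested (default 3).
#' @param fdr q-value threshold for a methylated call (default 0.05).
#' @return the site table with the `call` column set.
#' @export
call_site_methylation <- function(sites, rate, min_cov = 3L, fdr = 0.05) {
  if (is.list(rate)) rate <- rate$rate
  stopifnot(rate >= 0, rate < 1)
  out <- copy(sites)
  tested <- out$total_reads >= min_cov
  out[, call := "uncalled"]
  if (any(tested)) {
    p <- pbinom(out$mc_reads[tested] - 1L, out$total_reads[tested], rate,
                lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    out$call[tested] <- ifelse(q < fdr, "methylated", "unmethylated")
  }
  out[]
}

# restrict a site table to a named context; "CWA" and "CHH_nonCWA" are
# subcontexts of CHH, "all" pools everything
filter_context <- function(sites, context) {
  switch(context,
    all = sites,
    CG = sites[context == "CG"],
    CHG = sites[context == "CHG"],
    CHH = sites[context == "CHH"],
    CWA = sites[context == "CHH" & is_cwa(tri_context)],
    CHH_nonCWA = sites[context == "CHH" & !is_cwa(tri_context)],
    stop("unknown context '", context, "'")
  )
}

#' Weighted methylation level of an interval
#'
#' Sum of methylated reads over sum of total reads across covered in-context
#' cytosines inside the interval, the standard weighted methylation level.
#' Returns `NA` (distinct from 0) when no covered site falls in the interval.
#'
#' @param sites cytosine site table.
#' @param interval a single-range `GRanges` (1-based closed).
#' @param context `"CG"`, `"CHG"`, `"CHH"`, `"CWA"`, `"CHH_nonCWA"` or
#'   `"all"` (pooled).
#' @return numeric level in `[0,1]`, or `NA`.
#' @export
weighted_level <- function(sites, interval, context = "all") {
  stopifnot(length(interval) == 1L)
  sel <- filter_context(sites, context)
  sel <- sel[chrom == as.character(seqnames(interval)) &
               pos >= start(interval) & pos <= end(interval) &
               total_reads >= 1L]
  if (nrow(sel) == 0L) return(NA_real_)
  sum(sel$mc_reads) / sum(sel$total_reads)
}

#' Windowed methylation profile of a gene with flanks
#'
#' The gene span is divided into `body_windows` equal windows (remainder
#' bases assigned to the last window) and the regions `flank_bp` upstream and
#' downstream are each divided into 20 windows of `flank_window_bp`. Each
#' window's entry is its weighted methylation level. For minus-strand genes
#' the whole vector is reversed so index 1 is always the 5' upstream end.
#'
#' @param gene single-gene `GRanges` with a `gene_id` metadata column.
#' @param sites cytosine site table.
#' @param context methylation context (see [weighted_level()]).
#' @param flank_bp flank length in bp (default 1000).
#' @param body_windows number of gene-body windows (default 20).
#' @param flank_window_bp width of each flank window in bp (default 50).
#' @return list with `gene_id`, `context` and `levels`, a numeric vector of
#'   length `40 + body_windows` (`NA` where a window has no covered site).
#' @export
gene_window_profile <- function(gene, sites, context = "CG", flank_bp = 1000L,
                                body_windows = 20L, flank_window_bp = 50L) {
  stopifnot(length(gene) == 1L)
  n_flank <- as.integer(flank_bp / flank_window_bp)
  gs <- start(gene); ge <- end(gene)
  glen <- ge - gs + 1L

  sel <- filter_context(sites, context)
  sel <- sel[chrom == as.character(seqnames(gene)) & total_reads >= 1L]

  win_level <- function(lo, hi) {
    s <- sel[pos >= lo & pos <= hi]
    if (nrow(s) == 0L) NA_real_ else sum(s$mc_reads) / sum(s$total_reads)
  }

  left <- vapply(seq_len(n_flank), function(i) {
    lo <- gs - flank_bp + (i - 1L) * flank_window_bp
    win_level(lo, lo + flank_window_bp - 1L)
  }, 0)

  if (glen < body_windows) {
    warning("gene ", mcols(gene)$gene_id, " shorter than ", body_windows,
            " bp; body windows are all missing")
    body <- rep(NA_real_, body_windows)
  } else {
    w <- glen %/% body_windows
    bounds <- gs + w * seq_len(body_windows)  # exclusive upper bound per window
    bounds[body_windows] <- ge + 1L           # remainder goes to last window
    lo <- c(gs, bounds[-body_windows])
    body <- vapply(seq_len(body_windows), function(i) win_level(lo[i], bounds[i] - 1L), 0)
  }

  right <- vapply(seq_len(n_flank), function(i) {
    lo <- ge + 1L + (i - 1L) * flank_window_bp
    win_level(lo, lo + flank_window_bp - 1L)
  }, 0)

  levels <- c(left, body, right)
  if (as.character(strand(gene)) == "-") levels <- rev(levels)
  list(gene_id = mcols(gene)$gene_id, context = context, levels = levels)
}

#' Average windowed profiles across genes of a group
#'
#' Per-window mean over profiles, ignoring missing windows; a window missing
#' in every profile stays missing. All profiles must share the context.
#'
#' @param profiles list of profiles from [gene_window_profile()].
#' @return a profile list with `gene_id = "aggregate"`.
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  ctx <- unique(vapply(profiles, `[[`, "", "context"))
  if (length(ctx) != 1L) stop("profiles mix contexts: ", paste(ctx, collapse = ", "))
  mat <- do.call(rbind, lapply(profiles, `[[`, "levels"))
  means <- colMeans(mat, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  list(gene_id = "aggregate", context = ctx, levels = means)
}
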