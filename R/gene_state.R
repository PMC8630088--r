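#' Genome-wide background methylation rate over coding sequence
#'
#' The fraction of called cytosines in the given context, across the union of
#' all genes' CDS intervals, that are called methylated. A site falling in
#' overlapping CDS annotations is counted once. This is the background
#' probability of a single site being methylated used by the per-gene
#' binomial test.
#'
#' @param sites cytosine site table with calls set (see
#'   [call_site_methylation()]).
#' @param genes gene `GRanges` from [read_gene_models()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @return background rate in `[0,1]`.
#' @export
cds_background_rate <- function(sites, genes, context) {
  cds <- reduce(unlist(mcols(genes)$cds))
  sel <- filter_context(sites, context)
  sel <- sel[call != "uncalled"]
  if (nrow(sel) == 0L) stop("no called ", context, " sites in CDS")
  gr <- GRanges(sel$chrom, IRanges(sel$pos, sel$pos))
  hit <- unique(queryHits(findOverlaps(gr, cds)))
  if (length(hit) == 0L) stop("no called ", context, " sites in CDS")
  mean(sel$call[hit] == "methylated")
}

#' Upper-tail binomial p-value for a gene's methylated site count
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the probability of observing at
#' least as many methylated cytosines as the gene shows, if sites were
#' methylated independently at the genome-wide background rate.
#'
#' @param n number of called sites.
#' @param k number of methylated calls.
#' @param p0 background rate.
#' @return p-value (vectorised).
#' @export
gene_binomial_p <- function(n, k, p0) {
  stopifnot(all(k >= 0), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment, returned in input order.
#'
#' @param p p-values in `[0,1]`.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# count CG dyads where both strand sites are called methylated: a plus-strand
# CG at pos p pairs with a minus-strand CG at p+1
count_symmetric_mcg <- function(site_sub) {
  cg <- site_sub[context == "CG" & call == "methylated"]
  if (nrow(cg) < 2L) return(0L)
  plus <- cg[strand == "+", pos]
  minus <- cg[strand == "-", pos]
  length(intersect(plus + 1L, minus))
}

#' Classify genes by gene-body methylation state
#'
#' For each gene and context (CG, CHG, CHH), called sites within the primary
#' transcript's CDS are counted (`n`) along with methylated calls (`k`); an
#' upper-tail binomial p-value against the genome-wide CDS background rate is
#' computed and BH-adjusted per context across all genes. Genes are then
#' labelled:
#' \itemize{
#'   \item `teM_mCHH`: `n_CHH >= min_sites` and `q_CHH < alpha` (other
#'     contexts unconstrained);
#'   \item `teM_mCHG`: `n_CHG >= min_sites`, `q_CHG < alpha`, `q_CHH >=
#'     alpha` (CG unconstrained, as mCG commonly accompanies mCHG);
#'   \item `gbM`: `n_CG >= min_sites`, `q_CG < alpha`, and `q_CHG`, `q_CHH
#'     >= alpha`;
#'   \item `UM`: `n_CHH >= min_sites`, all q-values `>= alpha`, and at most
#'     `max_sym_mcg` symmetric methylated CG dyads;
#'   \item otherwise `unclassified`.
#' }
#' teM rules take precedence over gbM, which takes precedence over UM.
#'
#' @param genes gene `GRanges`.
#' @param sites cytosine site table with calls set.
#' @param rates list with `p0_CG`, `p0_CHG`, `p0_CHH` (see
#'   [cds_background_rate()]); computed from `sites` when `NULL`.
#' @param min_sites minimum called sites per context (default 20).
#' @param alpha q-value threshold (default 0.05).
#' @param max_sym_mcg symmetric-mCG ceiling for UM (default 2).
#' @return `data.frame` with one row per gene: per-context `n`, `k`, `p`,
#'   `q`, `n_sym_mcg` and `class`.
#' @export
classify_genes <- function(genes, sites, rates = NULL, min_sites = 20L,
                           alpha = 0.05, max_sym_mcg = 2L) {
  if (is.null(rates)) {
    rates <- list(p0_CG = cds_background_rate(sites, genes, "CG"),
                  p0_CHG = cds_background_rate(sites, genes, "CHG"),
                  p0_CHH = cds_background_rate(sites, genes, "CHH"))
  }
  called <- sites[call != "uncalled"]
  site_gr <- GRanges(called$chrom, IRanges(called$pos, called$pos))

  n_gene <- length(genes)
  res <- data.frame(gene_id = mcols(genes)$gene_id)
  no_cds <- lengths(mcols(genes)$cds) == 0L
  if (any(no_cds)) {
    warning(sum(no_cds), " gene(s) without CDS left unclassified")
  }

  cds_flat <- unlist(mcols(genes)$cds)
  gene_idx <- rep(seq_len(n_gene), lengths(mcols(genes)$cds))
  ov <- findOverlaps(site_gr, cds_flat)
  pairs <- unique(data.table(site = queryHits(ov),
                             gene = gene_idx[subjectHits(ov)]))
  pairs <- cbind(pairs, called[pairs$site,
                               .(context, call, strand, pos)])

  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- pairs[context == ctx]
    n <- integer(n_gene); k <- integer(n_gene)
    if (nrow(sub)) {
      agg <- sub[, .(n = .N, k = sum(call == "methylated")), by = gene]
      n[agg$gene] <- agg$n; k[agg$gene] <- agg$k
    }
    p0 <- rates[[paste0("p0_", ctx)]]
    p <- gene_binomial_p(n, k, p0)
    res[[paste0("n_", ctx)]] <- n
    res[[paste0("k_", ctx)]] <- k
    res[[paste0("p_", ctx)]] <- p
    res[[paste0("q_", ctx)]] <- bh_adjust(p)
  }

  sym <- integer(n_gene)
  mcg <- pairs[context == "CG" & call == "methylated"]
  if (nrow(mcg)) {
    sym_agg <- mcg[, {
      plus <- pos[strand == "+"]; minus <- pos[strand == "-"]
      .(n_sym = length(intersect(plus + 1L, minus)))
    }, by = gene]
    sym[sym_agg$gene] <- sym_agg$n_sym
  }
  res$n_sym_mcg <- sym

  sig <- function(ctx) res[[paste0("q_", ctx)]] < alpha
  floor_ok <- function(ctx) res[[paste0("n_", ctx)]] >= min_sites
  cls <- rep("unclassified", n_gene)
  is_um <- floor_ok("CHH") & !sig("CG") & !sig("CHG") & !sig("CHH") &
    sym <= max_sym_mcg
  cls[is_um] <- "UM"
  cls[floor_ok("CG") & sig("CG") & !sig("CHG") & !sig("CHH")] <- "gbM"
  cls[floor_ok("CHG") & sig("CHG") & !sig("CHH")] <- "teM_mCHG"
  cls[floor_ok("CHH") & sig("CHH")] <- "teM_mCHH"
  cls[no_cds] <- "unclassified"
  res$class <- cls
  res
}
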