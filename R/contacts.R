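# GRanges for the two anchors of a contact table
contact_anchors <- function(contacts) {
  list(a = GRanges(contacts$chrom1, IRanges(contacts$start1, contacts$end1)),
       b = GRanges(contacts$chrom2, IRanges(contacts$start2, contacts$end2)))
}

#' Summarise gene contacts with H3K9me2 regions
#'
#' A significant contact counts for a gene when one anchor overlaps at
#' least 1 bp of any H3K9me2 peak and the other anchor overlaps at least
#' 1 bp of the gene; multiple peak (or gene) overlaps of one anchor still
#' count the contact once per gene. The distance reported per gene is the
#' nearest-edge gap (0 when overlapping) between the gene and any contacted
#' peak on the same chromosome; inter-chromosomal contacts contribute to
#' counts but not distances.
#'
#' @param contacts data.frame from [read_contacts()], already filtered to
#'   significant contacts (or pass `q_max` to filter here).
#' @param peaks H3K9me2 peak `GRanges`.
#' @param genes gene `GRanges` with `gene_id` metadata.
#' @param q_max optional q-value cutoff applied to `contacts`.
#' @return data.frame per gene: `gene_id`, `n_contacts`, `min_distance_bp`
#'   (`NA` when the gene has no intra-chromosomal contacted peak).
#' @export
summarize_gene_contacts <- function(contacts, peaks, genes, q_max = NULL) {
  if (!is.null(q_max)) {
    contacts <- contacts[!is.na(contacts$q_value) & contacts$q_value <= q_max, ]
  }
  n_gene <- length(genes)
  n_contacts <- integer(n_gene)
  min_dist <- rep(NA_real_, n_gene)
  if (nrow(contacts)) {
    an <- contact_anchors(contacts)
    peak_hit_a <- unique(queryHits(quiet_overlaps(an$a, peaks)))
    peak_hit_b <- unique(queryHits(quiet_overlaps(an$b, peaks)))
    ov_a <- quiet_overlaps(an$a, genes)
    ov_b <- quiet_overlaps(an$b, genes)
    # (contact, gene) pairs where the opposite anchor touches a peak
    sel_a <- queryHits(ov_a) %in% peak_hit_b
    sel_b <- queryHits(ov_b) %in% peak_hit_a
    pairs <- rbind(
      data.frame(contact = queryHits(ov_a)[sel_a],
                 gene = subjectHits(ov_a)[sel_a],
                 peak_anchor = rep("b", sum(sel_a))),
      data.frame(contact = queryHits(ov_b)[sel_b],
                 gene = subjectHits(ov_b)[sel_b],
                 peak_anchor = rep("a", sum(sel_b)))
    )
    if (nrow(pairs)) {
      uniq <- unique(pairs[, c("contact", "gene")])
      tab <- table(factor(uniq$gene, levels = seq_len(n_gene)))
      n_contacts <- as.integer(tab)
      # distances: join each pair to the peaks overlapping its peak-side
      # anchor, then take the per-gene minimum edge gap (same chromosome)
      pk_a <- data.table(contact = queryHits(quiet_overlaps(an$a, peaks)),
                         peak = subjectHits(quiet_overlaps(an$a, peaks)),
                         peak_anchor = "a")
      pk_b <- data.table(contact = queryHits(quiet_overlaps(an$b, peaks)),
                         peak = subjectHits(quiet_overlaps(an$b, peaks)),
                         peak_anchor = "b")
      joined <- merge(as.data.table(pairs), rbind(pk_a, pk_b),
                      by = c("contact", "peak_anchor"), allow.cartesian = TRUE)
      if (nrow(joined)) {
        same <- as.character(seqnames(genes))[joined$gene] ==
          as.character(seqnames(peaks))[joined$peak]
        joined <- joined[same]
      }
      if (nrow(joined)) {
        gap <- pmax(0, pmax(start(peaks)[joined$peak] - end(genes)[joined$gene],
                            start(genes)[joined$gene] - end(peaks)[joined$peak]))
        dd <- data.table(gene = joined$gene, gap = gap)[
          , .(d = min(gap)), by = gene]
        min_dist[dd$gene] <- dd$d
      }
    }
  }
  data.frame(gene_id = mcols(genes)$gene_id, n_contacts = n_contacts,
             min_distance_bp = min_dist, stringsAsFactors = FALSE)
}

#' Enrichment of H3K9me2 contacts by gene class
#'
#' For each gene class, a one-sided Fisher test (odds ratio > 1) on the 2x2
#' table (contacted vs not) x (class vs rest) over the analysed gene
#' universe.
#'
#' @param summaries data.frame from [summarize_gene_contacts()] with an
#'   added `class` column.
#' @return data.frame per class: `n`, `n_contacted`, `prop_contacted`,
#'   `odds_ratio`, `p`.
#' @export
contact_class_enrichment <- function(summaries) {
  contacted <- summaries$n_contacts > 0
  cls <- sort(unique(summaries$class))
  rows <- lapply(cls, function(x) {
    a <- sum(contacted & summaries$class == x)
    b <- sum(contacted & summaries$class != x)
    cc <- sum(!contacted & summaries$class == x)
    dd <- sum(!contacted & summaries$class != x)
    ft <- fisher_enrichment_one_sided(a, b, cc, dd)
    data.frame(class = x, n = a + cc, n_contacted = a,
               prop_contacted = if (a + cc > 0) a / (a + cc) else NA_real_,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  do.call(rbind, rows)
}

#' Pairwise two-sided rank-sum comparisons between gene groups
#'
#' Wilcoxon rank-sum tests between every pair of groups on the chosen
#' measure, with no multiplicity adjustment. The exact null distribution is
#' used for small tie-free comparisons (`min(n1, n2) <= 8`); otherwise the
#' normal approximation with tie correction.
#'
#' @param values numeric measurements (e.g. contact counts or distances).
#' @param groups group labels parallel to `values`.
#' @return data.frame per pair: `group1`, `group2`, `n1`, `n2`, `p`.
#' @export
compare_groups <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lv <- sort(unique(groups))
  rows <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      x <- values[groups == lv[i]]
      y <- values[groups == lv[j]]
      if (length(x) == 0L || length(y) == 0L) next
      has_ties <- anyDuplicated(c(x, y)) > 0L
      exact <- min(length(x), length(y)) <= 8L && !has_ties
      p <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = !exact)$p.value
      )
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j], n1 = length(x), n2 = length(y),
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), p = numeric()))
  }
  do.call(rbind, rows)
}
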