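#' Call the parental state of a DMR marker in one line
#'
#' The marker's weighted methylation level (all contexts pooled by default;
#' the DMRs distinguish methylated from unmethylated regions, not contexts)
#' is thresholded at 0.5: below 0.5 the marker carries the unmethylated
#' ddm1 state (`"U"`), at or above 0.5 the methylated wild-type state
#' (`"M"`); `NA` when no covered site falls in the marker.
#'
#' @param sites cytosine site table for the line.
#' @param marker single-range `GRanges`.
#' @param context context pooled into the level (default `"all"`).
#' @return `"M"`, `"U"` or `NA`.
#' @export
call_marker_state <- function(sites, marker, context = "all") {
  lv <- weighted_level(sites, marker, context)
  if (is.na(lv)) NA_character_ else if (lv < 0.5) "U" else "M"
}

#' Call all marker states for one line
#'
#' @param sites cytosine site table for the line.
#' @param markers `GRanges` of DMR markers with a `name` metadata column.
#' @param context see [call_marker_state()].
#' @return named character vector of states over markers.
#' @export
call_marker_states <- function(sites, markers, context = "all") {
  sel <- filter_context(sites, context)
  sel <- sel[total_reads >= 1L]
  states <- rep(NA_character_, length(markers))
  if (nrow(sel)) {
    gr <- GRanges(sel$chrom, IRanges(sel$pos, sel$pos))
    ov <- quiet_overlaps(gr, markers)
    if (length(ov)) {
      agg <- data.table(marker = subjectHits(ov),
                        mc = sel$mc_reads[queryHits(ov)],
                        tot = sel$total_reads[queryHits(ov)])[
        , .(level = sum(mc) / sum(tot)), by = marker]
      states[agg$marker] <- ifelse(agg$level < 0.5, "U", "M")
    }
  }
  names(states) <- mcols(markers)$name
  states
}

#' Hypomethylation index of an epiRIL line
#'
#' Mean of the numeric marker states (methylated wild-type marker = 0,
#' unmethylated ddm1 marker = 1) over non-missing markers: a proxy for the
#' fraction of the genome inherited from the hypomethylated ddm1 parent.
#'
#' @param states character vector of `"M"`/`"U"`/`NA` marker states.
#' @return index in `[0,1]`.
#' @export
hypomethylation_index <- function(states) {
  ok <- !is.na(states)
  if (!any(ok)) stop("all marker states are NA")
  mean(states[ok] == "U")
}

#' Reconstruct parent-of-origin segments from marker states
#'
#' Between two consecutive markers with the same non-missing state the whole
#' span inherits that parent (M -> WT, U -> ddm1). Between discordant
#' markers the breakpoint is placed at the midpoint between the marker
#' interval edges. Spans flanking an uncalled (`NA`) marker and the
#' chromosome ends beyond the terminal markers are `"unknown"`. Segments
#' tile each chromosome without overlap.
#'
#' @param markers `GRanges` of markers (any order; sorted internally).
#' @param states marker states parallel to `markers`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return `GRanges` tiling each chromosome with a `parent` metadata column
#'   in `{WT, ddm1, unknown}`.
#' @export
haplotype_segments <- function(markers, states, chrom_lengths) {
  parent_of <- c(M = "WT", U = "ddm1")
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    idx <- which(as.character(seqnames(markers)) == chr)
    idx <- idx[order(start(markers)[idx])]
    if (length(idx) == 0L) {
      out[[chr]] <- data.frame(chrom = chr, start = 1, end = len,
                               parent = "unknown")
      next
    }
    mk_start <- start(markers)[idx]; mk_end <- end(markers)[idx]
    st <- states[idx]
    bnd_start <- numeric(0); bnd_end <- numeric(0); par <- character(0)
    add <- function(s, e, p) {
      if (e >= s) {
        bnd_start <<- c(bnd_start, s); bnd_end <<- c(bnd_end, e)
        par <<- c(par, p)
      }
    }
    add(1, mk_start[1L] - 1, "unknown")
    for (j in seq_along(idx)) {
      p <- if (is.na(st[j])) "unknown" else parent_of[[st[j]]]
      add(mk_start[j], mk_end[j], p)
      if (j < length(idx)) {
        gap_s <- mk_end[j] + 1; gap_e <- mk_start[j + 1L] - 1
        if (gap_e >= gap_s) {
          pj <- st[j]; pn <- st[j + 1L]
          if (is.na(pj) || is.na(pn)) {
            add(gap_s, gap_e, "unknown")
          } else if (pj == pn) {
            add(gap_s, gap_e, parent_of[[pj]])
          } else {
            mid <- floor((mk_end[j] + mk_start[j + 1L]) / 2)
            add(gap_s, mid, parent_of[[pj]])
            add(mid + 1, gap_e, parent_of[[pn]])
          }
        }
      }
    }
    add(mk_end[length(idx)] + 1, len, "unknown")
    seg <- data.frame(chrom = chr, start = bnd_start, end = bnd_end,
                      parent = par)
    # merge adjacent same-parent segments
    keep <- c(TRUE, seg$parent[-1L] != seg$parent[-nrow(seg)])
    grp <- cumsum(keep)
    seg <- data.frame(chrom = chr,
                      start = tapply(seg$start, grp, min),
                      end = tapply(seg$end, grp, max),
                      parent = seg$parent[keep])
    out[[chr]] <- seg
  }
  all <- do.call(rbind, out)
  gr <- GRanges(all$chrom, IRanges(all$start, all$end))
  mcols(gr)$parent <- all$parent
  gr
}

#' Assign a gene to the parental haplotype containing its midpoint
#'
#' @param gene single-gene `GRanges`.
#' @param segments segment `GRanges` from [haplotype_segments()].
#' @return `"WT"`, `"ddm1"` or `"unknown"`.
#' @export
assign_gene_parent <- function(gene, segments) {
  mid <- floor((start(gene) + end(gene)) / 2)
  pt <- GRanges(seqnames(gene), IRanges(mid, mid))
  hit <- quiet_overlaps(pt, segments)
  if (length(hit) == 0L) return("unknown")
  mcols(segments)$parent[subjectHits(hit)[1L]]
}

#' Locate met1-derived chromosome regions by gbM-exon mCG depletion
#'
#' Each chromosome is walked left to right, accumulating the exons (CDS
#' intervals) of gbM genes into consecutive bins of exactly `min_exons`
#' exons; a final short bin is merged into its predecessor. Per bin, the
#' weighted exonic mCG level is computed in the sample and in the control; a
#' bin is flagged met1-derived when the sample mean is reduced by more than
#' `reduction` relative to control, i.e. `sample < (1 - reduction) *
#' control`. Adjacent flagged bins are merged into maximal intervals.
#'
#' @param sample_sites,control_sites cytosine site tables.
#' @param gbm_genes `GRanges` of gbM genes (defined on the control sample)
#'   with `cds` metadata.
#' @param min_exons exons per bin (default 10).
#' @param reduction fractional mCG reduction calling a bin (default 0.25).
#' @return `GRanges` of met1-derived intervals.
#' @export
find_met1_derived_regions <- function(sample_sites, control_sites, gbm_genes,
                                      min_exons = 10L, reduction = 0.25) {
  exons <- unlist(mcols(gbm_genes)$cds)
  if (length(exons) == 0L) return(GRanges())
  flagged <- list()
  for (chr in unique(as.character(seqnames(exons)))) {
    ex <- exons[as.character(seqnames(exons)) == chr]
    ex <- ex[order(start(ex))]
    n <- length(ex)
    if (n == 0L) next
    n_bins <- max(1L, n %/% min_exons)
    bin_of <- pmin((seq_len(n) - 1L) %/% min_exons + 1L, n_bins)
    bins <- lapply(seq_len(n_bins), function(b) ex[bin_of == b])
    bin_level <- function(sites, bin) {
      sel <- filter_context(sites, "CG")
      sel <- sel[chrom == chr & total_reads >= 1L]
      if (nrow(sel) == 0L) return(NA_real_)
      gr <- GRanges(sel$chrom, IRanges(sel$pos, sel$pos))
      hit <- unique(queryHits(quiet_overlaps(gr, bin)))
      if (length(hit) == 0L) return(NA_real_)
      sum(sel$mc_reads[hit]) / sum(sel$total_reads[hit])
    }
    is_flag <- logical(n_bins)
    for (b in seq_len(n_bins)) {
      ctrl <- bin_level(control_sites, bins[[b]])
      if (is.na(ctrl) || ctrl == 0) {
        warning("control mCG level is 0 or missing in bin ", b, " on ", chr,
                "; bin skipped")
        next
      }
      samp <- bin_level(sample_sites, bins[[b]])
      if (is.na(samp)) next
      is_flag[b] <- samp < (1 - reduction) * ctrl
    }
    if (!any(is_flag)) next
    bin_start <- vapply(bins, function(b) min(start(b)), 0)
    bin_end <- vapply(bins, function(b) max(end(b)), 0)
    r <- rle(is_flag)
    stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(chrom = chr, start = bin_start[starts[k]],
                   end = bin_end[stops[k]])
    }
  }
  if (length(flagged) == 0L) return(GRanges())
  df <- do.call(rbind, flagged)
  GRanges(df$chrom, IRanges(df$start, df$end))
}
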