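suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(data.table)
})

# one gene with CDS covering its full span unless cds ranges are given
make_gene <- function(chrom = "Chr1", start = 1000L, end = 2999L,
                      strand = "+", id = "g1", cds = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$gene_id <- id
  if (is.null(cds)) cds <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$cds <- GRangesList(list(cds))
  gr
}

# site table with explicit calls, defaulting to deep uniform coverage
make_called_sites <- function(chrom, pos, tri, call,
                              mc = NULL, total = 10L, strand = "+") {
  if (is.null(mc)) mc <- ifelse(call == "methylated", total, 0L)
  cytosine_sites(chrom, pos, strand, tri, mc, total, call)
}

# brute-force binomial upper tail P(X >= k)
brute_binom_tail <- function(n, k, p0) {
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j), 0))
}

# brute-force one-sided Fisher p by enumerating tables at fixed margins
brute_fisher_one_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, 0)
  sum(pr[xs >= a])
}

# brute-force two-sided rank-sum p by enumerating all group assignments
brute_ranksum_two_sided <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  rk <- rank(all_v)
  obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  splits <- utils::combn(length(all_v), n1)
  ws <- apply(splits, 2L, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(ws - mu) >= abs(obs - mu))
}

# definitional step-up BH q-values
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q[ord] <- q_sorted
  q
}

# full-size cached simulation for the acceptance-level recovery checks
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_epiril_experiment(sim_config(seed = 2024L))
    }
    cache
  }
})

# small cached simulation shared by tests that only need structure
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_epiril_experiment(sim_config(
        seed = 42L, n_genes = c(gbM = 30L, teM = 12L, UM = 30L),
        n_lines = 12L, n_markers = 20L, n_chromosomes = 2L,
        het_sites_per_chrom = 60L, control_sites = 300L))
    }
    cache
  }
})
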