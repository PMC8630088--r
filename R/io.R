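#' epigain: spontaneous epiallele formation analysis for epiRIL methylomes
#'
#' Implements the computational layers of an epiallele-formation study in
#' *Arabidopsis thaliana*: per-cytosine binomial methylation calling, gene
#' methylation-state classification (gbM / teM / UM), epiRIL haplotype
#' reconstruction from DMR markers, ectopic non-CG gain calling, methylation
#' QTL interval mapping, and Hi-C contact enrichment against H3K9me2 regions.
#' A synthetic-data generator ([simulate_epiril_experiment()]) produces every
#' input with known ground truth so the whole pipeline can be exercised
#' without external data.
#'
#' @import data.table
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#'   findOverlaps reduce mcols mcols<- GRangesList
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats pbinom phyper p.adjust cor quantile rpois rbinom runif
#'   rlnorm wilcox.test setNames complete.cases lm coef plogis qlogis
#' @importFrom utils read.table write.table head tail
#' @keywords internal
"_PACKAGE"

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "tri_context", "context", "mc_reads",
  "total_reads", "call", "gene_id", "level", "window", "line_id", "J",
  "marker_id", "state", "delta", "is_gain", "n_sites", "class",
  "wt_rate", "ddm1_rate", "region", "gene", "s_level", "c_level",
  "marker", "mc", "tot"
))

VALID_CALLS <- c("methylated", "unmethylated", "uncalled")

# findOverlaps between ranges built ad hoc; disjoint seqlevels are routine
# here, so the Seqinfo merge warning is noise
quiet_overlaps <- function(query, subject, ...) {
  suppressWarnings(findOverlaps(query, subject, ...))
}

#' Derive the methylation context class from a trinucleotide context
#'
#' CG if the second base is G; CHG if the third base is G and the second is
#' not; CHH otherwise. CWA sites (`CAA`/`CTA`), the CMT2-preferred subcontext,
#' are a subset of CHH; see [is_cwa()].
#'
#' @param tri_context character vector of 3-mers over A,C,G,T,N read 5'->3'
#'   on the cytosine's strand.
#' @return character vector with values `"CG"`, `"CHG"` or `"CHH"`.
#' @export
#' @examples
#' context_class(c("CGT", "CAG", "CAA", "CTT"))
context_class <- function(tri_context) {
  stopifnot(is.character(tri_context), all(nchar(tri_context) == 3L))
  second <- substr(tri_context, 2L, 2L)
  third <- substr(tri_context, 3L, 3L)
  ifelse(second == "G", "CG", ifelse(third == "G", "CHG", "CHH"))
}

#' Is a trinucleotide context a CWA site?
#'
#' CWA (W = A or T) is the subcontext of CHH preferred by CMT2.
#'
#' @param tri_context character vector of 3-mers.
#' @return logical vector.
#' @export
is_cwa <- function(tri_context) {
  tri_context %chin% c("CAA", "CTA")
}

#' Construct a validated cytosine site table
#'
#' The per-cytosine container used throughout the package: one row per
#' cytosine with 1-based position, strand, trinucleotide context, methylated
#' and total read counts, derived context class, and a methylation call.
#'
#' @param chrom character contig names.
#' @param pos integer 1-based positions.
#' @param strand `"+"` or `"-"`.
#' @param tri_context 3-mers on the cytosine's strand.
#' @param mc_reads,total_reads non-negative integer read counts with
#'   `mc_reads <= total_reads`.
#' @param call one of `"methylated"`, `"unmethylated"`, `"uncalled"`.
#' @return a `data.table` with columns `chrom, pos, strand, tri_context,
#'   context, mc_reads, total_reads, call`.
#' @export
cytosine_sites <- function(chrom, pos, strand, tri_context, mc_reads,
                           total_reads, call = "uncalled") {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), tri_context = as.character(tri_context),
    mc_reads = as.integer(mc_reads), total_reads = as.integer(total_reads),
    call = as.character(call)
  )
  validate_sites(dt)
  dt[, context := context_class(tri_context)]
  setcolorder(dt, c("chrom", "pos", "strand", "tri_context", "context",
                    "mc_reads", "total_reads", "call"))
  dt[]
}

validate_sites <- function(dt) {
  bad <- which(dt$mc_reads > dt$total_reads)
  if (length(bad)) {
    stop("mc_reads > total_reads at row(s) ", paste(head(bad, 5L), collapse = ", "))
  }
  if (any(dt$mc_reads < 0L) || any(dt$total_reads < 0L)) {
    stop("negative read counts")
  }
  if (!all(dt$strand %chin% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(dt$pos < 1L)) stop("positions are 1-based; found pos < 1")
  if (!all(dt$call %chin% VALID_CALLS)) {
    stop("call must be one of ", paste(VALID_CALLS, collapse = ", "))
  }
  invisible(dt)
}

#' Read a per-cytosine methylation table (allc dialect)
#'
#' Expects a headerless TSV with columns chrom, pos (1-based), strand,
#' trinucleotide context, methylated reads, total reads, and an optional call
#' flag (`1` methylated, `0` unmethylated, `.` uncalled). When the flag
#' column is absent every site is `"uncalled"`.
#'
#' @param path file path.
#' @return a cytosine site `data.table` (see [cytosine_sites()]).
#' @export
read_allc <- function(path) {
  raw <- tryCatch(
    fread(path, header = FALSE, sep = "\t", colClasses = "character"),
    error = function(e) stop("failed to parse allc file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(raw) == 0L) {
    return(cytosine_sites(character(), integer(), character(), character(),
                          integer(), integer(), character()))
  }
  if (ncol(raw) < 6L) stop("allc file needs >= 6 columns, found ", ncol(raw))
  pos <- suppressWarnings(as.integer(raw[[2L]]))
  mc <- suppressWarnings(as.integer(raw[[5L]]))
  tot <- suppressWarnings(as.integer(raw[[6L]]))
  bad <- which(is.na(pos) | is.na(mc) | is.na(tot))
  if (length(bad)) stop("malformed allc row at line ", bad[1L])
  call <- if (ncol(raw) >= 7L) {
    ifelse(raw[[7L]] == "1", "methylated",
           ifelse(raw[[7L]] == "0", "unmethylated", "uncalled"))
  } else "uncalled"
  cytosine_sites(raw[[1L]], pos, raw[[3L]], raw[[4L]], mc, tot, call)
}

#' Write a cytosine site table in allc dialect
#'
#' Inverse of [read_allc()]: the call column is encoded as `1`/`0`/`.`.
#'
#' @param sites cytosine site table.
#' @param path output path.
#' @export
write_allc <- function(sites, path) {
  flag <- c(methylated = "1", unmethylated = "0", uncalled = ".")[sites$call]
  out <- data.table(sites$chrom, sites$pos, sites$strand, sites$tri_context,
                    sites$mc_reads, sites$total_reads, flag)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Takes `gene`, `mRNA` and `CDS` features. For each gene, CDS intervals of
#' the primary transcript only are retained: the mRNA whose ID ends in
#' `".1"`, or the first mRNA in file order when no such ID exists. Genes
#' without any CDS on the primary transcript are skipped with a warning.
#'
#' @param path GFF3 file path.
#' @return a `GRanges` of genes (1-based closed coordinates, as in GFF3) with
#'   metadata columns `gene_id` and `cds` (a `GRangesList` of per-gene CDS
#'   intervals).
#' @export
read_gene_models <- function(path) {
  empty <- GRanges()
  mcols(empty)$gene_id <- character()
  mcols(empty)$cds <- GRangesList()
  if (file.size(path) == 0L) return(empty)
  gff <- tryCatch(as.data.frame(rtracklayer::readGFF(path)),
                  error = function(e) stop("failed to parse GFF3 '", path,
                                           "': ", conditionMessage(e)))
  if (nrow(gff) == 0L) return(empty)
  if (any(gff$start > gff$end)) stop("GFF3 coordinate inversion (start > end)")
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  parent_of <- function(x) vapply(x, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  mrna_parent <- parent_of(mrna$Parent)
  cds_parent <- parent_of(cds$Parent)

  keep <- logical(nrow(genes))
  cds_list <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrna[mrna_parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) next
    primary <- tx$ID[endsWith(tx$ID, ".1")]
    primary <- if (length(primary)) primary[1L] else tx$ID[1L]
    gcds <- cds[cds_parent == primary, , drop = FALSE]
    if (nrow(gcds) == 0L) next
    keep[i] <- TRUE
    cds_list[[i]] <- GRanges(gcds$seqid, IRanges(gcds$start, gcds$end),
                             strand = genes$strand[i])
  }
  dropped <- genes$ID[!keep]
  if (length(dropped)) {
    warning("skipping ", length(dropped), " gene(s) without CDS: ",
            paste(head(dropped, 3L), collapse = ", "))
  }
  genes <- genes[keep, , drop = FALSE]
  gr <- GRanges(genes$seqid, IRanges(genes$start, genes$end),
                strand = genes$strand)
  mcols(gr)$gene_id <- genes$ID
  mcols(gr)$cds <- GRangesList(cds_list[keep])
  gr
}

#' Read a BED3/BED4 interval file
#'
#' BED's 0-based half-open coordinates are converted to the package-internal
#' 1-based closed `GRanges` convention at this boundary; the two denote the
#' same bases. Zero- or negative-width records are a validation error.
#'
#' @param path BED file path.
#' @return `GRanges`, with a `name` metadata column when BED4.
#' @export
read_intervals <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("BED file needs >= 3 columns")
  start0 <- as.numeric(raw[[2L]])
  end0 <- as.numeric(raw[[3L]])
  if (any(is.na(start0)) || any(is.na(end0))) stop("non-numeric BED coordinates")
  if (any(start0 >= end0)) {
    stop("invalid BED interval (start >= end) at line ", which(start0 >= end0)[1L])
  }
  gr <- GRanges(raw[[1L]], IRanges(start0 + 1L, end0))
  if (ncol(raw) >= 4L) mcols(gr)$name <- raw[[4L]]
  gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges`; a `name` metadata column becomes BED column 4.
#' @param path output path.
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(mcols(gr)$name)) df$name <- mcols(gr)$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read significant chromatin contacts from BEDPE
#'
#' Columns 1-6 are the two anchors in BED convention (converted to 1-based
#' closed internally); an optional 7th column is parsed as the contact's
#' q-value. Intra-chromosomal contacts joining a bin to itself are rejected.
#'
#' @param path BEDPE file path.
#' @return `data.frame` with columns `chrom1, start1, end1, chrom2, start2,
#'   end2, q_value` (`q_value` `NA` when absent).
#' @export
read_contacts <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 6L) stop("BEDPE file needs >= 6 columns")
  num <- function(i) {
    v <- as.numeric(raw[[i]])
    if (any(is.na(v))) stop("non-numeric BEDPE coordinate in column ", i)
    v
  }
  s1 <- num(2L); e1 <- num(3L); s2 <- num(5L); e2 <- num(6L)
  if (any(s1 >= e1) || any(s2 >= e2)) stop("invalid BEDPE anchor (start >= end)")
  q <- if (ncol(raw) >= 7L) as.numeric(raw[[7L]]) else NA_real_
  same <- raw[[1L]] == raw[[4L]] & s1 == s2 & e1 == e2
  if (any(same)) {
    stop("intra-chromosomal contact joins a bin to itself at line ",
         which(same)[1L])
  }
  data.frame(chrom1 = raw[[1L]], start1 = s1 + 1L, end1 = e1,
             chrom2 = raw[[4L]], start2 = s2 + 1L, end2 = e2,
             q_value = q, stringsAsFactors = FALSE)
}

#' Write contacts as BEDPE
#'
#' @param contacts data.frame as returned by [read_contacts()].
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  df <- data.frame(contacts$chrom1, contacts$start1 - 1L, contacts$end1,
                   contacts$chrom2, contacts$start2 - 1L, contacts$end2)
  if (!all(is.na(contacts$q_value))) df$q <- contacts$q_value
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a homogeneous result table as TSV
#'
#' Accepts a data.frame, or a list of identically named record lists (a
#' differing set of field names is a contract error). Floats are printed at 6
#' significant digits; the header and column order are deterministic.
#'
#' @param records result records.
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- as.data.frame(records)
  } else if (is.list(records)) {
    if (length(records) == 0L) stop("cannot infer columns from an empty list; pass a data.frame")
    nm <- lapply(records, names)
    if (!all(vapply(nm, identical, TRUE, y = nm[[1L]]))) {
      stop("mixed record types: field names differ between records")
    }
    df <- rbindlist(lapply(records, as.data.table))
  } else {
    stop("records must be a data.frame or a list of records")
  }
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6L)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  as.data.frame(fread(path, sep = "\t", header = TRUE))
}
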