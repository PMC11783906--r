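# Intact-TE counting in gene-centered windows and the CNV vs non-CNV group
# comparison.

#' Gene-centered flanking windows
#'
#' Window = `[gene_start - flank, gene_end + flank)`, strand-agnostic,
#' clamped to `[0, chrom_length)`.
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flank Flank size in bp on each side (default 2 kb).
#' @param chrom_lengths Named numeric vector chrom -> length in bp.
#' @return Data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_flank_windows <- function(genes, flank = 2000, chrom_lengths) {
  stopifnot(flank >= 0)
  unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(unknown) > 0L) {
    stop("gene on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, genes$start - flank),
             end = pmin(unname(chrom_lengths[genes$chrom]), genes$end + flank),
             stringsAsFactors = FALSE)
}

#' Count intact TEs overlapping each gene window
#'
#' A TE counts for a gene iff it is flagged intact and its interval
#' overlaps the gene's window by at least `min_overlap` bp (intervals are
#' 0-based half-open, so a TE starting exactly at the window end does not
#' overlap). A TE overlapping two gene windows counts once per gene.
#'
#' @param windows Data.frame from [gene_flank_windows()].
#' @param te_records Data.frame with `chrom`, `start`, `end`, `te_class`,
#'   `intact` (logical or 0/1).
#' @param min_overlap Minimum overlap in bp.
#' @return List: `per_gene` (data.frame `gene_id`, `n_te`) and `per_class`
#'   (data.frame `te_class`, `n` tally over all counted gene-TE overlaps).
#' @export
count_intact_te_per_gene <- function(windows, te_records, min_overlap = 1) {
  te <- te_records[as.logical(te_records$intact), , drop = FALSE]
  n_te <- setNames(integer(nrow(windows)), windows$gene_id)
  class_rows <- list()
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    t_c <- te[te$chrom == chrom, , drop = FALSE]
    if (nrow(t_c) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(w$start + 1L, w$end),
      IRanges::IRanges(t_c$start + 1L, t_c$end),
      minoverlap = min_overlap)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    n <- table(factor(qh, levels = seq_len(nrow(w))))
    n_te[w$gene_id] <- n_te[w$gene_id] + as.integer(n)
    class_rows[[chrom]] <- t_c$te_class[S4Vectors::subjectHits(ov)]
  }
  classes <- unlist(class_rows, use.names = FALSE)
  per_class <- if (length(classes) > 0L) {
    tab <- table(classes)
    data.frame(te_class = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(te_class = character(), n = integer(), stringsAsFactors = FALSE)
  }
  list(per_gene = data.frame(gene_id = windows$gene_id, n_te = unname(n_te),
                             stringsAsFactors = FALSE),
       per_class = per_class)
}

#' Welch t-test comparison of per-gene TE counts between groups
#'
#' Two-sided Welch (unequal-variance) t-test of per-gene intact-TE counts
#' between genes of CNV pangenes and genes of single-copy core pangenes.
#'
#' @param counts_cnv_group,counts_noncnv_group Numeric vectors of per-gene
#'   counts (each of length >= 2).
#' @return Data.frame with group means, sizes, `t` and two-sided `p`.
#' @export
compare_groups_ttest <- function(counts_cnv_group, counts_noncnv_group) {
  if (length(counts_cnv_group) < 2L || length(counts_noncnv_group) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(counts_cnv_group) == 0 && stats::var(counts_noncnv_group) == 0) {
    # degenerate: constant groups; t-test is undefined, report directly
    equal <- mean(counts_cnv_group) == mean(counts_noncnv_group)
    return(data.frame(mean_cnv = mean(counts_cnv_group),
                      mean_noncnv = mean(counts_noncnv_group),
                      n_cnv = length(counts_cnv_group),
                      n_noncnv = length(counts_noncnv_group),
                      t = if (equal) 0 else NA_real_,
                      p_value = if (equal) 1 else NA_real_,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(counts_cnv_group, counts_noncnv_group,
                      alternative = "two.sided", var.equal = FALSE)
  data.frame(mean_cnv = unname(tt$estimate[1]),
             mean_noncnv = unname(tt$estimate[2]),
             n_cnv = length(counts_cnv_group),
             n_noncnv = length(counts_noncnv_group),
             t = unname(tt$statistic), p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Read TE records from BED6 (or GFF3)
#'
#' The BED name field carries the TE class and intactness as
#' `<class>;intact=<0|1>`; for GFF3, attributes `te_class` and `intact`
#' are used.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `te_class`, `intact` (logical).
#' @export
read_te_records <- function(path) {
  if (grepl("\\.gff3?$", path)) {
    gr <- rtracklayer::import(path, format = "gff3")
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      te_class = if (!is.null(gr$te_class)) gr$te_class else "other",
                      intact = if (!is.null(gr$intact)) gr$intact == "1" else TRUE,
                      stringsAsFactors = FALSE))
  }
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#")
  name <- as.character(bed[[4]])
  te_class <- sub(";.*$", "", name)
  intact <- grepl("intact=1", name, fixed = TRUE)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), te_class = te_class, intact = intact,
             stringsAsFactors = FALSE)
}

#' Write TE records as BED6
#'
#' @param te Data.frame as returned by [read_te_records()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_te_bed <- function(te, path) {
  bed <- data.frame(te$chrom, te$start, te$end,
                    sprintf("%s;intact=%d", te$te_class, as.integer(te$intact)),
                    0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
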