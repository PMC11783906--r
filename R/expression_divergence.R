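# Pantranscriptome expression summaries per pangene, expression-profile
# clustering, and phylogeny-vs-expression tanglegram metrics.

#' Per-pangene expression summary across genomes
#'
#' For each pangene and tissue, computes the mean and SD of TPM across the
#' genomes containing the pangene (presence-aware averaging: genomes
#' lacking it are excluded, and multiple copies within a genome are summed
#' to a per-genome pangene value). Two transforms are reported: normalized
#' mean `log2(mean TPM + 1)` and relative SD `log2(SD / mean TPM + 1)`,
#' the latter defined as 0 when the mean is 0.
#'
#' @param tpm_tables Named list (genome id -> data.frame) of TPM tables:
#'   first column `gene_id`, remaining columns tissues (identical across
#'   genomes), values >= 0.
#' @param membership Named character vector gene_id -> pangene id.
#' @return Data.frame of class `expression_summary`: `pangene`, `tissue`,
#'   `n_genomes`, `mean_tpm`, `sd_tpm`, `norm_mean`, `rel_sd`.
#' @export
pangene_expression_summary <- function(tpm_tables, membership) {
  stopifnot(length(tpm_tables) > 0L)
  tissues <- setdiff(names(tpm_tables[[1]]), "gene_id")
  for (g in names(tpm_tables)) {
    if (!identical(setdiff(names(tpm_tables[[g]]), "gene_id"), tissues)) {
      stop("tissue columns differ across genomes", call. = FALSE)
    }
    if (any(as.matrix(tpm_tables[[g]][tissues]) < 0)) {
      stop("negative TPM in genome ", g, call. = FALSE)
    }
  }
  # per (genome, pangene) value = sum of member TPMs in that genome
  per_genome <- list()
  for (g in names(tpm_tables)) {
    tab <- tpm_tables[[g]]
    pg <- unname(membership[tab$gene_id])
    keep <- !is.na(pg)
    if (!any(keep)) next
    agg <- rowsum(as.matrix(tab[keep, tissues, drop = FALSE]), group = pg[keep])
    per_genome[[g]] <- agg
  }
  pangenes <- sort(unique(unlist(lapply(per_genome, rownames))))
  if (length(pangenes) == 0L) stop("no pangene has expression data", call. = FALSE)
  rows <- list()
  for (p in pangenes) {
    vals <- do.call(rbind, lapply(per_genome, function(m) {
      if (p %in% rownames(m)) m[p, , drop = FALSE] else NULL
    }))
    mu <- colMeans(vals)
    sdv <- apply(vals, 2L, function(x) if (length(x) < 2L) 0 else stats::sd(x))
    rel <- ifelse(mu == 0, 0, log2(sdv / mu + 1))
    rows[[p]] <- data.frame(pangene = p, tissue = tissues,
                            n_genomes = nrow(vals), mean_tpm = unname(mu),
                            sd_tpm = unname(sdv),
                            norm_mean = unname(log2(mu + 1)),
                            rel_sd = unname(rel),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_summary", class(out))
  out
}

# pangene x tissue matrix of normalized means from a summary table
.summary_profile_matrix <- function(summary, value = "norm_mean") {
  tissues <- unique(summary$tissue)
  pangenes <- unique(summary$pangene)
  m <- matrix(NA_real_, length(pangenes), length(tissues),
              dimnames = list(pangenes, tissues))
  m[cbind(match(summary$pangene, pangenes), match(summary$tissue, tissues))] <-
    summary[[value]]
  m
}

#' Hierarchical clustering of pangene expression profiles
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of
#' pangenes by their normalized mean tissue profiles, cut into `k`
#' clusters. Rows are ordered by pangene id before clustering so the
#' result does not depend on input order.
#'
#' @param summary An `expression_summary` data.frame.
#' @param k Number of clusters to cut (default 3, the number of major
#'   transcriptional clusters distinguished downstream).
#' @return List of class `expression_clustering`: `hclust` (the
#'   dendrogram), `clusters` (named integer vector pangene -> cluster),
#'   `leaf_order` (pangenes in dendrogram order), `profiles` (the matrix).
#' @export
cluster_expression_profiles <- function(summary, k = 3) {
  m <- .summary_profile_matrix(summary)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < k) stop("k exceeds the number of profiled pangenes", call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  cl <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, clusters = cl,
                 leaf_order = rownames(m)[hc$order], profiles = m),
            class = "expression_clustering")
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("expression_clustering: %d pangenes in %d clusters\n",
              length(x$clusters), length(unique(x$clusters))))
  invisible(x)
}

# exact inversion count between two orderings of the same leaves
.count_inversions <- function(rank_right) {
  n <- length(rank_right)
  if (n < 2L) return(0L)
  inv <- 0L
  for (i in seq_len(n - 1L)) {
    inv <- inv + sum(rank_right[(i + 1L):n] < rank_right[i])
  }
  as.integer(inv)
}

#' Tanglegram metrics between a phylogeny and an expression dendrogram
#'
#' Compares the leaf order of the gene phylogeny with the leaf order of
#' the expression clustering over their shared leaves. The crossing count
#' is the exact number of leaf-pair inversions between the two orders;
#' normalized entanglement divides by `choose(n, 2)`. When subfamily
#' labels are supplied, each subfamily's transcriptional divergence is
#' scored as the variance of its leaves' rank displacement (right rank
#' minus left rank), ranking subfamilies by how much their members scatter
#' across expression clusters.
#'
#' @param phylogeny An `ape::phylo` tree, or a character vector giving a
#'   leaf order.
#' @param dendrogram An `expression_clustering`, an `hclust`, or a
#'   character vector giving a leaf order.
#' @param subfamilies Optional named character vector leaf -> subfamily.
#' @return List of class `tanglegram_metrics`: `n_shared`, `crossings`,
#'   `entanglement`, and (optionally) `subfamily_divergence` (data.frame
#'   ranked by decreasing divergence).
#' @export
compare_tree_orders <- function(phylogeny, dendrogram, subfamilies = NULL) {
  left <- .leaf_order(phylogeny)
  right <- .leaf_order(dendrogram)
  shared <- intersect(left, right)
  if (length(shared) < 2L) stop("fewer than 2 shared leaves", call. = FALSE)
  left <- left[left %in% shared]
  right <- right[right %in% shared]
  rank_right <- match(left, right)
  crossings <- .count_inversions(rank_right)
  n <- length(shared)
  out <- list(n_shared = n, crossings = crossings,
              entanglement = crossings / choose(n, 2))
  if (!is.null(subfamilies)) {
    disp <- match(left, right) - seq_along(left)
    sf <- unname(subfamilies[left])
    keep <- !is.na(sf)
    agg <- tapply(disp[keep], sf[keep],
                  function(x) if (length(x) < 2L) 0 else stats::var(x))
    sub_df <- data.frame(subfamily = names(agg),
                         n_leaves = as.integer(table(sf[keep])[names(agg)]),
                         divergence = as.numeric(agg), stringsAsFactors = FALSE)
    sub_df <- sub_df[order(-sub_df$divergence, sub_df$subfamily), , drop = FALSE]
    rownames(sub_df) <- NULL
    out$subfamily_divergence <- sub_df
  }
  structure(out, class = "tanglegram_metrics")
}

.leaf_order <- function(x) {
  if (inherits(x, "phylo")) return(x$tip.label[x$edge[x$edge[, 2] <= ape::Ntip(x), 2]])
  if (inherits(x, "expression_clustering")) return(x$leaf_order)
  if (inherits(x, "hclust")) return(x$labels[x$order])
  if (is.character(x)) return(x)
  stop("cannot extract a leaf order from class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' @export
print.tanglegram_metrics <- function(x, ...) {
  cat(sprintf("tanglegram: %d shared leaves, %d crossings (entanglement %.3f)\n",
              x$n_shared, x$crossings, x$entanglement))
  invisible(x)
}

#' Correlation between expression level and expression variability
#'
#' Spearman correlation across pangene-by-tissue cells between the
#' normalized mean and the relative SD; a negative rho reproduces the
#' pattern that highly expressed genes vary less across genomes.
#'
#' @param summary An `expression_summary` data.frame (>= 3 cells).
#' @return List `rho`, `p_value`, `n`; constant input yields `rho = NA`
#'   flagged by `constant = TRUE`.
#' @export
correlate_mean_vs_relsd <- function(summary) {
  x <- summary$norm_mean
  y <- summary$rel_sd
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 pangene-tissue points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x), constant = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       constant = FALSE)
}
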