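# Domain alignment, neighbor-joining phylogeny and reference-anchored
# subfamily assignment.

#' Align domain amino-acid sequences
#'
#' Produces a multiple sequence alignment of the domain sequences of
#' pangene representatives (plus labeled references) by running MAFFT,
#' which is deterministic for fixed input. Ungapping any output row
#' recovers its input sequence; output preserves input order.
#'
#' @param sequences Named character vector (or `AAStringSet`) of domain
#'   sequences, each at least `min_len` residues; at least 2 sequences.
#' @param min_len Minimum input sequence length.
#' @return Named character vector of aligned rows (class
#'   `domain_alignment`).
#' @export
align_domains <- function(sequences, min_len = 20) {
  seqs <- if (is.character(sequences)) sequences else as.character(sequences)
  if (length(seqs) < 2L) stop("need >= 2 sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  short <- names(seqs)[nchar(seqs) < min_len]
  if (length(short) > 0L) {
    stop("sequence(s) below minimum length ", min_len, ": ",
         paste(head(short, 5), collapse = ", "), call. = FALSE)
  }
  if (!nzchar(Sys.which("mafft"))) stop("mafft not found on PATH", call. = FALSE)
  td <- tempfile("panfam_aln")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fin <- file.path(td, "in.fa"); fout <- file.path(td, "out.fa")
  # safe ids: mafft keeps order; map names through an index
  ids <- sprintf("s%06d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(seqs, ids)), fin)
  st <- system2("mafft", c("--auto", "--quiet", "--amino", fin),
                stdout = fout, stderr = FALSE)
  if (st != 0L) stop("mafft failed", call. = FALSE)
  aln <- Biostrings::readAAStringSet(fout)
  out <- as.character(aln)[ids]
  names(out) <- names(seqs)
  structure(toupper(out), class = "domain_alignment")
}

# pairwise p-distances (mismatches / compared columns) over columns where
# both rows are ungapped; error on pairs with no comparable columns
.pdist_matrix <- function(aln, max_p = 0.95) {
  chars <- do.call(rbind, strsplit(unname(unclass(aln)), ""))
  rownames(chars) <- names(aln)
  gap <- chars == "-" | chars == "." | chars == "X"
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) {
      stop(sprintf("no comparable columns between %s and %s",
                   rownames(chars)[i], rownames(chars)[j]), call. = FALSE)
    }
    p <- mean(chars[i, ok] != chars[j, ok])
    d[i, j] <- d[j, i] <- min(p, max_p)
  }
  d
}

#' Neighbor-joining tree from a domain alignment
#'
#' Computes Poisson-corrected distances `d = -ln(1 - p)` from pairwise
#' p-distances (pairwise deletion of gap columns) and builds a
#' neighbor-joining tree. Slightly negative NJ branch lengths are clamped
#' to zero.
#'
#' @param aln A `domain_alignment` (or named character vector of aligned
#'   rows) with at least 3 sequences, or a precomputed distance matrix.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(aln) {
  d <- if (is.matrix(aln)) aln else {
    if (length(aln) < 3L) stop("need >= 3 sequences", call. = FALSE)
    -log(1 - .pdist_matrix(aln))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Assign subfamilies by nearest labeled reference
#'
#' Each unlabeled leaf takes the subfamily of its nearest reference leaf
#' by patristic (tree-path) distance; ties go to the label of the
#' lexicographically smallest reference id. Leaves farther than
#' `max_distance` from every reference are labeled `unplaced_label`.
#'
#' @param tree An `ape::phylo` over query and reference leaves.
#' @param reference_labels Named character vector reference leaf id ->
#'   subfamily label.
#' @param max_distance Distance ceiling beyond which a query is unplaced.
#' @param unplaced_label Label used beyond the ceiling.
#' @return Data.frame `pangene`, `subfamily`, `nearest_ref`, `distance`.
#' @export
assign_subfamilies <- function(tree, reference_labels, max_distance = Inf,
                               unplaced_label = "SF_like") {
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (length(refs) == 0L) stop("no reference leaves in tree", call. = FALSE)
  queries <- setdiff(tree$tip.label, names(reference_labels))
  pd <- ape::cophenetic.phylo(tree)
  refs <- refs[order(refs)]  # tie rule: smallest reference id wins
  rows <- lapply(queries, function(q) {
    dists <- pd[q, refs]
    best <- which(dists == min(dists))[1]
    sf <- if (dists[best] <= max_distance) unname(reference_labels[refs[best]])
          else unplaced_label
    data.frame(pangene = q, subfamily = sf, nearest_ref = refs[best],
               distance = unname(dists[best]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dispensable-gene enrichment per subfamily
#'
#' For each subfamily, tests whether dispensable (non-core) pangenes are
#' over-represented with a hypergeometric upper-tail test, adjusting
#' across subfamilies by Benjamini-Hochberg.
#'
#' @param assignments Data.frame with `pangene`, `subfamily`.
#' @param categories Named character vector pangene -> category.
#' @return Data.frame `subfamily`, `n_pangenes`, `n_dispensable`,
#'   `p_value`, `q_value`, sorted by q then subfamily.
#' @export
dispensable_enrichment <- function(assignments, categories) {
  if (length(unique(assignments$subfamily)) < 2L) {
    stop("need >= 2 subfamilies", call. = FALSE)
  }
  disp <- categories[assignments$pangene] != "core"
  N <- nrow(assignments)
  K <- sum(disp)
  rows <- lapply(split(seq_len(N), assignments$subfamily), function(idx) {
    n <- length(idx)
    k <- sum(disp[idx])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(subfamily = assignments$subfamily[idx[1]], n_pangenes = n,
               n_dispensable = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}
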