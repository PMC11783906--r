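# Duplication-mechanism classification from homology hits, gene ranks and
# collinear blocks, following the five-rule scheme used by whole-genome
# duplicate classifiers: singleton -> dispersed -> proximal -> tandem ->
# WGD/segmental, with later rules overriding earlier ones.

#' Gene rank index per chromosome
#'
#' Ranks are 0-based ordinal positions of genes sorted by start coordinate
#' within each chromosome, recomputed from coordinates (never trusted from
#' input).
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start`.
#' @return Data.frame `gene_id`, `chrom`, `rank`.
#' @export
gene_rank_index <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids", call. = FALSE)
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               rank = seq_len(nrow(g)) - 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All-vs-all protein homology search with top-k retention
#'
#' Finds, for every query protein, its `k` best subjects at the E-value
#' threshold (self-hits excluded; ties broken by higher identity, then by
#' subject id). Engine `"blast"` shells out to NCBI `blastp`/`makeblastdb`
#' (the practical choice for whole-proteome input); engine `"native"`
#' computes exact Smith-Waterman scores with Biostrings and a
#' Karlin-Altschul E-value, suitable for small inputs and cross-checks.
#' `"auto"` picks blast when available.
#'
#' @param proteins Named character vector of protein sequences.
#' @param k Hits retained per query.
#' @param e_threshold E-value threshold.
#' @param engine `"auto"`, `"blast"` or `"native"`.
#' @return Data.frame `query`, `subject`, `bit_score`, `identity` (fraction
#'   of aligned columns), sorted by query then decreasing score.
#' @export
all_vs_all_top_hits <- function(proteins, k = 5, e_threshold = 1e-5,
                                engine = c("auto", "blast", "native")) {
  engine <- match.arg(engine)
  if (length(proteins) == 0L) stop("need at least one protein", call. = FALSE)
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("blastp")) && nzchar(Sys.which("makeblastdb")))
      "blast" else "native"
  }
  hits <- if (engine == "blast") .blast_all_vs_all(proteins, e_threshold)
          else .native_all_vs_all(proteins, e_threshold)
  .top_k_hits(hits, k)
}

.top_k_hits <- function(hits, k) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  hits <- hits[order(hits$query, -hits$bit_score, -hits$identity, hits$subject), ,
               drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query),
                        function(i) head(i, k)), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.blast_all_vs_all <- function(proteins, e_threshold) {
  td <- tempfile("panfam_blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fa <- file.path(td, "prot.fa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), fa)
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  st <- system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db,
                                 "-logfile", file.path(td, "mkdb.log")))
  if (st != 0L) stop("makeblastdb failed", call. = FALSE)
  st <- system2("blastp", c("-query", fa, "-db", db, "-outfmt", "6",
                            "-evalue", format(e_threshold, scientific = TRUE),
                            "-num_threads", "1", "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastp failed", call. = FALSE)
  h <- read_blast_outfmt6(out)
  # collapse multiple HSPs per pair to the best-scoring one
  h <- h[order(h$query, h$subject, -h$bit_score), , drop = FALSE]
  h <- h[!duplicated(h[, c("query", "subject")]), , drop = FALSE]
  h[, c("query", "subject", "bit_score", "identity")]
}

# BLOSUM62 gapped (11/1-like) Karlin-Altschul parameters for the native
# engine's E-values; adequate for the near-identical fixtures it serves.
.native_all_vs_all <- function(proteins, e_threshold, lambda = 0.267, kappa = 0.041) {
  ids <- names(proteins)
  n <- length(ids)
  total_len <- sum(nchar(proteins))
  rows <- list()
  set_all <- Biostrings::AAStringSet(proteins)
  for (i in seq_len(n)) {
    al <- Biostrings::pairwiseAlignment(
      set_all, Biostrings::AAString(proteins[[i]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "local")
    sc <- Biostrings::score(al)
    bit <- (lambda * sc - log(kappa)) / log(2)
    ev <- kappa * nchar(proteins[[i]]) * total_len * exp(-lambda * sc)
    nm <- Biostrings::nmatch(al); nmm <- Biostrings::nmismatch(al)
    pass <- which(ev <= e_threshold & ids != ids[i])
    if (length(pass) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = ids[i], subject = ids[pass], bit_score = bit[pass],
        identity = nm[pass] / pmax(1L, nm[pass] + nmm[pass]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      bit_score = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read tabular hits in BLAST outfmt-6 dialect
#'
#' @param path Path to a 12-column tab-separated hit table (qseqid sseqid
#'   pident length mismatch gapopen qstart qend sstart send evalue
#'   bitscore).
#' @return Data.frame `query`, `subject`, `identity` (fraction), `aln_len`,
#'   `e_value`, `bit_score`.
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("query", "subject", "pident", "aln_len", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "e_value", "bit_score")
  if (file.size(path) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$identity <- numeric(0)
    return(out[, c("query", "subject", "identity", "aln_len", "e_value", "bit_score")])
  }
  h <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = cols, quote = "", comment.char = "")
  h$identity <- h$pident / 100
  h[, c("query", "subject", "identity", "aln_len", "e_value", "bit_score")]
}

#' Detect collinear blocks by dynamic-programming chaining
#'
#' Anchors are homology hit pairs; a block is a maximal chain of anchors
#' whose ranks are strictly monotone on both chromosomes (same or reversed
#' orientation) with a per-step rank gap of at most `max_rank_gap` on each
#' side, and at least `min_anchors` anchors. Chains are extracted greedily
#' (best chain first, anchors removed, repeat).
#'
#' @param ranks Data.frame from [gene_rank_index()].
#' @param hits Data.frame with `query`, `subject` (gene ids).
#' @param min_anchors Minimum anchors per block.
#' @param max_rank_gap Maximum per-step rank gap on either chromosome.
#' @return Data.frame of anchors: `block_id`, `gene_a`, `gene_b`,
#'   `chrom_a`, `chrom_b`, `rank_a`, `rank_b`, `orientation`.
#' @export
detect_collinear_blocks <- function(ranks, hits, min_anchors = 5, max_rank_gap = 25) {
  empty <- data.frame(block_id = character(), gene_a = character(),
                      gene_b = character(), chrom_a = character(),
                      chrom_b = character(), rank_a = integer(),
                      rank_b = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  rk <- setNames(ranks$rank, ranks$gene_id)
  ch <- setNames(ranks$chrom, ranks$gene_id)
  # canonical unordered anchor pairs
  a <- ifelse(hits$query < hits$subject, hits$query, hits$subject)
  b <- ifelse(hits$query < hits$subject, hits$subject, hits$query)
  pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  pairs <- pairs[!is.na(rk[pairs$a]) & !is.na(rk[pairs$b]), , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  # orient each anchor so gene_a is on the lexicographically smaller chrom
  # (for same-chrom anchors: smaller rank first)
  swap <- ch[pairs$a] > ch[pairs$b] |
    (ch[pairs$a] == ch[pairs$b] & rk[pairs$a] > rk[pairs$b])
  ga <- ifelse(swap, pairs$b, pairs$a)
  gb <- ifelse(swap, pairs$a, pairs$b)
  anch <- data.frame(gene_a = ga, gene_b = gb,
                     chrom_a = unname(ch[ga]), chrom_b = unname(ch[gb]),
                     rank_a = unname(rk[ga]), rank_b = unname(rk[gb]),
                     stringsAsFactors = FALSE)
  blocks <- list()
  bid <- 0L
  for (key in unique(paste(anch$chrom_a, anch$chrom_b))) {
    sub <- anch[paste(anch$chrom_a, anch$chrom_b) == key, , drop = FALSE]
    repeat {
      if (nrow(sub) < min_anchors) break
      best <- NULL
      for (orient in c("same", "reversed")) {
        chain <- .best_chain(sub$rank_a, sub$rank_b, orient, max_rank_gap)
        if (length(chain) >= min_anchors &&
            (is.null(best) || length(chain) > length(best$chain))) {
          best <- list(chain = chain, orient = orient)
        }
      }
      if (is.null(best)) break
      bid <- bid + 1L
      blk <- sub[best$chain, , drop = FALSE]
      blk$block_id <- sprintf("block%03d", bid)
      blk$orientation <- best$orient
      blocks[[bid]] <- blk
      sub <- sub[-best$chain, , drop = FALSE]
    }
  }
  if (length(blocks) == 0L) return(empty)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[, c("block_id", "gene_a", "gene_b", "chrom_a", "chrom_b",
          "rank_a", "rank_b", "orientation")]
}

# Longest chain (indices) with rank_a strictly increasing and rank_b
# strictly increasing ("same") or strictly decreasing ("reversed"), per-step
# gaps <= max_gap on both sides. O(n^2) DP; anchors are few.
.best_chain <- function(ra, rb, orient, max_gap) {
  n <- length(ra)
  ord <- order(ra, if (orient == "same") rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      gap_a <- ra[j] - ra[i]
      gap_b <- if (orient == "same") rb[j] - rb[i] else rb[i] - rb[j]
      if (gap_a >= 1L && gap_a <= max_gap && gap_b >= 1L && gap_b <= max_gap &&
          len[i] + 1L > len[j]) {
        len[j] <- len[i] + 1L
        prev[j] <- i
      }
    }
  }
  j <- which.max(len)
  chain <- integer(0)
  while (!is.na(j)) { chain <- c(j, chain); j <- prev[j] }
  ord[chain]
}

#' Classify duplication mechanism for every gene
#'
#' Applies the five rules in order, later rules overriding earlier ones:
#' (1) every gene starts as a singleton; (2) genes with any homology hit
#' become dispersed; (3) genes with a same-chromosome hit at gene-rank
#' difference strictly between 1 and `proximal_rank_max` become proximal;
#' (4) genes with a same-chromosome hit at rank difference exactly 1 become
#' tandem; (5) genes that are anchors in a collinear block become
#' WGD/segmental. Rank differences are defined only within a chromosome;
#' cross-chromosome hits can yield only dispersed (or WGD/segmental via a
#' block).
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start` (ranks are
#'   recomputed from it).
#' @param hits Data.frame with `query`, `subject`.
#' @param blocks Data.frame from [detect_collinear_blocks()] (may be empty
#'   or `NULL`).
#' @param proximal_rank_max Exclusive upper bound on the proximal rank
#'   difference (the classifier's "< 20" rule).
#' @return Named character vector gene_id -> label in
#'   {singleton, dispersed, proximal, tandem, wgd_segmental}.
#' @export
classify_duplication_types <- function(genes, hits, blocks = NULL,
                                       proximal_rank_max = 20) {
  ranks <- gene_rank_index(genes)
  rk <- setNames(ranks$rank, ranks$gene_id)
  ch <- setNames(ranks$chrom, ranks$gene_id)
  labels <- setNames(rep("singleton", nrow(genes)), genes$gene_id)

  if (nrow(hits) > 0L) {
    bad <- setdiff(unique(c(hits$query, hits$subject)), genes$gene_id)
    if (length(bad) > 0L) {
      stop("hit references unknown gene(s): ", paste(head(bad, 3), collapse = ", "),
           call. = FALSE)
    }
    # rule 2: any hit -> dispersed (both sides of each hit)
    hit_genes <- unique(c(hits$query, hits$subject))
    labels[hit_genes] <- "dispersed"
    # rank differences for same-chromosome hits
    same <- ch[hits$query] == ch[hits$subject]
    rd <- abs(rk[hits$query] - rk[hits$subject])
    # rule 3: proximal (1 < rank diff < proximal_rank_max)
    prox <- same & rd > 1L & rd < proximal_rank_max
    labels[unique(c(hits$query[prox], hits$subject[prox]))] <- "proximal"
    # rule 4: tandem (rank diff = 1)
    tand <- same & rd == 1L
    labels[unique(c(hits$query[tand], hits$subject[tand]))] <- "tandem"
  }
  # rule 5: collinear block anchors -> WGD/segmental
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    anchor_genes <- unique(c(blocks$gene_a, blocks$gene_b))
    anchor_genes <- intersect(anchor_genes, names(labels))
    labels[anchor_genes] <- "wgd_segmental"
  }
  labels
}
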