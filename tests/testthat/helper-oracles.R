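# Independent brute-force oracles. These deliberately re-derive results
# from first principles with different code paths than the package.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_protein_frac <- function(prot, frac) {
  aa <- strsplit(prot, "")[[1]]
  k <- round(frac * length(aa))
  if (k > 0) {
    pos <- sample(seq_along(aa), k)
    for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1)
  }
  paste(aa, collapse = "")
}

# --- NG86 oracle: literal per-codon enumeration ------------------------------

GC_TAB <- Biostrings::GENETIC_CODE

oracle_syn_sites_codon <- function(codon) {
  nts <- c("A", "C", "G", "T")
  total_syn <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_valid <- 0
    for (b in nts) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GC_TAB[[mut]] == "*") next
      n_valid <- n_valid + 1
      if (GC_TAB[[mut]] == GC_TAB[[codon]]) n_syn <- n_syn + 1
    }
    if (n_valid > 0) total_syn <- total_syn + n_syn / n_valid
  }
  total_syn
}

oracle_paths_codon_pair <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diff_pos) == 0) return(c(0, 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  score_path <- function(order_pos, allow_stops) {
    cur <- c1; nd <- 0; sd <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC_TAB[[nxt]] == "*" && !allow_stops) return(NULL)
      if (GC_TAB[[nxt]] == GC_TAB[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd)
  }
  paths <- perm_list(diff_pos)
  scored <- list()
  for (p in paths) {
    r <- score_path(p, allow_stops = FALSE)
    if (!is.null(r)) scored[[length(scored) + 1]] <- r
  }
  if (length(scored) == 0) {
    for (p in paths) scored[[length(scored) + 1]] <- score_path(p, TRUE)
  }
  colMeans(do.call(rbind, scored))
}

oracle_ng86 <- function(cds1, cds2) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  co1 <- split3(cds1); co2 <- split3(cds2)
  ok <- rep(TRUE, length(co1))
  for (i in seq_along(co1)) {
    for (cd in c(co1[i], co2[i])) {
      if (!cd %in% names(GC_TAB) || GC_TAB[[cd]] == "*" ||
          grepl("[^ACGT]", cd)) ok[i] <- FALSE
    }
  }
  co1 <- co1[ok]; co2 <- co2[ok]
  S <- (sum(vapply(co1, oracle_syn_sites_codon, numeric(1))) +
        sum(vapply(co2, oracle_syn_sites_codon, numeric(1)))) / 2
  N <- 3 * length(co1) - S
  nd <- 0; sd <- 0
  for (i in seq_along(co1)) {
    r <- oracle_paths_codon_pair(co1[i], co2[i])
    nd <- nd + r[1]; sd <- sd + r[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else if (p <= 0) 0 else
    -3 / 4 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = nd, Sd = sd, ka = jc(nd / N), ks = jc(sd / S))
}

# --- greedy clustering oracle ------------------------------------------------

oracle_greedy_cluster <- function(proteins, id_thr = 0.95, cov_thr = 0.90) {
  ids <- names(proteins)[order(-nchar(proteins), names(proteins))]
  # precompute all-pairs identity/coverage
  pairmat <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    pairmat[[paste(ids[i], ids[j])]] <-
      align_pair_identity(proteins[[ids[i]]], proteins[[ids[j]]])
  }
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]][1]
      v <- pairmat[[paste(id, rep_id)]]
      if (v["identity"] >= id_thr && v["coverage"] >= cov_thr) {
        clusters[[k]] <- c(clusters[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- id
  }
  clusters
}

# --- interval overlap oracle -------------------------------------------------

oracle_te_counts <- function(windows, te) {
  counts <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(te))) {
      if (!te$intact[j]) next
      if (windows$chrom[i] != te$chrom[j]) next
      ov <- min(windows$end[i], te$end[j]) - max(windows$start[i], te$start[j])
      if (ov >= 1) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# --- inversion-count oracle --------------------------------------------------

oracle_crossings <- function(left, right) {
  pos <- match(left, right)
  n <- length(pos)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pos[i] > pos[j]) cnt <- cnt + 1L
  }
  cnt
}

# --- literal duplication-rule oracle -----------------------------------------

oracle_dup_labels <- function(genes, hits, block_anchor_genes,
                              proximal_max = 20) {
  ranks <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start, g$gene_id), ]
    for (i in seq_len(nrow(g))) ranks[[g$gene_id[i]]] <- i - 1L
  }
  chrom_of <- setNames(genes$chrom, genes$gene_id)
  lab <- setNames(rep("singleton", nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(hits))) {
    lab[hits$query[i]] <- "dispersed"; lab[hits$subject[i]] <- "dispersed"
  }
  for (i in seq_len(nrow(hits))) {
    q <- hits$query[i]; s <- hits$subject[i]
    if (chrom_of[q] == chrom_of[s]) {
      d <- abs(ranks[[q]] - ranks[[s]])
      if (d > 1 && d < proximal_max) { lab[q] <- "proximal"; lab[s] <- "proximal" }
    }
  }
  for (i in seq_len(nrow(hits))) {
    q <- hits$query[i]; s <- hits$subject[i]
    if (chrom_of[q] == chrom_of[s] && abs(ranks[[q]] - ranks[[s]]) == 1) {
      lab[q] <- "tandem"; lab[s] <- "tandem"
    }
  }
  lab[names(lab) %in% block_anchor_genes] <- "wgd_segmental"
  lab
}

# small synthetic corpus shared by several integration tests
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genomes = 6, n_core = 8, n_softcore = 0, n_shell = 3,
                        n_cloud = 0, n_subfamilies = 4,
                        chromosome_length = 200000, seed = 404)
      cache <<- simulate_pangenome(cfg, dir = file.path(tempdir(), "panfam_tiny"))
    }
    cache
  }
})
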