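# Presence/absence (PAV) and copy-number (CNV) matrices, conservation
# categories and systematic pangene names.

#' Build PAV and CNV matrices from clustered members
#'
#' @param oggs An `ogg_set` from [greedy_cluster()] (or a named list of
#'   member-id vectors).
#' @param genomes Named character vector member id -> genome id.
#' @param genome_ids Character vector of all genome ids (column order).
#' @return A list of class `pav_cnv`: `cnv` (pangene x genome integer copy
#'   counts), `pav` (logical presence matrix, count >= 1), `n_genomes`.
#' @export
build_pav_cnv_matrices <- function(oggs, genomes, genome_ids) {
  clusters <- if (inherits(oggs, "ogg_set")) oggs$clusters else oggs
  unknown <- setdiff(unique(unlist(lapply(clusters, function(m) genomes[m]))),
                     genome_ids)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown) > 0L) {
    stop("member with unknown genome id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cnv <- matrix(0L, nrow = length(clusters), ncol = length(genome_ids),
                dimnames = list(names(clusters), genome_ids))
  for (ogg in names(clusters)) {
    tab <- table(genomes[clusters[[ogg]]])
    cnv[ogg, names(tab)] <- as.integer(tab)
  }
  structure(list(cnv = cnv, pav = cnv >= 1L, n_genomes = length(genome_ids)),
            class = "pav_cnv")
}

#' Conservation category from a presence count
#'
#' Category boundaries (for presence fraction f over `n_genomes` genomes):
#' core iff present in every genome; softcore iff `f >= 0.90` (but not
#' all); cloud iff `f <= 0.10`; shell otherwise (the open interval). For 20
#' genomes this gives core = 20, softcore = 18-19, shell = 3-17,
#' cloud = 1-2.
#'
#' @param presence_count Number of genomes containing the pangene (>= 1).
#' @param n_genomes Panel size.
#' @return Character scalar (vectorized over `presence_count`).
#' @export
classify_category <- function(presence_count, n_genomes) {
  if (any(presence_count < 1L) || any(presence_count > n_genomes)) {
    stop("presence_count must be in 1..n_genomes (a pangene cannot be absent everywhere)",
         call. = FALSE)
  }
  f <- presence_count / n_genomes
  ifelse(presence_count == n_genomes, "core",
         ifelse(f >= 0.90, "softcore",
                ifelse(f <= 0.10, "cloud", "shell")))
}

#' Systematic pangene names
#'
#' Within each category, pangenes are sorted by the genomic location of
#' their anchor (chromosome, then start) and numbered consecutively with a
#' zero-padded width of 3, the numbering continuing across categories in
#' the order core (CR), softcore (SC), shell (SH), cloud (CL) -- so with
#' 140 core pangenes the first softcore pangene is `<prefix>.SC141`.
#'
#' @param pangenes Data.frame with columns `ogg_id`, `category`,
#'   `anchor_chrom`, `anchor_start`.
#' @param prefix Family prefix, e.g. `"HvFAM"`.
#' @return Named character vector ogg_id -> systematic name.
#' @export
name_pangenes <- function(pangenes, prefix = "FAM") {
  need <- c("ogg_id", "category", "anchor_chrom", "anchor_start")
  if (!all(need %in% names(pangenes))) {
    stop("pangenes must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(pangenes$anchor_chrom)) || any(is.na(pangenes$anchor_start))) {
    stop("missing anchor position", call. = FALSE)
  }
  cat_order <- c(core = "CR", softcore = "SC", shell = "SH", cloud = "CL")
  out <- character(nrow(pangenes)); names(out) <- pangenes$ogg_id
  counter <- 0L
  for (cat in names(cat_order)) {
    sub <- pangenes[pangenes$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$anchor_chrom, sub$anchor_start, sub$ogg_id), , drop = FALSE]
    nums <- counter + seq_len(nrow(sub))
    out[sub$ogg_id] <- sprintf("%s.%s%03d", prefix, cat_order[[cat]], nums)
    counter <- counter + nrow(sub)
  }
  out
}

#' Anchor positions for pangene naming
#'
#' The anchor of a pangene is its representative member's position in a
#' user-designated reference genome; for pangenes absent from that genome,
#' the position of its first member (by chromosome, start) in the
#' lexicographically first genome containing it.
#'
#' @param oggs An `ogg_set`.
#' @param members Data.frame with `gene_id`, `genome`, `chrom`, `start`.
#' @param reference_genome Genome id used as the primary anchor.
#' @return Data.frame `ogg_id`, `anchor_chrom`, `anchor_start`.
#' @export
pangene_anchors <- function(oggs, members, reference_genome = NULL) {
  if (is.null(reference_genome)) reference_genome <- sort(unique(members$genome))[1]
  rows <- lapply(names(oggs$clusters), function(ogg) {
    mem <- members[members$gene_id %in% oggs$clusters[[ogg]], , drop = FALSE]
    rep_id <- oggs$representatives[[ogg]]
    in_ref <- mem[mem$genome == reference_genome, , drop = FALSE]
    if (rep_id %in% in_ref$gene_id) {
      r <- in_ref[in_ref$gene_id == rep_id, , drop = FALSE][1, ]
    } else if (nrow(in_ref) > 0L) {
      r <- in_ref[order(in_ref$chrom, in_ref$start), , drop = FALSE][1, ]
    } else {
      g <- sort(unique(mem$genome))[1]
      sub <- mem[mem$genome == g, , drop = FALSE]
      r <- sub[order(sub$chrom, sub$start), , drop = FALSE][1, ]
    }
    data.frame(ogg_id = ogg, anchor_chrom = r$chrom, anchor_start = r$start,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Category report tables
#'
#' Produces the per-category totals and the per-genome breakdown of
#' annotated vs newly predicted members by core/dispensable status.
#'
#' @param matrices A `pav_cnv` object.
#' @param categories Named character vector ogg_id -> category.
#' @param members Data.frame with `gene_id`, `genome`, `status`.
#' @param membership Named character vector gene_id -> ogg_id.
#' @return List with `category_totals` (category, n_pangenes) and
#'   `per_genome` (genome x status x core/dispensable counts, long form).
#' @export
summarize_categories <- function(matrices, categories, members, membership) {
  cats <- factor(categories[rownames(matrices$cnv)],
                 levels = c("core", "softcore", "shell", "cloud"))
  category_totals <- data.frame(category = levels(cats),
                                n_pangenes = as.integer(table(cats)),
                                stringsAsFactors = FALSE)
  mem <- members
  mem$category <- unname(categories[membership[mem$gene_id]])
  mem$conservation <- ifelse(mem$category == "core", "core", "dispensable")
  tab <- as.data.frame(table(genome = mem$genome, status = mem$status,
                             conservation = mem$conservation),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_genes"
  list(category_totals = category_totals, per_genome = tab)
}

#' Long-form copy-number table for CNV pangenes
#'
#' Heatmap-ready analogue of a per-pangene copy-number heatmap: one row per
#' (pangene, genome) for pangenes whose copy count varies across the
#' genomes containing them (or that are absent somewhere while multi-copy
#' elsewhere).
#'
#' @param matrices A `pav_cnv` object.
#' @param names_map Optional named vector ogg_id -> systematic name.
#' @return Data.frame `pangene`, `genome`, `copies`.
#' @export
cnv_long_table <- function(matrices, names_map = NULL) {
  cnv <- matrices$cnv
  sub <- cnv[has_cnv(matrices), , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(pangene = character(), genome = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  }
  long <- data.frame(pangene = rep(rownames(sub), times = ncol(sub)),
                     genome = rep(colnames(sub), each = nrow(sub)),
                     copies = as.integer(sub), stringsAsFactors = FALSE)
  if (!is.null(names_map)) long$pangene <- unname(names_map[long$pangene])
  long[order(long$pangene, long$genome), , drop = FALSE]
}

#' Pangenes with copy-number variation
#'
#' A pangene has CNV when its copy count differs across genomes (including
#' absence in some genomes or multiple copies in any genome).
#'
#' @param matrices A `pav_cnv` object.
#' @return Named logical vector over pangene ids.
#' @export
has_cnv <- function(matrices) {
  apply(matrices$cnv, 1L, function(x) max(x) > 1L || any(x == 0L))
}
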