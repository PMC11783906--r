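# End-to-end orchestration: simulate (or load) a pangenome corpus, scan,
# cluster, classify, type duplications, count TEs, estimate selection,
# summarize expression and assign subfamilies; write a structured report.

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `input_dir` (a corpus
#' directory laid out as written by [simulate_pangenome()]) must be given.
#'
#' @param simulate Optional [sim_config()] describing a synthetic corpus.
#' @param input_dir Optional path to an existing corpus directory.
#' @param outdir Output directory for all stage outputs and the report.
#' @param seed Root seed for every stochastic stage.
#' @param e_threshold Domain-scan and homology E-value threshold.
#' @param min_domain_len Minimum domain envelope length (aa).
#' @param min_orf_aa Minimum ORF length for the genomic scan.
#' @param identity_threshold,coverage_threshold Clustering thresholds.
#' @param top_k Homology hits retained per query.
#' @param proximal_rank_max,min_anchors,max_rank_gap Duplication-classifier
#'   parameters.
#' @param te_flank TE window flank (bp).
#' @param expr_k Number of expression clusters.
#' @param family_prefix Prefix for systematic pangene names.
#' @param reference_genome Genome anchoring pangene names (default: first).
#' @param engine Homology engine for [all_vs_all_top_hits()].
#' @param subfamily_max_distance Patristic ceiling for subfamily placement.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            outdir = tempfile("panfam_run"), seed = 1,
                            e_threshold = 1e-5, min_domain_len = 30,
                            min_orf_aa = 60, identity_threshold = 0.95,
                            coverage_threshold = 0.90, top_k = 5,
                            proximal_rank_max = 20, min_anchors = 5,
                            max_rank_gap = 25, te_flank = 2000, expr_k = 3,
                            family_prefix = "FAM", reference_genome = NULL,
                            engine = "auto", subfamily_max_distance = Inf) {
  if (is.null(simulate) == is.null(input_dir)) {
    stop("give exactly one of `simulate` or `input_dir`", call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    stop("`simulate` must be a sim_config", call. = FALSE)
  }
  stopifnot(e_threshold > 0, min_domain_len >= 1, min_orf_aa >= 1,
            identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            top_k >= 1, proximal_rank_max > 1, min_anchors >= 2,
            max_rank_gap >= 1, te_flank >= 0, expr_k >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Run the full pangenome gene-family pipeline
#'
#' Executes all stages in dependency order on a simulated or loaded
#' corpus and returns a `run_report`. Identical configuration and seed
#' yield identical reports (and identical files from [write_report()]).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; see [write_report()] for the
#'   emitted tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  sp <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- .sub_seed(config$seed, "simulate")
    sp <- simulate_pangenome(sim_cfg, dir = file.path(config$outdir, "sim"))
    inputs <- read_pangenome_dir(sp$dir)
  } else {
    inputs <- read_pangenome_dir(config$input_dir)
  }
  genome_ids <- inputs$genome_ids

  # --- family scan -----------------------------------------------------------
  profile <- build_domain_profile(inputs$seed_alignment,
                                  seed = .sub_seed(config$seed, "calibration"))
  members <- list()
  annotation <- list()
  proteomes <- list()
  for (g in genome_ids) {
    p <- inputs$paths[[g]]
    ann <- .read_gff3_genes(p$gff3)
    prot <- Biostrings::readAAStringSet(p$proteins)
    cds <- Biostrings::readDNAStringSet(p$cds)
    hits <- filter_hits(scan_proteins(as.character(prot), profile,
                                      e_threshold = config$e_threshold,
                                      genome = g),
                        config$min_domain_len)
    ann_idx <- match(hits$seq_id, ann$gene_id)
    annotated <- data.frame(
      gene_id = hits$seq_id, genome = g,
      chrom = ann$chrom[ann_idx], start = ann$start[ann_idx],
      end = ann$end[ann_idx], strand = ann$strand[ann_idx],
      status = "annotated",
      protein = as.character(prot[hits$seq_id]),
      cds = as.character(cds[hits$seq_id]),
      domain_start = hits$start, domain_end = hits$end,
      domain_len = hits$domain_length, e_value = hits$e_value,
      stringsAsFactors = FALSE)
    novel <- scan_unannotated_regions(p$assembly, ann, profile,
                                      e_threshold = config$e_threshold,
                                      min_orf_aa = config$min_orf_aa,
                                      genome_id = g)
    names(novel)[names(novel) == "domain_len"] <- "domain_length"
    novel <- filter_hits(novel, config$min_domain_len)
    names(novel)[names(novel) == "domain_length"] <- "domain_len"
    members[[g]] <- rbind(annotated, novel[, names(annotated), drop = FALSE])
    annotation[[g]] <- ann
    proteomes[[g]] <- prot
  }
  members <- do.call(rbind, members)
  rownames(members) <- NULL

  # --- clustering ------------------------------------------------------------
  prot_vec <- setNames(members$protein, members$gene_id)
  oggs <- greedy_cluster(prot_vec,
                         identity_threshold = config$identity_threshold,
                         coverage_threshold = config$coverage_threshold)
  member_genome <- setNames(members$genome, members$gene_id)

  # --- PAV/CNV and categories ------------------------------------------------
  matrices <- build_pav_cnv_matrices(oggs, member_genome, genome_ids)
  presence_counts <- rowSums(matrices$pav)
  categories <- setNames(classify_category(presence_counts, length(genome_ids)),
                         rownames(matrices$pav))
  anchors <- pangene_anchors(oggs, members, config$reference_genome)
  name_map <- name_pangenes(
    data.frame(ogg_id = anchors$ogg_id, category = categories[anchors$ogg_id],
               anchor_chrom = anchors$anchor_chrom,
               anchor_start = anchors$anchor_start, stringsAsFactors = FALSE),
    prefix = config$family_prefix)
  cat_summary <- summarize_categories(matrices, categories, members,
                                      oggs$membership)

  # --- duplication typing ----------------------------------------------------
  dup_labels <- list()
  blocks_all <- list()
  for (g in genome_ids) {
    ann <- annotation[[g]]
    hits_g <- all_vs_all_top_hits(
      setNames(as.character(proteomes[[g]]), names(proteomes[[g]])),
      k = config$top_k, e_threshold = config$e_threshold,
      engine = config$engine)
    ranks <- gene_rank_index(ann)
    blocks <- detect_collinear_blocks(ranks, hits_g,
                                      min_anchors = config$min_anchors,
                                      max_rank_gap = config$max_rank_gap)
    labels <- classify_duplication_types(ann, hits_g, blocks,
                                         proximal_rank_max = config$proximal_rank_max)
    if (nrow(blocks) > 0L) blocks$genome <- g
    blocks_all[[g]] <- blocks
    dup_labels[[g]] <- data.frame(gene_id = names(labels), genome = g,
                                  dup_type = unname(labels),
                                  stringsAsFactors = FALSE)
  }
  dup_labels <- do.call(rbind, dup_labels)
  rownames(dup_labels) <- NULL
  fam_dup <- dup_labels[dup_labels$gene_id %in% members$gene_id, , drop = FALSE]
  fam_dup$pangene <- unname(name_map[oggs$membership[fam_dup$gene_id]])
  fam_dup$category <- unname(categories[oggs$membership[fam_dup$gene_id]])
  dup_by_category <- as.data.frame(table(dup_type = fam_dup$dup_type,
                                         category = fam_dup$category),
                                   stringsAsFactors = FALSE)
  names(dup_by_category)[3] <- "n_genes"

  # --- TE association --------------------------------------------------------
  cnv_flag <- has_cnv(matrices)
  te_counts <- list()
  te_class <- list()
  for (g in genome_ids) {
    te <- read_te_records(inputs$paths[[g]]$te)
    mg <- members[members$genome == g, , drop = FALSE]
    chrom_lengths <- .assembly_lengths(inputs$paths[[g]]$assembly)
    win <- gene_flank_windows(mg, flank = config$te_flank,
                              chrom_lengths = chrom_lengths)
    res <- count_intact_te_per_gene(win, te)
    res$per_gene$genome <- g
    te_counts[[g]] <- res$per_gene
    te_class[[g]] <- res$per_class
  }
  te_counts <- do.call(rbind, te_counts)
  rownames(te_counts) <- NULL
  te_counts$pangene_ogg <- unname(oggs$membership[te_counts$gene_id])
  te_counts$is_cnv <- unname(cnv_flag[te_counts$pangene_ogg])
  te_counts$category <- unname(categories[te_counts$pangene_ogg])
  grp_cnv <- te_counts$n_te[te_counts$is_cnv]
  grp_non <- te_counts$n_te[!te_counts$is_cnv & te_counts$category == "core"]
  te_test <- if (length(grp_cnv) >= 2L && length(grp_non) >= 2L) {
    compare_groups_ttest(grp_cnv, grp_non)
  } else NULL
  te_class_tab <- stats::aggregate(n ~ te_class, data = do.call(rbind, te_class),
                                   FUN = sum)

  # --- selection -------------------------------------------------------------
  cds_vec <- setNames(members$cds, members$gene_id)
  sel_rows <- list()
  pair_rows <- list()
  for (ogg in names(oggs$clusters)) {
    ids <- oggs$clusters[[ogg]]
    ids <- ids[!is.na(cds_vec[ids]) & nzchar(cds_vec[ids])]
    pn <- unname(name_map[ogg])
    if (length(ids) < 2L) {
      sel_rows[[ogg]] <- summarize_ogg_selection(NULL, pangene = pn)
      next
    }
    pairs <- pangene_kaks_pairs(cds_vec[ids], setNames(members$protein,
                                                       members$gene_id)[ids])
    pairs$pangene <- pn
    pair_rows[[ogg]] <- pairs
    sel_rows[[ogg]] <- summarize_ogg_selection(pairs, pangene = pn)
  }
  selection_summary <- do.call(rbind, sel_rows)
  rownames(selection_summary) <- NULL
  selection_pairs <- if (length(pair_rows) > 0L) do.call(rbind, pair_rows) else NULL
  cat_by_name <- setNames(unname(categories), unname(name_map[names(categories)]))
  sel_ok <- selection_summary[!selection_summary$insufficient_members &
                                !is.na(selection_summary$mean_omega), ,
                              drop = FALSE]
  sel_compare <- if (nrow(sel_ok) >= 4L &&
                     length(unique(cat_by_name[sel_ok$pangene] == "core")) == 2L) {
    compare_core_dispensable(sel_ok, cat_by_name)
  } else NULL

  # --- phylogeny and subfamilies --------------------------------------------
  rep_members <- oggs$representatives
  rep_domains <- vapply(names(rep_members), function(ogg) {
    m <- members[members$gene_id == rep_members[[ogg]], , drop = FALSE][1, ]
    substring(m$protein, m$domain_start + 1L, m$domain_end)
  }, character(1))
  names(rep_domains) <- unname(name_map[names(rep_domains)])
  phylo_in <- c(rep_domains, inputs$reference$domains)
  aln <- align_domains(phylo_in)
  tree <- nj_tree(aln)
  subfam <- assign_subfamilies(tree, inputs$reference$labels,
                               max_distance = config$subfamily_max_distance)
  subfam_map <- setNames(subfam$subfamily, subfam$pangene)
  enrichment <- dispensable_enrichment(subfam, cat_by_name)

  # --- expression ------------------------------------------------------------
  tpm_tables <- lapply(genome_ids, function(g) .read_tsv(inputs$paths[[g]]$expression))
  names(tpm_tables) <- genome_ids
  membership_named <- setNames(unname(name_map[oggs$membership]),
                               names(oggs$membership))
  has_expr <- any(vapply(tpm_tables, nrow, integer(1)) > 0L)
  expr_summary <- expr_clust <- expr_cor <- tangle <- NULL
  if (has_expr) {
    expr_summary <- pangene_expression_summary(tpm_tables, membership_named)
    if (length(unique(expr_summary$pangene)) >= config$expr_k) {
      expr_clust <- cluster_expression_profiles(expr_summary, k = config$expr_k)
      tangle <- compare_tree_orders(tree, expr_clust, subfamilies = subfam_map)
    }
    expr_cor <- correlate_mean_vs_relsd(expr_summary)
  }

  # --- subfamily table (per-subfamily pangene composition) -------------------
  single_copy <- apply(matrices$cnv, 1L, function(x) all(x <= 1L) && any(x == 1L))
  pangene_tab <- data.frame(
    pangene = unname(name_map[rownames(matrices$cnv)]),
    ogg_id = rownames(matrices$cnv),
    category = unname(categories[rownames(matrices$cnv)]),
    presence_count = unname(presence_counts),
    subfamily = unname(subfam_map[name_map[rownames(matrices$cnv)]]),
    single_copy = unname(single_copy),
    cnv = unname(cnv_flag),
    stringsAsFactors = FALSE)
  subfamily_table <- do.call(rbind, lapply(split(pangene_tab, pangene_tab$subfamily),
    function(d) data.frame(subfamily = d$subfamily[1], n_pangenes = nrow(d),
                           n_core = sum(d$category == "core"),
                           n_single_copy = sum(d$single_copy),
                           n_cnv = sum(d$cnv), stringsAsFactors = FALSE)))
  rownames(subfamily_table) <- NULL

  report <- structure(list(
    config = config, genome_ids = genome_ids,
    profile = profile, members = members, oggs = oggs, matrices = matrices,
    categories = categories, name_map = name_map, pangene_table = pangene_tab,
    category_summary = cat_summary,
    cnv_long = cnv_long_table(matrices, name_map),
    dup_labels = fam_dup, dup_by_category = dup_by_category,
    blocks = do.call(rbind, blocks_all),
    te_counts = te_counts, te_class = te_class_tab, te_test = te_test,
    selection_summary = selection_summary, selection_pairs = selection_pairs,
    selection_compare = sel_compare,
    tree = tree, subfamilies = subfam, enrichment = enrichment,
    expression_summary = expr_summary, expression_clusters = expr_clust,
    expression_correlation = expr_cor, tanglegram = tangle,
    subfamily_table = subfamily_table,
    simulated = sp), class = "run_report")
  report
}

.assembly_lengths <- function(path) {
  key <- paste0("falen_", path)
  fa <- Biostrings::readDNAStringSet(path)
  setNames(Biostrings::width(fa), sub("\\s.*$", "", names(fa)))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("run_report: %d genomes, %d family genes, %d pangenes ",
                     "(%s)\n"),
              length(x$genome_ids), nrow(x$members),
              length(x$oggs$clusters),
              paste(sprintf("%d %s", x$category_summary$category_totals$n_pangenes,
                            x$category_summary$category_totals$category),
                    collapse = ", ")))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits every report table as TSV plus a human-readable `summary.txt` and
#' a `MANIFEST.tsv` with an MD5 checksum per emitted file.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param outdir Output directory (defaults to the run's configured
#'   output directory).
#' @return Invisibly, the manifest data.frame.
#' @export
write_report <- function(report, outdir = report$config$outdir) {
  rep_dir <- file.path(outdir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    .write_tsv(df, file.path(rep_dir, name))
  }
  members_out <- report$members[, c("gene_id", "genome", "chrom", "start",
                                    "end", "strand", "status", "domain_start",
                                    "domain_end", "domain_len", "e_value")]
  emit(members_out, "members.tsv")
  clu <- do.call(rbind, lapply(names(report$oggs$clusters), function(ogg) {
    m <- report$oggs$clusters[[ogg]]
    data.frame(ogg_id = ogg, pangene = unname(report$name_map[ogg]),
               member_id = m, genome = unname(report$members$genome[
                 match(m, report$members$gene_id)]),
               is_representative = m == report$oggs$representatives[[ogg]],
               stringsAsFactors = FALSE)
  }))
  emit(clu, "clusters.tsv")
  cnv_df <- data.frame(pangene = unname(report$name_map[rownames(report$matrices$cnv)]),
                       report$matrices$cnv, check.names = FALSE,
                       stringsAsFactors = FALSE)
  emit(cnv_df, "cnv_matrix.tsv")
  pav_df <- cnv_df
  pav_df[, -1] <- as.integer(report$matrices$pav)
  emit(pav_df, "pav_matrix.tsv")
  emit(report$pangene_table, "pangenes.tsv")
  emit(report$category_summary$category_totals, "category_totals.tsv")
  emit(report$category_summary$per_genome, "members_per_genome.tsv")
  emit(report$cnv_long, "cnv_long.tsv")
  emit(report$dup_labels, "duplication_labels.tsv")
  emit(report$dup_by_category, "duplication_by_category.tsv")
  emit(report$blocks, "collinear_blocks.tsv")
  emit(report$te_counts, "te_counts.tsv")
  emit(report$te_class, "te_class_distribution.tsv")
  emit(report$te_test, "te_group_test.tsv")
  emit(report$selection_summary, "selection_summary.tsv")
  emit(report$selection_pairs, "selection_pairs.tsv")
  emit(report$selection_compare, "selection_core_vs_dispensable.tsv")
  emit(report$subfamilies, "subfamily_assignments.tsv")
  emit(report$enrichment, "subfamily_enrichment.tsv")
  emit(report$subfamily_table, "subfamily_table.tsv")
  emit(report$expression_summary, "expression_summary.tsv")
  if (!is.null(report$expression_clusters)) {
    emit(data.frame(pangene = names(report$expression_clusters$clusters),
                    cluster = unname(report$expression_clusters$clusters),
                    stringsAsFactors = FALSE), "expression_clusters.tsv")
  }
  if (!is.null(report$tanglegram)) {
    emit(data.frame(metric = c("n_shared", "crossings", "entanglement"),
                    value = c(report$tanglegram$n_shared,
                              report$tanglegram$crossings,
                              report$tanglegram$entanglement),
                    stringsAsFactors = FALSE), "tanglegram_metrics.tsv")
    emit(report$tanglegram$subfamily_divergence, "subfamily_divergence.tsv")
  }
  ape::write.tree(report$tree, file.path(rep_dir, "pangene_tree.nwk"))

  # summary.txt: terse human-readable account (no timestamps: reports are
  # byte-reproducible under a fixed seed)
  s <- c(sprintf("genomes: %d", length(report$genome_ids)),
         sprintf("family genes: %d (annotated %d, newly predicted %d)",
                 nrow(report$members),
                 sum(report$members$status == "annotated"),
                 sum(report$members$status == "newly_predicted")),
         sprintf("pangenes: %d", length(report$oggs$clusters)),
         sprintf("categories: %s",
                 paste(sprintf("%s=%d",
                               report$category_summary$category_totals$category,
                               report$category_summary$category_totals$n_pangenes),
                       collapse = " ")),
         if (!is.null(report$te_test))
           sprintf("TE means: CNV %.3f vs non-CNV core %.3f (p=%.4g)",
                   report$te_test$mean_cnv, report$te_test$mean_noncnv,
                   report$te_test$p_value),
         if (!is.null(report$selection_compare)) {
           om <- report$selection_compare[report$selection_compare$statistic == "omega", ]
           sprintf("omega medians: core %.3f vs dispensable %.3f (p=%.4g)",
                   om$median_core, om$median_dispensable, om$p_value)
         },
         if (!is.null(report$expression_correlation))
           sprintf("mean vs rel-SD Spearman rho: %.3f (p=%.4g)",
                   report$expression_correlation$rho,
                   report$expression_correlation$p_value))
  writeLines(s, file.path(rep_dir, "summary.txt"))

  files <- sort(setdiff(list.files(rep_dir), "MANIFEST.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(rep_dir, files))),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(rep_dir, "MANIFEST.tsv"))
  invisible(manifest)
}
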