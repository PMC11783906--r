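# Scoring a pipeline run against the generator's ground truth.

# map realized member ids to truth gene ids: annotated members share ids;
# newly predicted members are matched by exact genomic span
.match_members_to_truth <- function(members, truth_genes) {
  map <- setNames(rep(NA_character_, nrow(members)), members$gene_id)
  ann <- members$gene_id %in% truth_genes$gene_id
  map[ann] <- members$gene_id[ann]
  novel <- which(!ann)
  if (length(novel) > 0L) {
    key_truth <- paste(truth_genes$genome, truth_genes$chrom,
                       truth_genes$start, truth_genes$end)
    key_new <- paste(members$genome[novel], members$chrom[novel],
                     members$start[novel], members$end[novel])
    hitpos <- match(key_new, key_truth)
    map[novel] <- truth_genes$gene_id[hitpos]
  }
  map
}

#' Hidden-gene recovery report
#'
#' Compares newly predicted members against hidden truth genes and
#' accounts for every hidden gene: recovered (exact span), or missed --
#' split by whether the truth gene is multi-exon (the genomic ORF scan
#' recovers single-exon genes only, a documented limitation).
#'
#' @param predicted Data.frame of newly predicted members (`genome`,
#'   `chrom`, `start`, `end`).
#' @param hidden_truth Data.frame of hidden truth genes with the same
#'   coordinate columns; an optional logical `multi_exon` column marks
#'   genes whose domain is interrupted by an intron.
#' @return Data.frame with one row per outcome: `outcome` in
#'   {"recovered", "missed: multi-exon", "missed: other"} and `n`.
#' @export
hidden_recovery_report <- function(predicted, hidden_truth) {
  key_pred <- paste(predicted$genome, predicted$chrom, predicted$start,
                    predicted$end)
  key_truth <- paste(hidden_truth$genome, hidden_truth$chrom,
                     hidden_truth$start, hidden_truth$end)
  recovered <- key_truth %in% key_pred
  multi <- if (!is.null(hidden_truth$multi_exon)) hidden_truth$multi_exon
           else rep(FALSE, nrow(hidden_truth))
  data.frame(outcome = c("recovered", "missed: multi-exon", "missed: other"),
             n = c(sum(recovered), sum(!recovered & multi),
                   sum(!recovered & !multi)),
             stringsAsFactors = FALSE)
}

#' Score a pipeline run against generator ground truth
#'
#' Computes recovery and agreement metrics between a [run_pipeline()]
#' report and the truth tables of the [simulate_pangenome()] corpus it was
#' run on: hidden-gene recovery, clustering exactness, category accuracy,
#' duplication-label accuracy and subfamily accuracy.
#'
#' @param report A `run_report`.
#' @param sp The `synthetic_pangenome` the run consumed (defaults to the
#'   one embedded in the report for simulate-mode runs).
#' @return A list of metrics; see Details.
#' @details
#' * `hidden_recovery`: fraction of hidden truth genes recovered by the
#'   genomic scan with exactly correct coordinates.
#' * `cluster_exact_fraction`: fraction of truth pangenes whose realized
#'   cluster contains exactly the truth members (after mapping recovered
#'   hidden genes by coordinates).
#' * `category_accuracy`: fraction of realized clusters (majority-mapped
#'   to truth pangenes) with the correct conservation category.
#' * `dup_accuracy`: fraction of annotated family genes whose duplication
#'   label matches the generator's event type.
#' * `subfamily_accuracy`: fraction of majority-mapped clusters assigned
#'   their truth subfamily.
#' @export
evaluate_against_truth <- function(report, sp = report$simulated) {
  if (is.null(sp)) stop("no synthetic truth available", call. = FALSE)
  truth <- sp$truth_genes
  members <- report$members
  map <- .match_members_to_truth(members, truth)

  hidden <- truth[truth$status == "hidden", , drop = FALSE]
  hidden_recovered <- sum(hidden$gene_id %in% map[members$status == "newly_predicted"])
  hidden_recovery <- if (nrow(hidden) > 0L) hidden_recovered / nrow(hidden) else NA_real_

  # realized cluster (set of truth ids) per OGG
  truth_of_member <- map[members$gene_id]
  cluster_truth_sets <- lapply(report$oggs$clusters, function(m) {
    ids <- unname(truth_of_member[m])
    sort(ids[!is.na(ids)])
  })
  truth_sets <- lapply(split(truth$gene_id, truth$pangene),
                       function(x) sort(unname(x)))
  exact <- vapply(truth_sets, function(ts) {
    any(vapply(cluster_truth_sets, identical, logical(1), y = ts))
  }, logical(1))
  cluster_exact_fraction <- mean(exact)

  # majority mapping OGG -> truth pangene
  truth_pg_of <- setNames(truth$pangene, truth$gene_id)
  ogg_to_truth <- vapply(report$oggs$clusters, function(m) {
    tp <- truth_pg_of[truth_of_member[m]]
    tp <- tp[!is.na(tp)]
    if (length(tp) == 0L) return(NA_character_)
    names(sort(table(tp), decreasing = TRUE))[1]
  }, character(1))
  tp_tab <- sp$truth_pangenes
  rownames(tp_tab) <- tp_tab$pangene
  mapped <- !is.na(ogg_to_truth)
  category_accuracy <- mean(
    unname(report$categories[names(ogg_to_truth)[mapped]]) ==
      tp_tab[ogg_to_truth[mapped], "category"])

  # duplication accuracy over annotated family genes
  ann_truth <- truth[truth$status == "annotated", , drop = FALSE]
  dl <- report$dup_labels
  idx <- match(ann_truth$gene_id, dl$gene_id)
  ok <- !is.na(idx)
  dup_accuracy <- mean(dl$dup_type[idx[ok]] == ann_truth$dup_truth[ok])

  # subfamily accuracy via the systematic-name map
  sf_map <- setNames(report$subfamilies$subfamily, report$subfamilies$pangene)
  realized_sf <- unname(sf_map[report$name_map[names(ogg_to_truth)[mapped]]])
  subfamily_accuracy <- mean(realized_sf == tp_tab[ogg_to_truth[mapped], "subfamily"],
                             na.rm = TRUE)

  list(hidden_recovery = hidden_recovery,
       n_hidden = nrow(hidden),
       cluster_exact_fraction = cluster_exact_fraction,
       category_accuracy = category_accuracy,
       dup_accuracy = dup_accuracy,
       n_dup_scored = sum(ok),
       subfamily_accuracy = subfamily_accuracy,
       n_pangenes_truth = nrow(tp_tab),
       n_oggs = length(report$oggs$clusters))
}
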