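# Genome assembly construction and the top-level synthetic pangenome driver.

.GENE_INSULATOR <- "TGATAATGA"  # in-frame stops bracketing implanted genes

# fast CDS -> protein via genetic-code lookup (trims terminal stop)
.cds_to_protein <- function(cds) {
  gc <- .genetic_code()
  aa <- unname(gc[.split_codons(cds)])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

.nonstop_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

# n background gene records (random unique CDS)
.bg_block <- function(cfg, n) {
  if (n == 0L) return(NULL)
  cods <- .nonstop_codons()
  cds <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(sample(cods, cfg$bg_gene_codons - 1L, replace = TRUE),
                        collapse = ""), "TAA")
  }, character(1))
  data.frame(kind = "bg", pangene = NA_character_, subfamily = NA_character_,
             category = NA_character_, dup_truth = NA_character_,
             copy_index = NA_integer_, status = "annotated",
             strand = sample(c("+", "-"), n, replace = TRUE),
             cds = cds,
             protein = vapply(cds, .cds_to_protein, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# one family member record derived from the pangene ancestor
.family_record <- function(cfg, pg_row, copy_index, dup_truth) {
  omega <- if (pg_row$category == "core") cfg$omega_core else cfg$omega_dispensable
  cds <- mutate_cds_with_target_omega(pg_row$ancestor_cds, omega,
                                      cfg$mutation_events)
  data.frame(kind = "family", pangene = pg_row$pangene,
             subfamily = pg_row$subfamily, category = pg_row$category,
             dup_truth = dup_truth, copy_index = as.integer(copy_index),
             status = "annotated", strand = sample(c("+", "-"), 1L),
             cds = cds, protein = .cds_to_protein(cds),
             stringsAsFactors = FALSE)
}

# boundary-insertion target: a slot on another chromosome whose own and
# following family genes belong to a different subfamily
.pick_boundary <- function(slots, home_chrom, subfamily, pg_by_id) {
  cand <- slots[slots$chrom != home_chrom, , drop = FALSE]
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    ch <- cand$chrom[i]; sl <- cand$slot[i]
    here <- pg_by_id[cand$pangene[i], "subfamily"]
    nxt <- cand$pangene[cand$chrom == ch & cand$slot == sl + 1L]
    after <- if (length(nxt) == 1L) pg_by_id[nxt, "subfamily"] else NA_character_
    !identical(here, subfamily) && !identical(after, subfamily)
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  cand[sample.int(nrow(cand), 1L), , drop = FALSE]
}

# Build one genome: ordered gene table with coordinates plus chromosome
# sequences. Deterministic given the genome-stage seed set by the caller.
.build_genome <- function(cfg, g, arch, presence, cnv_plan, slots) {
  pg_by_id <- arch$pangenes
  rownames(pg_by_id) <- pg_by_id$pangene
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  base <- lapply(chroms, function(ch) {
    sl <- slots[slots$chrom == ch, , drop = FALSE]
    sl <- sl[order(sl$slot), , drop = FALSE]
    lapply(seq_len(nrow(sl)), function(i) {
      p <- sl$pangene[i]
      fam <- if (presence[p, g]) .family_record(cfg, pg_by_id[p, ], 1L, "dispersed")
             else NULL
      list(pre = .bg_block(cfg, 13L), fam = fam, post = .bg_block(cfg, 13L),
           pangene = p, tandem = NULL, proximal = NULL, boundary = NULL)
    })
  })
  names(base) <- chroms
  slot_of <- function(p) slots[slots$pangene == p, , drop = FALSE]

  plan_g <- cnv_plan[cnv_plan$genome == g, , drop = FALSE]
  for (i in seq_len(nrow(plan_g))) {
    p <- plan_g$pangene[i]; type <- plan_g$dup_type[i]
    extra <- plan_g$extra_copies[i]
    home <- slot_of(p)
    slot_obj <- base[[home$chrom]][[home$slot]]
    if (is.null(slot_obj$fam)) next
    label <- switch(type, tandem = "tandem", proximal = "proximal",
                    dispersed = "dispersed", segmental = "wgd_segmental")
    if (type %in% c("tandem", "proximal")) slot_obj$fam$dup_truth <- label
    if (type == "tandem") {
      for (e in seq_len(extra)) {
        slot_obj$tandem <- rbind(slot_obj$tandem,
                                 .family_record(cfg, pg_by_id[p, ], 1L + e, label))
      }
    } else if (type == "proximal") {
      for (e in seq_len(extra)) {
        rec <- .family_record(cfg, pg_by_id[p, ], 1L + e, label)
        rec$prox_offset <- sample(3:12, 1L)
        slot_obj$proximal <- rbind(slot_obj$proximal, rec)
      }
    } else if (type == "dispersed") {
      for (e in seq_len(extra)) {
        tgt <- .pick_boundary(slots, home$chrom, pg_by_id[p, "subfamily"], pg_by_id)
        rec <- .family_record(cfg, pg_by_id[p, ], 1L + e, label)
        tslot <- base[[tgt$chrom]][[tgt$slot]]
        tslot$boundary <- rbind(tslot$boundary, rec)
        base[[tgt$chrom]][[tgt$slot]] <- tslot
      }
    } else if (type == "segmental") {
      # source block: family gene + the 5 following background genes
      slot_obj$fam$dup_truth <- "wgd_segmental"
      slot_obj$post$dup_truth[1:5] <- "wgd_segmental"
      for (e in seq_len(extra)) {
        tgt <- .pick_boundary(slots, home$chrom, pg_by_id[p, "subfamily"], pg_by_id)
        fam_copy <- .family_record(cfg, pg_by_id[p, ], 1L + e, "wgd_segmental")
        bg_copy <- slot_obj$post[1:5, , drop = FALSE]
        bg_copy$dup_truth <- "wgd_segmental"
        block <- rbind(fam_copy, bg_copy)
        tslot <- base[[tgt$chrom]][[tgt$slot]]
        tslot$boundary <- rbind(tslot$boundary, block)
        base[[tgt$chrom]][[tgt$slot]] <- tslot
      }
    }
    base[[home$chrom]][[home$slot]] <- slot_obj
  }

  # flatten slots to an ordered gene table per chromosome
  tables <- lapply(chroms, function(ch) {
    rows <- list()
    for (slot_obj in base[[ch]]) {
      rows[[length(rows) + 1L]] <- slot_obj$pre
      mid <- slot_obj$fam
      if (!is.null(slot_obj$tandem)) mid <- rbind(mid, slot_obj$tandem)
      if (!is.null(mid)) rows[[length(rows) + 1L]] <- mid
      post <- slot_obj$post
      if (!is.null(slot_obj$proximal)) {
        prox <- slot_obj$proximal[order(slot_obj$proximal$prox_offset), , drop = FALSE]
        assembled <- NULL
        cursor <- 0L
        for (k in seq_len(nrow(prox))) {
          upto <- prox$prox_offset[k] - 1L
          if (upto > cursor) {
            assembled <- rbind(assembled, post[(cursor + 1L):min(upto, 13L), ,
                                               drop = FALSE])
            cursor <- min(upto, 13L)
          }
          assembled <- rbind(assembled,
                             prox[k, setdiff(names(prox), "prox_offset"),
                                  drop = FALSE])
        }
        if (cursor < 13L) assembled <- rbind(assembled,
                                             post[(cursor + 1L):13L, , drop = FALSE])
        post <- assembled
      }
      rows[[length(rows) + 1L]] <- post
      if (!is.null(slot_obj$boundary)) rows[[length(rows) + 1L]] <- slot_obj$boundary
    }
    tab <- do.call(rbind, rows)
    tab$chrom <- ch
    tab
  })
  genes <- do.call(rbind, tables)
  rownames(genes) <- NULL

  # gene ids in final order
  is_fam <- genes$kind == "family"
  genes$gene_id <- NA_character_
  genes$gene_id[!is_fam] <- sprintf("%s.bg%04d", g, seq_len(sum(!is_fam)))
  genes$gene_id[is_fam] <- sprintf("%s.%s.c%d", g, genes$pangene[is_fam],
                                   genes$copy_index[is_fam])
  # segmental background copies duplicate source CDS; ids stay unique
  if (anyDuplicated(genes$gene_id[is_fam])) {
    dup <- duplicated(genes$gene_id)
    genes$gene_id[dup] <- paste0(genes$gene_id[dup], "b")
  }

  # coordinates and sequence assembly per chromosome
  chrom_seqs <- setNames(vector("list", length(chroms)), chroms)
  genes$start <- NA_integer_; genes$end <- NA_integer_
  for (ch in chroms) {
    idx <- which(genes$chrom == ch)
    segs <- character(0)
    cur <- 0L
    prev_fam <- FALSE
    for (ii in idx) {
      fam_here <- genes$kind[ii] == "family"
      gap <- if (fam_here || prev_fam) 2200L else 350L
      cds <- genes$cds[ii]
      cassette <- paste0(.GENE_INSULATOR, cds, .GENE_INSULATOR)
      if (genes$strand[ii] == "-") cassette <- .revcomp(cassette)
      segs <- c(segs, .random_dna(gap), cassette)
      genes$start[ii] <- cur + gap + 9L
      genes$end[ii] <- cur + gap + 9L + nchar(cds)
      cur <- cur + gap + nchar(cassette)
      prev_fam <- fam_here
    }
    need <- cur + 200L
    if (need > cfg$chromosome_length) {
      stop(sprintf(paste0("chromosome too short to place requested genes: ",
                          "%s of %s needs %d bp but chromosome_length is %d"),
                   ch, g, need, cfg$chromosome_length), call. = FALSE)
    }
    segs <- c(segs, .random_dna(cfg$chromosome_length - cur))
    chrom_seqs[[ch]] <- paste(segs, collapse = "")
  }
  genes$genome <- g
  cols <- c("gene_id", "genome", "kind", "pangene", "subfamily", "category",
            "dup_truth", "copy_index", "status", "chrom", "start", "end",
            "strand", "cds", "protein")
  list(genes = genes[, cols], chrom_seqs = chrom_seqs)
}

#' Simulate a synthetic pangenome corpus
#'
#' Generates `n_genomes` genome assemblies carrying a focal gene family
#' with known pangene structure, writes the per-genome files (assembly
#' FASTA, GFF3, protein/CDS FASTA, TE BED6, expression TSV) together with
#' the family references and ground-truth tables into `dir`, and returns
#' an object describing the corpus. Identical configuration (including
#' the seed) yields byte-identical output files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created; must not pre-exist non-empty).
#' @return An object of class `synthetic_pangenome`: the config, file
#'   paths, the full gene table (background and family genes), truth
#'   tables, presence matrix, CNV plan, references and expression tables.
#' @export
simulate_pangenome <- function(config, dir = tempfile("pansim")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genome_ids <- sprintf("G%02d", seq_len(cfg$n_genomes))

  set.seed(.sub_seed(cfg$seed, "architecture"))
  arch <- .make_architecture(cfg)
  set.seed(.sub_seed(cfg$seed, "presence"))
  presence <- .plan_presence(cfg, arch$pangenes)
  set.seed(.sub_seed(cfg$seed, "cnv"))
  cnv_plan <- .plan_cnv(cfg, arch$pangenes, presence)
  slots <- .assign_slots(cfg, arch$pangenes)

  builds <- list()
  for (g in genome_ids) {
    set.seed(.sub_seed(cfg$seed, paste0("genome_", g)))
    builds[[g]] <- .build_genome(cfg, g, arch, presence, cnv_plan, slots)
  }
  genes <- do.call(rbind, lapply(builds, `[[`, "genes"))
  rownames(genes) <- NULL

  # hidden genes: annotation dropout among single-copy non-CNV family genes
  fam_idx <- which(genes$kind == "family")
  set.seed(.sub_seed(cfg$seed, "hidden"))
  eligible <- fam_idx[!(genes$pangene[fam_idx] %in% unique(cnv_plan$pangene))]
  n_hidden <- if (!is.null(cfg$n_hidden)) cfg$n_hidden
              else round(cfg$hidden_fraction * length(fam_idx))
  n_hidden <- min(n_hidden, length(eligible))
  if (n_hidden > 0L) {
    genes$status[sample(eligible, n_hidden)] <- "hidden"
  }

  # TE landscape per genome (family gene windows; CNV status by pangene)
  chrom_lengths <- setNames(rep(cfg$chromosome_length, cfg$n_chromosomes),
                            sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  cnv_pangenes <- unique(cnv_plan$pangene)
  te_by_genome <- list()
  te_truth <- list()
  for (g in genome_ids) {
    set.seed(.sub_seed(cfg$seed, paste0("te_", g)))
    fg <- genes[genes$genome == g & genes$kind == "family", , drop = FALSE]
    fg$is_cnv <- fg$pangene %in% cnv_pangenes
    sim <- simulate_te_landscape(fg, cfg$te_rate_cnv, cfg$te_rate_noncnv,
                                 chrom_lengths, flank = cfg$te_flank)
    te_by_genome[[g]] <- sim$te
    te_truth[[g]] <- sim$truth
  }
  te_truth <- do.call(rbind, te_truth)
  genes$n_te_window <- te_truth$n_te_window[match(genes$gene_id, te_truth$gene_id)]

  # expression: pangene base means/archetypes, then per-gene Gamma draws
  set.seed(.sub_seed(cfg$seed, "expression"))
  expr_pg <- data.frame(
    pangene = arch$pangenes$pangene,
    base_mean = stats::rlnorm(nrow(arch$pangenes), cfg$expr_meanlog, cfg$expr_sdlog),
    archetype = sample(c("broad", "specific", "half"), nrow(arch$pangenes),
                       replace = TRUE, prob = c(0.4, 0.3, 0.3)),
    stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(expr_pg)), function(i) {
    expr_pg$base_mean[i] * .archetype_profile(expr_pg$archetype[i], cfg$n_tissues)
  })
  names(profiles) <- expr_pg$pangene
  expression <- list()
  for (g in genome_ids) {
    fg <- genes[genes$genome == g & genes$kind == "family" &
                  genes$status == "annotated", , drop = FALSE]
    if (nrow(fg) == 0L) {
      tab <- as.data.frame(setNames(c(list(character(0)),
                                      rep(list(numeric(0)), cfg$n_tissues)),
                                    c("gene_id", cfg$tissue_names)))
    } else {
      vals <- t(vapply(fg$pangene, function(p) .draw_tpm(profiles[[p]],
                                                         cfg$expr_link),
                       numeric(cfg$n_tissues)))
      tab <- data.frame(gene_id = fg$gene_id, vals, stringsAsFactors = FALSE,
                        row.names = NULL)
      names(tab) <- c("gene_id", cfg$tissue_names)
    }
    expression[[g]] <- tab
  }

  truth_genes <- genes[genes$kind == "family",
                       c("gene_id", "genome", "pangene", "subfamily",
                         "category", "dup_truth", "copy_index", "status",
                         "chrom", "start", "end", "strand", "n_te_window")]
  rownames(truth_genes) <- NULL
  omega_of <- ifelse(arch$pangenes$category == "core", cfg$omega_core,
                     cfg$omega_dispensable)
  truth_pangenes <- data.frame(
    pangene = arch$pangenes$pangene, subfamily = arch$pangenes$subfamily,
    category = arch$pangenes$category,
    presence_count = rowSums(presence)[arch$pangenes$pangene],
    n_copies = as.integer(table(factor(truth_genes$pangene,
                                       levels = arch$pangenes$pangene))),
    is_cnv = arch$pangenes$pangene %in% cnv_pangenes,
    dup_type = cnv_plan$dup_type[match(arch$pangenes$pangene, cnv_plan$pangene)],
    target_omega = omega_of,
    expr_base_mean = expr_pg$base_mean, expr_archetype = expr_pg$archetype,
    stringsAsFactors = FALSE)

  ref_ids <- sprintf("REF_%s", names(arch$subfamily_domains))
  reference <- list(domains = setNames(unname(arch$subfamily_domains), ref_ids),
                    labels = setNames(names(arch$subfamily_domains), ref_ids))

  sp <- structure(list(config = cfg, dir = dir, genome_ids = genome_ids,
                       genes = genes, truth_genes = truth_genes,
                       truth_pangenes = truth_pangenes, presence = presence,
                       cnv_plan = cnv_plan, te = te_by_genome,
                       expression = expression, reference = reference,
                       seed_alignment = setNames(unname(arch$subfamily_domains),
                                                 names(arch$subfamily_domains)),
                       chrom_lengths = chrom_lengths),
                  class = "synthetic_pangenome")
  .write_pangenome(sp, builds)
  sp
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  cat(sprintf(paste0("synthetic_pangenome: %d genomes, %d pangenes, ",
                     "%d family gene instances (%d hidden); dir: %s\n"),
              length(x$genome_ids), nrow(x$truth_pangenes),
              nrow(x$truth_genes), sum(x$truth_genes$status == "hidden"),
              x$dir))
  invisible(x)
}

# write all corpus files; builds carries the chromosome sequences
.write_pangenome <- function(sp, builds) {
  dir <- sp$dir
  for (d in c("genomes", "ref", "truth")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (g in sp$genome_ids) {
    seqs <- Biostrings::DNAStringSet(unlist(builds[[g]]$chrom_seqs))
    Biostrings::writeXStringSet(seqs, file.path(dir, "genomes", paste0(g, ".fa")))
    ann <- sp$genes[sp$genes$genome == g & sp$genes$status == "annotated", ,
                    drop = FALSE]
    .write_gff3(ann, file.path(dir, "genomes", paste0(g, ".gff3")))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(setNames(ann$protein, ann$gene_id)),
      file.path(dir, "genomes", paste0(g, ".prot.fa")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(ann$cds, ann$gene_id)),
      file.path(dir, "genomes", paste0(g, ".cds.fa")))
    write_te_bed(sp$te[[g]], file.path(dir, "genomes", paste0(g, ".te.bed")))
    .write_tsv(sp$expression[[g]], file.path(dir, "genomes", paste0(g, ".expr.tsv")))
  }
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sp$seed_alignment),
    file.path(dir, "ref", "seed_domain_alignment.fa"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sp$reference$domains),
    file.path(dir, "ref", "reference_domains.fa"))
  .write_tsv(data.frame(ref_id = names(sp$reference$labels),
                        subfamily = unname(sp$reference$labels),
                        stringsAsFactors = FALSE),
             file.path(dir, "ref", "reference_labels.tsv"))
  .write_tsv(sp$truth_genes, file.path(dir, "truth", "truth_genes.tsv"))
  .write_tsv(sp$truth_pangenes, file.path(dir, "truth", "truth_pangenes.tsv"))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L,
                    unclass(sp$config))
  .write_tsv(data.frame(key = names(scalars),
                        value = vapply(scalars, as.character, character(1)),
                        stringsAsFactors = FALSE),
             file.path(dir, "config.tsv"))
  invisible(dir)
}

# GFF3 export (gene + mRNA + CDS per single-exon gene, source "pansim")
.write_gff3 <- function(ann, path) {
  if (nrow(ann) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  mk <- function(type, id, parent) {
    GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
      strand = ann$strand, source = "pansim", type = type,
      ID = id, Parent = parent)
  }
  gene <- mk("gene", ann$gene_id, NA_character_)
  mrna <- mk("mRNA", paste0(ann$gene_id, ".t1"), ann$gene_id)
  cds <- mk("CDS", paste0(ann$gene_id, ".cds"), paste0(ann$gene_id, ".t1"))
  gene$phase <- NA_integer_; mrna$phase <- NA_integer_; cds$phase <- 0L
  gr <- c(gene, mrna, cds)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 match(gr$type, c("gene", "mRNA", "CDS")))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read per-genome corpus files back into pipeline inputs
#'
#' @param dir A directory written by [simulate_pangenome()] (or laid out
#'   the same way).
#' @return List with `genome_ids`, per-genome file paths, reference
#'   domains/labels and the seed alignment.
#' @export
read_pangenome_dir <- function(dir) {
  fa <- sort(list.files(file.path(dir, "genomes"), pattern = "\\.fa$",
                        full.names = TRUE))
  fa <- fa[!grepl("\\.(prot|cds)\\.fa$", fa)]
  genome_ids <- sub("\\.fa$", "", basename(fa))
  paths <- lapply(setNames(genome_ids, genome_ids), function(g) {
    base <- file.path(dir, "genomes", g)
    list(assembly = paste0(base, ".fa"), gff3 = paste0(base, ".gff3"),
         proteins = paste0(base, ".prot.fa"), cds = paste0(base, ".cds.fa"),
         te = paste0(base, ".te.bed"), expression = paste0(base, ".expr.tsv"))
  })
  labels_df <- .read_tsv(file.path(dir, "ref", "reference_labels.tsv"))
  ref_dom <- Biostrings::readAAStringSet(
    file.path(dir, "ref", "reference_domains.fa"))
  seed_aln <- Biostrings::readAAStringSet(
    file.path(dir, "ref", "seed_domain_alignment.fa"))
  list(dir = dir, genome_ids = genome_ids, paths = paths,
       reference = list(domains = setNames(as.character(ref_dom), names(ref_dom)),
                        labels = setNames(labels_df$subfamily, labels_df$ref_id)),
       seed_alignment = as.character(seed_aln))
}
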