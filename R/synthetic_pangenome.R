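# Synthetic pangenome generator: multi-genome assemblies carrying a focal
# gene family with controlled presence/absence, copy-number variation by
# duplication type, intact-TE enrichment near CNV genes, codon divergence at
# category-specific target dN/dS, tissue expression with a mean-dispersion
# link, and a complete ground-truth table for every downstream stage.
#
# Layout design: each chromosome is a sequence of "family slots". A slot is
# 13 background genes, the family gene (when the pangene is present in the
# genome), then 13 more background genes, so consecutive family genes sit
# 27 gene ranks apart -- wider than the default collinearity rank gap, which
# prevents spurious chains of family-family anchors -- while duplication
# events insert copies at controlled rank offsets (tandem = 1, proximal =
# 3..12, dispersed/segmental = another chromosome). Implanted genes are
# bracketed by short stop-codon insulators so that the six-frame ORF scan
# recovers exactly the gene span of hidden (unannotated) members.

#' Configuration for the synthetic pangenome generator
#'
#' Defaults describe a 20-genome panel with 48 family pangenes (30 core,
#' 4 softcore, 8 shell, 6 cloud) in 6 subfamilies, category presence
#' ranges matching the classifier boundaries, a 30% CNV rate dominated by
#' dispersed duplication, intact-TE rates of 1.48 (genes of CNV pangenes)
#' vs 1.36 (others) per +/-2 kb window, target dN/dS of 0.2 (core) vs 0.8
#' (dispensable), five tissues, and 5% of family genes hidden from the
#' annotation.
#'
#' @param n_genomes,n_chromosomes,chromosome_length Panel geometry.
#' @param n_core,n_softcore,n_shell,n_cloud Pangene counts per category.
#' @param n_subfamilies Number of family subfamilies.
#' @param presence_freq_ranges Named list of presence-fraction intervals
#'   per category; converted to integer presence-count ranges consistent
#'   with [classify_category()].
#' @param cnv_prob Fraction of pangenes receiving copy-number variation.
#' @param dup_event_rates Named probabilities over duplication types
#'   (tandem, proximal, dispersed, segmental) for CNV events.
#' @param segmental_core_only Restrict segmental events to core pangenes
#'   (the conservation pattern the generator emulates).
#' @param cnv_max_copies,cnv_max_genomes Copy count (per genome) and
#'   number of genomes affected per CNV pangene.
#' @param omega_core,omega_dispensable Target dN/dS per category.
#' @param mutation_events Accepted substitution events per member CDS.
#' @param gene_codons,bg_gene_codons Coding length of family / background
#'   genes (codons, excluding the stop).
#' @param domain_aa,domain_offset_aa Domain length and 0-based offset
#'   within the family protein.
#' @param subfamily_divergence,pangene_divergence Amino-acid substitution
#'   fractions from the family root to subfamily ancestors, and from
#'   subfamily ancestors to pangene ancestors.
#' @param te_rate_cnv,te_rate_noncnv Expected intact TEs per gene window.
#' @param te_flank Window flank in bp.
#' @param n_tissues,tissue_names Expression panel.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of pangene base
#'   expression means.
#' @param expr_link Mean-CV link parameters `cv0`, `gamma`, `cv_min`:
#'   CV(mu) = cv0 * (mu+1)^(-gamma) + cv_min (decreasing in the mean).
#' @param hidden_fraction,n_hidden Fraction (or exact count, overriding
#'   the fraction) of eligible family genes removed from the annotation
#'   but kept in the genomic sequence.
#' @param dispensable_subfamilies Optional integer vector: concentrate all
#'   dispensable pangenes in these subfamilies while core pangenes occupy
#'   the remaining ones (dispensable-enrichment scenario).
#' @param family_prefix Prefix for systematic pangene names.
#' @param seed Root seed; every stage derives a sub-seed from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 20, n_chromosomes = 3,
                       chromosome_length = 400000,
                       n_core = 30, n_softcore = 4, n_shell = 8, n_cloud = 6,
                       n_subfamilies = 6,
                       presence_freq_ranges = NULL,
                       cnv_prob = 0.3,
                       dup_event_rates = c(tandem = 0.20, proximal = 0.15,
                                           dispersed = 0.55, segmental = 0.10),
                       segmental_core_only = TRUE,
                       cnv_max_copies = 3, cnv_max_genomes = 3,
                       omega_core = 0.2, omega_dispensable = 0.8,
                       mutation_events = 5,
                       gene_codons = 200, bg_gene_codons = 80,
                       domain_aa = 60, domain_offset_aa = 70,
                       subfamily_divergence = 0.25, pangene_divergence = 0.08,
                       te_rate_cnv = 1.48, te_rate_noncnv = 1.36,
                       te_flank = 2000,
                       n_tissues = 5,
                       tissue_names = c("caryopsis", "coleoptile",
                                        "inflorescence", "root", "shoot"),
                       expr_meanlog = 1.5, expr_sdlog = 1.2,
                       expr_link = list(cv0 = 1.2, gamma = 0.4, cv_min = 0.15),
                       hidden_fraction = 0.05, n_hidden = NULL,
                       dispensable_subfamilies = NULL,
                       family_prefix = "FAM", seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_genomes, n_chromosomes, n_core, n_softcore, n_shell, n_cloud,
              n_subfamilies, n_tissues)
  if (any(counts < 0) || n_genomes < 1 || n_chromosomes < 2 || n_tissues < 1) {
    stop("counts must be non-negative (>= 1 genome and tissue, >= 2 chromosomes)",
         call. = FALSE)
  }
  if (omega_core <= 0 || omega_dispensable <= 0) stop("omegas must be > 0", call. = FALSE)
  if (te_rate_cnv < 0 || te_rate_noncnv < 0) stop("TE rates must be >= 0", call. = FALSE)
  if (cnv_prob < 0 || cnv_prob > 1 || hidden_fraction < 0 || hidden_fraction > 1) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(dup_event_rates) - 1) > 1e-8 || any(dup_event_rates < 0)) {
    stop("dup_event_rates must be non-negative and sum to 1", call. = FALSE)
  }
  if (length(tissue_names) != n_tissues) {
    cfg$tissue_names <- sprintf("tissue%02d", seq_len(n_tissues))
  }
  if (is.null(presence_freq_ranges)) {
    cfg$presence_freq_ranges <- list(core = c(1, 1), softcore = c(0.90, 1),
                                     shell = c(0.10, 0.90), cloud = c(0, 0.10))
  }
  cfg$presence_count_ranges <- .presence_count_ranges(cfg$presence_freq_ranges,
                                                      n_genomes)
  asked <- c(core = n_core, softcore = n_softcore, shell = n_shell,
             cloud = n_cloud)
  unsat <- names(asked)[asked > 0 & !names(asked) %in%
                          names(cfg$presence_count_ranges)]
  if (length(unsat) > 0L) {
    stop("n_genomes too small to realize category: ",
         paste(unsat, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Integer presence-count ranges per category, consistent with
# classify_category(): core = n; softcore = [ceil(0.9 n), n-1];
# shell = (0.1 n, 0.9 n) exclusive; cloud = [1, floor(0.1 n)].
.presence_count_ranges <- function(ranges, n) {
  soft_lo <- ceiling(ranges$softcore[1] * n)
  cloud_hi <- floor(ranges$cloud[2] * n)
  out <- list(core = c(n, n),
              softcore = c(soft_lo, n - 1L),
              shell = c(cloud_hi + 1L, soft_lo - 1L),
              cloud = c(1L, cloud_hi))
  for (cat in names(out)) {
    r <- out[[cat]]
    if (r[1] > r[2] || r[1] < 1L) { out[[cat]] <- NULL; next }
    cats <- classify_category(seq.int(r[1], r[2]), n)
    if (!all(cats == cat)) {
      stop("presence ranges inconsistent with category boundaries for ", cat,
           call. = FALSE)
    }
  }
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genomes x %d chromosomes (%d bp); ",
                     "pangenes %d core / %d softcore / %d shell / %d cloud ",
                     "in %d subfamilies; seed %d\n"),
              x$n_genomes, x$n_chromosomes, x$chromosome_length, x$n_core,
              x$n_softcore, x$n_shell, x$n_cloud, x$n_subfamilies, x$seed))
  invisible(x)
}

# --- low-level sequence helpers ---------------------------------------------

# codons per amino acid (stops excluded)
.codons_by_aa <- function() {
  if (!is.null(.panfam_cache$codons_by_aa)) return(.panfam_cache$codons_by_aa)
  gc <- .genetic_code()
  out <- split(names(gc), unname(gc))
  out[["*"]] <- NULL
  .panfam_cache$codons_by_aa <- out
  out
}

#' Random coding sequence
#'
#' Generates a CDS of `n_codons` coding codons (starting with ATG, no
#' internal stops) plus a terminal stop codon.
#'
#' @param n_codons Number of coding codons (including the initial ATG).
#' @return Character scalar of length `3 * (n_codons + 1)`.
#' @export
random_cds <- function(n_codons) {
  prot <- c("M", sample(.aa_alphabet(), n_codons - 1L, replace = TRUE))
  paste0(.backtranslate_protein(paste(prot, collapse = "")), "TAA")
}

# random codon choice per amino acid (no terminal stop added)
.backtranslate_protein <- function(prot) {
  tab <- .codons_by_aa()
  aa <- strsplit(prot, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# substitute a fraction of residues (uniform random replacement aa),
# optionally protecting the initial methionine
.mutate_protein <- function(prot, rate, protect_first = TRUE) {
  aa <- strsplit(prot, "")[[1]]
  eligible <- seq_along(aa)
  if (protect_first) eligible <- eligible[-1]
  n_mut <- round(rate * length(eligible))
  if (n_mut > 0L) {
    pos <- sample(eligible, n_mut)
    for (p in pos) aa[p] <- sample(setdiff(.aa_alphabet(), aa[p]), 1L)
  }
  paste(aa, collapse = "")
}

#' Mutate a CDS towards a target dN/dS
#'
#' Applies `n_events` accepted single-nucleotide substitutions to a coding
#' sequence. Proposals pick a uniform codon position, then a uniform
#' alternative nucleotide among those not creating a stop codon, matching
#' the per-position site normalization of the NG86 estimator; synonymous
#' proposals are accepted with probability `min(1, 1/omega)` and
#' nonsynonymous ones with probability `min(1, omega)`, so accepted
#' changes hit nonsynonymous vs synonymous sites in the ratio
#' `omega * N : S` expected by NG86. A terminal stop codon is preserved
#' untouched.
#'
#' @param ancestral_cds CDS (length divisible by 3, no internal stops).
#' @param omega Target dN/dS (> 0).
#' @param n_events Number of accepted substitution events (>= 0).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return The derived CDS (same length, no internal stops).
#' @export
mutate_cds_with_target_omega <- function(ancestral_cds, omega, n_events,
                                         seed = NULL) {
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  codons <- .split_codons(toupper(ancestral_cds))
  gc <- .genetic_code()
  coding <- seq_along(codons)
  if (gc[codons[length(codons)]] == "*") coding <- coding[-length(coding)]
  if (any(gc[codons[coding]] == "*")) {
    stop("ancestral CDS contains internal stop codons", call. = FALSE)
  }
  if (n_events == 0L) return(paste(codons, collapse = ""))
  nt <- c("A", "C", "G", "T")
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  accepted <- 0L
  guard <- 0L
  while (accepted < n_events) {
    guard <- guard + 1L
    if (guard > 10000L * n_events) stop("mutation proposal loop stalled", call. = FALSE)
    ci <- coding[sample.int(length(coding), 1L)]
    pos <- sample.int(3L, 1L)
    old <- codons[ci]
    alts <- setdiff(nt, substring(old, pos, pos))
    cands <- vapply(alts, function(a) {
      x <- old; substring(x, pos, pos) <- a; x
    }, character(1))
    cands <- cands[gc[cands] != "*"]
    if (length(cands) == 0L) next
    cand <- cands[sample.int(length(cands), 1L)]
    syn <- gc[cand] == gc[old]
    if (stats::runif(1) <= (if (syn) p_syn else p_non)) {
      codons[ci] <- cand
      accepted <- accepted + 1L
    }
  }
  paste(codons, collapse = "")
}

# --- TE landscape ------------------------------------------------------------

.te_class_vocab <- function() {
  list(classes = c("DNA/TcMar", "DNA/PIF-Harbinger", "DNA/MULE", "DNA/hAT",
                   "DNA/CACTA", "LTR/Copia", "LTR/Gypsy", "LINE", "SINE",
                   "Helitron", "other"),
       weights = c(0.17, 0.16, 0.15, 0.14, 0.13, 0.07, 0.07, 0.04, 0.03,
                   0.03, 0.01))
}

#' Simulate an intact-TE landscape around genes
#'
#' Places intact TEs so that the count inside each gene's flanking window
#' is Poisson with the gene's group rate (CNV vs non-CNV); TEs are placed
#' entirely within the window, so for non-overlapping windows the realized
#' window count equals the placed count. A configurable rate of non-intact
#' decoy TEs is added uniformly per window to exercise intactness
#' filtering.
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `end` and a
#'   logical `is_cnv` column.
#' @param rate_cnv,rate_noncnv Expected intact TEs per window (>= 0).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param flank Window flank in bp.
#' @param decoy_rate Expected non-intact TEs per window.
#' @param te_len_range Intact TE length range in bp.
#' @param seed Optional seed.
#' @return List: `te` (data.frame `chrom`, `start`, `end`, `te_class`,
#'   `intact`) and `truth` (data.frame `gene_id`, `n_te_window` of placed
#'   intact TEs).
#' @export
simulate_te_landscape <- function(genes, rate_cnv, rate_noncnv, chrom_lengths,
                                  flank = 2000, decoy_rate = 0.2,
                                  te_len_range = c(300, 800), seed = NULL) {
  if (rate_cnv < 0 || rate_noncnv < 0) stop("rates must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vocab <- .te_class_vocab()
  windows <- gene_flank_windows(genes, flank = flank, chrom_lengths = chrom_lengths)
  te_rows <- list()
  truth <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    rate <- if (isTRUE(genes$is_cnv[i])) rate_cnv else rate_noncnv
    n_int <- stats::rpois(1L, rate)
    n_dec <- stats::rpois(1L, decoy_rate)
    truth[i] <- n_int
    n_all <- n_int + n_dec
    if (n_all == 0L) next
    w0 <- windows$start[i]; w1 <- windows$end[i]
    lens <- sample(seq.int(te_len_range[1], te_len_range[2]), n_all, replace = TRUE)
    lens <- pmin(lens, max(1L, w1 - w0))
    starts <- w0 + floor(stats::runif(n_all) * (w1 - w0 - lens + 1))
    te_rows[[i]] <- data.frame(
      chrom = genes$chrom[i], start = as.integer(starts),
      end = as.integer(starts + lens),
      te_class = sample(vocab$classes, n_all, replace = TRUE,
                        prob = vocab$weights),
      intact = rep(c(TRUE, FALSE), c(n_int, n_dec)),
      stringsAsFactors = FALSE)
  }
  te <- if (length(te_rows) > 0L) do.call(rbind, te_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               te_class = character(), intact = logical(),
               stringsAsFactors = FALSE)
  rownames(te) <- NULL
  list(te = te,
       truth = data.frame(gene_id = genes$gene_id, n_te_window = truth,
                          stringsAsFactors = FALSE))
}

# --- expression --------------------------------------------------------------

# one Gamma draw per tissue with mean mu and CV from the link
.draw_tpm <- function(mu, link) {
  out <- numeric(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    cv <- link$cv0 * (mu[pos] + 1)^(-link$gamma) + link$cv_min
    shape <- 1 / cv^2
    out[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape / mu[pos])
  }
  out
}

.archetype_profile <- function(archetype, n_tissues) {
  switch(archetype,
         broad = rep(1, n_tissues),
         specific = { v <- rep(0.05, n_tissues)
                      v[sample.int(n_tissues, 1L)] <- 1; v },
         half = { v <- rep(0.1, n_tissues)
                  v[sample.int(n_tissues, ceiling(n_tissues / 2))] <- 1; v },
         stop("unknown archetype: ", archetype, call. = FALSE))
}

#' Simulate per-genome TPM tables for a set of pangenes
#'
#' Each pangene has an expected mean per tissue (base mean times an
#' archetype profile); per genome, TPM is drawn from a Gamma distribution
#' whose coefficient of variation decreases in the expected mean according
#' to the configured link, reproducing the
#' higher-expression/lower-variability pattern.
#'
#' @param pangenes Data.frame with `pangene`, `base_mean` and optionally
#'   `archetype` (`broad`, `specific` or `half`; default `broad`).
#' @param presence Logical matrix pangene x genome.
#' @param n_tissues Number of tissues (>= 1).
#' @param link List with `cv0`, `gamma`, `cv_min` (all > 0 except
#'   `cv_min >= 0`).
#' @param tissue_names Optional tissue names.
#' @param seed Optional seed.
#' @return Named list genome -> data.frame (`gene_id` = pangene id plus
#'   one non-negative TPM column per tissue).
#' @export
simulate_expression_matrix <- function(pangenes, presence, n_tissues = 5,
                                       link = list(cv0 = 1.2, gamma = 0.4,
                                                   cv_min = 0.15),
                                       tissue_names = NULL, seed = NULL) {
  if (n_tissues < 1) stop("n_tissues must be >= 1", call. = FALSE)
  if (!all(c("cv0", "gamma", "cv_min") %in% names(link)) ||
      link$cv0 < 0 || link$cv_min < 0) {
    stop("invalid mean-CV link parameters", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tissue_names)) tissue_names <- sprintf("tissue%02d", seq_len(n_tissues))
  if (is.null(pangenes$archetype)) pangenes$archetype <- "broad"
  profiles <- lapply(seq_len(nrow(pangenes)), function(i) {
    pangenes$base_mean[i] * .archetype_profile(pangenes$archetype[i], n_tissues)
  })
  names(profiles) <- pangenes$pangene
  out <- list()
  for (g in colnames(presence)) {
    present <- pangenes$pangene[presence[pangenes$pangene, g]]
    if (length(present) == 0L) {
      tab <- as.data.frame(setNames(c(list(character(0)),
                                      rep(list(numeric(0)), n_tissues)),
                                    c("gene_id", tissue_names)))
    } else {
      vals <- t(vapply(present, function(p) .draw_tpm(profiles[[p]], link),
                       numeric(n_tissues)))
      tab <- data.frame(gene_id = present, vals, stringsAsFactors = FALSE)
      names(tab) <- c("gene_id", tissue_names)
    }
    out[[g]] <- tab
  }
  out
}

# --- architecture, presence and layout ---------------------------------------

.make_architecture <- function(cfg) {
  root_domain <- .random_aa(cfg$domain_aa)
  n_pg <- cfg$n_core + cfg$n_softcore + cfg$n_shell + cfg$n_cloud
  categories <- rep(c("core", "softcore", "shell", "cloud"),
                    c(cfg$n_core, cfg$n_softcore, cfg$n_shell, cfg$n_cloud))
  sf_ids <- sprintf("SF%02d", seq_len(cfg$n_subfamilies))
  # subfamily ancestors: shared flanks + diverged domain copies
  sf_prot <- vapply(sf_ids, function(sf) {
    dom <- .mutate_protein(root_domain, cfg$subfamily_divergence,
                           protect_first = FALSE)
    flank1 <- paste0("M", .random_aa(cfg$domain_offset_aa - 1L))
    flank2 <- .random_aa(cfg$gene_codons - cfg$domain_offset_aa - cfg$domain_aa)
    paste0(flank1, dom, flank2)
  }, character(1))

  # subfamily assignment: round-robin, optionally concentrating dispensables
  sf_of <- integer(n_pg)
  if (is.null(cfg$dispensable_subfamilies)) {
    sf_of <- (seq_len(n_pg) - 1L) %% cfg$n_subfamilies + 1L
  } else {
    disp <- categories != "core"
    pool <- cfg$dispensable_subfamilies
    core_pool <- setdiff(seq_len(cfg$n_subfamilies), pool)
    if (length(core_pool) == 0L) core_pool <- seq_len(cfg$n_subfamilies)
    sf_of[disp] <- pool[(seq_len(sum(disp)) - 1L) %% length(pool) + 1L]
    sf_of[!disp] <- core_pool[(seq_len(sum(!disp)) - 1L) %% length(core_pool) + 1L]
  }
  pangene_ids <- sprintf("PG%03d", seq_len(n_pg))
  prot <- character(n_pg); cds <- character(n_pg)
  for (i in seq_len(n_pg)) {
    prot[i] <- .mutate_protein(sf_prot[[sf_of[i]]], cfg$pangene_divergence)
    cds[i] <- paste0(.backtranslate_protein(prot[i]), "TAA")
  }
  dom_span <- c(cfg$domain_offset_aa + 1L, cfg$domain_offset_aa + cfg$domain_aa)
  list(pangenes = data.frame(pangene = pangene_ids, category = categories,
                             subfamily = sf_ids[sf_of],
                             ancestor_protein = prot, ancestor_cds = cds,
                             stringsAsFactors = FALSE),
       subfamily_domains = vapply(sf_prot, substring, character(1),
                                  dom_span[1], dom_span[2]),
       root_domain = root_domain)
}

.plan_presence <- function(cfg, pangenes) {
  genome_ids <- sprintf("G%02d", seq_len(cfg$n_genomes))
  n_pg <- nrow(pangenes)
  presence <- matrix(FALSE, n_pg, cfg$n_genomes,
                     dimnames = list(pangenes$pangene, genome_ids))
  for (i in seq_len(n_pg)) {
    rng <- cfg$presence_count_ranges[[pangenes$category[i]]]
    cnt <- if (rng[1] >= rng[2]) rng[1] else
      sample(seq.int(rng[1], rng[2]), 1L)
    presence[i, sample(genome_ids, cnt)] <- TRUE
  }
  presence
}

.plan_cnv <- function(cfg, pangenes, presence) {
  n_cnv <- round(cfg$cnv_prob * nrow(pangenes))
  if (n_cnv == 0L) {
    return(data.frame(pangene = character(), dup_type = character(),
                      stringsAsFactors = FALSE))
  }
  chosen <- sample(pangenes$pangene, n_cnv)
  types <- sample(names(cfg$dup_event_rates), n_cnv, replace = TRUE,
                  prob = cfg$dup_event_rates)
  if (cfg$segmental_core_only) {
    non_core <- pangenes$category[match(chosen, pangenes$pangene)] != "core"
    fix <- which(types == "segmental" & non_core)
    if (length(fix) > 0L) {
      rates <- cfg$dup_event_rates[names(cfg$dup_event_rates) != "segmental"]
      types[fix] <- sample(names(rates), length(fix), replace = TRUE,
                           prob = rates / sum(rates))
    }
  }
  plans <- lapply(seq_len(n_cnv), function(i) {
    present_in <- colnames(presence)[presence[chosen[i], ]]
    n_g <- min(length(present_in), sample.int(cfg$cnv_max_genomes, 1L))
    gnms <- sample(present_in, n_g)
    data.frame(pangene = chosen[i], dup_type = types[i], genome = gnms,
               extra_copies = sample(seq.int(1L, cfg$cnv_max_copies - 1L),
                                     n_g, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, plans)
}

# pangene -> (chrom, slot) home assignment, cycling subfamilies so that
# neighbouring family slots on a chromosome belong to different subfamilies
.assign_slots <- function(cfg, pangenes) {
  queues <- split(seq_len(nrow(pangenes)), pangenes$subfamily)
  order_idx <- integer(0)
  repeat {
    advanced <- FALSE
    for (sf in names(queues)) {
      if (length(queues[[sf]]) > 0L) {
        order_idx <- c(order_idx, queues[[sf]][1])
        queues[[sf]] <- queues[[sf]][-1]
        advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  n_pg <- length(order_idx)
  chrom <- sprintf("chr%d", (seq_len(n_pg) - 1L) %% cfg$n_chromosomes + 1L)
  slot <- integer(n_pg)
  for (cc in unique(chrom)) slot[chrom == cc] <- seq_len(sum(chrom == cc))
  data.frame(pangene = pangenes$pangene[order_idx], chrom = chrom,
             slot = slot, stringsAsFactors = FALSE)
}
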