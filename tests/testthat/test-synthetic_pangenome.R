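# The synthetic pangenome generator: configuration, determinism,
# ground-truth consistency and the per-feature simulators.

test_that("configuration validates counts, fractions and rates", {
  expect_error(sim_config(omega_core = 0), "omega")
  expect_error(sim_config(te_rate_cnv = -1), "TE rates")
  expect_error(sim_config(cnv_prob = 1.5), "fractions")
  expect_error(sim_config(dup_event_rates = c(tandem = 0.5, proximal = 0.2,
                                              dispersed = 0.2, segmental = 0.2)),
               "sum to 1")
  expect_error(sim_config(n_genomes = 6, n_softcore = 2), "too small")
  cfg <- sim_config()
  expect_equal(cfg$presence_count_ranges$softcore, c(18, 19))
  expect_equal(cfg$presence_count_ranges$shell, c(3, 17))
  expect_equal(cfg$presence_count_ranges$cloud, c(1, 2))
})

test_that("mutating with zero events is the identity; omega -> 0 suppresses amino-acid change", {
  set.seed(81)
  cds <- random_cds(80)
  expect_equal(mutate_cds_with_target_omega(cds, 0.5, 0), cds)
  derived <- mutate_cds_with_target_omega(cds, 1e-9, 40)
  expect_equal(panfam:::.translate_cds(derived), panfam:::.translate_cds(cds))
  expect_false(derived == cds)  # synonymous changes did land
  expect_error(mutate_cds_with_target_omega(cds, -1, 5), "omega")
  expect_error(mutate_cds_with_target_omega(cds, 0.5, -1), "n_events")
  expect_error(mutate_cds_with_target_omega("ATGTAAAAATTT", 0.5, 1), "stop")
  # derived CDS keeps length and stays stop-free internally
  d2 <- mutate_cds_with_target_omega(cds, 0.8, 25)
  expect_equal(nchar(d2), nchar(cds))
  expect_false(grepl("\\*", panfam:::.translate_cds(d2)))
})

test_that("NG86 recovers the target omega from mutated sequences on average", {
  set.seed(82)
  anc <- random_cds(100)
  est <- replicate(50, {
    ng86_pair(c(anc, mutate_cds_with_target_omega(anc, 0.5, 30)))$omega
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.5), 0.15)
})

test_that("TE landscape respects rates, intactness and zero cases", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      chrom = "chr1",
                      start = seq(10000, by = 20000, length.out = 200))
  genes$end <- genes$start + 1000
  genes$is_cnv <- rep(c(TRUE, FALSE), 100)
  lens <- c(chr1 = max(genes$end) + 20000)
  z <- simulate_te_landscape(genes, 0, 0, lens, decoy_rate = 0, seed = 83)
  expect_equal(nrow(z$te), 0L)
  expect_true(all(z$truth$n_te_window == 0L))
  sim <- simulate_te_landscape(genes, 1.5, 1.0, lens, seed = 84)
  w <- gene_flank_windows(genes, 2000, lens)
  counted <- count_intact_te_per_gene(w, sim$te)$per_gene
  # placed counts are recovered exactly for disjoint windows
  expect_equal(counted$n_te, sim$truth$n_te_window)
  m_cnv <- mean(sim$truth$n_te_window[genes$is_cnv])
  m_non <- mean(sim$truth$n_te_window[!genes$is_cnv])
  expect_lt(abs(m_cnv - 1.5), 3 * sqrt(1.5 / 100))
  expect_lt(abs(m_non - 1.0), 3 * sqrt(1.0 / 100))
  expect_error(simulate_te_landscape(genes, -0.5, 1, lens), "rates")
})

test_that("a single gene window hits its Poisson rate over many seeds", {
  gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 50000,
                     end = 51000, is_cnv = TRUE)
  lens <- c(chr1 = 200000)
  counts <- vapply(1:500, function(s)
    simulate_te_landscape(gene, 2.0, 0, lens, seed = s)$truth$n_te_window,
    numeric(1))
  expect_lt(abs(mean(counts) - 2.0), 3 * sqrt(2.0 / 500))
})

test_that("expression matrices are non-negative with a decreasing mean-CV link", {
  pg <- data.frame(pangene = c("lo", "hi", "zero"),
                   base_mean = c(1, 100, 0))
  presence <- matrix(TRUE, 3, 12,
                     dimnames = list(pg$pangene, sprintf("G%02d", 1:12)))
  tabs <- simulate_expression_matrix(pg, presence, n_tissues = 3, seed = 85)
  all_vals <- do.call(rbind, lapply(tabs, function(t) as.matrix(t[, -1])))
  expect_true(all(all_vals >= 0))
  zero_rows <- do.call(rbind, lapply(tabs, function(t) t[t$gene_id == "zero", -1]))
  expect_true(all(zero_rows == 0))
  # low-mean pangene shows the larger relative SD in most replicates
  wins <- 0
  for (s in 1:50) {
    tabs_s <- simulate_expression_matrix(pg[1:2, ], presence[1:2, ],
                                         n_tissues = 3, seed = 1000 + s)
    summ <- pangene_expression_summary(tabs_s, c(lo = "lo", hi = "hi"))
    rel <- tapply(summ$rel_sd, summ$pangene, mean)
    if (rel[["lo"]] > rel[["hi"]]) wins <- wins + 1
  }
  expect_gte(wins / 50, 0.8)
  expect_error(simulate_expression_matrix(pg, presence, n_tissues = 0), "n_tissues")
  expect_error(simulate_expression_matrix(pg, presence, link = list(cv0 = -1)),
               "link")
})

test_that("a degenerate all-core configuration puts every pangene everywhere", {
  cfg <- sim_config(n_genomes = 5, n_core = 6, n_softcore = 0, n_shell = 0,
                    n_cloud = 0, n_subfamilies = 3, cnv_prob = 0,
                    hidden_fraction = 0, chromosome_length = 150000, seed = 9)
  sp <- simulate_pangenome(cfg, dir = tempfile())
  expect_true(all(sp$presence))
  expect_true(all(sp$truth_pangenes$presence_count == 5))
  expect_true(all(sp$truth_genes$status == "annotated"))
})

test_that("identical seeds give byte-identical corpora; different seeds differ", {
  cfg <- sim_config(n_genomes = 4, n_core = 4, n_softcore = 0, n_shell = 2,
                    n_cloud = 0, n_subfamilies = 3,
                    chromosome_length = 150000, seed = 77)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_pangenome(cfg, dir = d1)
  simulate_pangenome(cfg, dir = d2)
  cfg2 <- cfg; cfg2$seed <- 78
  simulate_pangenome(cfg2, dir = d3)
  files <- list.files(d1, recursive = TRUE)
  md5 <- function(d) unname(tools::md5sum(file.path(d, files)))
  expect_identical(md5(d1), md5(d2))
  expect_false(all(md5(d1) == md5(d3)))
})

test_that("re-parsing emitted GFF3 and FASTA reconstructs the truth genes", {
  sp <- tiny_corpus()
  g <- sp$genome_ids[1]
  paths <- read_pangenome_dir(sp$dir)$paths[[g]]
  ann <- panfam:::.read_gff3_genes(paths$gff3)
  truth_ann <- sp$genes[sp$genes$genome == g & sp$genes$status == "annotated", ]
  expect_setequal(ann$gene_id, truth_ann$gene_id)
  idx <- match(ann$gene_id, truth_ann$gene_id)
  expect_equal(ann$start, truth_ann$start[idx])
  expect_equal(ann$end, truth_ann$end[idx])
  # CDS extracted from the assembly at GFF3 coordinates equals the CDS FASTA
  genome <- Biostrings::readDNAStringSet(paths$assembly)
  cds_fa <- Biostrings::readDNAStringSet(paths$cds)
  set.seed(86)
  for (i in sample(nrow(ann), 25)) {
    span <- as.character(Biostrings::subseq(genome[[ann$chrom[i]]],
                                            ann$start[i] + 1L, ann$end[i]))
    if (ann$strand[i] == "-") span <- panfam:::.revcomp(span)
    expect_equal(span, as.character(cds_fa[[ann$gene_id[i]]]))
  }
})

test_that("realized presence recounted from the GFF3s matches truth categories", {
  sp <- tiny_corpus()
  inputs <- read_pangenome_dir(sp$dir)
  counts <- setNames(integer(nrow(sp$truth_pangenes)), sp$truth_pangenes$pangene)
  for (g in sp$genome_ids) {
    ann <- panfam:::.read_gff3_genes(inputs$paths[[g]]$gff3)
    tg <- sp$truth_genes[sp$truth_genes$genome == g, ]
    present <- unique(tg$pangene[tg$gene_id %in% ann$gene_id |
                                   tg$status == "hidden"])
    counts[present] <- counts[present] + 1L
  }
  expect_equal(unname(counts), sp$truth_pangenes$presence_count)
  realized_cat <- classify_category(counts, length(sp$genome_ids))
  expect_gte(mean(realized_cat == sp$truth_pangenes$category), 0.95)
  # every configured presence count is inside its category range
  rng <- sp$config$presence_count_ranges
  for (i in seq_len(nrow(sp$truth_pangenes))) {
    r <- rng[[sp$truth_pangenes$category[i]]]
    expect_gte(sp$truth_pangenes$presence_count[i], r[1])
    expect_lte(sp$truth_pangenes$presence_count[i], r[2])
  }
})

test_that("a too-short chromosome fails with a placement error", {
  cfg <- sim_config(n_genomes = 4, n_core = 4, n_softcore = 0, n_shell = 2,
                    n_cloud = 0, n_subfamilies = 3,
                    chromosome_length = 20000, seed = 5)
  expect_error(simulate_pangenome(cfg, dir = tempfile()),
               "chromosome too short")
})
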