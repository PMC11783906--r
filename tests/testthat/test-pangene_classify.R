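# PAV/CNV matrices, conservation categories and systematic names.

test_that("category boundaries match the closed-form table for 20 genomes", {
  # enumeration oracle: category from the printed fraction thresholds
  oracle <- function(k, n) {
    f <- k / n
    if (k == n) "core" else if (f >= 0.9) "softcore"
    else if (f <= 0.1) "cloud" else "shell"
  }
  for (k in 1:20) {
    expect_equal(classify_category(k, 20), oracle(k, 20), info = paste("k =", k))
  }
  expect_equal(classify_category(20, 20), "core")
  expect_equal(classify_category(18, 20), "softcore")
  expect_equal(classify_category(2, 20), "cloud")
  expect_equal(classify_category(3, 20), "shell")
  expect_error(classify_category(0, 20), "absent")
  # monotone in presence count: category rank never inverts
  rank <- c(cloud = 1, shell = 2, softcore = 3, core = 4)
  ranks <- rank[classify_category(1:20, 20)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("PAV/CNV matrices count members per genome", {
  genomes <- setNames(c(rep(sprintf("G%02d", 1:20), 1), "G03", "G03"),
                      c(sprintf("a%02d", 1:20), "b1", "b2"))
  oggs <- list(OGG1 = sprintf("a%02d", 1:20), OGG2 = c("b1", "b2"))
  m <- build_pav_cnv_matrices(oggs, genomes, sprintf("G%02d", 1:20))
  expect_equal(unname(m$cnv["OGG1", ]), rep(1L, 20))
  expect_equal(sum(m$cnv["OGG2", ]), 2L)
  expect_equal(unname(m$cnv["OGG2", "G03"]), 2L)
  expect_equal(m$pav, m$cnv >= 1L)
  expect_error(build_pav_cnv_matrices(oggs, genomes, sprintf("G%02d", 1:2)),
               "unknown genome")
  expect_true(has_cnv(m)[["OGG2"]])
  expect_false(has_cnv(m)[["OGG1"]])
})

test_that("systematic names continue numbering across categories", {
  set.seed(31)
  n_core <- 140; n_soft <- 12
  tab <- data.frame(
    ogg_id = sprintf("OGG%04d", 1:(n_core + n_soft)),
    category = rep(c("core", "softcore"), c(n_core, n_soft)),
    anchor_chrom = "chr1",
    anchor_start = sample.int(1e6, n_core + n_soft))
  nm <- name_pangenes(tab, prefix = "HvTEST")
  core_names <- sort(nm[tab$category == "core"])
  soft_names <- sort(nm[tab$category == "softcore"])
  expect_equal(core_names[[n_core]], "HvTEST.CR140")
  expect_equal(soft_names[[1]], "HvTEST.SC141")
  expect_equal(anyDuplicated(nm), 0L)
})

test_that("names follow genomic location order and full category sequence", {
  tab <- data.frame(ogg_id = c("A", "B", "C", "D", "E"),
                    category = c("core", "core", "shell", "cloud", "softcore"),
                    anchor_chrom = c("chr1", "chr1", "chr2", "chr1", "chr3"),
                    anchor_start = c(500, 100, 50, 10, 10))
  nm <- name_pangenes(tab, prefix = "F")
  expect_equal(unname(nm["B"]), "F.CR001")  # chr1:100 before chr1:500
  expect_equal(unname(nm["A"]), "F.CR002")
  expect_equal(unname(nm["E"]), "F.SC003")  # continues after 2 core
  expect_equal(unname(nm["C"]), "F.SH004")
  expect_equal(unname(nm["D"]), "F.CL005")  # index = total preceding + 1
  tab$anchor_start[1] <- NA
  expect_error(name_pangenes(tab), "anchor")
})

test_that("category summaries partition the pangenes and genes", {
  genomes <- setNames(rep(c("G01", "G02"), each = 3),
                      c("x1", "x2", "x3", "y1", "y2", "y3"))
  oggs <- list(OGG1 = c("x1", "y1"), OGG2 = c("x2", "y2"), OGG3 = c("x3", "y3"))
  m <- build_pav_cnv_matrices(oggs, genomes, c("G01", "G02"))
  cats <- setNames(classify_category(rowSums(m$pav), 2), rownames(m$pav))
  members <- data.frame(gene_id = names(genomes), genome = unname(genomes),
                        status = c("annotated", "annotated", "newly_predicted",
                                   "annotated", "annotated", "annotated"))
  membership <- setNames(rep(names(oggs), 2),
                         c("x1", "x2", "x3", "y1", "y2", "y3"))
  s <- summarize_categories(m, cats, members, membership)
  expect_equal(sum(s$category_totals$n_pangenes), 3L)
  expect_equal(sum(s$per_genome$n_genes), nrow(members))
  # all-core corpus: dispensable counts all zero
  disp <- s$per_genome[s$per_genome$conservation == "dispensable", "n_genes"]
  expect_true(all(disp == 0))
})

test_that("anchors prefer the reference genome, then the first carrier", {
  members <- data.frame(
    gene_id = c("G01.a", "G02.a", "G03.b", "G02.b"),
    genome = c("G01", "G02", "G03", "G02"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100, 200, 50, 70))
  oggs <- structure(list(
    clusters = list(OGG1 = c("G01.a", "G02.a"), OGG2 = c("G03.b", "G02.b")),
    representatives = c(OGG1 = "G01.a", OGG2 = "G03.b"),
    membership = setNames(c("OGG1", "OGG1", "OGG2", "OGG2"),
                          members$gene_id)), class = "ogg_set")
  a <- pangene_anchors(oggs, members, reference_genome = "G01")
  expect_equal(a$anchor_start[a$ogg_id == "OGG1"], 100)
  # OGG2 absent from G01: lexicographically first carrier G02 anchors it
  expect_equal(a$anchor_start[a$ogg_id == "OGG2"], 70)
})
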