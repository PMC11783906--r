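# Duplication-mechanism classification: hits, ranks, blocks, five rules.

grid_genes <- function(n_per_chrom, chroms = c("c1", "c2")) {
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(gene_id = sprintf("%s_g%02d", ch, seq_len(n_per_chrom)),
               chrom = ch, start = seq(100, by = 100, length.out = n_per_chrom))
  }))
}

test_that("gene ranks are recomputed per chromosome from coordinates", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  chrom = c("c1", "c1", "c2", "c1"),
                  start = c(500, 100, 50, 300))
  r <- gene_rank_index(g)
  rk <- setNames(r$rank, r$gene_id)
  expect_equal(unname(rk[c("b", "d", "a")]), c(0L, 1L, 2L))
  expect_equal(unname(rk["c"]), 0L)
  expect_error(gene_rank_index(rbind(g, g[1, ])), "duplicated")
})

test_that("top-k retention keeps k best hits and excludes self-hits", {
  set.seed(41)
  base <- rand_protein(120)
  prot <- setNames(c(vapply(1:7, function(i) mutate_protein_frac(base, 0.02),
                            character(1)),
                     rand_protein(120)),
                   c(sprintf("p%d", 1:7), "solo"))
  hits <- all_vs_all_top_hits(prot, k = 5, engine = "native")
  expect_true(all(hits$query != hits$subject))
  per_q <- table(hits$query)
  expect_true(all(per_q[sprintf("p%d", 1:7)] == 5L))
  expect_false("solo" %in% hits$query)
  # symmetric scores on ungapped equal-length pairs
  h12 <- hits$bit_score[hits$query == "p1" & hits$subject == "p2"]
  h21 <- hits$bit_score[hits$query == "p2" & hits$subject == "p1"]
  expect_equal(h12, h21)
})

test_that("blast and native engines agree on near-identical paralog sets", {
  set.seed(42)
  base <- rand_protein(150)
  prot <- setNames(c(vapply(1:5, function(i) mutate_protein_frac(base, 0.03),
                            character(1)),
                     vapply(1:5, function(i) rand_protein(150), character(1))),
                   sprintf("q%02d", 1:10))
  hb <- all_vs_all_top_hits(prot, k = 5, engine = "blast")
  hn <- all_vs_all_top_hits(prot, k = 5, engine = "native")
  pair_set <- function(h) sort(paste(h$query, h$subject))
  expect_equal(pair_set(hb), pair_set(hn))
})

test_that("outfmt-6 tables are parsed with identity as a fraction", {
  f <- tempfile()
  writeLines(c("q1\ts1\t97.50\t200\t5\t0\t1\t200\t1\t200\t1e-50\t350",
               "q1\ts2\t88.00\t150\t18\t1\t10\t159\t5\t150\t2e-30\t210"), f)
  h <- read_blast_outfmt6(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$identity, c(0.975, 0.88))
  expect_equal(h$bit_score, c(350, 210))
  file.create(f2 <- tempfile())
  expect_equal(nrow(read_blast_outfmt6(f2)), 0L)
})

test_that("a duplicated run of 6 genes forms one block; 4 genes form none", {
  g <- grid_genes(30)
  rk <- gene_rank_index(g)
  hits6 <- data.frame(query = sprintf("c1_g%02d", 3:8),
                      subject = sprintf("c2_g%02d", 13:18))
  b <- detect_collinear_blocks(rk, hits6)
  expect_equal(length(unique(b$block_id)), 1L)
  expect_equal(nrow(b), 6L)
  expect_equal(b$orientation[1], "same")
  hits4 <- hits6[1:4, ]
  expect_equal(nrow(detect_collinear_blocks(rk, hits4)), 0L)
  # reversed orientation run is chained as a descending block
  hits_rev <- data.frame(query = sprintf("c1_g%02d", 3:8),
                         subject = sprintf("c2_g%02d", 18:13))
  b_rev <- detect_collinear_blocks(rk, hits_rev)
  expect_equal(nrow(b_rev), 6L)
  expect_equal(unique(b_rev$orientation), "reversed")
  # anchors exceeding the rank gap do not chain
  hits_gap <- data.frame(query = sprintf("c1_g%02d", c(1, 28)),
                         subject = sprintf("c2_g%02d", c(1, 28)))
  expect_equal(nrow(detect_collinear_blocks(rk, hits_gap, min_anchors = 2)), 0L)
})

test_that("the five rules label constructed fixtures including boundaries", {
  g <- grid_genes(40)
  rk_of <- function(i) sprintf("c1_g%02d", i + 1)  # rank i = (i+1)-th gene
  hits <- data.frame(
    query = c(rk_of(10), rk_of(10), rk_of(10), "c1_g01"),
    subject = c(rk_of(11), rk_of(29), rk_of(30), "c2_g05"))
  # tandem pair (10, 11); proximal (10, 29) diff 19; dispersed (10, 30) diff 20
  lab <- classify_duplication_types(g, hits[2, , drop = FALSE])
  expect_equal(unname(lab[c(rk_of(10), rk_of(29))]), rep("proximal", 2))
  lab <- classify_duplication_types(g, hits[3, , drop = FALSE])
  expect_equal(unname(lab[c(rk_of(10), rk_of(30))]), rep("dispersed", 2))
  lab <- classify_duplication_types(g, hits)
  expect_equal(unname(lab[rk_of(10)]), "tandem")     # rank diff 1 wins over 19
  expect_equal(unname(lab["c1_g01"]), "dispersed")   # cross-chromosome
  expect_equal(unname(lab["c1_g20"]), "singleton")   # no hits at all
  expect_error(classify_duplication_types(g, data.frame(query = "zz",
                                                        subject = "c1_g01")),
               "unknown gene")
})

test_that("block anchors override small-scale labels (rule 5)", {
  g <- grid_genes(30)
  rk <- gene_rank_index(g)
  hits <- rbind(data.frame(query = sprintf("c1_g%02d", 3:8),
                           subject = sprintf("c2_g%02d", 13:18)),
                data.frame(query = "c1_g03", subject = "c1_g04"))  # also tandem
  blocks <- detect_collinear_blocks(rk, hits)
  lab <- classify_duplication_types(g, hits, blocks)
  expect_equal(unname(lab["c1_g03"]), "wgd_segmental")
  expect_equal(unname(lab["c2_g13"]), "wgd_segmental")
})

test_that("labels equal the literal-rule oracle and ignore hit order", {
  set.seed(43)
  for (rep_i in 1:5) {
    g <- grid_genes(50)
    pool <- g$gene_id
    hits <- unique(data.frame(query = sample(pool, 30, replace = TRUE),
                              subject = sample(pool, 30, replace = TRUE)))
    hits <- hits[hits$query != hits$subject, ]
    blocks <- detect_collinear_blocks(gene_rank_index(g), hits)
    anchors <- unique(c(blocks$gene_a, blocks$gene_b))
    lab <- classify_duplication_types(g, hits, blocks)
    lab_oracle <- oracle_dup_labels(g, hits, anchors)
    expect_equal(lab[sort(names(lab))], lab_oracle[sort(names(lab_oracle))])
    shuffled <- hits[sample(nrow(hits)), ]
    lab2 <- classify_duplication_types(g, shuffled, blocks)
    expect_equal(lab[sort(names(lab))], lab2[sort(names(lab2))])
  }
})
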