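# Expression summaries, profile clustering and tanglegram metrics.

mk_tables <- function(values) {
  # values: list genome -> named list gene -> tissue vector
  n_tissue <- max(vapply(values, function(v)
    if (length(v)) length(v[[1]]) else 0L, integer(1)))
  lapply(values, function(v) {
    if (length(v) == 0L) {
      tab <- as.data.frame(setNames(c(list(character(0)),
                                      rep(list(numeric(0)), n_tissue)),
                                    c("gene_id", paste0("t", seq_len(n_tissue)))))
      return(tab)
    }
    tab <- data.frame(gene_id = names(v),
                      do.call(rbind, v), stringsAsFactors = FALSE)
    names(tab) <- c("gene_id", paste0("t", seq_len(n_tissue)))
    tab
  })
}

test_that("summary transforms match hand computation", {
  tabs <- mk_tables(list(G1 = list(a = c(3, 0)), G2 = list(a = c(3, 0)),
                         G3 = list(a = c(3, 0))))
  s <- pangene_expression_summary(tabs, c(a = "P1"))
  t1 <- s[s$tissue == "t1", ]
  expect_equal(t1$mean_tpm, 3)
  expect_equal(t1$sd_tpm, 0)
  expect_equal(t1$norm_mean, 2)          # log2(3 + 1)
  expect_equal(t1$rel_sd, 0)
  t2 <- s[s$tissue == "t2", ]
  expect_equal(t2$norm_mean, 0)          # zero expression everywhere
  expect_equal(t2$rel_sd, 0)             # mean 0 -> defined as 0
})

test_that("relative SD equals log2(SD/mean + 1) to 1e-12", {
  vals <- c(2.5, 7.25, 4.0)
  tabs <- mk_tables(list(G1 = list(a = vals[1]), G2 = list(a = vals[2]),
                         G3 = list(a = vals[3])))
  s <- pangene_expression_summary(tabs, c(a = "P1"))
  expect_equal(s$rel_sd, log2(sd(vals) / mean(vals) + 1), tolerance = 1e-12)
  expect_equal(s$norm_mean, log2(mean(vals) + 1), tolerance = 1e-12)
})

test_that("averaging is presence-aware and copies sum within a genome", {
  tabs <- mk_tables(list(G1 = list(a1 = 4, a2 = 6), G2 = list(b = 10),
                         G3 = list()))
  membership <- c(a1 = "P1", a2 = "P1", b = "P1")
  s <- pangene_expression_summary(tabs, membership)
  expect_equal(s$n_genomes, 2L)             # G3 lacks the pangene
  expect_equal(s$mean_tpm, mean(c(10, 10))) # copies summed per genome
  # removing the absent genome changes nothing
  s2 <- pangene_expression_summary(tabs[c("G1", "G2")], membership)
  expect_equal(s$mean_tpm, s2$mean_tpm)
  expect_equal(s$sd_tpm, s2$sd_tpm)
})

test_that("archetype profiles cluster into their three groups", {
  set.seed(61)
  genomes <- sprintf("G%02d", 1:6)
  genes <- c(sprintf("hi%02d", 1:4), sprintf("sp%02d", 1:4), sprintf("hf%02d", 1:4))
  prof <- function(g) {
    if (grepl("^hi", g)) rep(100, 5)
    else if (grepl("^sp", g)) c(100, rep(0.5, 4))
    else c(100, 100, 100, 0.5, 0.5)
  }
  tabs <- lapply(genomes, function(gn) {
    v <- lapply(genes, function(g) prof(g) * runif(5, 0.9, 1.1))
    names(v) <- genes
    tab <- data.frame(gene_id = genes, do.call(rbind, v))
    names(tab) <- c("gene_id", paste0("t", 1:5))
    tab
  })
  names(tabs) <- genomes
  s <- pangene_expression_summary(tabs, setNames(toupper(genes), genes))
  cl <- cluster_expression_profiles(s, k = 3)
  grp <- split(names(cl$clusters), cl$clusters)
  sig <- sort(vapply(grp, function(g) paste(sort(unique(substr(tolower(g), 1, 2))),
                                            collapse = ""), character(1)))
  expect_equal(unname(sig), c("hf", "hi", "sp"))
  cl1 <- cluster_expression_profiles(s, k = 1)
  expect_equal(length(unique(cl1$clusters)), 1L)
  expect_error(cluster_expression_profiles(s, k = 50), "exceeds")
})

test_that("crossing counts match trivial cases and the brute-force oracle", {
  expect_equal(compare_tree_orders(letters[1:5], letters[1:5])$crossings, 0L)
  rev4 <- compare_tree_orders(letters[1:4], letters[4:1])
  expect_equal(rev4$crossings, 6L)
  expect_equal(rev4$entanglement, 1)
  set.seed(62)
  for (i in 1:10) {
    left <- sample(letters[1:20])
    right <- sample(letters[1:20])
    m <- compare_tree_orders(left, right)
    expect_equal(m$crossings, oracle_crossings(left, right))
  }
  expect_error(compare_tree_orders("a", c("a", "b")), "shared")
})

test_that("subfamily divergence ranks scattering subfamilies first", {
  left <- sprintf("g%02d", 1:12)
  right <- c("g01", "g02", "g03", "g04",           # SF1 stays put
             "g09", "g06", "g11", "g08", "g05", "g10", "g07", "g12")
  sf <- setNames(rep(c("SF1", "SF2", "SF3"), each = 4), left)
  m <- compare_tree_orders(left, right, subfamilies = sf)
  expect_equal(m$subfamily_divergence$subfamily[3], "SF1")
  expect_equal(m$subfamily_divergence$divergence[3], 0)
})

test_that("mean vs relative-SD correlation behaves on monotone and constant input", {
  s <- data.frame(pangene = sprintf("p%02d", 1:10), tissue = "t1",
                  norm_mean = 1:10, rel_sd = 10:1)
  r <- correlate_mean_vs_relsd(s)
  expect_equal(r$rho, -1)
  expect_lt(r$p_value, 0.05)
  s$rel_sd <- 5
  r2 <- correlate_mean_vs_relsd(s)
  expect_true(r2$constant)
  expect_true(is.na(r2$rho))
  expect_error(correlate_mean_vs_relsd(s[1:2, ]), "points")
})
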