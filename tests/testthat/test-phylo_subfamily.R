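# Domain alignment, NJ reconstruction and subfamily assignment.

test_that("identical sequences align gapless; a deletion yields a single gap", {
  a <- "MKVLAANGGHWETRYKLPQSDFICWHNTEE"
  aln <- align_domains(c(s1 = a, s2 = a))
  expect_equal(unname(aln["s1"]), a)
  expect_equal(unname(aln["s2"]), a)
  b <- paste0(substr(a, 1, 9), substr(a, 13, 30))  # internal 3-aa deletion
  aln2 <- align_domains(c(s1 = a, s2 = b))
  expect_equal(gsub("-", "", aln2[["s2"]]), b)      # ungap recovers input
  expect_equal(nchar(aln2[["s1"]]), nchar(aln2[["s2"]]))
  expect_gte(nchar(aln2[["s1"]]), nchar(a))         # columns >= max input length
  expect_equal(sum(strsplit(aln2[["s2"]], "")[[1]] == "-"), 3L)
  expect_error(align_domains(c(s1 = a)), ">= 2")
  expect_error(align_domains(c(s1 = a, s2 = "MKV")), "minimum length")
})

test_that("NJ recovers an additive four-taxon tree with branch lengths", {
  # additive matrix from tree ((a:1,b:2):1,(c:3,d:4)) with internal edge 1
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-9)
  # true split ab|cd present
  splits <- ape::prop.part(tr)
  expect_true(any(vapply(splits, function(s)
    setequal(tr$tip.label[s], c("a", "b")) ||
      setequal(tr$tip.label[s], c("c", "d")), logical(1))))
})

test_that("three taxa solve the closed-form star branch lengths", {
  d <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["x"]), (2 + 4 - 6) / 2)
  expect_equal(unname(bl["y"]), (2 + 6 - 4) / 2)
  expect_equal(unname(bl["z"]), (4 + 6 - 2) / 2)
})

test_that("patristic distances are non-negative and four-point compliant", {
  set.seed(71)
  seqs <- setNames(vapply(1:8, function(i) rand_protein(60), character(1)),
                   sprintf("t%d", 1:8))
  tr <- nj_tree(align_domains(seqs))
  pd <- ape::cophenetic.phylo(tr)
  expect_true(all(pd >= 0))
  labs <- rownames(pd)
  for (i in 1:5) {
    q <- sample(labs, 4)
    sums <- c(pd[q[1], q[2]] + pd[q[3], q[4]],
              pd[q[1], q[3]] + pd[q[2], q[4]],
              pd[q[1], q[4]] + pd[q[2], q[3]])
    two_largest <- sort(sums, decreasing = TRUE)[1:2]
    expect_lte(two_largest[1] - two_largest[2], 1e-9)
  }
})

test_that("queries take the label of their nearest reference", {
  set.seed(72)
  refs <- setNames(vapply(1:4, function(i) rand_protein(60), character(1)),
                   sprintf("REF%d", 1:4))
  queries <- unlist(lapply(1:4, function(i) {
    setNames(vapply(1:3, function(j) mutate_protein_frac(refs[[i]], 0.1),
                    character(1)),
             sprintf("q%d_%d", i, 1:3))
  }))
  # one query identical to a reference
  queries["q1_1"] <- refs[["REF1"]]
  tr <- nj_tree(align_domains(c(queries, refs)))
  asg <- assign_subfamilies(tr, setNames(sprintf("SF%d", 1:4), names(refs)))
  expect_equal(asg$subfamily[asg$pangene == "q1_1"], "SF1")
  expect_lt(asg$distance[asg$pangene == "q1_1"], 1e-6)
  truth <- sprintf("SF%s", sub("^q(\\d)_.*", "\\1", asg$pangene))
  expect_gte(mean(asg$subfamily == truth), 0.95)
  # a ceiling relabels distant queries; an absent subfamily stays empty
  asg2 <- assign_subfamilies(tr, setNames(sprintf("SF%d", 1:4), names(refs)),
                             max_distance = 1e-9)
  expect_true(all(asg2$subfamily[asg2$pangene != "q1_1"] == "SF_like"))
  expect_error(assign_subfamilies(tr, c(nosuch = "SFX")), "reference")
})

test_that("hypergeometric enrichment flags the loaded subfamily", {
  asg <- data.frame(pangene = sprintf("p%02d", 1:30),
                    subfamily = rep(c("SF1", "SF2", "SF3"), each = 10))
  cats <- setNames(rep("core", 30), asg$pangene)
  cats[asg$subfamily == "SF2"] <- "shell"   # all dispensables in SF2
  e <- dispensable_enrichment(asg, cats)
  expect_equal(e$subfamily[1], "SF2")
  expect_equal(min(e$p_value), e$p_value[1])
  expect_lt(e$q_value[1], 0.05)
  expect_error(dispensable_enrichment(asg[asg$subfamily == "SF1", ], cats),
               "subfamilies")
})

test_that("enrichment p-values are near-uniform under a random null", {
  set.seed(73)
  n_sig <- 0
  for (i in 1:40) {
    asg <- data.frame(pangene = sprintf("p%02d", 1:36),
                      subfamily = sample(rep(sprintf("SF%d", 1:6), 6)))
    cats <- setNames(sample(rep(c("core", "shell"), c(27, 9))), asg$pangene)
    e <- dispensable_enrichment(asg, cats)
    if (any(e$q_value < 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 40, 0.10)
})
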