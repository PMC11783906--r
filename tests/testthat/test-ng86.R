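# Nei-Gojobori pairwise Ka/Ks estimation.

test_that("identical sequences give zero rates and undefined omega", {
  cds <- "ATGGCTAAATTTGGG"
  r <- ng86_pair(c(cds, cds))
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$n_sites + r$s_sites, 3 * r$n_codons)
})

test_that("a single synonymous third-position change matches the hand site count", {
  set.seed(101)
  cds <- random_cds(100)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  # find a codon with a synonymous third-position alternative
  gc <- Biostrings::GENETIC_CODE
  mutated <- NULL
  for (i in seq_len(length(codons) - 1)) {
    for (b in c("A", "C", "G", "T")) {
      cand <- codons[i]
      substr(cand, 3, 3) <- b
      if (cand != codons[i] && gc[[cand]] == gc[[codons[i]]]) {
        mutated <- codons; mutated[i] <- cand
        break
      }
    }
    if (!is.null(mutated)) break
  }
  cds2 <- paste(mutated, collapse = "")
  r <- ng86_pair(c(cds, cds2))
  o <- oracle_ng86(cds, cds2)
  expect_equal(r$ka, 0)
  expect_equal(r$sd, 1)
  expect_equal(r$ks, o$ks, tolerance = 1e-12)
  expect_equal(r$s_sites, o$S, tolerance = 1e-12)
})

test_that("ng86_pair agrees with the pathway-enumeration oracle on random pairs", {
  set.seed(77)
  for (i in 1:10) {
    a <- random_cds(30)
    b <- mutate_cds_with_target_omega(a, runif(1, 0.2, 2), sample(3:12, 1))
    r <- ng86_pair(c(a, b))
    o <- oracle_ng86(a, b)
    expect_equal(r$n_sites, o$N, tolerance = 1e-9)
    expect_equal(r$s_sites, o$S, tolerance = 1e-9)
    expect_equal(r$nd, o$Nd, tolerance = 1e-9)
    expect_equal(r$sd, o$Sd, tolerance = 1e-9)
  }
})

test_that("ng86_pair is symmetric and conserves sites", {
  set.seed(5)
  a <- random_cds(40)
  b <- mutate_cds_with_target_omega(a, 0.7, 10)
  r1 <- ng86_pair(c(a, b))
  r2 <- ng86_pair(c(b, a))
  expect_equal(r1$ka, r2$ka)
  expect_equal(r1$ks, r2$ks)
  expect_equal(r1$n_sites, r2$n_sites)
  expect_equal(r1$n_sites + r1$s_sites, 3 * r1$n_codons)
})

test_that("gapped and ambiguous codon columns are excluded pairwise", {
  a <- "ATGGCTAAA---TTT"
  b <- "ATGGCTAAACCCNTT"
  r <- ng86_pair(c(a, b))
  expect_equal(r$n_codons, 3L)  # ATG, GCT/AAA kept; gap and N columns dropped
  expect_error(ng86_pair(c("---", "AAA")), "comparable")
})

test_that("backtranslation expands gaps to codon gaps and round-trips", {
  cds <- c(x = "ATGAAACCCTTTTAA", y = "ATGAAATTTTAG")
  paln <- c(x = "MKPF", y = "MK-F")
  caln <- backtranslate_codon_alignment(paln, cds)
  expect_equal(unname(caln$dna["y"]), "ATGAAA---TTT")
  expect_equal(unname(caln$dna["x"]), "ATGAAACCCTTT")
  # round-trip: translating ungapped rows recovers the protein rows
  for (id in names(paln)) {
    ungapped <- gsub("-", "", caln$dna[[id]])
    expect_equal(panfam:::.translate_cds(ungapped),
                 gsub("-", "", paln[[id]]))
  }
  expect_error(backtranslate_codon_alignment(c(x = "MF"), c(x = "ATGAAA")),
               "mismatch")
})

test_that("pangene summaries match a manual three-member calculation", {
  set.seed(9)
  anc <- random_cds(60)
  cds <- setNames(c(anc,
                    mutate_cds_with_target_omega(anc, 0.5, 6),
                    mutate_cds_with_target_omega(anc, 0.5, 6)),
                  c("m1", "m2", "m3"))
  pairs <- pangene_kaks_pairs(cds)
  expect_equal(nrow(pairs), 3L)
  s <- summarize_ogg_selection(pairs, pangene = "PG1")
  ok <- pairs$omega[!is.na(pairs$omega)]
  expect_equal(s$mean_ka, mean(pairs$ka))
  expect_equal(s$sd_ks, sd(pairs$ks))
  if (length(ok) >= 2) expect_equal(s$mean_omega, mean(ok))
  expect_equal(s$n_pairs, 3L)
  # single-member pangene is flagged, not an error
  s0 <- summarize_ogg_selection(NULL, pangene = "PG2")
  expect_true(s0$insufficient_members)
})

test_that("core vs dispensable comparison reports medians and Welch p", {
  summaries <- data.frame(pangene = sprintf("p%02d", 1:20),
                          mean_ka = c(rep(0.01, 10), rep(0.03, 10)),
                          mean_ks = rep(0.05, 20),
                          mean_omega = c(rnorm(10, 0.2, 0.01), rnorm(10, 0.8, 0.01)))
  cats <- setNames(rep(c("core", "shell"), each = 10), summaries$pangene)
  cmp <- compare_core_dispensable(summaries, cats)
  om <- cmp[cmp$statistic == "omega", ]
  expect_lt(om$median_core, om$median_dispensable)
  expect_lt(om$p_value, 0.05)
  # identical groups: p close to 1
  summaries$mean_omega <- rep(c(0.3, 0.4), 10)
  cmp2 <- compare_core_dispensable(summaries, cats)
  expect_gt(cmp2[cmp2$statistic == "omega", "p_value"], 0.9)
})

test_that("selection regimes split strictly at omega = 1", {
  expect_equal(classify_selection(0.5), "purifying")
  expect_equal(classify_selection(0.99), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(1.7), "positive")
  expect_error(classify_selection(NA_real_), "defined")
})
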