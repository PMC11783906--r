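# Domain-profile construction and member scanning.

make_seed_alignment <- function(n = 6, len = 60, divergence = 0.25, seed = 31) {
  set.seed(seed)
  root <- rand_protein(len)
  setNames(vapply(seq_len(n), function(i) mutate_protein_frac(root, divergence),
                  character(1)),
           sprintf("seed%02d", seq_len(n)))
}

test_that("profile building is deterministic and calibrated on >= 1000 sequences", {
  aln <- make_seed_alignment()
  p1 <- build_domain_profile(aln, seed = 2)
  p2 <- build_domain_profile(aln, seed = 2)
  expect_identical(p1$calib, p2$calib)
  expect_identical(p1$pssm, p2$pssm)
  expect_gte(p1$calib$n_calib, 1000)
  expect_equal(p1$length, 60L)
  # E-value is monotone decreasing in score
  sc <- seq(0, 100, by = 10)
  ev <- vapply(sc, function(s) panfam:::.profile_evalue(p1, s, 100), numeric(1))
  expect_true(all(diff(ev) < 0))
  expect_error(build_domain_profile(character(0)), "empty")
  expect_error(build_domain_profile(c(a = "---", b = "---")), "gap")
})

test_that("identical seed sequences give best self-score = sum of column maxima", {
  aln <- setNames(rep(paste(rep("K", 40), collapse = ""), 5), paste0("s", 1:5))
  p <- build_domain_profile(aln, seed = 1)
  hit <- scan_proteins(aln[1], p, e_threshold = Inf)
  expect_equal(hit$score, sum(apply(p$pssm, 1, max)), tolerance = 1e-9)
})

test_that("all seed sequences are recovered at the 1e-5 threshold", {
  aln <- make_seed_alignment()
  p <- build_domain_profile(aln, seed = 3)
  hits <- scan_proteins(aln, p)
  expect_equal(sort(hits$seq_id), sort(names(aln)))
  expect_true(all(hits$e_value <= 1e-5))
})

test_that("random sequences yield no hits and short sequences cannot form envelopes", {
  aln <- make_seed_alignment()
  p <- build_domain_profile(aln, seed = 4)
  set.seed(11)
  rand <- setNames(vapply(1:300, function(i) rand_protein(300), character(1)),
                   sprintf("r%03d", 1:300))
  hits <- scan_proteins(rand, p)
  expect_lte(nrow(hits), 3)  # >= 99% of random sequences hit-free
  # shorter than half the profile: no envelope
  expect_equal(nrow(scan_proteins(c(s = rand_protein(29)), p, e_threshold = Inf)), 0L)
  # empty input is an empty result, not an error
  expect_equal(nrow(scan_proteins(character(0), p)), 0L)
})

test_that("scan finds the true domain span inside a flanked protein", {
  aln <- make_seed_alignment(seed = 77)
  p <- build_domain_profile(aln, seed = 5)
  set.seed(12)
  member <- paste0(rand_protein(70), mutate_protein_frac(aln[[1]], 0.1),
                   rand_protein(70))
  h <- scan_proteins(c(m = member), p)
  expect_equal(nrow(h), 1L)
  expect_lte(abs(h$start - 70), 5)
  expect_lte(abs(h$end - 130), 5)
})

test_that("lowering the E-threshold never enlarges the hit set", {
  aln <- make_seed_alignment(seed = 13)
  p <- build_domain_profile(aln, seed = 6)
  set.seed(14)
  seqs <- setNames(c(vapply(1:5, function(i)
    paste0(rand_protein(20), mutate_protein_frac(aln[[1]], runif(1, 0.1, 0.5)),
           rand_protein(20)), character(1)),
    vapply(1:5, function(i) rand_protein(100), character(1))),
    sprintf("q%02d", 1:10))
  loose <- scan_proteins(seqs, p, e_threshold = 1e-2)
  strict <- scan_proteins(seqs, p, e_threshold = 1e-8)
  expect_true(all(strict$seq_id %in% loose$seq_id))
})

test_that("malformed residues skip the record with a warning", {
  aln <- make_seed_alignment(seed = 15)
  p <- build_domain_profile(aln, seed = 7)
  seqs <- c(good = aln[[1]], bad = paste0(substr(aln[[1]], 1, 30), "1*Z",
                                          substr(aln[[1]], 34, 60)))
  expect_warning(h <- scan_proteins(seqs, p), "malformed")
  expect_equal(h$seq_id, "good")
})

test_that("domain-length filter keeps exactly the >= 30 aa hits in order", {
  hits <- data.frame(seq_id = c("a", "b", "c", "d"),
                     domain_length = c(29L, 30L, 36L, 82L))
  kept <- filter_hits(hits, 30)
  expect_equal(kept$seq_id, c("b", "c", "d"))
  expect_equal(nrow(filter_hits(hits, 83)), 0L)
})

test_that("domtblout tables are parsed with envelope coordinates half-open", {
  lines <- c(
    "# comment",
    paste("geneA -  250 famdom PF99999.1 60 1.2e-20 70.1 0.1 1 2",
          "3.1e-21 2.2e-18 65.0 0.1 2 59 10 68 8 70 0.93 desc text"),
    paste("geneA -  250 famdom PF99999.1 60 1.2e-20 70.1 0.1 2 2",
          "4.0e-09 3.0e-06 20.0 0.1 2 30 100 129 99 131 0.88 desc"),
    paste("geneB -  180 famdom PF99999.1 60 5.0e-08 30.5 0.0 1 1",
          "6.0e-09 4.4e-06 28.1 0.0 1 60 5 64 4 66 0.90 d"))
  f <- tempfile(fileext = ".domtblout")
  writeLines(lines, f)
  h <- read_domtblout(f)
  expect_equal(nrow(h), 2L)  # best hit per sequence
  ga <- h[h$seq_id == "geneA", ]
  expect_equal(ga$start, 7L)       # env from 8 -> 0-based 7
  expect_equal(ga$end, 70L)
  expect_equal(ga$domain_length, 63L)
  expect_equal(ga$e_value, 2.2e-18)
  hb <- read_domtblout(f, best_per_sequence = FALSE)
  expect_equal(nrow(hb), 3L)
})
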