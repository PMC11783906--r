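# Nei-Gojobori (1986) pairwise Ka/Ks with Jukes-Cantor correction.
#
# Site counting: each codon position contributes exactly one site, split
# between synonymous and nonsynonymous in proportion to the fraction of
# synonymous changes among the single-nucleotide changes that do not create
# a stop codon. Observed differences at codons differing at k positions are
# averaged with equal weight over the k! mutational pathways that avoid stop
# intermediates (all pathways if every pathway passes through a stop).

.genetic_code <- function() Biostrings::GENETIC_CODE

.codon_universe <- function() {
  nt <- c("T", "C", "A", "G")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

.is_stop <- function(codon) unname(.genetic_code()[codon] == "*")

# Per-codon synonymous site count (0..3); nonsynonymous = 3 - synonymous.
.ng86_syn_sites <- function() {
  if (!is.null(.panfam_cache$syn_sites)) return(.panfam_cache$syn_sites)
  gc <- .genetic_code()
  nt <- c("T", "C", "A", "G")
  codons <- .codon_universe()
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[cd] == "*") { syn[cd] <- NA_real_; next }
    s_total <- 0
    for (pos in 1:3) {
      alts <- setdiff(nt, substring(cd, pos, pos))
      alt_codons <- vapply(alts, function(a) {
        x <- cd; substring(x, pos, pos) <- a; x
      }, character(1))
      keep <- gc[alt_codons] != "*"
      if (!any(keep)) { s_total <- s_total + 0; next }  # position still 1 site
      s_total <- s_total + sum(gc[alt_codons[keep]] == gc[cd]) / sum(keep)
    }
    syn[cd] <- s_total
  }
  .panfam_cache$syn_sites <- syn
  syn
}

# Pathway-averaged (Nd, Sd) for one codon pair.
.ng86_pair_diff <- function(c1, c2) {
  gc <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(nd = 0, sd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- if (k == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(i) pos[i])
  }
  walk <- function(order_pos, allow_stop) {
    cur <- c1; nd <- 0; sd <- 0
    for (p in order_pos) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (!allow_stop && gc[nxt] == "*") return(NULL)
      if (gc[nxt] == gc[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]))
}

# Cached 64x64 pathway tables (rows/cols indexed by codon string).
.ng86_diff_tables <- function() {
  if (!is.null(.panfam_cache$nd_tab)) {
    return(list(nd = .panfam_cache$nd_tab, sd = .panfam_cache$sd_tab))
  }
  codons <- .codon_universe()
  gc <- .genetic_code()
  ok <- codons[gc[codons] != "*"]
  nd <- matrix(NA_real_, length(ok), length(ok), dimnames = list(ok, ok))
  sd <- nd
  for (i in seq_along(ok)) {
    nd[i, i] <- 0; sd[i, i] <- 0
    if (i < length(ok)) for (j in seq.int(i + 1L, length(ok))) {
      d <- .ng86_pair_diff(ok[i], ok[j])
      nd[i, j] <- nd[j, i] <- d["nd"]
      sd[i, j] <- sd[j, i] <- d["sd"]
    }
  }
  .panfam_cache$nd_tab <- nd
  .panfam_cache$sd_tab <- sd
  list(nd = nd, sd = sd)
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  if (p <= 0) return(0)
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Computes synonymous and nonsynonymous substitution rates per site for a
#' pair of codon-aligned coding sequences, with Jukes-Cantor multiple-hit
#' correction. Codon columns containing a gap or an ambiguity character in
#' either sequence are excluded pairwise.
#'
#' @param aln A codon alignment of exactly two sequences: either a
#'   `codon_alignment` object from [backtranslate_codon_alignment()] or a
#'   character vector of two equal-length aligned CDS strings (gaps as `-`).
#' @return A list of class `ng86_result` with elements `ka`, `ks`, `omega`
#'   (`NA` when `ks` is 0 or undefined), site counts `n_sites`/`s_sites`,
#'   observed differences `nd`/`sd`, proportions `pn`/`ps`, the number of
#'   comparable codons `n_codons`, and `estimator = "NG86"`.
#' @details Per codon, each of the three positions contributes exactly one
#'   site, partitioned by the fraction of synonymous single-nucleotide
#'   changes among those not creating a stop codon, so
#'   `n_sites + s_sites == 3 * n_codons`. Observed differences average all
#'   minimal mutational pathways (stop-free when possible) with equal
#'   weight. `pn` or `ps` at or above 3/4 makes the corresponding rate
#'   undefined (`NA`).
#' @examples
#' a <- "ATGGCTAAATTT"
#' b <- "ATGGCCAAATTT"  # one synonymous third-position change
#' ng86_pair(c(a, b))
#' @export
ng86_pair <- function(aln) {
  seqs <- if (inherits(aln, "codon_alignment")) aln$dna else aln
  if (length(seqs) != 2L) stop("ng86_pair() needs exactly two sequences", call. = FALSE)
  if (nchar(seqs[1]) != nchar(seqs[2])) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  cod1 <- toupper(.split_codons(seqs[1]))
  cod2 <- toupper(.split_codons(seqs[2]))
  gc <- .genetic_code()
  valid <- function(x) x %in% names(gc) & gc[x] != "*"
  keep <- valid(cod1) & valid(cod2)
  n_cod <- sum(keep)
  if (n_cod == 0L) stop("no comparable (ungapped, unambiguous) codons", call. = FALSE)
  cod1 <- cod1[keep]; cod2 <- cod2[keep]

  syn <- .ng86_syn_sites()
  s_sites <- (sum(syn[cod1]) + sum(syn[cod2])) / 2
  n_sites <- 3 * n_cod - s_sites

  tabs <- .ng86_diff_tables()
  idx <- cbind(match(cod1, rownames(tabs$nd)), match(cod2, colnames(tabs$nd)))
  nd <- sum(tabs$nd[idx])
  sd_ <- sum(tabs$sd[idx])

  pn <- if (n_sites > 0) nd / n_sites else NA_real_
  ps <- if (s_sites > 0) sd_ / s_sites else NA_real_
  ka <- .jc_correct(pn)
  ks <- .jc_correct(ps)
  omega <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, omega = omega,
                 n_sites = n_sites, s_sites = s_sites,
                 nd = nd, sd = sd_, pn = pn, ps = ps,
                 n_codons = n_cod, estimator = "NG86"),
            class = "ng86_result")
}

#' @export
print.ng86_result <- function(x, ...) {
  cat(sprintf("NG86: Ka=%.4g Ks=%.4g omega=%s (N=%.2f S=%.2f Nd=%.2f Sd=%.2f, %d codons)\n",
              x$ka, x$ks, ifelse(is.na(x$omega), "NA", sprintf("%.4g", x$omega)),
              x$n_sites, x$s_sites, x$nd, x$sd, x$n_codons))
  invisible(x)
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Maps each aligned amino-acid column to the corresponding codon of the
#' ungapped CDS, expanding protein gaps to `---` codon gaps. A terminal stop
#' codon on a CDS is trimmed before checking the translation.
#'
#' @param protein_alignment Named character vector (or `AAStringSet`) of
#'   aligned protein sequences, gaps as `-`.
#' @param cds_map Named character vector (or `DNAStringSet`) of unaligned
#'   CDS sequences; names must cover the alignment rows.
#' @return A list of class `codon_alignment` with `dna` (aligned CDS rows)
#'   and `protein` (the input alignment), both named.
#' @export
backtranslate_codon_alignment <- function(protein_alignment, cds_map) {
  prot <- if (is.character(protein_alignment)) protein_alignment else
    as.character(protein_alignment)
  cds <- if (is.character(cds_map)) cds_map else as.character(cds_map)
  if (is.null(names(prot)) || is.null(names(cds))) {
    stop("protein alignment and CDS map must be named", call. = FALSE)
  }
  missing <- setdiff(names(prot), names(cds))
  if (length(missing) > 0L) {
    stop("CDS missing for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  widths <- unique(nchar(prot))
  if (length(widths) != 1L) stop("alignment rows differ in length", call. = FALSE)

  out <- vapply(names(prot), function(id) {
    row <- strsplit(prot[[id]], "")[[1]]
    cds_i <- cds[[id]]
    if (nchar(cds_i) %% 3L != 0L) {
      stop(sprintf("CDS of %s not divisible by 3", id), call. = FALSE)
    }
    codons <- .split_codons(cds_i)
    aa <- .translate_cds(cds_i)
    if (length(codons) == nchar(aa) + 1L) codons <- head(codons, -1L)  # stop trimmed
    ungapped <- row[row != "-"]
    aa_chars <- strsplit(aa, "")[[1]]
    if (length(ungapped) != length(aa_chars) || any(ungapped != aa_chars)) {
      first_bad <- which(ungapped != aa_chars[seq_along(ungapped)])[1]
      stop(sprintf("translation mismatch for %s at protein position %d",
                   id, ifelse(is.na(first_bad), length(ungapped), first_bad)),
           call. = FALSE)
    }
    filled <- character(length(row))
    filled[row == "-"] <- "---"
    filled[row != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  structure(list(dna = out, protein = prot), class = "codon_alignment")
}

#' All pairwise Ka/Ks values among members of one pangene
#'
#' Aligns member proteins pairwise (global alignment, BLOSUM62), back-
#' translates to codon alignments and applies [ng86_pair()] to every pair.
#'
#' @param cds Named character vector of member CDS sequences (>= 2).
#' @param proteins Optional named character vector of member proteins;
#'   translated from `cds` when omitted.
#' @return A data.frame with one row per member pair: `member_a`,
#'   `member_b`, `ka`, `ks`, `omega`, `n_sites`, `s_sites`, `nd`, `sd`.
#' @export
pangene_kaks_pairs <- function(cds, proteins = NULL) {
  ids <- names(cds)
  if (is.null(ids) || length(cds) < 2L) {
    stop("need >= 2 named CDS sequences", call. = FALSE)
  }
  if (is.null(proteins)) {
    proteins <- vapply(cds, .translate_cds, character(1))
  }
  pairs <- utils::combn(ids, 2L)
  res <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    gapless <- proteins[[a]] == proteins[[b]]
    if (!gapless && nchar(proteins[[a]]) == nchar(proteins[[b]])) {
      # equal-length, highly similar pairs align without gaps: for affine
      # gap penalties >> mismatch penalties the gapless alignment is optimal
      # whenever few residues differ, so skip the DP
      pa <- strsplit(proteins[[a]], "")[[1]]
      pb <- strsplit(proteins[[b]], "")[[1]]
      gapless <- mean(pa == pb) >= 0.8
    }
    if (gapless) {
      paln <- setNames(c(proteins[[a]], proteins[[b]]), c(a, b))
    } else {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[a]]), Biostrings::AAString(proteins[[b]]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
        type = "global")
      paln <- setNames(c(as.character(Biostrings::alignedPattern(al)),
                         as.character(Biostrings::alignedSubject(al))), c(a, b))
    }
    caln <- backtranslate_codon_alignment(paln, cds[c(a, b)])
    r <- ng86_pair(caln)
    res[[i]] <- data.frame(member_a = a, member_b = b, ka = r$ka, ks = r$ks,
                           omega = r$omega, n_sites = r$n_sites,
                           s_sites = r$s_sites, nd = r$nd, sd = r$sd,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Summarize selection statistics for one pangene
#'
#' @param pair_df Data.frame of pairwise results from
#'   [pangene_kaks_pairs()] (may be empty).
#' @param pangene Pangene identifier recorded in the output row.
#' @return One-row data.frame with pair counts and mean/SD of Ka, Ks and
#'   omega over defined pairs; pairs with undefined omega are excluded from
#'   the omega aggregates and counted in `n_omega_na`. A single-member
#'   pangene yields a row flagged `insufficient_members = TRUE`.
#' @export
summarize_ogg_selection <- function(pair_df, pangene = NA_character_) {
  if (is.null(pair_df) || nrow(pair_df) == 0L) {
    return(data.frame(pangene = pangene, n_pairs = 0L, n_omega_na = 0L,
                      mean_ka = NA_real_, sd_ka = NA_real_,
                      mean_ks = NA_real_, sd_ks = NA_real_,
                      mean_omega = NA_real_, sd_omega = NA_real_,
                      insufficient_members = TRUE, stringsAsFactors = FALSE))
  }
  om <- pair_df$omega[!is.na(pair_df$omega)]
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  data.frame(pangene = pangene, n_pairs = nrow(pair_df),
             n_omega_na = sum(is.na(pair_df$omega)),
             mean_ka = mean(pair_df$ka, na.rm = TRUE),
             sd_ka = sd0(pair_df$ka[!is.na(pair_df$ka)]),
             mean_ks = mean(pair_df$ks, na.rm = TRUE),
             sd_ks = sd0(pair_df$ks[!is.na(pair_df$ks)]),
             mean_omega = if (length(om) > 0) mean(om) else NA_real_,
             sd_omega = if (length(om) > 0) sd0(om) else NA_real_,
             insufficient_members = FALSE, stringsAsFactors = FALSE)
}

#' Compare selection pressure between core and dispensable pangenes
#'
#' Reports per-group medians and a two-sided Welch t-test for each of Ka,
#' Ks and omega over per-pangene means. An optional Mann-Whitney test is
#' available for sensitivity analysis.
#'
#' @param summaries Data.frame from [summarize_ogg_selection()] rows, with
#'   columns `pangene`, `mean_ka`, `mean_ks`, `mean_omega`.
#' @param categories Named character vector mapping pangene to
#'   core/softcore/shell/cloud (anything non-core counts as dispensable).
#' @param test `"welch"` (default) or `"wilcox"`.
#' @return Data.frame with one row per statistic: group medians, group
#'   sizes and the p-value.
#' @export
compare_core_dispensable <- function(summaries, categories, test = c("welch", "wilcox")) {
  test <- match.arg(test)
  grp <- ifelse(categories[summaries$pangene] == "core", "core", "dispensable")
  if (length(unique(grp[!is.na(grp)])) < 2L) {
    stop("both core and dispensable groups must be non-empty", call. = FALSE)
  }
  one <- function(col, label) {
    x <- summaries[[col]][grp == "core"]
    y <- summaries[[col]][grp == "dispensable"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- if (length(x) >= 2L && length(y) >= 2L) {
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        # degenerate constant groups: identical means are indistinguishable
        if (mean(x) == mean(y)) 1 else NA_real_
      } else if (test == "welch") {
        stats::t.test(x, y)$p.value
      } else {
        stats::wilcox.test(x, y, exact = FALSE)$p.value
      }
    } else NA_real_
    data.frame(statistic = label, median_core = stats::median(x),
               median_dispensable = stats::median(y),
               n_core = length(x), n_dispensable = length(y),
               p_value = p, test = test, stringsAsFactors = FALSE)
  }
  rbind(one("mean_ka", "ka"), one("mean_ks", "ks"), one("mean_omega", "omega"))
}

#' Classify selection regime from an omega value
#'
#' @param omega Ka/Ks ratio (must be defined).
#' @param neutral_tol Half-width of the neutrality band around 1.
#' @return `"purifying"`, `"neutral"` or `"positive"`.
#' @export
classify_selection <- function(omega, neutral_tol = 1e-12) {
  if (length(omega) != 1L || is.na(omega)) stop("omega must be a defined scalar", call. = FALSE)
  if (abs(omega - 1) <= neutral_tol) "neutral"
  else if (omega < 1) "purifying"
  else "positive"
}
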