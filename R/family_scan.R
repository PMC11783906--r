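# Domain-profile construction and family-member scanning.
#
# A position-specific score matrix (PSSM) built from a seed alignment stands
# in for a profile HMM. Scores are log2 odds against a uniform background;
# E-values come from a Gumbel fit to the maximum window scores of random
# background sequences, scaled by the number of windows scanned.

EULER_GAMMA <- 0.5772156649015329

#' Build a domain profile from a seed alignment
#'
#' Constructs a PSSM over the 20 standard amino acids from an aligned set of
#' domain sequences and calibrates a score-to-E-value mapping by fitting a
#' Gumbel distribution to maximum window scores of random background
#' sequences.
#'
#' @param seed_alignment Aligned amino-acid sequences (named character
#'   vector, `AAStringSet` or `AAMultipleAlignment`); gaps as `-` or `.`.
#' @param pseudocount Per-residue pseudocount added to column counts.
#' @param max_gap_frac Columns with a higher gap fraction are dropped from
#'   the profile.
#' @param n_calib Number of random sequences used for calibration (>= 1000
#'   recommended; the default satisfies the calibration contract).
#' @param calib_len Length of each calibration sequence.
#' @param seed Integer seed making the calibration deterministic.
#' @return A list of class `domain_profile`: `pssm` (length x 20 score
#'   matrix), `length`, `background`, and `calib` (Gumbel `mu`, `beta`, the
#'   calibration window count and parameters).
#' @export
build_domain_profile <- function(seed_alignment, pseudocount = 1,
                                 max_gap_frac = 0.5, n_calib = 1000,
                                 calib_len = 200, seed = 1) {
  aln <- if (is.character(seed_alignment)) seed_alignment else
    as.character(seed_alignment)
  if (length(aln) == 0L) stop("empty seed alignment", call. = FALSE)
  widths <- unique(nchar(aln))
  if (length(widths) != 1L) stop("seed alignment rows differ in length", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(aln), ""))
  chars[chars == "."] <- "-"
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0L) stop("seed alignment has only gap columns", call. = FALSE)

  aa <- .aa_alphabet()
  bg <- setNames(rep(1 / length(aa), length(aa)), aa)
  pssm <- matrix(0, nrow = length(keep), ncol = length(aa),
                 dimnames = list(NULL, aa))
  for (i in seq_along(keep)) {
    col <- chars[, keep[i]]
    col <- col[col %in% aa]
    counts <- table(factor(col, levels = aa))
    freq <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + pseudocount * length(aa))
    pssm[i, ] <- log2(freq / bg)
  }

  profile <- structure(list(pssm = pssm, length = nrow(pssm), background = bg,
                            calib = NULL),
                       class = "domain_profile")
  # Calibration: Gumbel moment fit to max window scores of random sequences.
  set.seed(seed)
  calib_scores <- vapply(seq_len(n_calib), function(i) {
    s <- sample(aa, calib_len, replace = TRUE)
    max(.pssm_window_scores(match(s, aa), pssm))
  }, numeric(1))
  beta <- stats::sd(calib_scores) * sqrt(6) / pi
  mu <- mean(calib_scores) - EULER_GAMMA * beta
  profile$calib <- list(mu = mu, beta = beta,
                        calib_windows = calib_len - nrow(pssm) + 1L,
                        calib_len = calib_len, n_calib = n_calib, seed = seed)
  profile
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("domain_profile: length %d aa; Gumbel mu=%.2f beta=%.2f (%d calib seqs)\n",
              x$length, x$calib$mu, x$calib$beta, x$calib$n_calib))
  invisible(x)
}

# Window scores of one integer-coded sequence (idx into the 20-aa alphabet;
# NA codes score 0). Returns numeric(0) when no full window fits.
.pssm_window_scores <- function(idx, pssm) {
  L <- nrow(pssm); m <- length(idx)
  if (m < L) return(numeric(0))
  W <- m - L + 1L
  sc <- numeric(W)
  for (o in seq_len(L)) {
    v <- pssm[o, idx[o:(o + W - 1L)]]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

# E-value for a score given the number of windows scanned.
.profile_evalue <- function(profile, score, n_windows) {
  cal <- profile$calib
  (n_windows / cal$calib_windows) * exp(-(score - cal$mu) / cal$beta)
}

#' Scan protein sequences for the family domain
#'
#' Scores every window of each protein against the profile and retains the
#' best (lowest-E) hit per sequence at the E-value threshold. Sequences
#' shorter than half the profile length cannot form an envelope and yield
#' no hit; sequences between half and full profile length are scanned with
#' partial windows (the envelope is clipped to the sequence).
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param profile A `domain_profile`.
#' @param e_threshold Maximum E-value for a reported hit.
#' @param genome Optional genome identifier stored with the hits.
#' @return Data.frame of domain hits: `seq_id`, `genome`, `start`, `end`
#'   (amino acids, 0-based half-open), `score`, `e_value`, `domain_length`.
#'   Empty input yields an empty data.frame. Records containing residues
#'   outside the 20-aa alphabet (plus `X`) are skipped with a warning.
#' @export
scan_proteins <- function(proteins, profile, e_threshold = 1e-5, genome = NA_character_) {
  seqs <- if (is.character(proteins)) proteins else as.character(proteins)
  empty <- data.frame(seq_id = character(), genome = character(),
                      start = integer(), end = integer(), score = numeric(),
                      e_value = numeric(), domain_length = integer(),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))

  aa <- .aa_alphabet()
  ok_chars <- c(aa, "X")
  L <- profile$length
  half <- ceiling(L / 2)
  rows <- vector("list", length(seqs))

  split_all <- strsplit(toupper(seqs), "")
  bad <- vapply(split_all, function(ch) any(!ch %in% ok_chars), logical(1))
  if (any(bad)) {
    warning(sprintf("skipping %d record(s) with malformed residues: %s",
                    sum(bad), paste(head(names(seqs)[bad], 5), collapse = ", ")))
  }

  lens <- nchar(seqs)
  for (i in which(!bad)) {
    m <- lens[i]
    if (m < half) next
    idx <- match(split_all[[i]], aa)  # X and friends -> NA -> score 0
    pad <- L - half
    if (m < L) idx_scan <- c(rep(NA_integer_, pad), idx, rep(NA_integer_, pad))
    else idx_scan <- idx
    sc <- .pssm_window_scores(idx_scan, profile$pssm)
    if (length(sc) == 0L) next
    best <- which.max(sc)  # ties -> leftmost envelope
    n_win <- length(sc)
    ev <- .profile_evalue(profile, sc[best], n_win)
    if (ev > e_threshold) next
    off <- if (m < L) best - 1L - pad else best - 1L  # 0-based start on sequence
    start <- max(0L, off)
    end <- min(m, off + L)
    rows[[i]] <- data.frame(seq_id = names(seqs)[i], genome = genome,
                            start = as.integer(start), end = as.integer(end),
                            score = sc[best], e_value = ev,
                            domain_length = as.integer(end - start),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Filter domain hits by minimum domain length
#'
#' @param hits Data.frame with a `domain_length` column.
#' @param min_domain_len Minimum envelope length, in amino acids, for a hit
#'   to be retained (the boundary is inclusive).
#' @return The retained hits, input order preserved.
#' @export
filter_hits <- function(hits, min_domain_len = 30) {
  if (is.null(hits$domain_length)) stop("hits lack domain_length", call. = FALSE)
  hits[hits$domain_length >= min_domain_len, , drop = FALSE]
}

#' Read domain hits in HMMER domtblout format
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmscan --domtblout` / `hmmsearch --domtblout` so that precomputed
#' profile scans can be injected in place of the native scanner. Envelope
#' coordinates are converted to 0-based half-open; the independent
#' (i-Evalue) per-domain E-value is reported.
#'
#' @param path Path to a domtblout file (comment lines start with `#`).
#' @param best_per_sequence Keep only the lowest-E hit per target sequence.
#' @return Data.frame with the same columns as [scan_proteins()].
#' @export
read_domtblout <- function(path, best_per_sequence = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(), genome = character(),
                      start = integer(), end = integer(), score = numeric(),
                      e_value = numeric(), domain_length = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(fields, length, integer(1)) < 22L
  if (any(bad)) stop("malformed domtblout line(s): ", which(bad)[1], call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  env_from <- as.integer(get(20)); env_to <- as.integer(get(21))
  out <- data.frame(seq_id = get(1), genome = NA_character_,
                    start = env_from - 1L, end = env_to,
                    score = as.numeric(get(14)),
                    e_value = as.numeric(get(13)),
                    domain_length = env_to - env_from + 1L,
                    stringsAsFactors = FALSE)
  if (best_per_sequence && nrow(out) > 0L) {
    out <- out[order(out$seq_id, out$e_value, out$start), , drop = FALSE]
    out <- out[!duplicated(out$seq_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# --- six-frame ORF scan of unannotated regions -------------------------------

# Extract ATG-initiated ORFs (>= min_aa residues, stop-bounded) from all six
# frames of one chromosome. Returns a data.frame with 0-based half-open
# genomic coordinates, strand, protein and CDS. Works on plain character
# sequences with a vectorized genetic-code lookup for speed.
.extract_orfs <- function(chrom_seq, chrom_name, min_aa) {
  gc <- Biostrings::GENETIC_CODE
  res <- list()
  fwd <- toupper(as.character(chrom_seq))
  n <- nchar(fwd)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else rev
    for (frame in 0:2) {
      len <- n - frame
      len <- len - (len %% 3L)
      if (len < 3L * (min_aa + 1L)) next
      starts <- seq.int(frame + 1L, frame + len, by = 3L)
      aa <- unname(gc[substring(s, starts, starts + 2L)])
      aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      bounds <- c(0L, stops, length(aa) + 1L)
      ms <- which(aa == "M")
      for (b in seq_len(length(bounds) - 1L)) {
        seg_start <- bounds[b] + 1L          # 1-based aa on frame translation
        seg_end <- bounds[b + 1L] - 1L
        if (seg_end - seg_start + 1L < min_aa) next
        m_in <- ms[ms >= seg_start & ms <= seg_end]
        if (length(m_in) == 0L) next
        aa_start <- m_in[1]
        if (seg_end - aa_start + 1L < min_aa) next
        has_stop <- bounds[b + 1L] <= length(aa)
        # nucleotide span on the translated strand (0-based half-open),
        # including the terminal stop codon when present
        nt_start <- frame + (aa_start - 1L) * 3L
        nt_end <- frame + (seg_end + (if (has_stop) 1L else 0L)) * 3L
        if (strand == "+") {
          g_start <- nt_start; g_end <- nt_end
        } else {
          g_start <- n - nt_end; g_end <- n - nt_start
        }
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom_name, start = g_start, end = g_end, strand = strand,
          protein = paste(aa[aa_start:seg_end], collapse = ""),
          cds = substring(s, nt_start + 1L, nt_end), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      cds = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Scan unannotated genomic regions for family members
#'
#' Translates ATG-initiated, stop-bounded open reading frames in all six
#' frames of a genome assembly, discards ORFs overlapping annotated gene
#' spans, and scans the remaining ORF proteins against the domain profile.
#' This recovers single-exon family genes missing from the annotation;
#' members whose domain is split by an intron are not recoverable by design
#' and are reported as a limitation.
#'
#' @param genome `DNAStringSet` (or path to a FASTA) of chromosome sequences.
#' @param annotation Data.frame of annotated gene spans with columns
#'   `chrom`, `start`, `end` (0-based half-open), or a path to a GFF3 file
#'   whose `gene` features are used.
#' @param profile A `domain_profile`.
#' @param e_threshold Maximum E-value.
#' @param min_orf_aa Minimum ORF length in amino acids.
#' @param genome_id Genome identifier stored with the members.
#' @return Data.frame of newly predicted members: `gene_id`, `genome`,
#'   `chrom`, `start`, `end` (genomic, 0-based half-open), `strand`,
#'   `status = "newly_predicted"`, `protein`, `cds`, `domain_start`,
#'   `domain_end`, `domain_len`, `e_value`. Overlapping candidate ORFs are
#'   reduced to the best (lowest-E) per locus.
#' @export
scan_unannotated_regions <- function(genome, annotation, profile,
                                     e_threshold = 1e-5, min_orf_aa = 60,
                                     genome_id = NA_character_) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  ann <- .as_gene_spans(annotation)
  missing_contig <- setdiff(unique(ann$chrom), names(genome))
  if (length(missing_contig) > 0L) {
    stop("contig in annotation missing from assembly: ",
         paste(missing_contig, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (chrom in names(genome)) {
    orfs <- .extract_orfs(genome[[chrom]], chrom, min_orf_aa)
    if (nrow(orfs) == 0L) next
    ann_c <- ann[ann$chrom == chrom, , drop = FALSE]
    if (nrow(ann_c) > 0L) {
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(orfs$start + 1L, orfs$end),
        IRanges::IRanges(ann_c$start + 1L, ann_c$end)) > 0L
      orfs <- orfs[!ov, , drop = FALSE]
    }
    if (nrow(orfs) == 0L) next
    prots <- setNames(orfs$protein, sprintf("%s_orf%05d", chrom, seq_len(nrow(orfs))))
    hits <- scan_proteins(prots, profile, e_threshold = e_threshold)
    if (nrow(hits) == 0L) next
    sel <- match(hits$seq_id, names(prots))
    cand <- cbind(orfs[sel, c("chrom", "start", "end", "strand", "protein", "cds")],
                  data.frame(domain_start = hits$start, domain_end = hits$end,
                             domain_len = hits$domain_length,
                             e_value = hits$e_value, stringsAsFactors = FALSE))
    out[[chrom]] <- cand
  }
  empty <- data.frame(gene_id = character(), genome = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), status = character(),
                      protein = character(), cds = character(),
                      domain_start = integer(), domain_end = integer(),
                      domain_len = integer(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(out) == 0L) return(empty)
  cand <- do.call(rbind, out)
  rownames(cand) <- NULL
  # best hit per locus: drop candidates overlapping a better one
  cand <- cand[order(cand$chrom, cand$e_value, cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (chrom in unique(cand$chrom)) {
    i_c <- which(cand$chrom == chrom)
    taken <- IRanges::IRanges()
    for (i in i_c) {
      r <- IRanges::IRanges(cand$start[i] + 1L, cand$end[i])
      if (length(taken) > 0L && sum(IRanges::countOverlaps(r, taken)) > 0L) {
        keep[i] <- FALSE
      } else {
        taken <- c(taken, r)
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  data.frame(gene_id = sprintf("%s.novel%03d",
                               ifelse(is.na(genome_id), "novel", genome_id),
                               seq_len(nrow(cand))),
             genome = genome_id,
             cand[, c("chrom", "start", "end", "strand")],
             status = "newly_predicted",
             cand[, c("protein", "cds", "domain_start", "domain_end",
                      "domain_len", "e_value")],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Normalize gene-span input: data.frame(chrom,start,end) 0-based half-open,
# or a GFF3 path (gene features; GFF3 is 1-based inclusive).
.as_gene_spans <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(annotation)))
    return(annotation[, c("chrom", "start", "end")])
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    gr <- rtracklayer::import(annotation, format = "gff3")
    gr <- gr[gr$type == "gene"]
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr), stringsAsFactors = FALSE))
  }
  stop("annotation must be a data.frame or a GFF3 path", call. = FALSE)
}
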