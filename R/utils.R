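# Internal helpers shared across modules.

.panfam_cache <- new.env(parent = emptyenv())

#' @importFrom utils head tail read.table write.table
NULL

# Derive a reproducible sub-seed from a root seed and a stage label.
# Keeps results < 2^31 so set.seed() accepts them.
.sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 97L + h) %% 2147483647)
}

.stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %s", name, min), call. = FALSE)
  }
  invisible(x)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "", check.names = FALSE, ...)
}

# Random amino-acid / nucleotide string helpers (uniform background).
.aa_alphabet <- function() {
  c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
}

.random_aa <- function(n) paste(sample(.aa_alphabet(), n, replace = TRUE), collapse = "")

.random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

# fast character-level reverse complement (avoids S4 dispatch per gene)
.revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
}

# Split a nucleotide string into codons.
.split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.paste_codons <- function(codons) paste(codons, collapse = "")

# Translate a CDS (character scalar) to protein, trimming a terminal stop.
# Pure-R genetic-code lookup (codons with ambiguity characters become X);
# avoids per-call S4 dispatch overhead on hot paths.
.translate_cds <- function(cds, trim_stop = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[.split_codons(toupper(cds))])
  aa[is.na(aa)] <- "X"
  if (trim_stop && length(aa) > 0L && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}
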