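# Greedy incremental clustering of family members into orthologous gene
# groups (OGGs / pangenes), following CD-HIT semantics: members are visited
# in order of decreasing protein length and compared against cluster
# representatives only.

#' Global identity and coverage between two proteins
#'
#' Aligns two protein sequences globally (BLOSUM62, affine gaps) and
#' returns the identity fraction relative to the shorter sequence and the
#' coverage of the longer sequence, the two quantities thresholded by
#' [greedy_cluster()].
#'
#' @param a,b Protein sequences (non-empty character scalars).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Named numeric vector `c(identity, coverage)`: identity =
#'   identical aligned residues / length of the shorter sequence; coverage
#'   = residue-residue aligned columns / length of the longer sequence.
#'   Symmetric in `(a, b)`.
#' @examples
#' align_pair_identity("AAAAAAAAAA", "AAAAAAAAAC")  # identity 0.9
#' @export
align_pair_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  # canonical order for exact symmetry: longer first, ties lexicographic
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  c(identity = nm / min(nchar(a), nchar(b)),
    coverage = (nm + nmm) / max(nchar(a), nchar(b)))
}

# Vectorized member-vs-representatives comparison used by greedy_cluster():
# one pairwiseAlignment call against all current representatives.
.batch_identity_coverage <- function(member, reps, gap_opening = 10,
                                     gap_extension = 0.5) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(reps), Biostrings::AAString(member),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  shorter <- pmin(nchar(reps), nchar(member))
  longer <- pmax(nchar(reps), nchar(member))
  list(identity = nm / shorter, coverage = (nm + nmm) / longer)
}

#' Greedy incremental clustering into orthologous gene groups
#'
#' Processes members in order of decreasing protein length (ties broken by
#' member id, ascending). Each member joins the first existing cluster, in
#' founding order, whose representative satisfies both the identity and the
#' coverage threshold; otherwise it founds a new cluster and becomes its
#' representative. Because members arrive longest-first, every
#' representative is the longest (tie: lexicographically smallest id)
#' member of its cluster.
#'
#' @param proteins Named character vector of member protein sequences.
#' @param identity_threshold Minimum identity vs the representative
#'   (fraction of the shorter sequence).
#' @param coverage_threshold Minimum aligned coverage of the longer
#'   sequence.
#' @param full_linkage If `TRUE`, a member must additionally satisfy the
#'   thresholds against every current cluster member (sensitivity-analysis
#'   variant; default is CD-HIT's representative-only rule).
#' @return A list of class `ogg_set`: `clusters` (list of member-id
#'   vectors, representative first), `representatives` (named character
#'   vector ogg_id -> member id), and `membership` (named character vector
#'   member id -> ogg_id). Cluster ids are `OGG0001`, ... in founding
#'   order.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.95,
                           coverage_threshold = 0.90, full_linkage = FALSE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  if (length(proteins) == 0L) {
    return(structure(list(clusters = list(), representatives = character(),
                          membership = character()), class = "ogg_set"))
  }
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("proteins must have unique names", call. = FALSE)
  }
  ord <- order(-nchar(proteins), names(proteins))
  ids <- names(proteins)[ord]
  seqs <- unname(proteins[ord])

  clusters <- list()        # member ids, representative first
  rep_seqs <- character(0)  # representative sequences, founding order
  membership <- character(length(ids)); names(membership) <- ids

  for (i in seq_along(ids)) {
    assigned <- NA_integer_
    if (length(rep_seqs) > 0L) {
      bc <- .batch_identity_coverage(seqs[i], rep_seqs)
      ok <- bc$identity >= identity_threshold & bc$coverage >= coverage_threshold
      if (full_linkage && any(ok)) {
        for (ci in which(ok)) {
          mem_seqs <- proteins[clusters[[ci]]]
          pass <- all(vapply(mem_seqs, function(ms) {
            v <- align_pair_identity(seqs[i], ms)
            v["identity"] >= identity_threshold & v["coverage"] >= coverage_threshold
          }, logical(1)))
          if (pass) { assigned <- ci; break }
        }
      } else if (any(ok)) {
        assigned <- which(ok)[1]  # first cluster in founding order
      }
    }
    if (is.na(assigned)) {
      clusters[[length(clusters) + 1L]] <- ids[i]
      rep_seqs <- c(rep_seqs, seqs[i])
      membership[ids[i]] <- length(clusters)
    } else {
      clusters[[assigned]] <- c(clusters[[assigned]], ids[i])
      membership[ids[i]] <- assigned
    }
  }
  ogg_ids <- sprintf("OGG%04d", seq_along(clusters))
  names(clusters) <- ogg_ids
  reps <- vapply(clusters, `[[`, character(1), 1L)
  membership <- setNames(ogg_ids[as.integer(membership)], names(membership))
  structure(list(clusters = clusters, representatives = reps,
                 membership = membership), class = "ogg_set")
}

#' @export
print.ogg_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("ogg_set: %d clusters over %d members (sizes %s..%s)\n",
              length(x$clusters), length(x$membership),
              if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

#' Representative member of each cluster
#'
#' The representative is the member with maximal protein length; ties are
#' broken by the lexicographically smallest member id.
#'
#' @param oggs An `ogg_set` (or a plain list of member-id vectors).
#' @param proteins Named character vector of member proteins.
#' @return Named character vector ogg_id -> representative member id.
#' @export
select_representatives <- function(oggs, proteins) {
  clusters <- if (inherits(oggs, "ogg_set")) oggs$clusters else oggs
  if (any(lengths(clusters) == 0L)) stop("empty cluster", call. = FALSE)
  vapply(clusters, function(members) {
    lens <- nchar(proteins[members])
    members[order(-lens, members)][1]
  }, character(1))
}

#' Write cluster membership as a TSV table
#'
#' @param oggs An `ogg_set`.
#' @param genomes Named character vector member id -> genome id.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_clusters_tsv <- function(oggs, genomes, path) {
  rows <- lapply(names(oggs$clusters), function(ogg) {
    members <- oggs$clusters[[ogg]]
    data.frame(ogg_id = ogg, member_id = members,
               genome = unname(genomes[members]),
               is_representative = members == oggs$representatives[[ogg]],
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}
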