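# Pairwise protein alignment, global identity, greedy centroid clustering,
# and a best-hit search engine (internal scoring backend + external hit-file
# backend with identical best-hit selection).

.align_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$B62 <- e$BLOSUM62
  }
  .align_env$B62
}

# Karlin-Altschul parameters for gapped BLOSUM62 scoring
KA_LAMBDA <- 0.267
KA_K <- 0.041

check_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop(what, " must be a non-empty string")
  invisible(x)
}

#' Optimal global pairwise protein alignment
#'
#' End-to-end (Needleman-Wunsch with penalised terminal gaps) alignment under
#' BLOSUM62 with affine gap costs (open 11, extend 1 by default), computed by
#' Biostrings. A gap of length k costs `gap_open + k * gap_ext`.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_ext Affine gap penalties (positive costs).
#' @return An object of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `matches`, `columns`, `score`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                         gap_ext = 1) {
  check_seq(a, "sequence 'a'"); check_seq(b, "sequence 'b'")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_ext)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  structure(list(aligned_a = ga, aligned_b = gb,
                 matches = Biostrings::nmatch(aln),
                 columns = nchar(ga),
                 score = Biostrings::score(aln)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("matches %d / %d columns, score %.1f\n",
              x$matches, x$columns, x$score))
  invisible(x)
}

#' Global percent identity between two protein sequences
#'
#' Identical columns divided by total alignment columns of the optimal global
#' alignment, counting internal and terminal gap columns (USEARCH-style
#' global identity). Symmetric in its arguments.
#'
#' @inheritParams global_align
#' @return Percent in \[0, 100\].
#' @export
global_identity <- function(a, b, matrix = blosum62(), gap_open = 11,
                            gap_ext = 1) {
  aln <- global_align(a, b, matrix, gap_open, gap_ext)
  100 * aln$matches / aln$columns
}

# identity of many sequences against one reference, one vectorised call
global_identity_many <- function(seqs, ref, matrix = blosum62(),
                                 gap_open = 11, gap_ext = 1) {
  if (length(seqs) == 0L) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(seqs)), Biostrings::AAString(ref),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_ext)
  # end-to-end alignment: every residue occupies exactly one column, so
  # columns = n_a + n_b - (match + mismatch columns); avoids materialising
  # the gapped strings
  mm <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- nchar(seqs) + nchar(ref) - mm
  stats::setNames(100 * Biostrings::nmatch(aln) / cols, names(seqs))
}

#' Greedy centroid clustering at a global-identity threshold
#'
#' Sequences are processed in decreasing length order (ties broken by id);
#' each joins the first existing centroid whose global identity is at or
#' above the threshold, otherwise it founds a new centroid. The result is a
#' partition of the input.
#'
#' @param seqs Named character vector of sequences (ids as names).
#' @param threshold Percent identity in (0, 100\].
#' @return List of clusters; each element is `list(centroid = id,
#'   members = ids)` with the centroid included among members, in founding
#'   order.
#' @export
greedy_centroid_cluster <- function(seqs, threshold) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  stopifnot(threshold > 0, threshold <= 100)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must have unique names")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  cent_ids <- character(0)
  cent_seqs <- character(0)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (length(cent_ids)) {
      ident <- global_identity_many(cent_seqs, seqs[[i]])
      pass <- which(ident >= threshold)
      if (length(pass)) hit <- pass[1L]
    }
    if (hit == 0L) {
      cent_ids <- c(cent_ids, names(seqs)[i])
      cent_seqs <- c(cent_seqs, seqs[[i]])
      hit <- length(cent_ids)
    }
    assign_to[i] <- hit
  }
  lapply(seq_along(cent_ids), function(k)
    list(centroid = cent_ids[k], members = names(seqs)[assign_to == k]))
}

#' Dereplicate sequences
#'
#' At the default threshold of 100, exact duplicate sequences collapse to a
#' single representative (the lexicographically smallest id). Below 100,
#' representatives are the centroids of [greedy_centroid_cluster()].
#'
#' @param seqs Named character vector.
#' @param threshold Percent identity in (0, 100\].
#' @return Named character vector of representatives, with a `members`
#'   attribute listing the ids each representative absorbed.
#' @export
dereplicate <- function(seqs, threshold = 100) {
  if (length(seqs) == 0L) stop("no sequences to dereplicate")
  if (threshold >= 100) {
    groups <- split(names(seqs), unname(seqs))
    reps <- vapply(groups, function(ids) sort(ids)[1L], character(1))
    keep <- names(seqs) %in% reps
    out <- seqs[keep]
    attr(out, "members") <- stats::setNames(
      groups[match(unname(out), names(groups))], names(out))
    return(out)
  }
  cl <- greedy_centroid_cluster(seqs, threshold)
  ids <- vapply(cl, `[[`, character(1), "centroid")
  out <- seqs[ids]
  attr(out, "members") <- stats::setNames(lapply(cl, `[[`, "members"), ids)
  out
}

# local (Smith-Waterman-style) scoring of all queries against all db records,
# with Karlin-Altschul e-values; returns a full 12-column hit table
local_search_all <- function(queries, subjects, matrix = blosum62(),
                             gap_open = 11, gap_ext = 1) {
  stopifnot(length(queries) >= 1L, length(subjects) >= 1L)
  db_len <- sum(nchar(subjects))
  qset <- Biostrings::AAStringSet(unname(queries))
  out <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    aln <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(subjects[[j]]), type = "local",
      substitutionMatrix = matrix, gapOpening = gap_open,
      gapExtension = gap_ext)
    # for local alignments pattern()/subject() already carry the gapped HSP
    ga <- as.character(Biostrings::pattern(aln))
    gb <- as.character(Biostrings::subject(aln))
    cols <- nchar(ga)
    sc <- Biostrings::score(aln)
    gapopen <- vapply(seq_along(ga), function(i) {
      n_runs <- function(s) {
        r <- gregexpr("-+", s, perl = TRUE)[[1L]]
        if (r[1L] == -1L) 0L else length(r)
      }
      n_runs(ga[i]) + n_runs(gb[i])
    }, integer(1))
    ev <- KA_K * nchar(queries) * db_len * exp(-KA_LAMBDA * sc)
    bits <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
    out[[j]] <- data.frame(
      qseqid = names(queries), sseqid = names(subjects)[j],
      pident = ifelse(cols > 0, 100 * Biostrings::nmatch(aln) / cols, 0),
      length = cols,
      mismatch = Biostrings::nmismatch(aln),
      gapopen = gapopen,
      qstart = Biostrings::start(Biostrings::pattern(aln)),
      qend = Biostrings::end(Biostrings::pattern(aln)),
      sstart = Biostrings::start(Biostrings::subject(aln)),
      send = Biostrings::end(Biostrings::subject(aln)),
      evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  hits[hits$length >= 1L, , drop = FALSE]
}

#' Reduce a hit table to the single best hit per query
#'
#' Hits above `max_evalue` are dropped; among the rest, the best hit per
#' query is the highest bit score, ties broken by higher identity, then the
#' lexicographically smallest subject id.
#'
#' @param hits 12-column hit data.frame.
#' @param max_evalue E-value gate (inclusive).
#' @return Hit data.frame with at most one row per query.
#' @export
select_best_hits <- function(hits, max_evalue = 1e-5) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Search queries against a reference database, best hit per query
#'
#' The internal backend scores every query against every database record with
#' local (Smith-Waterman-style) alignment under BLOSUM62/affine gaps and
#' converts raw scores to e-values with standard gapped Karlin-Altschul
#' constants (lambda 0.267, K 0.041; database length = summed record
#' lengths). The external backend consumes a user-supplied 12-column hit file
#' produced by any standard search tool (e.g. DIAMOND, BLASTP). Both apply
#' identical e-value gating and best-hit selection.
#'
#' @param queries Named character vector of protein sequences.
#' @param db A `ref_db`.
#' @param max_evalue E-value gate (inclusive), default 1e-5.
#' @param backend "internal" or "external".
#' @param hits For the external backend: a hit file path or a hit data.frame.
#' @return Best-hit data.frame (one row per query with a retained hit).
#' @export
search_best_hits <- function(queries, db, max_evalue = 1e-5,
                             backend = c("internal", "external"),
                             hits = NULL) {
  backend <- match.arg(backend)
  if (backend == "internal") {
    if (length(queries) == 0L) stop("empty query set")
    if (is.null(names(queries))) stop("queries must be named")
    all_hits <- local_search_all(queries, db_seqs(db))
  } else {
    if (is.null(hits)) stop("external backend requires a hit file or table")
    all_hits <- if (is.character(hits)) read_hits(hits) else hits
  }
  select_best_hits(all_hits, max_evalue)
}
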