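# Best-hit annotation under identity / hit-length / e-value filters, and
# gene-family abundance as summed per-ORF read depth normalised per Gb:
#   coverage = sum over ORFs of (N * l / L) / S
# with N mapped reads, l read length (bases), L ORF length (bases), S sample
# sequencing size (Gb).

#' Filter alignment hits on identity, hit length and e-value
#'
#' Keeps exactly the hits with `pident >= min_identity`, `length >=
#' min_aln_len` and `evalue <= max_evalue` (all inclusive); row order is
#' preserved. Applying the same filter twice is a no-op.
#'
#' @param hits 12-column hit data.frame.
#' @param params A [filter_params()] object.
#' @return The filtered hit data.frame.
#' @export
filter_hits <- function(hits, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  keep <- hits$pident >= params$min_identity &
    hits$length >= params$min_aln_len &
    hits$evalue <= params$max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign gene families from best hits
#'
#' Implements the decoy-aware annotation rule: a query with no retained hit
#' is unassigned (`no_hit`); a best hit failing the filters rejects the query
#' (`failed_filter`); a best hit to a homologue record rejects the query
#' terminally (`homologue_hit`) even when a lower-ranked representative hit
#' exists; otherwise the query is annotated with the subject
#' representative's family.
#'
#' @param hits Best-hit data.frame, at most one row per query (see
#'   [search_best_hits()]).
#' @param db A `ref_db`; every hit subject must be one of its records.
#' @param params A [filter_params()].
#' @param query_ids Optional character vector of all query ids, so queries
#'   with no hit at all appear as `no_hit` rows; defaults to the queries
#'   present in `hits`.
#' @return data.frame with columns `query_id`, `family` (NA when
#'   unassigned), `rejection_reason` ("none", "no_hit", "failed_filter",
#'   "homologue_hit") and the best-hit columns `sseqid`, `pident`, `length`,
#'   `evalue`, `bitscore`.
#' @export
assign_families <- function(hits, db, params = filter_params(),
                            query_ids = NULL) {
  stopifnot(inherits(db, "ref_db"))
  if (anyDuplicated(hits$qseqid))
    stop("hits must be best-hit reduced (one row per query)")
  unknown <- setdiff(hits$sseqid, db$records$id)
  if (length(unknown))
    stop("hit subject(s) absent from database: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  if (is.null(query_ids)) query_ids <- hits$qseqid
  idx <- match(query_ids, hits$qseqid)
  ann <- data.frame(query_id = query_ids,
                    family = NA_character_,
                    rejection_reason = "no_hit",
                    sseqid = NA_character_, pident = NA_real_,
                    length = NA_integer_, evalue = NA_real_,
                    bitscore = NA_real_, stringsAsFactors = FALSE)
  has <- !is.na(idx)
  h <- hits[idx[has], , drop = FALSE]
  ann$sseqid[has] <- h$sseqid
  ann$pident[has] <- h$pident
  ann$length[has] <- h$length
  ann$evalue[has] <- h$evalue
  ann$bitscore[has] <- h$bitscore
  pass <- h$pident >= params$min_identity &
    h$length >= params$min_aln_len & h$evalue <= params$max_evalue
  role <- db$records$role[match(h$sseqid, db$records$id)]
  fam <- db$records$family[match(h$sseqid, db$records$id)]
  reason <- ifelse(!pass, "failed_filter",
                   ifelse(role == "homologue", "homologue_hit", "none"))
  ann$rejection_reason[has] <- reason
  ann$family[has] <- ifelse(reason == "none", fam, NA_character_)
  rownames(ann) <- NULL
  ann
}

#' Annotate query sequences against a reference database
#'
#' Convenience wrapper: best-hit search (internal or external backend)
#' followed by [assign_families()] under the given filters.
#'
#' @param queries Named character vector of protein sequences, or a FASTA
#'   path.
#' @param db A `ref_db`.
#' @param params A [filter_params()].
#' @param backend,hits Passed to [search_best_hits()].
#' @return Annotation data.frame (see [assign_families()]).
#' @export
annotate <- function(queries, db, params = filter_params(),
                     backend = "internal", hits = NULL) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries))
    queries <- read_fasta(queries)
  bh <- search_best_hits(queries, db, max_evalue = params$max_evalue,
                         backend = backend, hits = hits)
  assign_families(bh, db, params, query_ids = names(queries))
}

check_mappings <- function(mappings) {
  need <- c("N", "L", "l", "S")
  miss <- setdiff(need, names(mappings))
  if (length(miss)) stop("mappings missing column(s): ", paste(miss, collapse = ", "))
  if (any(mappings$N < 0)) stop("N (mapped reads) must be >= 0")
  if (any(mappings$L <= 0)) stop("L (ORF length) must be > 0")
  if (any(mappings$l <= 0)) stop("l (read length) must be > 0")
  if (any(mappings$S <= 0)) stop("S (sequencing size, Gb) must be > 0")
  invisible(mappings)
}

#' Coverage of one gene family in one sample
#'
#' Sums, over the family's ORFs, the per-ORF read depth `N * l / L`
#' normalised by the sample sequencing size `S` in Gb. `S` is interpreted as
#' total sequenced bases / 1e9.
#'
#' @param mappings data.frame of the family's ORFs in one sample, columns
#'   `N` (reads mapped), `L` (ORF length, bases), `l` (read length, bases),
#'   `S` (sample size, Gb).
#' @return Non-negative real coverage.
#' @export
orf_coverage <- function(mappings) {
  check_mappings(mappings)
  if (nrow(mappings) == 0L) return(0)
  sum(mappings$N * mappings$l / (mappings$L * mappings$S))
}

#' Family-by-sample abundance profile
#'
#' Cell (f, s) is the summed coverage of the ORFs annotated to family f in
#' sample s; unassigned ORFs are excluded and families with no ORFs are 0.
#'
#' @param annotations Annotation data.frame ([assign_families()]).
#' @param mappings data.frame with columns `sample`, `orf_id`, `N`, `L`,
#'   `l`, `S`; one row per (ORF, sample).
#' @param families Optional row universe (default: families observed in the
#'   annotations).
#' @return Numeric matrix, rows = families (lexicographic), columns =
#'   samples (lexicographic).
#' @export
abundance_profile <- function(annotations, mappings, families = NULL) {
  stopifnot(all(c("sample", "orf_id") %in% names(mappings)))
  check_mappings(mappings)
  key <- paste(mappings$sample, mappings$orf_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (orf, sample) mapping row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  fam_of <- stats::setNames(annotations$family, annotations$query_id)
  fam <- unname(fam_of[mappings$orf_id])
  if (is.null(families))
    families <- sort(unique(stats::na.omit(annotations$family)))
  samples <- sort(unique(as.character(mappings$sample)))
  m <- matrix(0, length(families), length(samples),
              dimnames = list(families, samples))
  keep <- !is.na(fam) & fam %in% families
  if (any(keep)) {
    cov <- mappings$N[keep] * mappings$l[keep] /
      (mappings$L[keep] * mappings$S[keep])
    agg <- stats::aggregate(
      cov, by = list(family = fam[keep],
                     sample = as.character(mappings$sample[keep])), FUN = sum)
    m[cbind(agg$family, agg$sample)] <- agg$x
  }
  m
}
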