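# Reference-database construction: keyword-based candidate extraction,
# core clustering with family-label inheritance, orthology expansion at 30%
# identity, strict bulk merge at 80%, and per-family compaction at 95%.
# Every stage revalidates the database invariants and records a
# machine-readable review table of its assignments.

#' Construct a candidate pool
#'
#' @param records data.frame with columns `id`, `seq`, optionally `family`
#'   (claimed family, NA when unlabelled) and `source`.
#' @param tier One of "curated", "orthology", "bulk". Curated-tier records
#'   must all carry a claimed family.
#' @return An object of class `candidate_pool`.
#' @export
candidate_pool <- function(records, tier = c("curated", "orthology", "bulk")) {
  tier <- match.arg(tier)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  records$id <- as.character(records$id)
  records$seq <- as.character(records$seq)
  if (is.null(records$family)) records$family <- NA_character_
  records$family <- as.character(records$family)
  if (is.null(records$source)) records$source <- tier
  if (anyDuplicated(records$id))
    stop("duplicate candidate id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (tier == "curated" && anyNA(records$family))
    stop("curated-tier records must carry a claimed family")
  rownames(records) <- NULL
  structure(list(records = records, tier = tier), class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("candidate pool (%s tier): %d records, %d labelled\n",
              x$tier, nrow(x$records), sum(!is.na(x$records$family))))
  invisible(x)
}

#' Extract candidate sequences by keyword rules
#'
#' A record is claimed by family F iff any of F's keywords matches its gene
#' name or function description token-wise (case-insensitive, multiword
#' keywords match as contiguous token phrases). Records matching rules of
#' more than one family are excluded as ambiguous; the exclusions are
#' returned in the pool's `ambiguous` attribute for review.
#'
#' @param records data.frame with columns `id`, `seq` and at least one of
#'   `name` (gene symbol) or `description`.
#' @param family_rules data.frame with columns `family`, `keyword` (one row
#'   per keyword).
#' @param tier Pool tier of the output (default "curated").
#' @return A `candidate_pool` of the claimed records.
#' @export
extract_candidates <- function(records, family_rules, tier = "curated") {
  rules <- check_family_rules(family_rules)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  text <- paste(records$name %||% "", records$description %||% "")
  fams <- unique(rules$family)
  claimed <- lapply(seq_len(nrow(records)), function(i) {
    hit <- vapply(seq_len(nrow(rules)), function(r)
      keyword_matches(rules$keyword[r], text[i]), logical(1))
    unique(rules$family[hit])
  })
  n_claims <- lengths(claimed)
  amb <- which(n_claims > 1L)
  keep <- which(n_claims == 1L)
  out <- data.frame(id = as.character(records$id[keep]),
                    seq = as.character(records$seq[keep]),
                    family = vapply(claimed[keep], `[[`, character(1), 1L),
                    source = "keyword", stringsAsFactors = FALSE)
  pool <- candidate_pool(out, tier = tier)
  attr(pool, "ambiguous") <- data.frame(
    id = as.character(records$id[amb]),
    families = vapply(claimed[amb], paste, character(1), collapse = ","),
    reason = "matched multiple family rules", stringsAsFactors = FALSE)
  pool
}

# build one review row per record assignment
review_row <- function(id, family, role, identity, note) {
  data.frame(id = id, family = ifelse(is.na(family), "", family),
             role = role, identity = identity, note = note,
             stringsAsFactors = FALSE)
}

append_review <- function(db, review, stage) {
  if (nrow(review)) review$stage <- stage
  db$metadata$review <- rbind(db$metadata$review, review)
  db
}

#' Build the core database from a candidate pool
#'
#' All pool records (labelled and unlabelled) are greedily clustered at the
#' identity threshold. Clusters whose labelled members agree on one family
#' become representatives of that family; unlabelled members of such clusters
#' inherit the label. Clusters mixing families are demoted wholesale to
#' homologues (the conservative reading that avoids false representatives),
#' as are clusters founded entirely by unlabelled records. Families left with
#' no representatives are dropped with a warning. All decisions are logged in
#' the database's review table (`metadata$review`).
#'
#' @param pool A `candidate_pool` containing at least one labelled record.
#' @param identity Clustering threshold, percent (default 30).
#' @param process_map Optional named vector family -> process.
#' @return A `ref_db`.
#' @export
build_core <- function(pool, identity = 30, process_map = NULL) {
  stopifnot(inherits(pool, "candidate_pool"))
  rec <- pool$records
  if (!any(!is.na(rec$family))) stop("pool contains no labelled (curated) records")
  seqs <- stats::setNames(rec$seq, rec$id)
  clusters <- greedy_centroid_cluster(seqs, identity)
  fam_of <- stats::setNames(rec$family, rec$id)
  role <- character(0); family <- character(0); ids <- character(0)
  review <- empty_review()
  for (cl in clusters) {
    labs <- unique(stats::na.omit(fam_of[cl$members]))
    if (length(labs) == 1L) {
      ids <- c(ids, cl$members)
      role <- c(role, rep("representative", length(cl$members)))
      family <- c(family, rep(labs, length(cl$members)))
      note <- ifelse(is.na(fam_of[cl$members]), "label inherited from cluster",
                     "labelled member")
      review <- rbind(review, review_row(cl$members, labs, "representative",
                                         NA_real_, note))
    } else {
      reason <- if (length(labs) == 0L) "cluster founded by unlabelled records"
                else paste0("mixed-family cluster: ", paste(labs, collapse = ","))
      if (length(labs) > 1L)
        warning("demoting mixed-family cluster around '", cl$centroid,
                "' (", paste(labs, collapse = ", "), ") to homologues")
      ids <- c(ids, cl$members)
      role <- c(role, rep("homologue", length(cl$members)))
      family <- c(family, rep(NA_character_, length(cl$members)))
      review <- rbind(review, review_row(cl$members, NA_character_,
                                         "homologue", NA_real_, reason))
    }
  }
  records <- data.frame(id = ids, seq = unname(seqs[ids]), role = role,
                        family = family,
                        source = rec$source[match(ids, rec$id)],
                        stringsAsFactors = FALSE)
  lost <- setdiff(unique(stats::na.omit(rec$family)),
                  unique(stats::na.omit(records$family)))
  if (length(lost))
    warning("family label(s) lost to demotion: ", paste(lost, collapse = ", "))
  fams <- sort(unique(stats::na.omit(records$family)))
  families <- data.frame(
    family = fams,
    process = if (is.null(process_map)) rep("others", length(fams))
              else unname(process_map[fams]),
    description = rep(NA_character_, length(fams)), stringsAsFactors = FALSE)
  db <- ref_db(records, families = families,
               metadata = list(name = "core",
                               params = list(core_identity = identity)))
  validate_ref_db(append_review(db, review, "build_core"))
}

empty_review <- function() {
  data.frame(id = character(), family = character(), role = character(),
             identity = numeric(), note = character(), stringsAsFactors = FALSE)
}

# shared engine for orthology expansion and bulk merge: candidates whose best
# identity against the representatives reaches `identity` join the database,
# as representatives when their claimed label is absent or agrees with the
# best representative's family, as homologues otherwise; the result is
# dereplicated at 100% (existing records win over additions).
merge_pool <- function(db, source, identity, stage, source_tag) {
  stopifnot(inherits(db, "ref_db"), inherits(source, "candidate_pool"))
  validate_ref_db(db)
  rec <- source$records
  if (nrow(rec) == 0L) return(db)
  reps <- db$records[db$records$role == "representative", , drop = FALSE]
  review <- empty_review()
  add <- list()
  best_id <- numeric(nrow(rec)); best_fam <- character(nrow(rec))
  # identity of every candidate against every representative, one call per rep
  idmat <- matrix(0, nrow(rec), nrow(reps))
  for (j in seq_len(nrow(reps)))
    idmat[, j] <- global_identity_many(stats::setNames(rec$seq, rec$id),
                                       reps$seq[j])
  jbest <- max.col(idmat, ties.method = "first")
  best_id <- idmat[cbind(seq_len(nrow(rec)), jbest)]
  best_fam <- reps$family[jbest]
  for (i in seq_len(nrow(rec))) {
    if (best_id[i] < identity) {
      review <- rbind(review, review_row(rec$id[i], NA_character_, "discarded",
                                         best_id[i], "below identity threshold"))
      next
    }
    claimed <- rec$family[i]
    if (is.na(claimed) || claimed == best_fam[i]) {
      add[[length(add) + 1L]] <- data.frame(
        id = rec$id[i], seq = rec$seq[i], role = "representative",
        family = best_fam[i], source = source_tag, stringsAsFactors = FALSE)
      review <- rbind(review, review_row(rec$id[i], best_fam[i],
                                         "representative", best_id[i],
                                         if (is.na(claimed)) "unlabelled, family from best representative"
                                         else "claimed family confirmed"))
    } else {
      add[[length(add) + 1L]] <- data.frame(
        id = rec$id[i], seq = rec$seq[i], role = "homologue",
        family = NA_character_, source = source_tag, stringsAsFactors = FALSE)
      review <- rbind(review, review_row(rec$id[i], NA_character_, "homologue",
                                         best_id[i],
                                         paste0("claimed '", claimed,
                                                "' conflicts with best hit '",
                                                best_fam[i], "'")))
    }
  }
  records <- rbind(db$records, do.call(rbind, c(add, list(empty_records()))))
  if (anyDuplicated(records$id))
    stop("candidate id(s) collide with database ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  # dereplicate at 100%: drop added records whose sequence already exists
  records <- records[!duplicated(records$seq), , drop = FALSE]
  rownames(records) <- NULL
  out <- db
  out$records <- records
  out$metadata$params[[paste0(stage, "_identity")]] <- identity
  validate_ref_db(append_review(out, review, stage))
}

empty_records <- function() {
  data.frame(id = character(), seq = character(), role = character(),
             family = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Expand a database against an orthology-tier candidate pool
#'
#' Source records whose best global identity against the representatives
#' reaches the threshold (default 30%) are added: as representatives of the
#' best representative's family when unlabelled or consistently labelled, as
#' homologues when their claimed family conflicts. Records below threshold
#' are discarded. The result is dereplicated at 100% identity.
#'
#' @param db A `ref_db`.
#' @param source A `candidate_pool` (orthology tier).
#' @param identity Percent threshold, default 30.
#' @return The expanded `ref_db` with an updated review table.
#' @export
expand_orthology <- function(db, source, identity = 30) {
  merge_pool(db, source, identity, "expand_orthology", "orthology")
}

#' Merge a bulk sequence source at a strict identity threshold
#'
#' Same rules as [expand_orthology()] but with the stricter default of 80%
#' global identity, appropriate for very large unlabelled sources; added
#' records carry the provenance tag "bulk".
#'
#' @inheritParams expand_orthology
#' @param identity Percent threshold, default 80.
#' @export
merge_bulk <- function(db, source, identity = 80) {
  merge_pool(db, source, identity, "merge_bulk", "bulk")
}

#' Compact named families by clustering their representatives
#'
#' Representatives of the named families are replaced by their centroids at
#' the given identity (default 95%); all other families and all homologues
#' are untouched, and the family count is unchanged.
#'
#' @param db A `ref_db`.
#' @param families Character vector of family names to compact.
#' @param identity Percent threshold, default 95.
#' @return The compacted `ref_db`.
#' @export
compact_family <- function(db, families, identity = 95) {
  validate_ref_db(db)
  unknown <- setdiff(families, db$families$family)
  if (length(unknown))
    stop("unknown family name(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(db$records))
  review <- empty_review()
  for (f in families) {
    idx <- which(db$records$role == "representative" &
                   db$records$family == f)
    if (length(idx) < 2L) next
    seqs <- stats::setNames(db$records$seq[idx], db$records$id[idx])
    reps <- dereplicate(seqs, identity)
    drop_ids <- setdiff(names(seqs), names(reps))
    keep[idx[db$records$id[idx] %in% drop_ids]] <- FALSE
    if (length(drop_ids))
      review <- rbind(review, review_row(drop_ids, f, "compacted-away",
                                         NA_real_,
                                         sprintf("absorbed at %g%% centroid", identity)))
  }
  out <- db
  out$records <- db$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$metadata$params$compact_identity <- identity
  validate_ref_db(append_review(out, review, "compact_family"))
}
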