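# Seeded generators for synthetic gene families, homologue decoys, unrelated
# negatives, mock genomes and read mappings. Substitution-only mutation by
# default (an indel-rate knob exists, default 0) so realised identities track
# 100 * (1 - divergence) analytically. All generators are pure functions of
# the spec's seed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification for synthetic data generation
#'
#' @param seed Integer RNG seed; identical specs give identical output.
#' @param n_families Number of gene families.
#' @param members_per_family Members drawn per family (>= 2; half become
#'   database representatives, half truth-labelled queries).
#' @param ancestor_length Ancestor protein length (aa).
#' @param within_divergence Expected fraction of substituted positions
#'   between a member and its family ancestor.
#' @param decoy_divergence Divergence of homologue-decoy ancestors from the
#'   family ancestor; must exceed `within_divergence`.
#' @param n_negatives Number of unrelated true-negative sequences.
#' @param indel_rate Per-position indel probability (default 0).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_families = 10L, members_per_family = 6L,
                       ancestor_length = 300L, within_divergence = 0.1,
                       decoy_divergence = 0.45, n_negatives = 20L,
                       indel_rate = 0) {
  stopifnot(n_families >= 1L, members_per_family >= 1L, ancestor_length >= 10L,
            within_divergence >= 0, within_divergence <= 1,
            decoy_divergence >= 0, decoy_divergence <= 1,
            n_negatives >= 0L, indel_rate >= 0, indel_rate <= 1)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 ancestor_length = as.integer(ancestor_length),
                 within_divergence = within_divergence,
                 decoy_divergence = decoy_divergence,
                 n_negatives = as.integer(n_negatives),
                 indel_rate = indel_rate), class = "synth_spec")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# i.i.d. substitutions at `rate`; substituted positions always change letter
mutate_seq <- function(seq, rate, indel_rate = 0) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  if (indel_rate > 0) {
    keep <- stats::runif(length(ch)) >= indel_rate / 2
    ch <- ch[keep]
    ins <- which(stats::runif(length(ch)) < indel_rate / 2)
    for (i in rev(ins)) ch <- append(ch, sample(AA20, 1L), after = i)
  }
  paste(ch, collapse = "")
}

#' Generate synthetic gene families with a database and labelled queries
#'
#' Per family an ancestor is drawn uniformly over the 20 amino acids and
#' members derive from it by i.i.d. substitutions at `within_divergence`.
#' The first half of each family's members become database representatives,
#' the rest truth-labelled positive queries. Family ancestors are retained in
#' the database metadata so decoys can be planted later.
#'
#' @param spec A [synth_spec()].
#' @return List: `db` (a `ref_db`), `queries` (named character vector),
#'   `truth` (truth-label data.frame).
#' @export
make_families <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$members_per_family < 2L)
    stop("members_per_family must be >= 2 (database half + query half)")
  with_seed(spec$seed, {
    fams <- sprintf("fam%02d", seq_len(spec$n_families))
    procs <- rep_len(setdiff(default_processes(), "others"), spec$n_families)
    anc <- stats::setNames(
      vapply(fams, function(f) random_protein(spec$ancestor_length),
             character(1)), fams)
    recs <- list(); queries <- character(0); truth <- list()
    n_rep <- ceiling(spec$members_per_family / 2)
    for (f in fams) {
      # the founder (unmutated ancestor) is the family's first
      # representative, so member-to-best-representative identity tracks
      # 100 * (1 - within_divergence) analytically
      mem <- c(anc[[f]],
               vapply(seq_len(spec$members_per_family - 1L), function(i)
                 mutate_seq(anc[[f]], spec$within_divergence, spec$indel_rate),
                 character(1)))
      rep_ids <- sprintf("%s_rep%d", f, seq_len(n_rep))
      q_ids <- sprintf("%s_q%d", f,
                       seq_len(spec$members_per_family - n_rep))
      recs[[f]] <- data.frame(id = rep_ids, seq = mem[seq_len(n_rep)],
                              role = "representative", family = f,
                              source = "synthetic", stringsAsFactors = FALSE)
      if (length(q_ids)) {
        q <- stats::setNames(mem[n_rep + seq_along(q_ids)], q_ids)
        queries <- c(queries, q)
        truth[[f]] <- truth_labels(q_ids, TRUE, f)
      }
    }
    db <- ref_db(do.call(rbind, recs),
                 families = data.frame(family = fams, process = procs,
                                       description = NA_character_,
                                       stringsAsFactors = FALSE),
                 metadata = list(name = "synthetic",
                                 ancestors = anc, spec = spec))
    list(db = db, queries = queries, truth = do.call(rbind, c(truth, list(
      truth_labels(character(0), logical(0), character(0)))))[, , drop = FALSE])
  })
}

#' Plant homologue decoys for a family
#'
#' A decoy ancestor is derived from the family ancestor at
#' `decoy_divergence`; database homologue records and decoy queries are then
#' drawn around it at `within_divergence`, so a decoy query's best database
#' hit is the homologue record (the false-positive rejection scenario), with
#' identity to the true representatives intermediate between members and
#' unrelated sequences.
#'
#' @param spec A [synth_spec()]; `decoy_divergence` must exceed
#'   `within_divergence`.
#' @param db Database from [make_families()] (supplies the ancestors).
#' @param family Family name to plant decoys for.
#' @param n_records Homologue records added to the database.
#' @param n_queries Decoy query sequences emitted (truth: non-target).
#' @return List: `records` (homologue record data.frame), `queries` (named
#'   vector), `truth`.
#' @export
make_decoys <- function(spec, db, family, n_records = 1L, n_queries = 1L) {
  stopifnot(inherits(spec, "synth_spec"), inherits(db, "ref_db"))
  if (spec$decoy_divergence <= spec$within_divergence)
    stop("decoy_divergence must exceed within_divergence, or decoys are ",
         "indistinguishable from family members")
  anc <- db$metadata$ancestors
  if (is.null(anc) || !family %in% names(anc))
    stop("no ancestor recorded for family '", family, "'")
  idx <- match(family, names(anc))
  with_seed(spec$seed + 7919L * idx, {
    dec_anc <- mutate_seq(anc[[family]], spec$decoy_divergence)
    rec_ids <- sprintf("%s_hom%d", family, seq_len(n_records))
    q_ids <- sprintf("%s_decq%d", family, seq_len(n_queries))
    records <- if (n_records > 0L)
      data.frame(id = rec_ids,
                 # first homologue record is the decoy founder itself
                 seq = c(dec_anc,
                         vapply(seq_len(n_records - 1L), function(i)
                           mutate_seq(dec_anc, spec$within_divergence),
                           character(1))),
                 role = "homologue", family = NA_character_,
                 source = "synthetic-decoy", stringsAsFactors = FALSE)
    else empty_records()
    queries <- if (n_queries > 0L)
      stats::setNames(vapply(q_ids, function(i)
        mutate_seq(dec_anc, spec$within_divergence), character(1)), q_ids)
    else character(0)
    list(records = records, queries = queries,
         truth = truth_labels(q_ids[seq_len(n_queries)],
                              rep(FALSE, n_queries)))
  })
}

#' Add records (e.g. decoys) to a reference database
#' @param db A `ref_db`.
#' @param records Record data.frame (id, seq, role, family, source).
#' @return The enlarged, revalidated `ref_db`.
#' @export
db_add_records <- function(db, records) {
  db$records <- rbind(db$records, records[, names(db$records), drop = FALSE])
  rownames(db$records) <- NULL
  validate_ref_db(db)
  db
}

#' Generate unrelated true-negative sequences
#'
#' Independent uniform-random proteins, unrelated to any database family
#' (background global identity, empirically well below 30% at typical
#' lengths).
#'
#' @param spec A [synth_spec()].
#' @return List: `queries` (named vector of `n_negatives` sequences),
#'   `truth` (is_target = FALSE).
#' @export
make_negatives <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 104729L, {
    ids <- sprintf("neg%03d", seq_len(spec$n_negatives))
    queries <- stats::setNames(
      vapply(ids, function(i) random_protein(spec$ancestor_length),
             character(1)), ids)
    list(queries = queries, truth = truth_labels(ids, rep(FALSE, length(ids))))
  })
}

#' Generate a mock genome with known family content
#'
#' The proteome carries one member per present family (drawn at
#' `within_divergence` from the family ancestor) plus unrelated background
#' proteins; the GFF3 annotation lists exactly the present families via
#' `gene=` attributes. Optionally, members of additional families are
#' planted in the proteome but omitted from the GFF (`fp_families`), so a
#' permissive annotation run predicts `length(families_present) + k`
#' families and the detection ratio becomes (F + k) / F.
#'
#' @param spec A [synth_spec()].
#' @param db Database from [make_families()].
#' @param families_present Non-empty subset of the database's families.
#' @param n_background Unrelated background proteins.
#' @param fp_families Families planted in the proteome but not annotated.
#' @param genome_id Genome identifier (GFF seqid).
#' @return List: `proteome` (named vector), `gff` (character lines),
#'   `families_present`, `genome_id`.
#' @export
make_mock_genome <- function(spec, db, families_present, n_background = 5L,
                             fp_families = character(0),
                             genome_id = "mock_genome") {
  stopifnot(inherits(spec, "synth_spec"), inherits(db, "ref_db"))
  if (length(families_present) == 0L) stop("families_present must be non-empty")
  bad <- setdiff(c(families_present, fp_families), db$families$family)
  if (length(bad))
    stop("not database families: ", paste(bad, collapse = ", "))
  if (length(intersect(families_present, fp_families)))
    stop("fp_families must be disjoint from families_present")
  anc <- db$metadata$ancestors
  with_seed(spec$seed + 15485863L, {
    genes <- c(families_present, fp_families)
    prot <- stats::setNames(
      vapply(genes, function(f)
        mutate_seq(anc[[f]], spec$within_divergence), character(1)),
      sprintf("%s_%s_orf", genome_id, genes))
    if (n_background > 0L) {
      bg <- stats::setNames(
        vapply(seq_len(n_background), function(i)
          random_protein(spec$ancestor_length), character(1)),
        sprintf("%s_bg%02d_orf", genome_id, seq_len(n_background)))
      prot <- c(prot, bg)
    }
    n_feat <- length(families_present) + n_background
    gene_attr <- c(families_present,
                   sprintf("hyp%02d", seq_len(n_background)))
    prod_attr <- c(paste(families_present, "protein"),
                   rep("hypothetical protein", n_background))
    starts <- (seq_len(n_feat) - 1L) * 1000L + 1L
    gff <- c("##gff-version 3",
             sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=g%03d;gene=%s;product=%s",
                     genome_id, starts, starts + 899L, seq_len(n_feat),
                     gene_attr, prod_attr))
    list(proteome = prot, gff = gff, families_present = families_present,
         genome_id = genome_id)
  })
}

#' Construct read mappings that realise a target abundance profile
#'
#' Inverts the coverage formula: for target coverage c the mapped-read count
#' is N = c * S * L / l, which must be a whole number; otherwise the nearest
#' achievable coverage is reported in the error. One ORF per family, mapped
#' in every sample.
#'
#' @param profile_truth Numeric matrix family x sample of target coverages
#'   (>= 0).
#' @param l Read length (bases), per-sample constant.
#' @param L ORF length (bases).
#' @param S Sample sequencing size (Gb).
#' @return List: `mappings` (data.frame sample, orf_id, N, L, l, S),
#'   `annotations` (orf -> family annotation table).
#' @export
make_read_mappings <- function(profile_truth, l = 150, L = 1500, S = 5) {
  stopifnot(is.matrix(profile_truth), all(profile_truth >= 0),
            !is.null(rownames(profile_truth)), !is.null(colnames(profile_truth)))
  fams <- rownames(profile_truth); samples <- colnames(profile_truth)
  rows <- list()
  for (s in samples) {
    n_exact <- profile_truth[, s] * S * L / l
    N <- round(n_exact)
    off <- abs(N - n_exact) > 1e-9
    if (any(off))
      stop("coverage not representable with integer reads for ",
           fams[off][1L], "/", s, "; nearest achievable coverage is ",
           N[off][1L] * l / (L * S))
    rows[[s]] <- data.frame(sample = s, orf_id = paste0(fams, "_orf1"),
                            N = as.integer(N), L = L, l = l, S = S,
                            stringsAsFactors = FALSE)
  }
  ann <- data.frame(query_id = paste0(fams, "_orf1"), family = fams,
                    rejection_reason = "none", stringsAsFactors = FALSE)
  list(mappings = do.call(rbind, c(rows, list(NULL))), annotations = ann)
}

#' Generate a complete labelled benchmark set
#'
#' Families with representatives and positive queries, one decoy sub-family
#' per database family (homologue records plus decoy queries), and unrelated
#' negatives: everything the simulated-gene validation design needs.
#'
#' @param spec A [synth_spec()].
#' @param decoys_per_family Homologue records (and decoy queries) per family.
#' @return List: `db` (with decoy records), `queries`, `truth`.
#' @export
make_benchmark <- function(spec, decoys_per_family = 1L) {
  base <- make_families(spec)
  db <- base$db; queries <- base$queries; truth <- base$truth
  if (decoys_per_family > 0L) {
    for (f in db$families$family) {
      d <- make_decoys(spec, db, f, n_records = decoys_per_family,
                       n_queries = decoys_per_family)
      db <- db_add_records(db, d$records)
      queries <- c(queries, d$queries)
      truth <- rbind(truth, d$truth)
    }
  }
  neg <- make_negatives(spec)
  list(db = db, queries = c(queries, neg$queries),
       truth = rbind(truth, neg$truth))
}
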