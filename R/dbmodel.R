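# Domain containers and plain-text readers/writers:
#   reference databases (FASTA + id->family map), 12-column tabular hit files,
#   filter parameter sets, and family-by-sample abundance profiles.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Token used for unassigned queries in exported annotation tables
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Read a protein FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header and must
#' be unique. Sequences are upper-cased; terminal stop codons (`*`) are
#' stripped, internal stops or letters outside the amino-acid alphabet
#' (20 standard residues plus `X`) are rejected with the offending record id.
#'
#' @param path Path to a FASTA text file.
#' @return Named character vector of sequences (names = record ids), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicated FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_aa(seqs)
}

# strip terminal '*', reject internal '*' and non-alphabet letters
validate_aa <- function(seqs) {
  seqs <- sub("\\*+$", "", seqs)
  ok_chars <- c(AA_ALPHABET)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) < 1L)
      stop("empty sequence for record '", names(seqs)[i], "'")
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(ch), ok_chars)
    if (length(bad))
      stop("record '", names(seqs)[i],
           "' contains invalid amino-acid letter(s): ",
           paste(bad, collapse = ", "))
  }
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a reference database
#'
#' A reference database holds representative sequences, each labelled with a
#' gene family, and nontarget homologue decoys carrying no family label. A
#' best hit to a representative annotates a query; a best hit to a homologue
#' rejects it, suppressing false positives from related non-target genes.
#'
#' @param records data.frame with columns `id`, `seq`, `role`
#'   ("representative" or "homologue"), `family` (NA for homologues) and
#'   optionally `source`.
#' @param families Optional data.frame with columns `family`, `process`,
#'   `description`; derived from `records` when omitted.
#' @param process_list Character vector of allowed metabolic processes.
#' @param metadata Named list of free-form provenance (name, version,
#'   creation parameters).
#' @return An object of class `ref_db`.
#' @export
ref_db <- function(records, families = NULL,
                   process_list = default_processes(),
                   metadata = list()) {
  stopifnot(is.data.frame(records))
  need <- c("id", "seq", "role", "family")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  records$id <- as.character(records$id)
  records$seq <- as.character(records$seq)
  records$role <- as.character(records$role)
  records$family <- as.character(records$family)
  if (is.null(records$source)) records$source <- NA_character_
  rownames(records) <- NULL
  if (is.null(families)) {
    fam <- sort(unique(records$family[records$role == "representative"]))
    families <- data.frame(family = fam,
                           process = rep("others", length(fam)),
                           description = rep(NA_character_, length(fam)),
                           stringsAsFactors = FALSE)
  }
  db <- structure(list(records = records, families = families,
                       process_list = process_list, metadata = metadata),
                  class = "ref_db")
  validate_ref_db(db)
  db
}

#' Default phosphorus metabolic process vocabulary
#' @return Character vector of the ten P-cycling processes plus "others".
#' @export
default_processes <- function() {
  c("two-component system", "transporters",
    "organic phosphoester hydrolysis", "pyruvate metabolism",
    "pentose phosphate pathway", "phosphotransferase system",
    "oxidative phosphorylation", "phosphonate and phosphinate metabolism",
    "purine metabolism", "pyrimidine metabolism", "others")
}

#' Check reference-database invariants
#'
#' Errors unless: ids are unique, roles valid, every representative carries a
#' family listed in `families`, homologues carry none, every family has at
#' least one representative, and processes are drawn from the declared list.
#'
#' @param db A `ref_db`.
#' @return `db`, invisibly.
#' @export
validate_ref_db <- function(db) {
  r <- db$records
  if (anyDuplicated(r$id))
    stop("duplicate record id(s): ",
         paste(unique(r$id[duplicated(r$id)]), collapse = ", "))
  if (!all(r$role %in% c("representative", "homologue")))
    stop("record role must be 'representative' or 'homologue'")
  if (any(nchar(r$seq) < 1L)) stop("zero-length sequence in records")
  rep_idx <- r$role == "representative"
  if (any(is.na(r$family[rep_idx])))
    stop("representative without family label")
  if (any(!is.na(r$family[!rep_idx])))
    stop("homologue records must not carry a family label")
  f <- db$families
  if (anyDuplicated(f$family)) stop("duplicate family names")
  if (any(!nzchar(f$family))) stop("empty family name")
  if (!all(r$family[rep_idx] %in% f$family))
    stop("representative references unknown family")
  no_rep <- setdiff(f$family, r$family[rep_idx])
  if (length(no_rep))
    stop("family without representatives: ", paste(no_rep, collapse = ", "))
  if (!is.null(f$process) && !all(is.na(f$process) | f$process %in% db$process_list))
    stop("family process outside the declared process list")
  invisible(db)
}

#' @export
print.ref_db <- function(x, ...) {
  nr <- sum(x$records$role == "representative")
  nh <- sum(x$records$role == "homologue")
  cat("Reference database", if (!is.null(x$metadata$name)) x$metadata$name else "",
      "\n  families:       ", nrow(x$families),
      "\n  representatives:", nr,
      "\n  homologues:     ", nh, "\n")
  invisible(x)
}

# convenient accessors ------------------------------------------------------

#' Sequences of a reference database as a named vector
#' @param db A `ref_db`.
#' @param role Optional role filter.
#' @return Named character vector.
#' @export
db_seqs <- function(db, role = NULL) {
  r <- db$records
  if (!is.null(role)) r <- r[r$role == role, , drop = FALSE]
  stats::setNames(r$seq, r$id)
}

#' Family label of each record id (NA for homologues)
#' @param db A `ref_db`.
#' @return Named character vector id -> family.
#' @export
db_family_of <- function(db) stats::setNames(db$records$family, db$records$id)

#' Read a reference database from disk
#'
#' On-disk layout: one protein FASTA plus one TSV id-map with header columns
#' `id`, `family` (and optionally `process`). Rows whose family equals
#' `homologue_token` are decoys. Alternatively, when `idmap` is `NULL` and
#' `id_delim` is given, the family is parsed from each FASTA id as the suffix
#' after the last delimiter (compatibility with releases that encode families
#' in identifiers).
#'
#' @param fasta Path to the sequence FASTA.
#' @param idmap Path to the id->family TSV, or `NULL` to parse from ids.
#' @param homologue_token Family value marking decoys (default "homologue").
#' @param id_delim Delimiter for suffix-encoded families.
#' @param process_list Allowed process vocabulary.
#' @return A `ref_db`.
#' @export
read_db <- function(fasta, idmap = NULL, homologue_token = "homologue",
                    id_delim = NULL, process_list = default_processes()) {
  seqs <- read_fasta(fasta)
  if (is.null(idmap)) {
    if (is.null(id_delim))
      stop("either an id-map TSV or an id_delim must be supplied")
    ids <- names(seqs)
    has <- grepl(id_delim, ids, fixed = TRUE)
    if (!all(has))
      stop("id(s) lack the family delimiter '", id_delim, "': ",
           paste(utils::head(ids[!has], 3L), collapse = ", "))
    fam <- sub(paste0(".*", escape_regex(id_delim)), "", ids)
    map <- data.frame(id = ids, family = fam, stringsAsFactors = FALSE)
  } else {
    map <- utils::read.delim(idmap, stringsAsFactors = FALSE)
    if (!all(c("id", "family") %in% names(map)))
      stop("id-map must have header columns 'id' and 'family'")
    if (anyDuplicated(map$id))
      stop("duplicate id-map row(s) for: ",
           paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  }
  missing_in_fasta <- setdiff(map$id, names(seqs))
  if (length(missing_in_fasta))
    stop("id-map references id(s) absent from FASTA: ",
         paste(utils::head(missing_in_fasta, 5L), collapse = ", "))
  unmapped <- setdiff(names(seqs), map$id)
  if (length(unmapped))
    stop("FASTA record(s) absent from id-map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  map <- map[match(names(seqs), map$id), , drop = FALSE]
  is_hom <- map$family == homologue_token
  records <- data.frame(
    id = map$id, seq = unname(seqs),
    role = ifelse(is_hom, "homologue", "representative"),
    family = ifelse(is_hom, NA_character_, map$family),
    source = "disk", stringsAsFactors = FALSE)
  families <- NULL
  if (!is.null(map$process)) {
    fm <- unique(map[!is_hom, c("family", "process")])
    families <- data.frame(family = fm$family, process = fm$process,
                           description = NA_character_,
                           stringsAsFactors = FALSE)
    families <- families[order(families$family), , drop = FALSE]
    rownames(families) <- NULL
  }
  ref_db(records, families = families, process_list = process_list,
         metadata = list(name = basename(fasta)))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Write a reference database to disk
#'
#' Emits `db.fasta` and `db_map.tsv` (columns id, family, process) in `dir`.
#'
#' @param db A `ref_db`.
#' @param dir Output directory (created if absent).
#' @param homologue_token Family token written for decoys.
#' @return The directory, invisibly.
#' @export
write_db <- function(db, dir, homologue_token = "homologue") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db_seqs(db), file.path(dir, "db.fasta"))
  fam <- ifelse(is.na(db$records$family), homologue_token, db$records$family)
  proc <- db$families$process[match(db$records$family, db$families$family)]
  utils::write.table(
    data.frame(id = db$records$id, family = fam,
               process = ifelse(is.na(proc), "", proc)),
    file.path(dir, "db_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# hit tables -----------------------------------------------------------------

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT_NUMERIC <- HIT_COLS[3:12]

#' Read a 12-column tabular hit file
#'
#' Standard tab-separated homology-search output (`outfmt 6` compatible):
#' query id, subject id, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bit score. Coordinates
#' are 1-based inclusive. Row order is preserved.
#'
#' @param path Path to the hit file; an empty file yields zero rows.
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("hit file row ", which(nf != 12L)[1L], " has ", nf[nf != 12L][1L],
         " column(s); expected 12")
  m <- do.call(rbind, parts)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("unparseable numeric in hit file column ", j, ", row ",
           which(is.na(v))[1L])
    hits[[HIT_COLS[j]]] <- v
  }
  for (cn in c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send"))
    hits[[cn]] <- as.integer(hits[[cn]])
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  h <- data.frame(qseqid = character(), sseqid = character(),
                  pident = numeric(), length = integer(),
                  mismatch = integer(), gapopen = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  stringsAsFactors = FALSE)
  h
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("identity outside [0, 100]")
  if (any(hits$length < 1L)) stop("alignment length < 1")
  if (any(hits$evalue < 0)) stop("negative e-value")
  if (any(hits$qstart > hits$qend)) stop("qstart > qend")
  invisible(hits)
}

#' Write a 12-column tabular hit file
#' @param hits data.frame as returned by [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(HIT_COLS %in% names(hits)))
  ev <- formatC(hits$evalue, format = "g", digits = 15)
  out <- cbind(hits$qseqid, hits$sseqid,
               formatC(hits$pident, format = "g", digits = 15),
               hits$length, hits$mismatch, hits$gapopen,
               hits$qstart, hits$qend, hits$sstart, hits$send,
               ev, formatC(hits$bitscore, format = "g", digits = 15))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

# filter parameters -----------------------------------------------------------

#' Best-hit filter parameters
#'
#' Defaults follow the published metagenome annotation criteria: identity
#' >= 30.0%, hit length >= 25 aa, e-value <= 1e-5. All thresholds are
#' inclusive.
#'
#' @param min_identity Minimum percent identity in \[0, 100\].
#' @param min_aln_len Minimum aligned length (amino acids), >= 1.
#' @param max_evalue Maximum e-value, > 0.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_identity = 30.0, min_aln_len = 25L,
                          max_evalue = 1e-5) {
  stopifnot(is.numeric(min_identity), min_identity >= 0, min_identity <= 100,
            is.numeric(min_aln_len), min_aln_len >= 1,
            is.numeric(max_evalue), max_evalue > 0)
  structure(list(min_identity = as.numeric(min_identity),
                 min_aln_len = as.numeric(min_aln_len),
                 max_evalue = as.numeric(max_evalue)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("filters: identity >= %.1f%%, hit length >= %d aa, e-value <= %g\n",
              x$min_identity, as.integer(x$min_aln_len), x$max_evalue))
  invisible(x)
}

# abundance profiles -----------------------------------------------------------

#' Write a family-by-sample abundance profile
#'
#' TSV with a `family` column followed by one column per sample; rows and
#' columns in lexicographic order.
#'
#' @param profile Numeric matrix, rownames = families, colnames = samples.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(is.matrix(profile))
  if (nrow(profile) > 0 || ncol(profile) > 0)
    profile <- profile[order(rownames(profile)), order(colnames(profile)),
                       drop = FALSE]
  df <- data.frame(family = rownames(profile) %||% character(0), profile,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family-by-sample abundance profile written by [write_profile()]
#' @param path Path to the TSV.
#' @return Numeric matrix with family rownames and sample colnames.
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "family") stop("profile file must start with a 'family' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(df) > 0 && !is.numeric(m)) storage.mode(m) <- "double"
  rownames(m) <- df$family
  m
}
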