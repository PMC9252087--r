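# Independent brute-force oracles, kept deliberately simple and separate from
# the implementation paths they check.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

rand_protein <- function(n) paste(sample(AA20_T, n, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20_T, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Full three-state (Gotoh) dynamic programme, affine gap cost go + k * ge.
# type "global": end-to-end with penalised terminal gaps; type "local":
# Smith-Waterman (zero floor, maximum over match-ending cells).
# Returns the optimal score only -- an independent check of the alignment
# engine's scoring.
dp_align_score <- function(a, b, type = c("global", "local"),
                           go = 11, ge = 1, mat = b62) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  if (type == "global") {
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
    for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      if (type == "local") diag_best <- max(diag_best, 0)
      M[i + 1, j + 1] <- s + diag_best
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else max(0, max(M[-1, -1]))
}

# all-pairs global identity matrix, direct per-pair calls
identity_matrix_oracle <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    m[i, j] <- m[j, i] <- global_identity(seqs[[i]], seqs[[j]])
  }
  m
}

# brute-force best hit: per-pair local alignments, argmax bit score with the
# engine's documented tie-breaks, e-value gate recomputed from first
# principles (lambda 0.267, K 0.041, n = summed db length)
brute_force_best_hit <- function(query, subjects, max_evalue = 1e-5) {
  db_len <- sum(nchar(subjects))
  score <- numeric(length(subjects))
  ident <- numeric(length(subjects))
  for (k in seq_along(subjects)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subjects[[k]]),
      type = "local", substitutionMatrix = b62, gapOpening = 11,
      gapExtension = 1)
    score[k] <- Biostrings::score(aln)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    ident[k] <- if (cols == 0) 0 else 100 * Biostrings::nmatch(aln) / cols
  }
  ev <- 0.041 * nchar(query) * db_len * exp(-0.267 * score)
  ok <- which(ev <= max_evalue)
  if (length(ok) == 0L) return(NA_character_)
  ord <- ok[order(-score[ok], -ident[ok], names(subjects)[ok])]
  names(subjects)[ord[1L]]
}

# tiny ad-hoc reference database around explicit sequences
tiny_db <- function(rep_seqs, hom_seqs = character(0), family = "famA") {
  recs <- data.frame(
    id = c(names(rep_seqs), names(hom_seqs)),
    seq = c(unname(rep_seqs), unname(hom_seqs)),
    role = c(rep("representative", length(rep_seqs)),
             rep("homologue", length(hom_seqs))),
    family = c(rep(family, length(rep_seqs)),
               rep(NA_character_, length(hom_seqs))),
    stringsAsFactors = FALSE)
  ref_db(recs)
}

# a minimal valid best-hit row for constructing annotation inputs
mk_hit <- function(qseqid, sseqid, pident, length, evalue = 1e-10,
                   bitscore = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = as.integer(length), mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = as.integer(length), sstart = 1L,
             send = as.integer(length), evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}
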