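# Validation designs: simulated-gene confusion metrics with identity /
# hit-length threshold sweeps, per-family detection rates, and mock-genome
# detection ratios with over/exact/under classification.

#' Truth-label table constructor
#'
#' @param query_id Character vector of query ids.
#' @param is_target Logical: does the query belong to a database family?
#' @param true_family Family name for targets, NA otherwise.
#' @return data.frame with the three columns, validated.
#' @export
truth_labels <- function(query_id, is_target, true_family = NA_character_) {
  df <- data.frame(query_id = as.character(query_id),
                   is_target = as.logical(is_target),
                   true_family = rep_len(as.character(true_family),
                                         length(query_id)),
                   stringsAsFactors = FALSE)
  if (any(df$is_target & is.na(df$true_family)))
    stop("target queries must carry a true_family")
  if (any(!df$is_target & !is.na(df$true_family)))
    stop("non-target queries must not carry a true_family")
  if (anyDuplicated(df$query_id)) stop("duplicate truth query ids")
  df
}

#' Score annotations against truth labels
#'
#' At the `binary` level a true positive is a target query assigned to any
#' family; at the `family` level it must be assigned to its own family, and
#' a target assigned to a wrong family counts as a false positive (not a
#' false negative), so that precision penalises cross-family confusion.
#'
#' @param annotations Annotation data.frame ([assign_families()]).
#' @param truth Truth data.frame ([truth_labels()]); every annotated query
#'   must have a label.
#' @param level "binary" (default) or "family".
#' @return Object of class `confusion_counts`: integers TP, FP, TN, FN.
#' @export
score_queries <- function(annotations, truth, level = c("binary", "family")) {
  level <- match.arg(level)
  idx <- match(annotations$query_id, truth$query_id)
  if (anyNA(idx))
    stop("annotation(s) without truth label: ",
         paste(utils::head(annotations$query_id[is.na(idx)], 5L), collapse = ", "))
  is_t <- truth$is_target[idx]
  true_f <- truth$true_family[idx]
  assigned <- !is.na(annotations$family)
  if (level == "binary") {
    TP <- sum(is_t & assigned)
    FN <- sum(is_t & !assigned)
    FP <- sum(!is_t & assigned)
    TN <- sum(!is_t & !assigned)
  } else {
    correct <- assigned & is_t & annotations$family == true_f
    TP <- sum(correct)
    FP <- sum(assigned & !correct)   # negatives assigned + targets misassigned
    FN <- sum(is_t & !assigned)
    TN <- sum(!is_t & !assigned)
  }
  confusion_counts(TP, FP, TN, FN)
}

#' Confusion counts
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Accuracy, PPV, specificity, sensitivity and NPV from confusion counts
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN); PPV = TP/(TP+FP); specificity =
#' TN/(TN+FP); sensitivity = TP/(TP+FN); NPV = TN/(TN+FN). A ratio whose
#' denominator is zero is reported as `NA` (undefined), never an error.
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector of the five metrics in \[0, 1\] or NA.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, c(
    accuracy = safe(TP + TN, TP + FP + TN + FN),
    ppv = safe(TP, TP + FP),
    specificity = safe(TN, TN + FP),
    sensitivity = safe(TP, TP + FN),
    npv = safe(TN, TN + FN)))
}

#' Default sweep axes
#'
#' Identity from 0.2 to 99.9% in steps of 0.1 (998 points); hit length from
#' 2 to 99 aa in steps of 1 (98 points).
#' @name sweep_axes
#' @export
default_identity_grid <- function() seq(0.2, 99.9, by = 0.1)

#' @rdname sweep_axes
#' @export
default_len_grid <- function() seq(2L, 99L, by = 1L)

#' Confusion metrics over an identity x hit-length threshold grid
#'
#' For every grid cell the best hits are re-filtered at that (identity, hit
#' length), families re-assigned and confusion counts re-scored. The grid is
#' computed cumulatively from a single pass over the sorted hits (a 2-D
#' suffix-sum of the per-query threshold histogram), which is exactly
#' equivalent to naive per-cell recomputation.
#'
#' @param best_hits Best-hit data.frame, at most one row per query.
#' @param db A `ref_db`.
#' @param truth Truth data.frame covering all queries.
#' @param identity_grid,len_grid Strictly increasing threshold axes.
#' @param level "binary" or "family" (see [score_queries()]).
#' @param max_evalue E-value gate applied before sweeping.
#' @param query_ids All query ids (defaults to the truth table's ids).
#' @return Object of class `sweep_grid`: the axes plus matrices TP, FP, TN,
#'   FN and the five metric matrices (rows = identity, cols = length;
#'   undefined cells NA).
#' @export
threshold_sweep <- function(best_hits, db, truth,
                            identity_grid = default_identity_grid(),
                            len_grid = default_len_grid(),
                            level = c("binary", "family"),
                            max_evalue = 1e-5, query_ids = NULL) {
  level <- match.arg(level)
  if (nrow(truth) == 0L) stop("empty truth table")
  if (is.unsorted(identity_grid, strictly = TRUE) ||
      is.unsorted(len_grid, strictly = TRUE))
    stop("grid axes must be strictly increasing")
  if (anyDuplicated(best_hits$qseqid))
    stop("best_hits must be one row per query")
  if (is.null(query_ids)) query_ids <- truth$query_id
  idx <- match(query_ids, truth$query_id)
  if (anyNA(idx)) stop("query id(s) missing from truth")
  is_t <- truth$is_target[idx]
  true_f <- truth$true_family[idx]

  h <- best_hits[match(query_ids, best_hits$qseqid), , drop = FALSE]
  gated <- !is.na(h$qseqid) & h$evalue <= max_evalue
  role <- db$records$role[match(h$sseqid, db$records$id)]
  fam <- db$records$family[match(h$sseqid, db$records$id)]
  # a query can ever be assigned only via a representative best hit that
  # passed the e-value gate; homologue hits and no-hits are never assigned
  assignable <- gated & !is.na(role) & role == "representative"
  correct <- assignable & is_t & !is.na(fam) & fam == true_f

  ni <- length(identity_grid); nl <- length(len_grid)
  # count, per class, queries passing each (identity, length) cell
  pass_grid <- function(sel) {
    m <- matrix(0L, ni, nl)
    if (!any(sel)) return(m)
    im <- findInterval(h$pident[sel], identity_grid)  # passes cells 1..im
    lm <- findInterval(h$length[sel], len_grid)
    keep <- im >= 1L & lm >= 1L
    if (!any(keep)) return(m)
    hist2 <- matrix(0L, ni, nl)
    tab <- table(factor(im[keep], levels = seq_len(ni)),
                 factor(lm[keep], levels = seq_len(nl)))
    hist2[] <- as.integer(tab)
    # suffix -> prefix: query passes all cells (i <= im, j <= lm)
    s <- apply(apply(hist2, 2L, rev_cumsum_rev), 1L, rev_cumsum_rev)
    t(s)
  }
  if (level == "binary") {
    TPg <- pass_grid(assignable & is_t)
    FPg <- pass_grid(assignable & !is_t)
    TN <- sum(!is_t) - FPg
    FN <- sum(is_t) - TPg
    TP <- TPg; FP <- FPg
  } else {
    TP <- pass_grid(correct)
    wrong_t <- pass_grid(assignable & is_t & !correct)
    FP <- pass_grid(assignable & !is_t) + wrong_t
    FN <- sum(is_t) - TP - wrong_t
    TN <- sum(!is_t) - pass_grid(assignable & !is_t)
  }
  total <- length(query_ids)
  safe_div <- function(num, den) { r <- num / den; r[den == 0] <- NA_real_; r }
  structure(list(
    identity = identity_grid, aln_len = len_grid, level = level,
    n_queries = total,
    TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = (TP + TN) / total,
    ppv = safe_div(TP, TP + FP),
    specificity = safe_div(TN, TN + FP),
    sensitivity = safe_div(TP, TP + FN),
    npv = safe_div(TN, TN + FN)), class = "sweep_grid")
}

rev_cumsum_rev <- function(x) rev(cumsum(rev(x)))

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("threshold sweep (%s level): %d identity x %d length cells, %d queries\n",
              x$level, length(x$identity), length(x$aln_len), x$n_queries))
  invisible(x)
}

#' Flatten a sweep grid to a long data.frame
#' @param x A `sweep_grid`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with one row per grid cell.
#' @method as.data.frame sweep_grid
#' @export
as.data.frame.sweep_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  g <- expand.grid(identity = x$identity, aln_len = x$aln_len,
                   KEEP.OUT.ATTRS = FALSE)
  for (f in c("TP", "FP", "TN", "FN", "accuracy", "ppv", "specificity",
              "sensitivity", "npv"))
    g[[f]] <- as.vector(x[[f]])
  g
}

#' Per-family detection rate
#'
#' 100 x (truth-positive queries of the family annotated to that family) /
#' (truth-positive queries of the family).
#'
#' @param annotations Annotation data.frame.
#' @param truth Truth data.frame.
#' @param family Family name(s); default: every family with at least one
#'   truth-positive query.
#' @return Named numeric vector of percentages.
#' @export
family_detection_rate <- function(annotations, truth, family = NULL) {
  pos <- truth[truth$is_target, , drop = FALSE]
  if (is.null(family)) family <- sort(unique(pos$true_family))
  absent <- setdiff(family, pos$true_family)
  if (length(absent))
    stop("family absent from truth positives: ", paste(absent, collapse = ", "))
  fam_of <- stats::setNames(annotations$family, annotations$query_id)
  vapply(family, function(f) {
    q <- pos$query_id[pos$true_family == f]
    100 * sum(!is.na(fam_of[q]) & fam_of[q] == f) / length(q)
  }, numeric(1))
}

#' Evaluate one genome's predicted family content against its annotation
#'
#' Detection ratio = predicted family count / annotated family count;
#' ratio > 1 is "overestimated", = 1 "exact", < 1 "underestimated"
#' (exact integer-count comparison, no tolerance).
#'
#' @param predicted Character set of predicted families, or their count.
#' @param annotated Character set of annotation-derived families, or their
#'   count; must be positive.
#' @param genome_id Identifier recorded in the result.
#' @return One-row data.frame: genome_id, predicted_families,
#'   annotated_families, detection_ratio, klass.
#' @export
eval_genome <- function(predicted, annotated, genome_id = "genome") {
  np <- if (is.numeric(predicted)) as.integer(predicted)
        else length(unique(predicted))
  na_ <- if (is.numeric(annotated)) as.integer(annotated)
         else length(unique(annotated))
  if (na_ <= 0L) stop("annotated family count must be positive")
  if (np < 0L) stop("predicted family count must be non-negative")
  klass <- if (np > na_) "overestimated" else if (np == na_) "exact"
           else "underestimated"
  data.frame(genome_id = genome_id, predicted_families = np,
             annotated_families = na_, detection_ratio = np / na_,
             klass = klass, stringsAsFactors = FALSE)
}

#' Summarise genome evaluations
#'
#' @param evals data.frame of rows from [eval_genome()] (rbind'ed).
#' @return List with class counts (`overestimated`, `exact`,
#'   `underestimated`), and `min`, `max`, `mean`, `sd` (sample sd, n-1) of
#'   the detection ratios.
#' @export
summarize_genomes <- function(evals) {
  if (!is.data.frame(evals) || nrow(evals) == 0L)
    stop("need at least one genome evaluation")
  r <- evals$detection_ratio
  list(n = nrow(evals),
       overestimated = sum(evals$klass == "overestimated"),
       exact = sum(evals$klass == "exact"),
       underestimated = sum(evals$klass == "underestimated"),
       min = min(r), max = max(r), mean = mean(r),
       sd = if (length(r) > 1L) stats::sd(r) else 0)
}

#' Extract the annotated gene-family set from a GFF3 file
#'
#' Families whose keyword rules match a feature's `gene` or `product`
#' attribute (token-wise, case-insensitive) constitute the genome's
#' annotation-derived family content, the denominator of the detection
#' ratio. Feature lines must have the 9 standard GFF3 columns; a malformed
#' line is reported with its line number.
#'
#' @param gff Path to a GFF3 file.
#' @param family_rules data.frame with columns `family`, `keyword`.
#' @return Character vector of matched family names (sorted, unique).
#' @export
extract_annotated_families <- function(gff, family_rules) {
  rules <- check_family_rules(family_rules)
  if (!file.exists(gff)) stop("GFF file not found: ", gff)
  lines <- readLines(gff)
  feat <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[feat], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9L))
    stop("malformed GFF line ", feat[nf != 9L][1L], ": expected 9 columns, got ",
         nf[nf != 9L][1L])
  if (length(feat) == 0L) return(character(0))
  gr <- rtracklayer::import(gff, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  text <- character(length(gr))
  for (col in c("gene", "product", "Name"))
    if (!is.null(mc[[col]]))
      text <- paste(text, vapply(mc[[col]], function(v)
        paste(as.character(v), collapse = " "), character(1)))
  found <- unique(unlist(lapply(seq_len(nrow(rules)), function(r) {
    hit <- vapply(text, function(tx) keyword_matches(rules$keyword[r], tx),
                  logical(1))
    if (any(hit)) rules$family[r] else character(0)
  })))
  sort(found)
}
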