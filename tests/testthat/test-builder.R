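rules_df <- function(...) {
  kv <- list(...)
  do.call(rbind, lapply(names(kv), function(f)
    data.frame(family = f, keyword = kv[[f]], stringsAsFactors = FALSE)))
}

test_that("keyword extraction claims, excludes ambiguity, drops non-matches", {
  recs <- data.frame(
    id = c("u1", "u2", "u3"),
    seq = c("MKVAWLE", "MKVAWLD", "MKVAWLN"),
    name = c("", "phoD", ""),
    description = c("alkaline phosphatase D precursor",
                    "alkaline phosphatase X",   # matches phoD (name) and phoX
                    "unrelated kinase"),
    stringsAsFactors = FALSE)
  rules <- rules_df(phoD = c("phoD", "alkaline phosphatase D"),
                    phoX = c("phoX", "alkaline phosphatase X"))
  pool <- extract_candidates(recs, rules)
  expect_equal(pool$records$id, "u1")
  expect_equal(pool$records$family, "phoD")
  amb <- attr(pool, "ambiguous")
  expect_equal(amb$id, "u2")
  expect_match(amb$families, "phoD")
  expect_match(amb$families, "phoX")
  expect_false("u3" %in% c(pool$records$id, amb$id))
  expect_error(extract_candidates(recs, rules[0, ]), "empty")
})

make_planted_pool <- function(seed = 21, n_fam = 3, n_mem = 5, len = 150,
                              within = 0.05, extra = NULL) {
  set.seed(seed)
  fams <- paste0("fam", seq_len(n_fam))
  anc <- stats::setNames(vapply(fams, function(f) rand_protein(len),
                                character(1)), fams)
  recs <- do.call(rbind, lapply(fams, function(f)
    data.frame(id = paste0(f, "_c", seq_len(n_mem)),
               seq = vapply(seq_len(n_mem), function(i)
                 mutate_protein(anc[[f]], within), character(1)),
               family = f, stringsAsFactors = FALSE)))
  if (!is.null(extra)) recs <- rbind(recs, extra)
  list(pool = candidate_pool(recs, "curated"), ancestors = anc)
}

test_that("core construction clusters curated families and inherits labels", {
  p <- make_planted_pool(n_fam = 1, n_mem = 5)
  db <- build_core(p$pool, identity = 30)
  expect_equal(nrow(db$families), 1L)
  expect_equal(sum(db$records$role == "representative"), 5L)

  # an unlabelled sequence close to fam1 inherits its label
  set.seed(22)
  p2 <- make_planted_pool(seed = 23, n_fam = 2)
  unl <- data.frame(id = "trembl1",
                    seq = mutate_protein(p2$ancestors[["fam1"]], 0.08),
                    family = NA_character_, source = "trembl",
                    stringsAsFactors = FALSE)
  # curated tier forbids NA families, so the mixed pool rides the orthology tier
  pool <- candidate_pool(rbind(p2$pool$records, unl), "orthology")
  ident_to_fam1 <- global_identity(unl$seq, p2$ancestors[["fam1"]])
  ident_to_fam2 <- global_identity(unl$seq, p2$ancestors[["fam2"]])
  expect_gt(ident_to_fam1, 80)
  expect_lt(ident_to_fam2, 25)
  db2 <- build_core(pool, identity = 30)
  expect_equal(db2$records$family[db2$records$id == "trembl1"], "fam1")
  expect_equal(db2$records$role[db2$records$id == "trembl1"], "representative")
})

test_that("mixed-family clusters demote to homologues with a warning", {
  set.seed(24)
  anc <- rand_protein(150)
  recs <- data.frame(
    id = c("a1", "a2", "b1"),
    seq = c(mutate_protein(anc, 0.05), mutate_protein(anc, 0.05),
            mutate_protein(anc, 0.1)),
    family = c("famA", "famA", "famB"), stringsAsFactors = FALSE)
  # demotion warns twice: once for the mixed cluster, once for the lost labels
  expect_warning(
    expect_warning(db <- build_core(candidate_pool(recs, "curated"), 30),
                   "mixed-family"),
    "lost to demotion")
  expect_true(all(db$records$role == "homologue"))
  expect_equal(nrow(db$families), 0L)
  rev <- db$metadata$review
  expect_true(all(c("a1", "a2", "b1") %in% rev$id))
})

test_that("core construction is idempotent on its own output", {
  p <- make_planted_pool(seed = 25, n_fam = 3)
  db1 <- build_core(p$pool, identity = 30)
  again <- candidate_pool(db1$records[db1$records$role == "representative",
                                      c("id", "seq", "family")], "curated")
  db2 <- build_core(again, identity = 30)
  fam_members <- function(db) {
    r <- db$records[db$records$role == "representative", ]
    lapply(split(r$id, r$family), sort)
  }
  expect_equal(fam_members(db2), fam_members(db1))
})

test_that("orthology expansion adds consistent records, demotes conflicts, discards strangers", {
  p <- make_planted_pool(seed = 26, n_fam = 2)
  db <- build_core(p$pool, identity = 30)
  set.seed(27)
  src <- candidate_pool(data.frame(
    id = c("o_good", "o_conflict", "o_far"),
    seq = c(mutate_protein(p$ancestors[["fam1"]], 0.05),
            mutate_protein(p$ancestors[["fam1"]], 0.3),
            rand_protein(150)),
    family = c("fam1", "fam2", NA), stringsAsFactors = FALSE), "orthology")
  out <- expand_orthology(db, src, identity = 30)
  r <- out$records
  expect_equal(r$family[r$id == "o_good"], "fam1")
  expect_equal(r$role[r$id == "o_good"], "representative")
  expect_equal(r$role[r$id == "o_conflict"], "homologue")
  expect_false("o_far" %in% r$id)
  validate_ref_db(out)
})

test_that("bulk merge applies the strict threshold and dereplicates", {
  p <- make_planted_pool(seed = 28, n_fam = 1)
  db <- build_core(p$pool, identity = 30)
  set.seed(29)
  near <- mutate_protein(p$ancestors[["fam1"]], 0.05)  # well above 80%
  mid <- mutate_protein(p$ancestors[["fam1"]], 0.3)    # below 80%
  best_of <- function(s) max(vapply(
    db$records$seq[db$records$role == "representative"],
    function(r) global_identity(s, r), numeric(1)))
  expect_gt(best_of(near), 80)
  expect_lt(best_of(mid), 80)
  out <- merge_bulk(db, candidate_pool(
    data.frame(id = c("b_near", "b_mid"), seq = c(near, mid),
               stringsAsFactors = FALSE), "bulk"))
  expect_true("b_near" %in% out$records$id)
  expect_equal(out$records$source[out$records$id == "b_near"], "bulk")
  expect_false("b_mid" %in% out$records$id)
  # exact duplicate of an existing record changes nothing
  dup <- candidate_pool(data.frame(id = "dup1", seq = db$records$seq[1],
                                   stringsAsFactors = FALSE), "bulk")
  out2 <- merge_bulk(db, dup)
  expect_setequal(out2$records$id, db$records$id)
  # raising the threshold never adds records
  lo <- merge_bulk(db, candidate_pool(
    data.frame(id = c("b_near", "b_mid"), seq = c(near, mid),
               stringsAsFactors = FALSE), "bulk"), identity = 60)
  expect_true(all(out$records$id %in% lo$records$id))
})

test_that("family compaction replaces representatives by centroids, others untouched", {
  set.seed(30)
  ancA <- rand_protein(150); ancB <- rand_protein(150)
  # famA: 10 near-identical sequences; famB: two clearly separated subgroups
  recs <- rbind(
    data.frame(id = paste0("A", 1:10),
               seq = vapply(1:10, function(i) mutate_protein(ancA, 0.005),
                            character(1)),
               role = "representative", family = "famA",
               stringsAsFactors = FALSE),
    local({
      ancB2 <- mutate_protein(ancB, 0.2)   # second subgroup ancestor
      data.frame(id = paste0("B", 1:4),
                 seq = c(vapply(1:2, function(i) mutate_protein(ancB, 0.01),
                                character(1)),
                         vapply(1:2, function(i) mutate_protein(ancB2, 0.01),
                                character(1))),
                 role = "representative", family = "famB",
                 stringsAsFactors = FALSE)
    }))
  db <- ref_db(recs)
  out <- compact_family(db, "famA", identity = 95)
  expect_equal(sum(out$records$family == "famA", na.rm = TRUE), 1L)
  famB_out <- out$records[out$records$family %in% "famB", c("id", "seq")]
  famB_db <- db$records[db$records$family %in% "famB", c("id", "seq")]
  rownames(famB_out) <- rownames(famB_db) <- NULL
  expect_identical(famB_out, famB_db)
  expect_equal(nrow(out$families), nrow(db$families))
  outB <- compact_family(db, "famB", identity = 95)
  expect_equal(sum(outB$records$family == "famB", na.rm = TRUE), 2L)
  expect_error(compact_family(db, "famZ"), "famZ")
})
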