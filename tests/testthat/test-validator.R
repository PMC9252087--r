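# helper: annotation table from explicit (query, family) pairs
mk_ann <- function(query_id, family) {
  data.frame(query_id = query_id, family = family,
             rejection_reason = ifelse(is.na(family), "no_hit", "none"),
             stringsAsFactors = FALSE)
}

test_that("confusion scoring distinguishes binary and family levels", {
  truth <- truth_labels(c("t1", "t2", "n1", "n2"),
                        c(TRUE, TRUE, FALSE, FALSE),
                        c("phoD", "gcd", NA, NA))
  ann <- mk_ann(c("t1", "t2", "n1", "n2"),
                c("phoD", "gcd", NA, NA))
  cc <- score_queries(ann, truth)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  # a target assigned to the wrong family: binary TP, family-level FP
  ann_wrong <- mk_ann(c("t1", "t2", "n1", "n2"), c("gcd", "gcd", NA, NA))
  expect_equal(score_queries(ann_wrong, truth, "binary")$TP, 2L)
  fam <- score_queries(ann_wrong, truth, "family")
  expect_equal(fam$TP, 1L)
  expect_equal(fam$FP, 1L)
  expect_equal(fam$FN, 0L)
  expect_error(score_queries(mk_ann("ghost", "phoD"), truth), "ghost")
})

test_that("confusion counts match exhaustive enumeration on a 20-query set", {
  set.seed(51)
  fams <- c("phoD", "gcd", "ppx")
  truth <- truth_labels(sprintf("q%02d", 1:20),
                        rep(c(TRUE, FALSE), each = 10),
                        c(sample(fams, 10, TRUE), rep(NA, 10)))
  called <- sample(c(fams, NA), 20, TRUE)
  ann <- mk_ann(truth$query_id, called)
  for (level in c("binary", "family")) {
    cc <- score_queries(ann, truth, level)
    # brute-force per-query tabulation
    TP <- FP <- TN <- FN <- 0L
    for (i in 1:20) {
      assigned <- !is.na(called[i])
      if (level == "binary") {
        if (truth$is_target[i] && assigned) TP <- TP + 1L
        else if (truth$is_target[i]) FN <- FN + 1L
        else if (assigned) FP <- FP + 1L
        else TN <- TN + 1L
      } else {
        correct <- assigned && truth$is_target[i] &&
          called[i] == truth$true_family[i]
        if (correct) TP <- TP + 1L
        else if (assigned) FP <- FP + 1L
        else if (truth$is_target[i]) FN <- FN + 1L
        else TN <- TN + 1L
      }
    }
    expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
                 list(TP = TP, FP = FP, TN = TN, FN = FN), info = level)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 20L)
  }
})

test_that("metric ratios are exact and undefined denominators yield NA", {
  m <- confusion_metrics(confusion_counts(85, 15, 0, 0))
  expect_equal(unname(m["ppv"]), 0.85)
  m <- confusion_metrics(confusion_counts(0, 0, 100, 0))
  expect_equal(unname(m["specificity"]), 1.0)
  expect_true(is.na(m["ppv"]))          # TP + FP = 0
  expect_true(is.na(m["sensitivity"]))  # TP + FN = 0
  m <- confusion_metrics(confusion_counts(999, 0, 0, 1))
  expect_equal(unname(m["sensitivity"]), 0.999)
  expect_equal(unname(m["accuracy"]), 0.999)
})

test_that("sweep axes match their specification", {
  expect_length(default_identity_grid(), 998)
  expect_length(default_len_grid(), 98)
  expect_equal(default_identity_grid()[1], 0.2)
  expect_equal(default_identity_grid()[998], 99.9, tolerance = 1e-9)
  expect_equal(range(default_len_grid()), c(2L, 99L))
})

# small planted benchmark reused by the sweep tests
sweep_fixture <- function(seed = 52) {
  spec <- synth_spec(seed = seed, n_families = 3, members_per_family = 4,
                     ancestor_length = 150, n_negatives = 5)
  bm <- make_benchmark(spec)
  bh <- search_best_hits(bm$queries, bm$db)
  list(bm = bm, bh = bh)
}

test_that("cumulative sweep equals naive per-cell recomputation", {
  fx <- sweep_fixture()
  id_grid <- seq(20, 95, by = 5)
  len_grid <- c(10L, 50L, 100L, 140L)
  for (level in c("binary", "family")) {
    grid <- threshold_sweep(fx$bh, fx$bm$db, fx$bm$truth, id_grid, len_grid,
                            level = level, query_ids = names(fx$bm$queries))
    for (i in seq_along(id_grid)) for (j in seq_along(len_grid)) {
      ann <- assign_families(
        fx$bh, fx$bm$db,
        filter_params(min_identity = id_grid[i], min_aln_len = len_grid[j]),
        query_ids = names(fx$bm$queries))
      cc <- score_queries(ann, fx$bm$truth, level)
      expect_equal(grid$TP[i, j], cc$TP,
                   info = sprintf("%s TP @(%g,%d)", level, id_grid[i], len_grid[j]))
      expect_equal(grid$FP[i, j], cc$FP)
      expect_equal(grid$TN[i, j], cc$TN)
      expect_equal(grid$FN[i, j], cc$FN)
    }
  }
})

test_that("sweep metrics are monotone and class totals conserved along identity", {
  fx <- sweep_fixture(seed = 53)
  grid <- threshold_sweep(fx$bh, fx$bm$db, fx$bm$truth,
                          query_ids = names(fx$bm$queries))
  for (j in seq_along(grid$aln_len)) {
    sens <- grid$sensitivity[, j]
    spec_ <- grid$specificity[, j]
    expect_true(all(diff(sens[!is.na(sens)]) <= 1e-12))
    expect_true(all(diff(spec_[!is.na(spec_)]) >= -1e-12))
    expect_true(all(diff(grid$TP[, j] + grid$FP[, j]) <= 0))
    expect_true(all(diff(grid$TN[, j] + grid$FN[, j]) >= 0))
    # binary level: class margins are invariant along the sweep
    expect_equal(unique(grid$TP[, j] + grid$FN[, j]),
                 sum(fx$bm$truth$is_target))
    expect_equal(unique(grid$TN[, j] + grid$FP[, j]),
                 sum(!fx$bm$truth$is_target))
  }
  # most permissive corner retains the most assignments
  expect_equal(grid$sensitivity[1, 1],
               max(grid$sensitivity, na.rm = TRUE))
})

test_that("precision rises steeply between decoy and member identity levels", {
  # positives near 90% identity, decoy queries near 55%: PPV's largest jump
  # along the identity axis falls inside that window (S-shape)
  spec <- synth_spec(seed = 54, n_families = 4, members_per_family = 4,
                     ancestor_length = 200, within_divergence = 0.05,
                     decoy_divergence = 0.4, n_negatives = 5)
  base <- make_families(spec)
  db <- base$db; queries <- base$queries; truth <- base$truth
  # decoy queries against a database WITHOUT the homologue records behave as
  # would-be false positives that only the identity threshold can remove
  for (f in db$families$family) {
    d <- make_decoys(spec, db, f, n_records = 0L, n_queries = 2L)
    queries <- c(queries, d$queries)
    truth <- rbind(truth, d$truth)
  }
  bh <- search_best_hits(queries, db)
  grid <- threshold_sweep(bh, db, truth, identity_grid = seq(10, 99, 1),
                          len_grid = c(25L, 50L), query_ids = names(queries))
  ppv <- grid$ppv[, 1]
  jumps <- diff(ppv)
  jump_at <- grid$identity[-1][which.max(jumps)]
  expect_gt(jump_at, 40)
  expect_lt(jump_at, 92)
  expect_lt(min(ppv, na.rm = TRUE), 0.75)
  expect_equal(max(ppv, na.rm = TRUE), 1.0)
})

test_that("per-family detection rates match manual tabulation", {
  truth <- truth_labels(sprintf("q%02d", 1:20), rep(TRUE, 20),
                        rep(c("phoD", "gcd"), each = 10))
  called <- c(rep("phoD", 10), rep("gcd", 5), rep(NA, 5))
  ann <- mk_ann(truth$query_id, called)
  rates <- family_detection_rate(ann, truth)
  expect_equal(unname(rates["phoD"]), 100)
  expect_equal(unname(rates["gcd"]), 50)
  expect_error(family_detection_rate(ann, truth, "phoX"), "phoX")
  # enumeration across a random assignment
  set.seed(55)
  called2 <- ifelse(runif(20) < 0.7, truth$true_family, NA)
  rates2 <- family_detection_rate(mk_ann(truth$query_id, called2), truth)
  for (f in c("phoD", "gcd")) {
    idx <- truth$true_family == f
    expect_equal(unname(rates2[f]),
                 100 * sum(!is.na(called2[idx]) & called2[idx] == f) / sum(idx))
  }
})

test_that("genome evaluation classifies detection ratios exactly", {
  ev <- eval_genome(paste0("f", 1:10), paste0("f", 1:10), "g1")
  expect_equal(ev$detection_ratio, 1.0)
  expect_equal(ev$klass, "exact")
  ev <- eval_genome(12, 10, "g2")
  expect_equal(ev$detection_ratio, 1.2)
  expect_equal(ev$klass, "overestimated")
  expect_equal(eval_genome(9, 10)$klass, "underestimated")
  expect_error(eval_genome(5, 0), "positive")
})

test_that("genome summaries count classes and use the sample deviation", {
  evals <- rbind(eval_genome(10, 10, "a"), eval_genome(10, 10, "b"))
  s <- summarize_genomes(evals)
  expect_equal(s$exact, 2L)
  expect_equal(s$mean, 1.0)
  expect_equal(s$sd, 0.0)
  evals <- rbind(eval_genome(5, 10, "a"), eval_genome(15, 10, "b"))
  s <- summarize_genomes(evals)
  expect_equal(c(s$underestimated, s$overestimated, s$mean), c(1, 1, 1.0))
  # moments against direct formulas on 50 random ratios
  set.seed(56)
  pred <- sample(5:20, 50, TRUE)
  evals <- do.call(rbind, lapply(1:50, function(i)
    eval_genome(pred[i], 10, paste0("g", i))))
  s <- summarize_genomes(evals)
  r <- pred / 10
  expect_equal(s$mean, sum(r) / 50)
  expect_equal(s$sd, sqrt(sum((r - mean(r))^2) / 49))
  expect_equal(s$overestimated + s$exact + s$underestimated, 50L)
  expect_error(summarize_genomes(evals[0, ]), "at least one")
})

test_that("annotated family sets are extracted from GFF attributes", {
  rules <- data.frame(family = c("phoD", "gcd"),
                      keyword = c("phoD", "gcd"), stringsAsFactors = FALSE)
  gff <- c("##gff-version 3",
           "g1\tsrc\tgene\t1\t900\t.\t+\t.\tID=a;gene=phoD;product=alkaline phosphatase D",
           "g1\tsrc\tgene\t1001\t1900\t.\t+\t.\tID=b;gene=gcd",
           "g1\tsrc\tgene\t2001\t2900\t.\t+\t.\tID=c;gene=phoD",
           "g1\tsrc\tgene\t3001\t3900\t.\t+\t.\tID=d;gene=hypX;product=hypothetical protein")
  f <- tempfile(fileext = ".gff")
  writeLines(gff, f)
  # 3 rule-matching genes across 2 families
  expect_equal(extract_annotated_families(f, rules), c("gcd", "phoD"))
  writeLines(gff[c(1, 5)], f)
  expect_equal(extract_annotated_families(f, rules), character(0))
  writeLines(c(gff[1:2], "g1\tsrc\tgene\t10\t90"), f)
  expect_error(extract_annotated_families(f, rules), "line 3")
})
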