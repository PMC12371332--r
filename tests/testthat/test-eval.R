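rset <- function(ids, chain = "A") {
  residue_ref(chain, "GLY", ids)
}

test_that("residue precision/recall/F1 follow the set formulas", {
  a <- rset(1:2); e <- rset(1:4)
  prf <- residue_prf(a, e)
  expect_equal(prf$precision, 0.5)
  expect_equal(prf$recall, 1.0)
  expect_equal(prf$f1, 2 / 3)
  same <- residue_prf(a, a)
  expect_equal(unlist(same), c(precision = 1, recall = 1, f1 = 1))
  disj <- residue_prf(rset(1:3), rset(10:12))
  expect_equal(unlist(disj), c(precision = 0, recall = 0, f1 = 0))
  # empty extracted set: precision defined 0
  expect_equal(residue_prf(a, rset(integer()))$precision, 0)
})

test_that("jaccard handles identity, disjointness and the 2/5 worked case", {
  expect_equal(jaccard(rset(1:3), rset(1:3)), 1)
  expect_equal(jaccard(rset(1:3), rset(7:9)), 0)
  expect_equal(jaccard(rset(1:3), rset(2:5)), 0.4)  # |I|=2, |U|=5
  expect_equal(jaccard(rset(integer()), rset(integer())), 0)
})

test_that("greedy matching pairs by decreasing annotated-residue recall", {
  # single clean pair at overlap 0.8
  m <- match_pockets(list(rset(1:10)), list(rset(1:8)), match_threshold = 0.5)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$overlap, 0.8)
  expect_equal(m$n_misses, 0)

  # negative-control paper: extraction without annotation is a miss
  m2 <- match_pockets(list(), list(rset(1:3)))
  expect_equal(m2$n_matched_annotated, 0)
  expect_equal(m2$n_misses, 1)

  # one extracted pocket overlapping two annotations (0.9 vs 0.6): the
  # higher-recall annotation wins, the other stays unmatched, no misses
  ann <- list(rset(1:10), rset(11:20))
  ext <- list(rset(c(1:9, 11:16)))
  m3 <- match_pockets(ann, ext, match_threshold = 0.5)
  expect_equal(m3$pairs$ann_idx, 1L)
  expect_equal(m3$pairs$overlap, 0.9)
  expect_equal(m3$n_misses, 0)
  expect_equal(m3$n_matched_annotated, 1)
})

test_that("greedy matching agrees with exhaustive maximum matching on benchmark-like fixtures", {
  # exhaustive maximum-cardinality matching by recursion over assignments
  brute_max <- function(ann, ext, thr) {
    ok <- outer(seq_along(ann), seq_along(ext), Vectorize(function(i, j) {
      ov <- length(intersect(ann[[i]], ext[[j]])) / length(ann[[i]])
      ov >= thr && ov > 0
    }))
    best <- 0
    rec <- function(i, used_e, cnt) {
      if (i > length(ann)) { best <<- max(best, cnt); return(invisible()) }
      rec(i + 1, used_e, cnt)
      for (j in seq_along(ext)) {
        if (!used_e[[j]] && ok[i, j]) {
          used_e[[j]] <- TRUE
          rec(i + 1, used_e, cnt + 1)
          used_e[[j]] <- FALSE
        }
      }
    }
    rec(1, rep(FALSE, length(ext)), 0)
    best
  }
  # benchmark-like fixtures: disjoint annotated pockets, extracted pockets
  # that are noisy copies of single annotations plus decoys (each extracted
  # pocket strongly overlaps at most one annotation)
  set.seed(42)
  for (rep in 1:40) {
    n_ann <- sample(1:5, 1)
    ann <- lapply(seq_len(n_ann), function(i)
      res_keyify(((i - 1) * 12 + 1):((i - 1) * 12 + sample(4:8, 1))))
    ext <- list()
    for (i in seq_len(n_ann)) {
      if (runif(1) < 0.7) {
        base <- ann[[i]]
        keep <- sample(base, max(2, floor(length(base) * runif(1, 0.4, 1))))
        ext[[length(ext) + 1]] <- union(keep, res_keyify(sample(500:600, 2)))
      }
    }
    for (d in seq_len(sample(0:2, 1))) {
      ext[[length(ext) + 1]] <- res_keyify(sample(700:800, 5))
    }
    if (length(ext) == 0) ext <- list(res_keyify(900:905))
    m <- match_pockets(ann, ext, match_threshold = 0.5)
    expect_equal(m$n_matched_annotated, brute_max(ann, ext, 0.5))
  }
})

test_that("matching is invariant to input permutation up to tie-breaking", {
  ann <- list(res_keyify(1:6), res_keyify(10:16), res_keyify(20:27))
  ext <- list(res_keyify(1:5), res_keyify(11:16), res_keyify(40:44))
  m1 <- match_pockets(ann, ext)
  m2 <- match_pockets(rev(ann), rev(ext))
  expect_equal(m1$n_matched_annotated, m2$n_matched_annotated)
  expect_equal(m1$n_misses, m2$n_misses)
  expect_setequal(round(m1$pairs$overlap, 10), round(m2$pairs$overlap, 10))
})

test_that("the two-paper worked example gives accuracy 0.5, recall 1.0, specificity 0.75", {
  # paper 1: 2 annotated, 2 extracted, both matched; paper 2: 1 annotated,
  # 2 extracted, 1 matched + 1 miss
  p1 <- match_pockets(list(rset(1:5), rset(11:15)),
                      list(rset(1:5), rset(11:15)))
  p2 <- match_pockets(list(rset(21:25)), list(rset(21:25), rset(31:35)))
  rep <- pocket_metrics(list(p1, p2))
  expect_equal(rep$pocket_number_accuracy, 0.5)
  expect_equal(rep$pocket_recall, 1.0)
  expect_equal(rep$pocket_specificity, 0.75)  # 1 - 1/4
  # perfect extraction on every paper
  perfect <- pocket_metrics(list(p1))
  expect_equal(perfect$pocket_number_accuracy, 1)
  expect_equal(perfect$pocket_recall, 1)
  expect_equal(perfect$pocket_specificity, 1)
  expect_equal(perfect$residue_f1, 1)
  # nothing extracted anywhere: recall 0, specificity defined 1
  m0 <- match_pockets(list(rset(1:5)), list())
  expect_message(rep0 <- pocket_metrics(list(m0)), "specificity")
  expect_equal(rep0$pocket_recall, 0)
  expect_equal(rep0$pocket_specificity, 1)
  expect_equal(rep0$pocket_number_accuracy, 0)
})

test_that("specificity is identically 1 - misses/extracted over random match fixtures", {
  set.seed(99)
  for (rep in 1:1000) {
    n_papers <- sample(1:4, 1)
    results <- lapply(seq_len(n_papers), function(i) {
      ann <- lapply(seq_len(sample(0:3, 1)), function(j)
        res_keyify(sample(1:40, sample(3:8, 1))))
      ext <- lapply(seq_len(sample(0:3, 1)), function(j)
        res_keyify(sample(1:40, sample(3:8, 1))))
      match_pockets(ann, ext, match_threshold = 0.5)
    })
    n_ext <- sum(vapply(results, `[[`, 0L, "n_extracted"))
    n_miss <- sum(vapply(results, `[[`, 0L, "n_misses"))
    rep_ <- suppressMessages(pocket_metrics(results))
    expected <- if (n_ext == 0) 1 else 1 - n_miss / n_ext
    expect_identical(rep_$pocket_specificity, expected)
    expect_true(all(unlist(rep_[c("pocket_number_accuracy", "pocket_recall",
                                  "pocket_specificity")]) >= 0))
    expect_true(all(unlist(rep_[c("pocket_number_accuracy", "pocket_recall",
                                  "pocket_specificity")]) <= 1))
  }
})

test_that("at threshold zero every extracted pocket with nonzero overlap is paired", {
  ann <- list(rset(1:6), rset(10:15), rset(20:25))
  ext <- list(rset(5:8), rset(12:13), rset(40:45))
  m <- match_pockets(ann, ext, match_threshold = 0)
  # the two overlapping extracted pockets pair; the disjoint one is a miss
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$n_misses, 1)
})

test_that("relevance metrics reproduce the benchmark worked example", {
  # 20 relevant + 11 irrelevant papers; all relevant kept, 4 false positives
  truth <- tibble::tibble(doc_id = sprintf("p%02d", 1:31),
                          relevant = c(rep(TRUE, 20), rep(FALSE, 11)))
  decisions <- tibble::tibble(doc_id = truth$doc_id,
                              relevant = c(rep(TRUE, 20), rep(TRUE, 4),
                                           rep(FALSE, 7)))
  m <- relevance_metrics(decisions, truth)
  expect_equal(m$accuracy, 27 / 31)
  expect_equal(round(m$accuracy, 2), 0.87)
  expect_equal(round(m$precision, 3), 0.833)
  expect_equal(m$recall, 1.0)
  expect_equal(m$fpr, 4 / 11)
  expect_equal(m$fpr, 0.363, tolerance = 2e-3)
  expect_equal(m$fnr, 0)
  expect_equal(m$fnr, 1 - m$recall)

  # all correct
  all_ok <- relevance_metrics(truth, truth)
  expect_equal(all_ok$accuracy, 1)
  expect_equal(all_ok$fpr, 0)

  # everything predicted relevant, half truly relevant
  t2 <- tibble::tibble(doc_id = as.character(1:10),
                       relevant = rep(c(TRUE, FALSE), 5))
  d2 <- tibble::tibble(doc_id = t2$doc_id, relevant = TRUE)
  m2 <- relevance_metrics(d2, t2)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1.0)
  expect_equal(m2$fpr, 1.0)

  expect_error(relevance_metrics(d2[1:5, ], t2),
               class = "pocketlit_validation_error")
})

test_that("tidy and glance methods return well-formed tibbles", {
  m <- match_pockets(list(rset(1:5)), list(rset(1:5)))
  rep <- pocket_metrics(list(m))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_true(all(td$value >= 0 & td$value <= 1))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  truth <- tibble::tibble(doc_id = "a", relevant = TRUE)
  rm <- relevance_metrics(truth, truth)
  expect_equal(nrow(tidy(rm)), 5)
})
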