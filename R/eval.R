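# Benchmark evaluation. Extracted pockets are matched one-to-one against
# annotated pockets per paper by greedy assignment in decreasing order of
# annotated-residue recall |A n E| / |A| (ties broken by annotated index
# then extracted index); a pair is accepted iff the overlap reaches
# `match_threshold`. Extracted pockets left unmatched are "misses" and
# drive Pocket Specificity = 1 - sum(misses) / sum(extracted).

residue_keyset <- function(residues, ignore_chain = FALSE) {
  if (is.character(residues)) return(unique(residues))
  if (is.null(residues) || nrow(residues) == 0) return(character())
  if (ignore_chain) {
    unique(res_key_nochain(residues$res_id, residues$icode))
  } else {
    unique(res_key(residues$chain_id, residues$res_id, residues$icode))
  }
}

#' Residue-level precision, recall and F1
#'
#' Canonical residue identity is (chain, residue number, insertion code).
#' Precision is defined 0 for an empty extracted set and F1 is 0 when both
#' precision and recall are 0.
#'
#' @param annotated,extracted Residue-ref tibbles (or character key sets).
#' @param ignore_chain Compare on (residue number, insertion code) only.
#' @return Named list `precision`, `recall`, `f1`.
#' @examples
#' a <- parse_residue_token(c("A:TYR:1", "A:LYS:2"))
#' e <- parse_residue_token(c("A:TYR:1", "A:LYS:2", "A:GLU:3", "A:SER:4"))
#' residue_prf(a, e)
#' @export
residue_prf <- function(annotated, extracted, ignore_chain = FALSE) {
  a <- if (is.character(annotated)) unique(annotated) else
    residue_keyset(annotated, ignore_chain)
  e <- if (is.character(extracted)) unique(extracted) else
    residue_keyset(extracted, ignore_chain)
  inter <- length(intersect(a, e))
  precision <- if (length(e) == 0) 0 else inter / length(e)
  recall <- if (length(a) == 0) 0 else inter / length(a)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Jaccard index between residue sets
#'
#' `|A n B| / |A u B|`, with the empty-vs-empty case defined as 0.
#'
#' @inheritParams residue_prf
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(annotated, extracted, ignore_chain = FALSE) {
  a <- if (is.character(annotated)) unique(annotated) else
    residue_keyset(annotated, ignore_chain)
  b <- if (is.character(extracted)) unique(extracted) else
    residue_keyset(extracted, ignore_chain)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Match extracted pockets against annotated pockets
#'
#' Greedy one-to-one matching for a single paper. Pairs are considered in
#' decreasing order of annotated-residue recall `|A n E| / |A|`, breaking
#' ties by annotated index then extracted index; a pair is accepted iff its
#' overlap is at least `match_threshold`, and each pocket joins at most one
#' pair. Extracted pockets matching no annotation are counted as misses.
#'
#' @param annotated,extracted Lists of residue-ref tibbles (or pocket
#'   tables with a `residues` list-column).
#' @param match_threshold Minimum annotated-residue recall for a match.
#' @param ignore_chain Compare residues without the chain id.
#' @return A `match_result`: list with a `pairs` tibble (`ann_idx`,
#'   `ext_idx`, `overlap`, `precision`, `recall`, `f1`) and counts
#'   `n_annotated`, `n_extracted`, `n_matched_annotated`, `n_misses`.
#' @export
match_pockets <- function(annotated, extracted, match_threshold = 0.5,
                          ignore_chain = FALSE) {
  as_sets <- function(x) {
    if (is.data.frame(x) && "residues" %in% names(x)) x <- x$residues
    lapply(x, residue_keyset, ignore_chain = ignore_chain)
  }
  ann <- as_sets(annotated)
  ext <- as_sets(extracted)
  pairs <- tibble(ann_idx = integer(), ext_idx = integer(),
                  overlap = double(), precision = double(),
                  recall = double(), f1 = double())
  if (length(ann) > 0 && length(ext) > 0) {
    cand <- tidyr::expand_grid(ann_idx = seq_along(ann),
                               ext_idx = seq_along(ext))
    cand$overlap <- purrr::map2_dbl(cand$ann_idx, cand$ext_idx, function(i, j) {
      if (length(ann[[i]]) == 0) return(0)
      length(intersect(ann[[i]], ext[[j]])) / length(ann[[i]])
    })
    # a zero-overlap pair is never a match, even at threshold 0
    cand <- cand[cand$overlap >= match_threshold & cand$overlap > 0, ]
    cand <- arrange(cand, desc(.data$overlap), .data$ann_idx, .data$ext_idx)
    used_ann <- logical(length(ann))
    used_ext <- logical(length(ext))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$ann_idx[[k]]; j <- cand$ext_idx[[k]]
      if (!used_ann[[i]] && !used_ext[[j]]) {
        used_ann[[i]] <- TRUE; used_ext[[j]] <- TRUE; keep[[k]] <- TRUE
      }
    }
    cand <- cand[keep, ]
    if (nrow(cand) > 0) {
      prf <- purrr::map2(cand$ann_idx, cand$ext_idx,
                         function(i, j) residue_prf(ann[[i]], ext[[j]]))
      cand$precision <- purrr::map_dbl(prf, "precision")
      cand$recall <- purrr::map_dbl(prf, "recall")
      cand$f1 <- purrr::map_dbl(prf, "f1")
      pairs <- as_tibble(cand)
    }
  }
  structure(
    list(pairs = pairs,
         n_annotated = length(ann),
         n_extracted = length(ext),
         n_matched_annotated = nrow(pairs),
         n_misses = length(ext) - nrow(pairs)),
    class = "match_result")
}

#' Pocket-level and residue-level benchmark metrics
#'
#' Pools [match_pockets()] results across papers:
#' * Pocket Number Accuracy — fraction of papers where the extracted pocket
#'   count equals the annotated count.
#' * Pocket Recall — pooled `sum(matched annotated) / sum(annotated)`
#'   (per-paper averaging available via `pooled = FALSE`).
#' * Pocket Specificity (TNR) — `1 - sum(misses) / sum(extracted)`.
#' * Residue precision/recall/F1 — macro-averaged over matched pairs.
#'
#' Degenerate denominators are defined explicitly: with zero extracted
#' pockets overall, specificity is 1 (no fake pocket was possible); with
#' zero annotated pockets overall, recall is 1. Both cases are logged.
#'
#' @param results List of `match_result` objects, one per paper.
#' @param pooled Pool pocket recall across papers (default) or average the
#'   per-paper recalls.
#' @return A `metrics_report` list with fields `pocket_number_accuracy`,
#'   `pocket_recall`, `pocket_specificity`, `residue_precision`,
#'   `residue_recall`, `residue_f1`, plus counts `n_papers`, `n_annotated`,
#'   `n_extracted`, `n_matched`, `n_misses`.
#' @export
pocket_metrics <- function(results, pooled = TRUE) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "match_result")))
  n_ann <- vapply(results, `[[`, 0L, "n_annotated")
  n_ext <- vapply(results, `[[`, 0L, "n_extracted")
  n_match <- vapply(results, `[[`, 0L, "n_matched_annotated")
  n_miss <- vapply(results, `[[`, 0L, "n_misses")
  accuracy <- mean(n_ann == n_ext)
  if (sum(n_ann) == 0) {
    inform("no annotated pockets in any paper; pocket recall defined as 1")
    recall <- 1
  } else if (pooled) {
    recall <- sum(n_match) / sum(n_ann)
  } else {
    per <- ifelse(n_ann == 0, 1, n_match / pmax(n_ann, 1))
    recall <- mean(per)
  }
  if (sum(n_ext) == 0) {
    inform("no extracted pockets in any paper; pocket specificity defined as 1")
    specificity <- 1
  } else {
    specificity <- 1 - sum(n_miss) / sum(n_ext)
  }
  pairs <- bind_rows(lapply(results, `[[`, "pairs"))
  structure(
    list(
      pocket_number_accuracy = accuracy,
      pocket_recall = recall,
      pocket_specificity = specificity,
      residue_precision = if (nrow(pairs)) mean(pairs$precision) else NA_real_,
      residue_recall = if (nrow(pairs)) mean(pairs$recall) else NA_real_,
      residue_f1 = if (nrow(pairs)) mean(pairs$f1) else NA_real_,
      n_papers = length(results),
      n_annotated = sum(n_ann), n_extracted = sum(n_ext),
      n_matched = sum(n_match), n_misses = sum(n_miss)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$n_papers, "paper(s)\n")
  cat(sprintf("  pocket number accuracy: %.3f\n", x$pocket_number_accuracy))
  cat(sprintf("  pocket recall:          %.3f\n", x$pocket_recall))
  cat(sprintf("  pocket specificity:     %.3f\n", x$pocket_specificity))
  cat(sprintf("  residue P/R/F1:         %.3f / %.3f / %.3f\n",
              x$residue_precision, x$residue_recall, x$residue_f1))
  invisible(x)
}

#' Relevance-filter metrics
#'
#' Scores the relevance-assessment stage as a binary classifier against the
#' annotated ground truth, aligned by `doc_id`. Reports accuracy,
#' precision, recall, false-positive rate and false-negative rate
#' (`fnr = 1 - recall`).
#'
#' @param decisions List of `relevance_decision` objects (or a tibble with
#'   `doc_id` and `relevant` columns).
#' @param truth List of `paper_annotation` objects (or a tibble with
#'   `doc_id` and `relevant`).
#' @return A `relevance_metrics` list with the five rates and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' truth <- tibble::tibble(doc_id = as.character(1:4),
#'                         relevant = c(TRUE, TRUE, FALSE, FALSE))
#' dec <- tibble::tibble(doc_id = as.character(1:4),
#'                       relevant = c(TRUE, TRUE, TRUE, FALSE))
#' relevance_metrics(dec, truth)
#' @export
relevance_metrics <- function(decisions, truth) {
  as_tab <- function(x) {
    if (is.data.frame(x)) return(as_tibble(x[, c("doc_id", "relevant")]))
    tibble(doc_id = vapply(x, `[[`, "", "doc_id"),
           relevant = vapply(x, `[[`, TRUE, "relevant"))
  }
  d <- as_tab(decisions)
  t <- as_tab(truth)
  if (!setequal(d$doc_id, t$doc_id) || nrow(d) != nrow(t)) {
    stopf("decisions and truth cover different doc_ids",
          class = "pocketlit_validation_error")
  }
  m <- left_join(d, rename(t, truth = "relevant"), by = "doc_id")
  tp <- sum(m$relevant & m$truth)
  fp <- sum(m$relevant & !m$truth)
  tn <- sum(!m$relevant & !m$truth)
  fn <- sum(!m$relevant & m$truth)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  fpr <- if (fp + tn == 0) 0 else fp / (fp + tn)
  structure(
    list(accuracy = (tp + tn) / nrow(m),
         precision = precision, recall = recall,
         fpr = fpr, fnr = 1 - recall,
         tp = tp, fp = fp, tn = tn, fn = fn),
    class = "relevance_metrics")
}

#' @export
print.relevance_metrics <- function(x, ...) {
  cat(sprintf(
    "<relevance_metrics> acc %.3f | prec %.3f | rec %.3f | FPR %.3f | FNR %.3f\n",
    x$accuracy, x$precision, x$recall, x$fpr, x$fnr))
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report` or `relevance_metrics` object.
#' @param ... Unused.
#' @return A tibble with one row per metric (`metric`, `value`).
#' @export
tidy.metrics_report <- function(x, ...) {
  fields <- c("pocket_number_accuracy", "pocket_recall", "pocket_specificity",
              "residue_precision", "residue_recall", "residue_f1")
  tibble(metric = fields, value = unlist(x[fields], use.names = FALSE))
}

#' @rdname tidy.metrics_report
#' @export
tidy.relevance_metrics <- function(x, ...) {
  fields <- c("accuracy", "precision", "recall", "fpr", "fnr")
  tibble(metric = fields, value = unlist(x[fields], use.names = FALSE))
}

#' Glance at a metrics report
#'
#' @param x A `metrics_report` or `relevance_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble of all metrics and counts.
#' @export
glance.metrics_report <- function(x, ...) {
  as_tibble(x[!vapply(x, is.null, TRUE)])
}

#' @rdname glance.metrics_report
#' @export
glance.relevance_metrics <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
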