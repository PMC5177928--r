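#' Confusion counts at a score cutoff
#'
#' An example is predicted positive iff its score is `>=` the cutoff
#' (inclusive rule, fixed for reproducibility).
#'
#' @param scores Numeric score vector.
#' @param labels Character or logical labels; `"positive"`/`TRUE` marks a
#'   true site.
#' @param cutoff Score cutoff.
#' @return A named list with integer elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels), length(scores) >= 1L)
  pos <- as_positive(labels)
  pred <- scores >= cutoff
  list(TP = sum(pred & pos), FP = sum(pred & !pos),
       TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

as_positive <- function(labels) {
  if (is.logical(labels)) labels else labels == "positive"
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Pr = TP/(TP+FP). A ratio with a zero
#' denominator is undefined and reported as `NA`, not 0.
#'
#' @param counts A list with elements `TP`, `FP`, `TN`, `FN`
#'   (see [confusion_at()]).
#' @return Named numeric vector `c(Sn =, Sp =, Pr =)`.
#' @export
sn_sp_pr <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(Sn = ratio(TP, TP + FN), Sp = ratio(TN, TN + FP),
                 Pr = ratio(TP, TP + FP)))
}

#' ROC curve and area under the curve
#'
#' The ROC is traced over all distinct score cutoffs (one vertex per distinct
#' score, so tied scores move the curve diagonally) and the AUC is the
#' trapezoidal area, equivalent to the Mann-Whitney statistic with half
#' credit for ties.
#'
#' @inheritParams confusion_at
#' @return A list with `points` (data frame of `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("ROC needs at least one positive and one negative example")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores: one vertex after each distinct score block
  last_of_block <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(p)[last_of_block]
  fp <- cumsum(!p)[last_of_block]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Sensitivity at the specificity-anchored cutoff used as the training
# objective. The cutoff is placed just above the k-th smallest negative
# score (k = ceiling(sp_anchor * n_neg)); negatives tied with it fall below
# the cutoff, so the achieved specificity is >= sp_anchor.
sn_at_sp_anchor <- function(pos_scores, neg_scores, sp_anchor) {
  stopifnot(length(pos_scores) >= 1L, length(neg_scores) >= 1L)
  k <- ceiling(sp_anchor * length(neg_scores))
  if (k == 0L) return(1)
  thr <- sort(neg_scores, partial = k)[k]
  mean(pos_scores > thr)
}

#' Leave-one-out validation report for one HAT
#'
#' Rebuilds the labeled dataset at the model's window geometry, scores every
#' positive with itself withheld from the reference peptides and every
#' negative against all positives, then assembles per-example scores, the
#' ROC curve/AUC, and Sn/Sp/Pr at the model's calibrated thresholds (if set).
#'
#' @inheritParams build_dataset
#' @param model A `hat_model` for the same HAT.
#' @return An object of class `eval_report`: list with `hat`, `scheme`,
#'   `scores` (data frame with per-example scores and labels), `roc`
#'   (ROC points), `auc` and `metrics_at` (per-threshold Sn/Sp/Pr).
#' @export
loo_validate <- function(substrates, annotations, hat, model) {
  stopifnot(inherits(model, "hat_model"))
  dataset <- build_dataset(substrates, annotations, hat, model$m, model$n)
  scored <- score_dataset(dataset, model, loo = TRUE)
  make_eval_report(hat, "loo", scored, model$thresholds)
}

make_eval_report <- function(hat, scheme, scored, thresholds = NULL) {
  roc <- roc_auc(scored$score, scored$label)
  metrics <- NULL
  if (!is.null(thresholds) && !anyNA(thresholds)) {
    metrics <- t(vapply(thresholds, function(cut) {
      sn_sp_pr(confusion_at(scored$score, scored$label, cut))
    }, numeric(3)))
  }
  structure(list(hat = hat, scheme = scheme, scores = scored,
                 roc = roc$points, auc = roc$auc, metrics_at = metrics),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$hat, paste0("[", x$scheme, "]"),
      sprintf("AUC = %.3f", x$auc), "-",
      sum(x$scores$label == "positive"), "positives /",
      sum(x$scores$label == "negative"), "negatives\n")
  if (!is.null(x$metrics_at)) {
    print(round(x$metrics_at, 4))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Positives and negatives are independently split into `k` folds (so each
#' fold preserves class balance), with fold assignment drawn from the given
#' seed. Examples in each held-out fold are scored with only the other
#' folds' positives as reference peptides; by default weights and matrix are
#' kept from the supplied model (only the reference set is re-partitioned),
#' optionally the weight-training and matrix-mutation steps are re-run on
#' each fold's training positives. Scores from all folds are pooled into a
#' single ROC.
#'
#' @inheritParams loo_validate
#' @param k Number of folds; must not exceed the number of positives.
#' @param seed Integer seed for fold assignment.
#' @param retrain Re-run weight training and matrix mutation per fold.
#' @param config Training configuration used when `retrain = TRUE`
#'   (see [train_config()]).
#' @return An `eval_report` with scheme `"kfold(k)"`.
#' @export
kfold_validate <- function(substrates, annotations, hat, model, k, seed = 1L,
                           retrain = FALSE, config = train_config()) {
  stopifnot(inherits(model, "hat_model"), k >= 2L)
  dataset <- build_dataset(substrates, annotations, hat, model$m, model$n)
  np <- nrow(dataset$positives); nn <- nrow(dataset$negatives)
  if (k > np) {
    stop("k = ", k, " exceeds the number of positive sites (", np, ")")
  }
  folds_of <- function(nx) {
    # balanced random fold labels 1..k
    sample(rep_len(seq_len(k), nx))
  }
  scored <- with_seed(as.integer(seed), {
    pf <- folds_of(np)
    nf <- folds_of(nn)
    out <- vector("list", k)
    for (fold in seq_len(k)) {
      train_pos <- dataset$positives[pf != fold, , drop = FALSE]
      if (nrow(train_pos) == 0L) stop("empty training fold; decrease k")
      fold_model <- new_hat_model(hat, model$m, model$n, train_pos,
                                  matrix = model$matrix,
                                  weights = model$weights)
      if (retrain) {
        train_ds <- structure(list(hat = hat, m = model$m, n = model$n,
                                   positives = train_pos,
                                   negatives = dataset$negatives[nf != fold, ,
                                                                 drop = FALSE]),
                              class = "hat_dataset")
        if (nrow(train_pos) >= 2L && nrow(train_ds$negatives) >= 1L) {
          wt <- train_weights(train_ds, fold_model, config)
          fold_model$weights <- wt$weights
          mm <- mutate_matrix(train_ds, fold_model, config)
          fold_model$matrix <- mm$matrix
        }
      }
      held <- structure(list(hat = hat, m = model$m, n = model$n,
                             positives = dataset$positives[pf == fold, ,
                                                           drop = FALSE],
                             negatives = dataset$negatives[nf == fold, ,
                                                           drop = FALSE]),
                        class = "hat_dataset")
      out[[fold]] <- score_dataset(held, fold_model, loo = FALSE)
    }
    do.call(rbind, out)
  })
  make_eval_report(hat, sprintf("kfold(%d)", k), scored, model$thresholds)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Calibrate High/Medium/Low prediction thresholds
#'
#' Each tier's cutoff is the smallest observed score value whose leave-one-out
#' specificity (fraction of negatives scoring strictly below it) reaches the
#' tier's target: ~95% (high), ~90% (medium) and ~85% (low). The three
#' cutoffs always satisfy high >= medium >= low.
#'
#' @param report An `eval_report` from [loo_validate()] (or any object with
#'   `$scores`).
#' @param targets Named specificity targets.
#' @return Named numeric vector `c(high =, medium =, low =)`.
#' @export
calibrate_thresholds <- function(report,
                                 targets = c(high = 0.95, medium = 0.90,
                                             low = 0.85)) {
  scored <- report$scores
  neg <- scored$score[scored$label == "negative"]
  if (length(neg) == 0L) stop("threshold calibration needs negative examples")
  candidates <- sort(unique(scored$score))
  vapply(targets, function(tgt) {
    k <- ceiling(tgt * length(neg))
    ok <- candidates[vapply(candidates, function(c) sum(neg < c) >= k,
                            logical(1))]
    if (length(ok)) ok[1L] else max(scored$score) + 1
  }, numeric(1))
}

#' Export an evaluation report
#'
#' Writes the per-example scores as TSV and the summary (AUC, ROC points,
#' threshold metrics) as JSON next to it.
#'
#' @param report An `eval_report`.
#' @param prefix Output path prefix; writes `<prefix>_scores.tsv` and
#'   `<prefix>_summary.json`.
#' @export
write_eval_report <- function(report, prefix) {
  scores_path <- paste0(prefix, "_scores.tsv")
  utils::write.table(report$scores, scores_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(hat = report$hat, scheme = report$scheme, auc = report$auc,
                  roc = report$roc)
  if (!is.null(report$metrics_at)) {
    summary$metrics_at <- as.data.frame(report$metrics_at)
  }
  jsonlite::write_json(summary, paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(scores_path, paste0(prefix, "_summary.json")))
}
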