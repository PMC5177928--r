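#' Raw peptide similarity between two equal-length windows
#'
#' The sum over aligned positions of the substitution-matrix score between
#' the two residues, clamped to zero if the sum is negative. With the initial
#' BLOSUM62 matrix this is symmetric; after matrix mutation it need not be
#' (the query residue indexes rows, the reference residue columns).
#'
#' @param a,b Peptide window strings of equal length.
#' @param matrix Substitution matrix (default [blosum62_matrix()]).
#' @return A single non-negative number (integer-valued for integer matrices).
#' @examples
#' peptide_similarity("GKS", "GKS")  # 15
#' peptide_similarity("WWW", "CCC")  # negative sum, clamped to 0
#' @export
peptide_similarity <- function(a, b, matrix = blosum62_matrix()) {
  weighted_similarity(a, b, matrix, rep(1, nchar(a)))
}

#' Position-weighted peptide similarity
#'
#' Like [peptide_similarity()] but each aligned position's substitution score
#' is multiplied by a non-negative position weight before summing; the sum is
#' clamped to zero if negative.
#'
#' @inheritParams peptide_similarity
#' @param weights Numeric vector of non-negative position weights, one per
#'   window position.
#' @return A single non-negative number.
#' @export
weighted_similarity <- function(a, b, matrix = blosum62_matrix(), weights) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("peptides must have equal length (", nchar(a), " vs ", nchar(b), ")")
  }
  if (length(weights) != nchar(a)) {
    stop("weights must have one entry per window position")
  }
  if (any(weights < 0)) stop("position weights must be non-negative")
  check_matrix(matrix)
  S <- score_pairs_cpp(windows_to_idx(a), windows_to_idx(b),
                       as_numeric_matrix(matrix), as.numeric(weights))
  S[1L, 1L]
}

# coerce an integer matrix to double without copying dimnames handling
as_numeric_matrix <- function(m) {
  storage.mode(m) <- "double"
  m
}

#' Score of a query window under a trained HAT model
#'
#' The model score is the arithmetic mean of the position-weighted similarity
#' between the query and each of the model's positive training peptides. For
#' leave-one-out evaluation, a training peptide can be excluded by its origin
#' (protein, position) identity - not by sequence equality, so duplicate
#' peptide sequences from different proteins are retained.
#'
#' @param query A peptide window string of the model's window length.
#' @param model A `hat_model` (see [train_model()] / [new_hat_model()]).
#' @param exclude `NULL`, or a list/vector with elements `protein_id` and
#'   `position` identifying the training peptide to leave out.
#' @return A single non-negative score.
#' @export
model_score <- function(query, model, exclude = NULL) {
  stopifnot(inherits(model, "hat_model"))
  if (nchar(query) != model$m + 1L + model$n) {
    stop("query window length ", nchar(query), " does not match model ASP(",
         model$m, ", ", model$n, ")")
  }
  refs <- model$positives
  keep <- rep(TRUE, nrow(refs))
  if (!is.null(exclude)) {
    keep <- !(refs$protein_id == exclude[["protein_id"]] &
                refs$position == as.integer(exclude[["position"]]))
  }
  if (!any(keep)) stop("no reference peptides left after exclusion")
  S <- score_pairs_cpp(windows_to_idx(query),
                       windows_to_idx(refs$window[keep]),
                       as_numeric_matrix(model$matrix),
                       as.numeric(model$weights))
  mean(S[1L, ])
}

#' Score every window of a labeled dataset under a model
#'
#' Negatives are always scored against all of the model's positive peptides.
#' With `loo = TRUE`, each positive is scored with itself (matched by origin)
#' withheld from the reference set, giving leave-one-out scores.
#'
#' @param dataset A `hat_dataset` whose windows match the model's `(m, n)`.
#' @param model A `hat_model`.
#' @param loo Use leave-one-out scoring for positives.
#' @return A data frame with columns `protein_id`, `position`, `label`
#'   (`"positive"`/`"negative"`) and `score`.
#' @export
score_dataset <- function(dataset, model, loo = FALSE) {
  stopifnot(inherits(dataset, "hat_dataset"), inherits(model, "hat_model"))
  if (dataset$m != model$m || dataset$n != model$n) {
    stop("dataset ASP(", dataset$m, ", ", dataset$n,
         ") does not match model ASP(", model$m, ", ", model$n, ")")
  }
  if (loo && nrow(model$positives) < 2L) {
    stop("leave-one-out scoring needs at least 2 positive peptides")
  }
  refs <- model$positives
  pos <- dataset$positives; pos$label <- rep("positive", nrow(pos))
  neg <- dataset$negatives; neg$label <- rep("negative", nrow(neg))
  queries <- rbind(pos, neg)
  exclude <- integer(nrow(queries))
  if (loo) {
    key_ref <- paste(refs$protein_id, refs$position)
    key_q <- paste(queries$protein_id, queries$position)
    hit <- match(key_q, key_ref)
    hit[queries$label != "positive"] <- NA_integer_
    exclude <- ifelse(is.na(hit), 0L, hit)
  }
  sc <- model_scores_cpp(windows_to_idx(queries$window),
                         windows_to_idx(refs$window),
                         as_numeric_matrix(model$matrix),
                         as.numeric(model$weights), as.integer(exclude))
  data.frame(protein_id = queries$protein_id, position = queries$position,
             label = queries$label, score = sc, stringsAsFactors = FALSE)
}

#' Construct a HAT model object
#'
#' A `hat_model` bundles everything needed to score a lysine window: the
#' window geometry `(m, n)`, a substitution matrix, position weights, the
#' positive training peptides it averages over, and the calibrated score
#' thresholds. [train_model()] is the usual way to obtain one; this
#' constructor is exposed for building models directly (e.g. untrained
#' baselines in analyses and tests).
#'
#' @param hat One of the seven HAT names.
#' @param m,n Window half-widths (1..30).
#' @param positives Data frame with `protein_id`, `position`, `window`.
#' @param matrix Substitution matrix; defaults to BLOSUM62.
#' @param weights Non-negative position weights; default all 1.
#' @param thresholds Named numeric vector with entries `high`, `medium`,
#'   `low` (may be `NA` before calibration); must satisfy high >= medium >=
#'   low when set.
#' @return An object of class `hat_model`.
#' @export
new_hat_model <- function(hat, m, n, positives,
                          matrix = blosum62_matrix(),
                          weights = rep(1L, m + 1L + n),
                          thresholds = c(high = NA_real_, medium = NA_real_,
                                         low = NA_real_)) {
  hat <- match.arg(hat, HAT_NAMES)
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(m >= 1L, m <= 30L, n >= 1L, n <= 30L)
  stopifnot(is.data.frame(positives),
            all(c("protein_id", "position", "window") %in% names(positives)),
            nrow(positives) >= 1L)
  if (any(nchar(positives$window) != m + 1L + n)) {
    stop("all positive peptides must have length m + 1 + n")
  }
  if (length(weights) != m + 1L + n || any(weights < 0)) {
    stop("weights must be non-negative with one entry per window position")
  }
  check_matrix(matrix)
  th <- thresholds[c("high", "medium", "low")]
  if (!anyNA(th) && !(th[["high"]] >= th[["medium"]] &&
                      th[["medium"]] >= th[["low"]])) {
    stop("thresholds must satisfy high >= medium >= low")
  }
  structure(list(hat = hat, m = m, n = n, matrix = matrix,
                 weights = as.numeric(weights),
                 positives = positives[c("protein_id", "position", "window")],
                 thresholds = th),
            class = "hat_model")
}

#' @export
print.hat_model <- function(x, ...) {
  cat("hat_model:", x$hat, sprintf("ASP(%d, %d),", x$m, x$n),
      nrow(x$positives), "reference peptides\n")
  cat("  weights:", paste(x$weights, collapse = " "), "\n")
  if (!anyNA(x$thresholds)) {
    cat(sprintf("  thresholds: high %.3f / medium %.3f / low %.3f\n",
                x$thresholds[["high"]], x$thresholds[["medium"]],
                x$thresholds[["low"]]))
  }
  invisible(x)
}
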