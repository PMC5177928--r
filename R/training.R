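#' Training configuration
#'
#' Bundles the tunable parameters of the three-step training procedure.
#' During training the specificity is fixed at `sp_anchor` and leave-one-out
#' sensitivity at that specificity is the objective being maximized. Window
#' half-widths are searched exhaustively over `m_range` x `n_range`. The
#' weight-training and matrix-mutation steps propose random +1/-1 moves and
#' use simulated-annealing acceptance: a proposal that improves the current
#' objective is always adopted; a worsening proposal is adopted with
#' probability `exp(delta/T)`, with `T` starting at `sa_T0` and shrinking
#' geometrically by `sa_cooling` per proposal. A step stops after
#' `max_stagnation` consecutive proposals without a new best objective, or
#' after `max_proposals` proposals in total.
#'
#' @param sp_anchor Specificity fixed during training (default 0.90).
#' @param m_range,n_range Candidate upstream/downstream half-widths (1..30).
#' @param max_stagnation Proposals without a new best before a step stops.
#' @param max_proposals Hard cap on proposals per step.
#' @param sa_T0 Initial annealing temperature (on the Sn scale).
#' @param sa_cooling Geometric cooling factor per proposal, in (0, 1).
#' @param seed Integer RNG seed; all training randomness derives from it.
#' @param step_order Permutation of `c("length", "weights", "matrix")`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(sp_anchor = 0.90,
                         m_range = 1:30, n_range = 1:30,
                         max_stagnation = 500L, max_proposals = 10000L,
                         sa_T0 = 0.05, sa_cooling = 0.995,
                         seed = 1L,
                         step_order = c("length", "weights", "matrix")) {
  stopifnot(sp_anchor > 0, sp_anchor < 1,
            all(m_range >= 1L), all(m_range <= 30L),
            all(n_range >= 1L), all(n_range <= 30L),
            sa_cooling > 0, sa_cooling < 1, sa_T0 > 0,
            max_stagnation >= 0L, max_proposals >= 0L,
            setequal(step_order, c("length", "weights", "matrix")))
  structure(list(sp_anchor = sp_anchor,
                 m_range = as.integer(m_range), n_range = as.integer(n_range),
                 max_stagnation = as.integer(max_stagnation),
                 max_proposals = as.integer(max_proposals),
                 sa_T0 = sa_T0, sa_cooling = sa_cooling,
                 seed = as.integer(seed), step_order = step_order),
            class = "train_config")
}

#' Leave-one-out training objective: Sn at anchored Sp
#'
#' Computes all leave-one-out scores of the dataset under the model and
#' returns the sensitivity at the score cutoff whose specificity is at least
#' `sp_anchor` and closest to it. The cutoff is placed just above the k-th
#' smallest negative score (k = ceiling(sp_anchor * n_negatives)); negatives
#' tied with that score fall below the cutoff.
#'
#' @inheritParams score_dataset
#' @param sp_anchor Specificity level, in (0, 1).
#' @return Sensitivity (fraction of positives above the cutoff), in [0, 1].
#' @export
loo_objective <- function(dataset, model, sp_anchor = 0.90) {
  if (nrow(dataset$positives) < 2L || nrow(dataset$negatives) < 1L) {
    stop("objective needs >= 2 positives and >= 1 negative")
  }
  scored <- score_dataset(dataset, model, loo = TRUE)
  sn_at_sp_anchor(scored$score[scored$label == "positive"],
                  scored$score[scored$label == "negative"], sp_anchor)
}

#' Exhaustive motif length selection
#'
#' Evaluates the leave-one-out objective (unit weights, unmutated BLOSUM62)
#' for every combination of `m` in `config$m_range` and `n` in
#' `config$n_range`, and returns the maximizer. Ties are broken toward the
#' smaller `m + n`, then the smaller `m`.
#'
#' @inheritParams build_dataset
#' @param config A [train_config()].
#' @return A list with `m`, `n`, `objective`, and `surface` (matrix of
#'   objective values, rows = m, cols = n).
#' @export
select_motif_length <- function(substrates, annotations, hat,
                                config = train_config()) {
  mmax <- max(config$m_range); nmax <- max(config$n_range)
  dataset <- build_dataset(substrates, annotations, hat, mmax, nmax)
  np <- nrow(dataset$positives); nn <- nrow(dataset$negatives)
  if (np < 2L || nn < 1L) {
    stop("motif length selection needs >= 2 positives and >= 1 negative")
  }
  queries <- rbind(dataset$positives, dataset$negatives)
  labels <- rep(c("positive", "negative"), c(np, nn))
  exclude <- c(seq_len(np), rep(0L, nn))
  scores <- length_scan_scores_cpp(
    windows_to_idx(queries$window), windows_to_idx(dataset$positives$window),
    as_numeric_matrix(blosum62_matrix()), as.integer(exclude), mmax, nmax)
  surface <- matrix(NA_real_, nrow = mmax, ncol = nmax,
                    dimnames = list(m = seq_len(mmax), n = seq_len(nmax)))
  is_pos <- labels == "positive"
  for (m in config$m_range) {
    for (n in config$n_range) {
      sc <- scores[, (m - 1L) * nmax + n]
      surface[m, n] <- sn_at_sp_anchor(sc[is_pos], sc[!is_pos],
                                       config$sp_anchor)
    }
  }
  cand <- expand.grid(m = config$m_range, n = config$n_range)
  cand$obj <- surface[cbind(cand$m, cand$n)]
  best <- max(cand$obj)
  cand <- cand[cand$obj == best, , drop = FALSE]
  cand <- cand[order(cand$m + cand$n, cand$m), , drop = FALSE]
  list(m = cand$m[1L], n = cand$n[1L], objective = best, surface = surface)
}

# Shared simulated-annealing loop over +1/-1 proposals.
#   state: initial parameter object
#   propose(state) -> list(state =, desc =) or NULL for an infeasible move
#   objective(state) -> Sn at the anchored Sp
# Returns list(best_state, best_objective, trace).
sa_optimize <- function(step_name, state, propose, objective, config) {
  cur <- state; cur_obj <- objective(state)
  best <- cur; best_obj <- cur_obj
  temp <- config$sa_T0
  stagnation <- 0L
  trace <- list()
  proposal <- 0L
  while (stagnation < config$max_stagnation &&
         proposal < config$max_proposals) {
    proposal <- proposal + 1L
    obj_before <- cur_obj
    move <- propose(cur)
    accepted <- FALSE
    new_obj <- cur_obj
    if (!is.null(move)) {
      new_obj <- objective(move$state)
      delta <- new_obj - cur_obj
      accepted <- delta > 0 || stats::runif(1) < exp(delta / temp)
      if (accepted) {
        cur <- move$state; cur_obj <- new_obj
      }
    }
    if (cur_obj > best_obj) {
      best <- cur; best_obj <- cur_obj
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    trace[[proposal]] <- data.frame(
      step = step_name, proposal = proposal,
      move = if (is.null(move)) "infeasible" else move$desc,
      objective_before = obj_before, objective_after = new_obj,
      accepted = accepted, best = best_obj, temperature = temp,
      stringsAsFactors = FALSE)
    temp <- temp * config$sa_cooling
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = character(), proposal = integer(), move = character(),
               objective_before = numeric(), objective_after = numeric(),
               accepted = logical(), best = numeric(),
               temperature = numeric(), stringsAsFactors = FALSE)
  list(state = best, objective = best_obj, trace = trace)
}

#' Train position weights by stochastic +1/-1 moves
#'
#' Starting from the model's current weights (all 1 for a fresh model), a
#' random position is repeatedly picked and its integer weight changed by +1
#' or -1; improvements of the leave-one-out objective are kept and worsening
#' moves are accepted with the simulated-annealing probability. A -1 move on
#' a zero weight is infeasible (weights stay non-negative). The best-so-far
#' weights are returned, never a worse final annealing state.
#'
#' @inheritParams loo_objective
#' @param config A [train_config()]; `config$seed` makes the run
#'   reproducible.
#' @return A list with `weights`, `objective` and `trace` (one row per
#'   proposal; column `best` is monotone non-decreasing).
#' @export
train_weights <- function(dataset, model, config = train_config()) {
  L <- model$m + 1L + model$n
  refs_idx <- windows_to_idx(model$positives$window)
  prep <- prepare_objective(dataset, model)
  # per-position contributions let each +-1 proposal be scored with one
  # rank-1 update instead of a full rescoring pass
  contrib <- position_contrib_cpp(prep$Q, refs_idx,
                                  as_numeric_matrix(model$matrix))
  state0 <- list(
    w = as.integer(model$weights),
    raw = weighted_contrib_sum_cpp(contrib, as.numeric(model$weights)))
  objective <- function(state) {
    sc <- clamped_rowmeans_cpp(state$raw, prep$exclude)
    sn_at_sp_anchor(sc[prep$is_pos], sc[!prep$is_pos], config$sp_anchor)
  }
  propose <- function(state) {
    i <- sample.int(L, 1L)
    delta <- sample(c(-1L, 1L), 1L)
    if (state$w[i] + delta < 0L) return(NULL)
    state$w[i] <- state$w[i] + delta
    state$raw <- add_contrib_cpp(state$raw, contrib, i, delta)
    list(state = state, desc = sprintf("w[%d] %+d", i, delta))
  }
  res <- with_seed(config$seed, {
    sa_optimize("weights", state0, propose, objective, config)
  })
  list(weights = res$state$w, objective = res$objective, trace = res$trace)
}

#' Mutate the substitution matrix by stochastic +1/-1 moves
#'
#' Starting from the model's current matrix (BLOSUM62 for a fresh model), a
#' random ordered residue pair over the 20-letter alphabet is repeatedly
#' picked and its score changed by +1 or -1, with the same
#' accept/anneal/stop rules as [train_weights()]. Padding and `'X'`
#' rows/columns are never touched. Mutation of a single ordered pair means
#' the trained matrix may become asymmetric.
#'
#' @inheritParams train_weights
#' @return A list with `matrix`, `objective` and `trace`.
#' @export
mutate_matrix <- function(dataset, model, config = train_config()) {
  refs_idx <- windows_to_idx(model$positives$window)
  prep <- prepare_objective(dataset, model)
  w <- as.numeric(model$weights)
  objective <- function(M) {
    sc <- model_scores_cpp(prep$Q, refs_idx, as_numeric_matrix(M), w,
                           prep$exclude)
    sn_at_sp_anchor(sc[prep$is_pos], sc[!prep$is_pos], config$sp_anchor)
  }
  propose <- function(M) {
    i <- sample.int(20L, 1L); j <- sample.int(20L, 1L)
    delta <- sample(c(-1L, 1L), 1L)
    M[i, j] <- M[i, j] + delta
    list(state = M,
         desc = sprintf("M[%s,%s] %+d", AA_ALPHABET[i], AA_ALPHABET[j], delta))
  }
  res <- with_seed(config$seed, {
    sa_optimize("matrix", model$matrix, propose, objective, config)
  })
  list(matrix = res$state, objective = res$objective, trace = res$trace)
}

# Precompute query index matrix, LOO exclusion map and label mask for the
# repeated objective evaluations inside a training step.
prepare_objective <- function(dataset, model) {
  if (nrow(dataset$positives) < 2L || nrow(dataset$negatives) < 1L) {
    stop("training needs >= 2 positives and >= 1 negative")
  }
  if (dataset$m != model$m || dataset$n != model$n) {
    stop("dataset ASP(", dataset$m, ", ", dataset$n,
         ") does not match model ASP(", model$m, ", ", model$n, ")")
  }
  queries <- rbind(dataset$positives, dataset$negatives)
  np <- nrow(dataset$positives)
  key_ref <- paste(model$positives$protein_id, model$positives$position)
  key_q <- paste(queries$protein_id, queries$position)
  exclude <- match(key_q, key_ref)
  exclude[seq_len(nrow(queries)) > np] <- NA_integer_
  exclude[is.na(exclude)] <- 0L
  list(Q = windows_to_idx(queries$window), exclude = as.integer(exclude),
       is_pos = seq_len(nrow(queries)) <= np)
}

#' Train a full HAT model
#'
#' Runs the three performance-improvement steps in `config$step_order`
#' (default: motif length selection, then weight training, then matrix
#' mutation), each maximizing leave-one-out sensitivity at the anchored
#' specificity, and finally calibrates the High/Medium/Low thresholds from
#' the leave-one-out score distribution of the trained model.
#'
#' @inheritParams select_motif_length
#' @return A trained `hat_model` with attributes `trace` (combined proposal
#'   log of the stochastic steps) and `objective` (final training objective).
#' @export
train_model <- function(substrates, annotations, hat,
                        config = train_config()) {
  hat <- match.arg(hat, HAT_NAMES)
  n_pos <- sum(annotations$hat == hat)
  if (n_pos < 2L) {
    stop("HAT ", hat, " has ", n_pos,
         " annotated site(s); at least 2 are required for training")
  }
  step_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, 3L))
  names(step_seeds) <- c("length", "weights", "matrix")
  m <- max(config$m_range); n <- max(config$n_range)
  model <- NULL
  dataset <- NULL
  traces <- list()
  objective <- NA_real_
  rebuild <- function(m, n) {
    ds <- build_dataset(substrates, annotations, hat, m, n)
    md <- new_hat_model(hat, m, n, ds$positives)
    list(ds = ds, md = md)
  }
  # default geometry if "length" is not first in the order
  state <- rebuild(m, n)
  dataset <- state$ds; model <- state$md
  for (step in config$step_order) {
    cfg <- config; cfg$seed <- step_seeds[[step]]
    if (step == "length") {
      sel <- select_motif_length(substrates, annotations, hat, cfg)
      state <- rebuild(sel$m, sel$n)
      dataset <- state$ds
      # keep any already-trained matrix; weights are geometry-specific and
      # only survive a length step if the geometry is unchanged
      old <- model
      model <- state$md
      if (!is.null(old)) {
        model$matrix <- old$matrix
        if (old$m == model$m && old$n == model$n) {
          model$weights <- old$weights
        }
      }
      objective <- sel$objective
      traces[[length(traces) + 1L]] <- data.frame(
        step = "length", proposal = 0L,
        move = sprintf("ASP(%d, %d)", sel$m, sel$n),
        objective_before = NA_real_, objective_after = sel$objective,
        accepted = TRUE, best = sel$objective, temperature = NA_real_,
        stringsAsFactors = FALSE)
    } else if (step == "weights") {
      wt <- train_weights(dataset, model, cfg)
      model$weights <- as.numeric(wt$weights)
      objective <- wt$objective
      traces[[length(traces) + 1L]] <- wt$trace
    } else {
      mm <- mutate_matrix(dataset, model, cfg)
      model$matrix <- mm$matrix
      objective <- mm$objective
      traces[[length(traces) + 1L]] <- mm$trace
    }
  }
  scored <- score_dataset(dataset, model, loo = TRUE)
  report <- make_eval_report(hat, "loo", scored)
  model$thresholds <- calibrate_thresholds(report)
  attr(model, "trace") <- do.call(rbind, traces)
  attr(model, "objective") <- objective
  model
}
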