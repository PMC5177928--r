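TIERS <- c("high", "medium", "low", "all")

tier_cutoff <- function(model, tier) {
  tier <- match.arg(tier, TIERS)
  if (tier == "all") return(0)  # every lysine is reported with its score
  cut <- model$thresholds[[tier]]
  if (is.na(cut)) {
    stop("model for ", model$hat, " has no calibrated '", tier, "' threshold")
  }
  cut
}

#' Predict HAT-specific acetylation sites in a protein sequence
#'
#' Scores every lysine of the sequence under every supplied model and
#' reports the sites whose score reaches the requested tier's calibrated
#' cutoff. The `"all"` tier reports every lysine with its score, with no
#' stringency.
#'
#' @param sequence A single amino-acid sequence string.
#' @param models A list of `hat_model` objects (or a single model).
#' @param tier One of `"high"`, `"medium"`, `"low"`, `"all"`.
#' @param protein_id Identifier used in the output (default `"query"`).
#' @return A data frame with columns `protein_id`, `position`, `hat`,
#'   `score`, `cutoff`, `tier` and `window`. Zero rows if the sequence has
#'   no lysine or nothing passes the tier.
#' @export
predict_protein <- function(sequence, models, tier = "medium",
                            protein_id = "query") {
  models <- as_model_list(models)
  tier <- match.arg(tier, TIERS)
  positions <- lysine_positions(sequence)
  out <- list()
  for (model in models) {
    if (length(positions) == 0L) next
    cut <- tier_cutoff(model, tier)
    windows <- extract_windows(sequence, positions, model$m, model$n)
    sc <- model_scores_cpp(windows_to_idx(windows),
                           windows_to_idx(model$positives$window),
                           as_numeric_matrix(model$matrix),
                           as.numeric(model$weights),
                           integer(length(windows)))
    keep <- sc >= cut
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        protein_id = protein_id, position = positions[keep],
        hat = model$hat, score = sc[keep], cutoff = cut, tier = tier,
        window = windows[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      hat = character(), score = numeric(),
                      cutoff = numeric(), tier = character(),
                      window = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$hat), , drop = FALSE]
  rownames(res) <- NULL
  res
}

as_model_list <- function(models) {
  if (inherits(models, "hat_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "hat_model")))
  models
}

#' Annotate an acetylome site table with potential upstream HATs
#'
#' For each experimentally identified acetylation site (a row of the site
#' table), every supplied model scores the site's window and the HATs whose
#' score reaches the tier cutoff (default `"high"`, to limit false
#' positives) are assigned to it. Only lysines listed in the table are
#' scored - ab initio scanning of whole sequences is left to
#' [predict_protein()]. Rows whose position is not a lysine in the provided
#' sequence are flagged and skipped with a warning.
#'
#' @param site_table Data frame with columns `protein_id` and `position`
#'   (1-based lysine positions); extra columns are ignored.
#' @param substrates Named character vector of sequences.
#' @param models List of trained `hat_model` objects.
#' @param tier Threshold tier applied to every model.
#' @return A list of class `acetylome_annotation` with elements
#'   `predictions` (data frame: `protein_id`, `position`, `hat`, `score`,
#'   `cutoff`, `tier`, `window`), `skipped` (flagged input rows) and
#'   `summary` (an `acetylome_summary`, see below). The summary holds the
#'   counts of annotated sites/proteins, the distribution of the number of
#'   HATs per site and per substrate (with fractions), and the pairwise
#'   overlap counts of sites shared between HAT pairs.
#' @export
annotate_acetylome <- function(site_table, substrates, models,
                               tier = "high") {
  models <- as_model_list(models)
  tier <- match.arg(tier, TIERS)
  stopifnot(all(c("protein_id", "position") %in% names(site_table)))
  missing_prot <- setdiff(site_table$protein_id, names(substrates))
  if (length(missing_prot)) {
    stop("site table references sequence(s) not provided: ",
         paste(missing_prot, collapse = ", "))
  }
  centers <- substring(substrates[site_table$protein_id],
                       site_table$position, site_table$position)
  bad <- centers != "K"
  if (any(bad)) {
    warning(sum(bad), " site-table row(s) whose position is not a lysine ",
            "were skipped")
  }
  sites <- site_table[!bad, c("protein_id", "position"), drop = FALSE]
  sites <- sites[!duplicated(sites), , drop = FALSE]
  preds <- list()
  for (model in models) {
    cut <- tier_cutoff(model, tier)
    for (prot in unique(sites$protein_id)) {
      pp <- sites$position[sites$protein_id == prot]
      windows <- extract_windows(substrates[[prot]], pp, model$m, model$n)
      sc <- model_scores_cpp(windows_to_idx(windows),
                             windows_to_idx(model$positives$window),
                             as_numeric_matrix(model$matrix),
                             as.numeric(model$weights), integer(length(pp)))
      keep <- sc >= cut
      if (any(keep)) {
        preds[[length(preds) + 1L]] <- data.frame(
          protein_id = prot, position = pp[keep], hat = model$hat,
          score = sc[keep], cutoff = cut, tier = tier,
          window = windows[keep], stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(protein_id = character(), position = integer(),
               hat = character(), score = numeric(), cutoff = numeric(),
               tier = character(), window = character(),
               stringsAsFactors = FALSE)
  predictions <- predictions[order(predictions$protein_id,
                                   predictions$position, predictions$hat), ,
                             drop = FALSE]
  rownames(predictions) <- NULL
  structure(list(predictions = predictions,
                 skipped = site_table[bad, , drop = FALSE],
                 summary = summarize_acetylome(predictions, nrow(sites),
                                               length(unique(sites$protein_id)))),
            class = "acetylome_annotation")
}

summarize_acetylome <- function(predictions, n_sites_in, n_proteins_in) {
  site_key <- paste(predictions$protein_id, predictions$position)
  hats_per_site <- if (nrow(predictions)) table(tapply(
    predictions$hat, site_key, function(h) length(unique(h)))) else table(integer())
  hats_per_protein <- if (nrow(predictions)) table(tapply(
    predictions$hat, predictions$protein_id,
    function(h) length(unique(h)))) else table(integer())
  as_dist <- function(tab) {
    counts <- as.integer(tab)
    data.frame(n_hats = as.integer(names(tab)), count = counts,
               fraction = if (sum(counts)) counts / sum(counts) else numeric(0))
  }
  hats <- sort(unique(predictions$hat))
  overlap <- matrix(0L, length(hats), length(hats),
                    dimnames = list(hats, hats))
  if (length(hats)) {
    by_hat <- split(site_key, predictions$hat)
    for (a in hats) for (b in hats) {
      overlap[a, b] <- length(intersect(by_hat[[a]], by_hat[[b]]))
    }
  }
  structure(list(
    n_sites_input = n_sites_in, n_proteins_input = n_proteins_in,
    n_sites_annotated = length(unique(site_key)),
    n_proteins_annotated = length(unique(predictions$protein_id)),
    site_coverage = if (n_sites_in) length(unique(site_key)) / n_sites_in else 0,
    protein_coverage = if (n_proteins_in)
      length(unique(predictions$protein_id)) / n_proteins_in else 0,
    hats_per_site = as_dist(hats_per_site),
    hats_per_protein = as_dist(hats_per_protein),
    site_overlap = overlap), class = "acetylome_summary")
}

#' @export
print.acetylome_annotation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("acetylome annotation: %d/%d sites (%.2f%%) and ",
                     "%d/%d proteins (%.2f%%) assigned >= 1 HAT\n"),
              s$n_sites_annotated, s$n_sites_input, 100 * s$site_coverage,
              s$n_proteins_annotated, s$n_proteins_input,
              100 * s$protein_coverage))
  if (nrow(s$hats_per_site)) {
    cat("HATs per annotated site:\n")
    print(s$hats_per_site, row.names = FALSE)
  }
  invisible(x)
}

#' Restrict HAT models to those with an ortholog in the target species
#'
#' Large-scale prediction in a non-human species only applies the models of
#' HATs detected in that species (e.g. by a reciprocal-best-hit screen, see
#' [detect_hat_presence()]).
#'
#' @param models List of `hat_model` objects.
#' @param presence Either a named logical vector (HAT name -> present) or a
#'   data frame with columns `hat` and `present` as returned by
#'   [detect_hat_presence()].
#' @return The subset of `models` whose HAT is flagged present.
#' @export
restrict_models_by_orthology <- function(models, presence) {
  models <- as_model_list(models)
  if (is.data.frame(presence)) {
    flags <- stats::setNames(as.logical(presence$present), presence$hat)
  } else {
    flags <- presence
  }
  if (length(flags) == 0L || !any(flags)) {
    stop("no HAT is flagged present in the target species; nothing to predict")
  }
  keep <- vapply(models, function(mo) isTRUE(flags[[mo$hat]]), logical(1))
  out <- models[keep]
  if (length(out) == 0L) {
    stop("none of the supplied models matches a present HAT")
  }
  out
}

#' Write a prediction table as TSV
#'
#' Columns `protein_id`, `position`, `hat`, `score`, `cutoff`, `tier`,
#' `window`; scores and cutoffs printed with 3 decimals.
#'
#' @param predictions Data frame from [predict_protein()] or
#'   [annotate_acetylome()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$score <- sprintf("%.3f", out$score)
  out$cutoff <- sprintf("%.3f", out$cutoff)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
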