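#' Read a tabular similarity-search hit file
#'
#' Accepts the standard 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/
#' end, subject start/end, e-value, bit score) with no header, as produced
#' by BLAST-style tools with tabular output. Only the columns needed for
#' best-hit selection are returned.
#'
#' @param path Path to the hit table.
#' @return Data frame with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) {
    stop("hit table must have the 12 standard tabular columns; found ",
         ncol(tab))
  }
  data.frame(query_id = as.character(tab[[1L]]),
             subject_id = as.character(tab[[2L]]),
             evalue = as.numeric(tab[[11L]]),
             bitscore = as.numeric(tab[[12L]]),
             stringsAsFactors = FALSE)
}

#' Best hit per query
#'
#' For each query, the hit with the highest bit score; ties are broken by
#' the lowest e-value, then by lexicographically smallest subject id.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore` (see [read_hit_table()]); `max_evalue` optionally drops
#'   hits above an e-value ceiling first (none by default).
#' @param max_evalue Optional e-value ceiling.
#' @return Named character vector: query id -> best subject id.
#' @export
best_hits <- function(hits, max_evalue = Inf) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$query_id)
  stats::setNames(hits$subject_id[first], hits$query_id[first])
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (x, y) is reported iff y is x's best hit in the A-to-B search and
#' x is y's best hit in the B-to-A search - the standard reciprocal-best-hit
#' ortholog criterion.
#'
#' @param a_to_b,b_to_a Hit tables for the two search directions.
#' @param max_evalue Optional e-value ceiling applied to both tables.
#' @return Data frame with columns `a_id`, `b_id`, sorted by `a_id`.
#' @export
reciprocal_best_hits <- function(a_to_b, b_to_a, max_evalue = Inf) {
  fwd <- best_hits(a_to_b, max_evalue)
  bwd <- best_hits(b_to_a, max_evalue)
  a_ids <- names(fwd)
  mutual <- !is.na(bwd[fwd]) & bwd[fwd] == a_ids
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(a_id = a_ids[mutual], b_id = unname(fwd[mutual]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' HAT presence in a species from reciprocal best hits
#'
#' A HAT is marked present in the target species iff its reference protein
#' id appears on the reference side of a reciprocal-best-hit pair.
#'
#' @param rbh_pairs Data frame from [reciprocal_best_hits()] with the
#'   reference proteome as side A.
#' @param hat_ids Named character vector mapping each HAT name to its
#'   reference proteome protein id.
#' @param species Species label recorded in the output.
#' @return Data frame with columns `species`, `hat`, `present` (logical)
#'   and `ortholog` (target-species protein id, or `NA`).
#' @export
detect_hat_presence <- function(rbh_pairs, hat_ids, species = NA_character_) {
  bad <- setdiff(names(hat_ids), HAT_NAMES)
  if (length(bad)) {
    stop("hat_ids has names outside the seven HATs: ",
         paste(bad, collapse = ", "))
  }
  hit <- match(unname(hat_ids), rbh_pairs$a_id)
  data.frame(species = species, hat = names(hat_ids),
             present = !is.na(hit),
             ortholog = rbh_pairs$b_id[hit],
             stringsAsFactors = FALSE)
}

#' Write a HAT presence table as TSV
#'
#' @param presence Data frame from [detect_hat_presence()].
#' @param path Output path.
#' @export
write_presence <- function(presence, path) {
  utils::write.table(presence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
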