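#' Read substrate protein sequences from a FASTA file
#'
#' Reads amino-acid sequences, uppercases them and strips `'*'` stop symbols.
#' A light pre-scan reports malformed headers or empty records with their
#' line number before handing parsing to [Biostrings::readAAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each header (the protein accession).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: file is empty: ", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1L],
         ": expected a '>' header before sequence data")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", trimws(lines[h]))))) {
      stop("FASTA parse error at line ", h, ": empty header")
    }
    nxt <- headers[headers > h]
    upto <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    body <- lines[seq.int(h + 1L, length.out = max(0L, upto - h))]
    if (!any(nzchar(gsub("\\s", "", body)))) {
      stop("FASTA parse error at line ", h, ": record '",
           trimws(lines[h]), "' has no sequence")
    }
  }
  aas <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("*", "", as.character(aas), fixed = TRUE))
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Read a HAT acetylation-site annotation table
#'
#' Expects a tab-separated file with header columns `protein_id`, `position`,
#' `hat` and `species`. Positions are 1-based. Duplicate
#' (protein, position, HAT) rows are collapsed to one; HAT names must be one
#' of the seven standard gene names (`CREBBP`, `EP300`, `HAT1`, `KAT2A`,
#' `KAT2B`, `KAT5`, `KAT8`) - common aliases such as `TIP60` are rejected
#' with a suggestion of the canonical name.
#'
#' @param path Path to a TSV annotation table.
#' @return A data frame with columns `protein_id` (character), `position`
#'   (integer, 1-based), `hat` (character) and `species` (character).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "position", "hat")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$species)) tab$species <- NA_character_
  pos <- suppressWarnings(as.integer(trimws(tab$position)))
  bad <- which(!grepl("^[0-9]+$", trimws(tab$position)) | is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("site table row ", bad[1L], ": position '", tab$position[bad[1L]],
         "' is not a positive 1-based integer")
  }
  hat <- toupper(trimws(tab$hat))
  unknown <- which(!hat %in% HAT_NAMES)
  if (length(unknown)) {
    i <- unknown[1L]
    hint <- HAT_ALIASES[hat[i]]
    stop("site table row ", i, ": unknown HAT '", tab$hat[i], "'",
         if (!is.na(hint)) paste0("; did you mean the standard name ", hint, "?")
         else paste0("; expected one of ", paste(HAT_NAMES, collapse = ", ")))
  }
  out <- data.frame(protein_id = trimws(tab$protein_id), position = pos,
                    hat = hat, species = tab$species,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("protein_id", "position", "hat")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract an acetylation-site peptide window ASP(m, n)
#'
#' Returns the peptide of `m` residues upstream and `n` residues downstream
#' of a central lysine, padding positions beyond the sequence termini with
#' `'*'` (which scores zero against every residue).
#'
#' @param sequence A single amino-acid sequence string.
#' @param position 1-based position of the central residue; must be `'K'`
#'   unless `require_k = FALSE`.
#' @param m,n Number of upstream / downstream flanking residues.
#' @param require_k Enforce that the center residue is a lysine.
#' @return A string of length `m + 1 + n`.
#' @examples
#' extract_window("MKKA", 2, 1, 1)  # "MKK"
#' extract_window("KAAA", 1, 2, 1)  # "**KA"
#' @export
extract_window <- function(sequence, position, m, n, require_k = TRUE) {
  extract_windows(sequence, position, m, n, require_k = require_k)
}

# Vectorised over positions within one sequence.
extract_windows <- function(sequence, positions, m, n, require_k = TRUE) {
  stopifnot(length(sequence) == 1L, m >= 0L, n >= 0L)
  len <- nchar(sequence)
  if (any(positions < 1L | positions > len)) {
    stop("position out of range 1..", len)
  }
  centers <- substring(sequence, positions, positions)
  if (require_k && any(centers != "K")) {
    bad <- positions[centers != "K"][1L]
    stop("residue at position ", bad, " is '",
         substring(sequence, bad, bad), "', not the required 'K'")
  }
  padded <- paste0(strrep(PAD_CHAR, m), sequence, strrep(PAD_CHAR, n))
  substring(padded, positions, positions + m + n)
}

# All lysine positions (1-based) in a sequence.
lysine_positions <- function(sequence) {
  as.integer(gregexpr("K", sequence, fixed = TRUE)[[1L]][
    gregexpr("K", sequence, fixed = TRUE)[[1L]] > 0L])
}

#' Build the labeled training dataset for one HAT
#'
#' For the given HAT, windows at its annotated acetylation sites are the
#' positives; windows at every other lysine in the same substrate proteins
#' are the negatives. A lysine annotated only for a *different* HAT counts
#' as a negative here, since per-HAT annotation is the only label available.
#'
#' @param substrates Named character vector of sequences (see [read_fasta()]).
#' @param annotations Annotation data frame (see [read_site_table()]).
#' @param hat One of the seven HAT names.
#' @param m,n Window half-widths.
#' @return An object of class `hat_dataset`: a list with elements `hat`, `m`,
#'   `n`, `positives` and `negatives`; the latter two are data frames with
#'   columns `protein_id`, `position` and `window`, sorted by protein then
#'   position.
#' @export
build_dataset <- function(substrates, annotations, hat, m, n) {
  stopifnot(is.character(substrates), !is.null(names(substrates)))
  hat <- match.arg(hat, HAT_NAMES)
  ann <- annotations[annotations$hat == hat, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("no annotated sites for HAT ", hat, ": cannot build a dataset")
  }
  missing_prot <- setdiff(ann$protein_id, names(substrates))
  if (length(missing_prot)) {
    stop("annotated substrate(s) without a provided sequence: ",
         paste(missing_prot, collapse = ", "))
  }
  ann <- ann[order(ann$protein_id, ann$position), , drop = FALSE]
  pos_list <- list(); neg_list <- list()
  for (prot in unique(ann$protein_id)) {
    seq <- substrates[[prot]]
    sites <- ann$position[ann$protein_id == prot]
    centers <- substring(seq, sites, sites)
    if (any(centers != "K")) {
      stop("annotated position ", sites[centers != "K"][1L], " in ", prot,
           " is not a lysine")
    }
    others <- setdiff(lysine_positions(seq), sites)
    pos_list[[prot]] <- data.frame(
      protein_id = prot, position = sites,
      window = extract_windows(seq, sites, m, n),
      stringsAsFactors = FALSE)
    neg_list[[prot]] <- if (length(others)) data.frame(
      protein_id = prot, position = sort(others),
      window = extract_windows(seq, sort(others), m, n),
      stringsAsFactors = FALSE) else NULL
  }
  positives <- do.call(rbind, pos_list)
  neg_list <- Filter(Negate(is.null), neg_list)
  negatives <- if (length(neg_list)) do.call(rbind, neg_list) else
    data.frame(protein_id = character(), position = integer(),
               window = character(), stringsAsFactors = FALSE)
  rownames(positives) <- NULL
  rownames(negatives) <- NULL
  structure(list(hat = hat, m = as.integer(m), n = as.integer(n),
                 positives = positives, negatives = negatives),
            class = "hat_dataset")
}

#' @export
print.hat_dataset <- function(x, ...) {
  cat("hat_dataset:", x$hat, sprintf("ASP(%d, %d)", x$m, x$n), "-",
      nrow(x$positives), "positive /", nrow(x$negatives),
      "negative lysine windows\n")
  invisible(x)
}

#' Write a labeled dataset as TSV
#'
#' Columns: `hat`, `protein_id`, `position`, `label`, `window`.
#'
#' @param dataset A `hat_dataset`.
#' @param path Output file path.
#' @export
write_dataset <- function(dataset, path) {
  df <- rbind(
    cbind(dataset$positives, label = "positive"),
    cbind(dataset$negatives, label = "negative"))
  df <- data.frame(hat = dataset$hat, df[c("protein_id", "position",
                                           "label", "window")],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
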