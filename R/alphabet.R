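# Residue alphabet used throughout: the 20 standard amino acids, 'X' for
# unknown residues and '*' for positions padded beyond a sequence terminus.
# 'X' and '*' score 0 against everything, so padded/unknown positions make a
# neutral contribution to peptide similarity.

HAT_NAMES <- c("CREBBP", "EP300", "HAT1", "KAT2A", "KAT2B", "KAT5", "KAT8")

# Common aliases -> UniProt standard gene names, used for input validation.
HAT_ALIASES <- c(
  CBP = "CREBBP", P300 = "EP300", KAT1 = "HAT1", GCN5 = "KAT2A",
  GCN5L2 = "KAT2A", PCAF = "KAT2B", TIP60 = "KAT5", HTATIP = "KAT5",
  ESA1 = "KAT5", MOF = "KAT8", MYST1 = "KAT8"
)

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PAD_CHAR <- "*"
AA_ALPHABET <- c(AA_STANDARD, "X", PAD_CHAR)

.B62_VALUES <- c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4
)

#' BLOSUM62 substitution matrix over the package alphabet
#'
#' Returns the standard BLOSUM62 amino-acid substitution scores as an integer
#' matrix over the 22-symbol alphabet used by this package (20 standard
#' residues, `"X"` for unknown and `"*"` for terminal padding). The `"X"` and
#' `"*"` rows and columns are all zero, so unknown and padded positions
#' contribute nothing to a similarity score. This is the initial state of
#' every model's scoring matrix before matrix mutation.
#'
#' @return A 22 x 22 integer matrix with `dimnames` equal to the alphabet.
#' @examples
#' m <- blosum62_matrix()
#' m["G", "G"] + m["K", "K"] + m["S", "S"]  # 15
#' @export
blosum62_matrix <- function() {
  m <- matrix(0L, nrow = 22L, ncol = 22L,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[1:20, 1:20] <- matrix(as.integer(.B62_VALUES), nrow = 20L, byrow = TRUE)
  m
}

# Convert a character vector of equal-length windows into an integer index
# matrix (one row per window) over AA_ALPHABET. Residues outside the alphabet
# map to 'X'.
windows_to_idx <- function(windows) {
  if (length(windows) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) {
    stop("windows must all have equal length")
  }
  chars <- unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE)
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- match("X", AA_ALPHABET)
  matrix(idx, nrow = length(windows), ncol = lens[1L], byrow = TRUE)
}

# Validate a substitution matrix argument: 22x22 numeric with the alphabet
# dimnames; X/pad rows and columns all zero.
check_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(22L, 22L))) {
    stop("substitution matrix must be 22 x 22 over the package alphabet")
  }
  if (!identical(rownames(matrix), AA_ALPHABET) ||
      !identical(colnames(matrix), AA_ALPHABET)) {
    stop("substitution matrix dimnames must equal the package alphabet")
  }
  neutral <- 21:22
  if (any(matrix[neutral, ] != 0) || any(matrix[, neutral] != 0)) {
    stop("'X' and padding rows/columns of the matrix must be all zero")
  }
  invisible(matrix)
}
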