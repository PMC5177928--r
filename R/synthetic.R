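#' Motif specifications for synthetic benchmark studies
#'
#' Builds a position-specific motif specification emulating the sequence
#' preferences observed around HAT-specific acetylation sites: a set of
#' informative offsets relative to the central lysine, each enriched for one
#' residue with a given probability, over an i.i.d. background. Presets:
#'
#' * `"crebbp-like"`: G at -1, S at +1, K at +3..+5 (annotated as CREBBP);
#' * `"ep300-like"`: A at -1, K at +1, K at +3..+5 (EP300);
#' * `"kat2b-like"`: G at -2, G at -4 (KAT2B);
#' * `"null"`: no informative positions (annotated as KAT5) - planted sites
#'   are indistinguishable from background lysines.
#'
#' @param preset One of the preset names above.
#' @param effect `"clean"` (enrichment probability 0.9), `"weak"` (0.4) or
#'   `"null"` (informative positions dropped).
#' @param background Named amino-acid frequency vector over the 20 standard
#'   residues, summing to 1. `"uniform"` (default) or `"swissprot"` for
#'   average database composition.
#' @return A list of class `motif_spec` with elements `hat_name`,
#'   `informative` (data frame `offset`, `residue`, `prob`), `background`
#'   and `effect`.
#' @export
make_motif_spec <- function(preset = c("crebbp-like", "ep300-like",
                                       "kat2b-like", "null"),
                            effect = c("clean", "weak", "null"),
                            background = "uniform") {
  if (!is.character(preset) || !preset[1L] %in%
        c("crebbp-like", "ep300-like", "kat2b-like", "null")) {
    stop("unknown preset '", preset[1L], "'; available presets: ",
         "crebbp-like, ep300-like, kat2b-like, null")
  }
  preset <- preset[1L]
  effect <- match.arg(effect)
  prob <- switch(effect, clean = 0.9, weak = 0.4, null = NA_real_)
  inf <- switch(preset,
    "crebbp-like" = data.frame(offset = c(-1L, 1L, 3L, 4L, 5L),
                               residue = c("G", "S", "K", "K", "K")),
    "ep300-like" = data.frame(offset = c(-1L, 1L, 3L, 4L, 5L),
                              residue = c("A", "K", "K", "K", "K")),
    "kat2b-like" = data.frame(offset = c(-4L, -2L),
                              residue = c("G", "G")),
    "null" = data.frame(offset = integer(), residue = character()))
  if (preset == "null" || effect == "null") {
    inf <- data.frame(offset = integer(), residue = character(),
                      prob = numeric())
  } else {
    inf$prob <- prob
  }
  hat_name <- switch(preset, "crebbp-like" = "CREBBP",
                     "ep300-like" = "EP300", "kat2b-like" = "KAT2B",
                     "null" = "KAT5")
  if (identical(background, "uniform")) {
    bg <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else if (identical(background, "swissprot")) {
    # average database amino-acid composition, renormalized over 20 residues
    bg <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
            Q = 0.0393, E = 0.0672, G = 0.0708, H = 0.0227, I = 0.0591,
            L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0474,
            S = 0.0665, T = 0.0536, W = 0.0110, Y = 0.0292, V = 0.0686)
    bg <- bg / sum(bg)
  } else {
    stopifnot(is.numeric(background), length(background) == 20L,
              setequal(names(background), AA_STANDARD))
    bg <- background[AA_STANDARD] / sum(background)
  }
  structure(list(hat_name = hat_name, informative = inf, background = bg,
                 effect = effect, preset = preset),
            class = "motif_spec")
}

#' Sample a synthetic study of substrates and planted acetylation sites
#'
#' Generates substrate sequences with residues drawn i.i.d. from the spec's
#' background distribution, plants `sites_per_substrate` lysines per
#' substrate with the spec's informative offsets enriched, and records them
#' as the annotation table. Background lysines occur naturally and act as
#' negatives. Planted sites are spaced at least 61 residues apart (the
#' maximal ASP(30, 30) window width) so no two positive windows overlap,
#' and sit at least 30 residues from either terminus. Regeneration from the
#' same spec and seed is bit-identical.
#'
#' @param spec A [make_motif_spec()] result.
#' @param n_substrates Number of substrate proteins.
#' @param sites_per_substrate Planted sites per substrate.
#' @param seq_length Substrate length; must be able to host the requested
#'   sites (`seq_length >= 61 * sites_per_substrate + 60`).
#' @param seed Integer seed.
#' @return A list of class `synthetic_study`: `substrates` (named character
#'   vector), `annotations` (data frame as from [read_site_table()]),
#'   `truth` (the spec) and `seed`.
#' @export
sample_study <- function(spec, n_substrates = 60L, sites_per_substrate = 3L,
                         seq_length = 360L, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"), n_substrates >= 1L,
            sites_per_substrate >= 1L)
  block <- (seq_length - 60L) %/% sites_per_substrate
  if (block < 61L) {
    stop("infeasible packing: seq_length = ", seq_length, " cannot host ",
         sites_per_substrate, " sites spaced >= 61 apart with 30-residue ",
         "margins; need seq_length >= ", 61L * sites_per_substrate + 60L)
  }
  with_seed(as.integer(seed), {
    substrates <- character(n_substrates)
    names(substrates) <- sprintf("SYN%04d", seq_len(n_substrates))
    ann <- vector("list", n_substrates)
    for (s in seq_len(n_substrates)) {
      seq_chars <- sample(AA_STANDARD, seq_length, replace = TRUE,
                          prob = spec$background)
      offsets_in_block <- sample.int(block - 60L, sites_per_substrate,
                                     replace = TRUE) - 1L
      sites <- 31L + (seq_len(sites_per_substrate) - 1L) * block +
        offsets_in_block
      for (p in sites) {
        seq_chars[p] <- "K"
        for (r in seq_len(nrow(spec$informative))) {
          if (stats::runif(1) < spec$informative$prob[r]) {
            seq_chars[p + spec$informative$offset[r]] <-
              spec$informative$residue[r]
          }
        }
      }
      substrates[[s]] <- paste(seq_chars, collapse = "")
      ann[[s]] <- data.frame(protein_id = names(substrates)[s],
                             position = sites, hat = spec$hat_name,
                             species = "synthetic",
                             stringsAsFactors = FALSE)
    }
    structure(list(substrates = substrates,
                   annotations = do.call(rbind, ann),
                   truth = spec, seed = as.integer(seed)),
              class = "synthetic_study")
  })
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits `substrates.fa` (FASTA), `sites.tsv` (annotation table readable by
#' [read_site_table()]) and `truth.json` (the generating motif spec). The
#' files round-trip losslessly through the dataset readers.
#'
#' @param study A [sample_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "substrates.fa")
  writeLines(paste0(">", names(study$substrates), "\n", study$substrates),
             fa)
  tsv <- file.path(dir, "sites.tsv")
  utils::write.table(study$annotations, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    preset = study$truth$preset, hat_name = study$truth$hat_name,
    effect = study$truth$effect,
    informative = study$truth$informative,
    background = as.list(study$truth$background), seed = study$seed),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fa, tsv, truth))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$substrates), "substrates,",
      nrow(x$annotations), "planted", x$truth$hat_name, "sites (preset",
      paste0(x$truth$preset, ", effect ", x$truth$effect, ")\n"))
  invisible(x)
}
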