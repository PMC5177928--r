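# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/C++ code paths: plain double loops and pairwise enumeration.

# clamped (weighted) peptide similarity by explicit per-position lookup
oracle_similarity <- function(a, b, M = blosum62_matrix(),
                              w = rep(1, nchar(a))) {
  aa <- strsplit(a, "", fixed = TRUE)[[1L]]
  bb <- strsplit(b, "", fixed = TRUE)[[1L]]
  s <- 0
  for (i in seq_along(aa)) {
    s <- s + w[i] * M[aa[i], bb[i]]
  }
  max(0, s)
}

# Mann-Whitney AUC: mean pairwise comparison with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# sensitivity at anchored specificity by exhaustive scan over all cutoffs
oracle_sn_at_sp <- function(pos, neg, anchor) {
  candidates <- sort(unique(c(pos, neg, max(c(pos, neg)) + 1)))
  for (c in candidates) {
    if (mean(neg < c) >= anchor) {
      return(mean(pos >= c))
    }
  }
  0
}

# best hit per query by explicit per-row comparison
oracle_best_hits <- function(tab) {
  out <- character(0)
  for (q in sort(unique(tab$query_id))) {
    rows <- tab[tab$query_id == q, , drop = FALSE]
    best <- rows[1L, ]
    if (nrow(rows) > 1L) {
      for (j in 2:nrow(rows)) {
        r <- rows[j, ]
        better <- r$bitscore > best$bitscore ||
          (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
          (r$bitscore == best$bitscore && r$evalue == best$evalue &&
             r$subject_id < best$subject_id)
        if (better) best <- r
      }
    }
    out[q] <- best$subject_id
  }
  out
}

oracle_rbh <- function(ab, ba) {
  fa <- oracle_best_hits(ab)
  fb <- oracle_best_hits(ba)
  pairs <- list()
  for (x in names(fa)) {
    y <- fa[[x]]
    if (y %in% names(fb) && fb[[y]] == x) {
      pairs[[length(pairs) + 1L]] <- c(x, y)
    }
  }
  if (!length(pairs)) {
    return(data.frame(a_id = character(), b_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(a_id = vapply(pairs, `[`, character(1), 1L),
                    b_id = vapply(pairs, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out[order(out$a_id), , drop = FALSE]
}

# random peptide window over the alphabet (occasionally X / padding)
random_window <- function(len) {
  paste(sample(c(rep(hatsite:::AA_STANDARD, 3), "X", "*"), len,
               replace = TRUE), collapse = "")
}

# random tabular hit table between two id sets
random_hit_table <- function(queries, subjects, n_hits) {
  data.frame(
    query_id = sample(queries, n_hits, replace = TRUE),
    subject_id = sample(subjects, n_hits, replace = TRUE),
    evalue = signif(10^stats::runif(n_hits, -20, 0), 3),
    bitscore = sample(50:200, n_hits, replace = TRUE),
    stringsAsFactors = FALSE)
}

# small fully in-memory toy study for fast tests
toy_substrates <- c(
  P1 = "MKKKAGSKAAAKTTTKGGGSKAAAV",
  P2 = "GGKASKKLLLPKSSSTKYWKAAAAA",
  P3 = "AAAKGSKPPPKWWKCCCKDDEKAAG")

toy_annotations <- data.frame(
  protein_id = c("P1", "P1", "P2", "P2", "P3"),
  position = c(2L, 8L, 3L, 12L, 4L),
  hat = "EP300", species = "human", stringsAsFactors = FALSE)

# reduced training configuration used throughout the tests: search windows
# up to ASP(8, 8) and a few hundred annealing proposals, which the methods
# vignette documents as the benchmark problem size
test_config <- function(seed = 1L) {
  train_config(m_range = 1:8, n_range = 1:8, max_stagnation = 120L,
               max_proposals = 400L, seed = seed)
}
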