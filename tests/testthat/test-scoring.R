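test_that("peptide similarity matches hand-derived BLOSUM62 sums", {
  expect_equal(peptide_similarity("GKS", "GKS"), oracle_similarity("GKS", "GKS"))
  expect_equal(peptide_similarity("GKS", "GKS"), 15)
  # negative raw sum is clamped to zero
  expect_true(sum(diag(blosum62_matrix()[c("W", "W", "W"),
                                         c("C", "C", "C")])) < 0)
  expect_equal(peptide_similarity("WWW", "CCC"), 0)
  # all-zero matrix scores everything zero
  zero <- blosum62_matrix(); zero[, ] <- 0L
  expect_equal(peptide_similarity("GKS", "AKV", zero), 0)
})

test_that("weighted similarity scales positions and validates input", {
  expect_equal(weighted_similarity("GKS", "GKS", weights = c(2, 1, 1)), 21)
  expect_equal(weighted_similarity("GKS", "AKV", weights = c(1, 1, 1)),
               peptide_similarity("GKS", "AKV"))
  expect_equal(weighted_similarity("GKS", "AKV", weights = c(0, 0, 0)), 0)
  expect_error(weighted_similarity("GKS", "AKVA", weights = c(1, 1, 1)),
               "equal length")
  expect_error(weighted_similarity("GKS", "AKV", weights = c(1, -1, 1)),
               "non-negative")
})

test_that("padding and unknown residues contribute nothing", {
  expect_equal(peptide_similarity("**K", "GAK"), peptide_similarity("K", "K"))
  expect_equal(peptide_similarity("XKX", "GKS"), peptide_similarity("K", "K"))
})

test_that("similarity agrees exactly with the double-loop oracle", {
  set.seed(71)
  for (rep in 1:60) {
    len <- sample(3:15, 1)
    a <- random_window(len); b <- random_window(len)
    w <- sample(0:3, len, replace = TRUE)
    expect_equal(weighted_similarity(a, b, weights = w),
                 oracle_similarity(a, b, w = w))
  }
})

test_that("doubling all weights doubles every unclamped similarity", {
  set.seed(5)
  for (rep in 1:20) {
    len <- sample(3:9, 1)
    a <- random_window(len); b <- random_window(len)
    w <- sample(1:3, len, replace = TRUE)
    s1 <- weighted_similarity(a, b, weights = w)
    s2 <- weighted_similarity(a, b, weights = 2 * w)
    if (s1 > 0) expect_equal(s2, 2 * s1) else expect_equal(s2, 0)
  }
})

test_that("similarity under BLOSUM62 is symmetric", {
  set.seed(6)
  for (rep in 1:20) {
    a <- random_window(7); b <- random_window(7)
    expect_equal(peptide_similarity(a, b), peptide_similarity(b, a))
  }
})

test_that("model score is the mean over reference peptides", {
  refs <- data.frame(protein_id = c("A", "B"), position = c(5L, 9L),
                     window = c("GKS", "AKV"), stringsAsFactors = FALSE)
  model <- new_hat_model("EP300", 1, 1, refs)
  q <- "GKS"
  expect_equal(model_score(q, model),
               mean(c(oracle_similarity(q, "GKS"), oracle_similarity(q, "AKV"))))
  # single reference: mean of one
  m1 <- new_hat_model("EP300", 1, 1, refs[1, ])
  expect_equal(model_score("GKS", m1), oracle_similarity("GKS", "GKS"))
})

test_that("leave-one-out exclusion is by origin, not sequence", {
  # two distinct origins with the SAME window sequence
  refs <- data.frame(protein_id = c("A", "B"), position = c(5L, 9L),
                     window = c("GKS", "GKS"), stringsAsFactors = FALSE)
  model <- new_hat_model("EP300", 1, 1, refs)
  s <- model_score("GKS", model, exclude = list(protein_id = "A", position = 5))
  # the duplicate from protein B must remain in the mean
  expect_equal(s, oracle_similarity("GKS", "GKS"))
  expect_error(model_score("GKS", new_hat_model("EP300", 1, 1, refs[1, ]),
                           exclude = list(protein_id = "A", position = 5)),
               "no reference peptides")
})

test_that("LOO on two positives scores each against the other", {
  subs <- c(S1 = "AGKSAAAKVA")
  ann <- data.frame(protein_id = c("S1", "S1"), position = c(3L, 8L),
                    hat = "EP300", species = "human", stringsAsFactors = FALSE)
  ds <- build_dataset(subs, ann, "EP300", 1, 1)
  model <- new_hat_model("EP300", 1, 1, ds$positives)
  sc <- score_dataset(ds, model, loo = TRUE)
  expect_equal(sc$score[sc$position == 3],
               oracle_similarity("GKS", "AKV"))
  expect_equal(sc$score[sc$position == 8],
               oracle_similarity("AKV", "GKS"))
})

test_that("LOO score over k identical positives is independent of k", {
  vals <- vapply(c(2L, 4L, 7L), function(k) {
    refs <- data.frame(protein_id = paste0("P", 1:k), position = 1L,
                       window = "GKS", stringsAsFactors = FALSE)
    ds <- structure(list(hat = "EP300", m = 1L, n = 1L, positives = refs,
                         negatives = data.frame(protein_id = "N",
                                                position = 2L,
                                                window = "AKA")),
                    class = "hat_dataset")
    model <- new_hat_model("EP300", 1, 1, refs)
    sc <- score_dataset(ds, model, loo = TRUE)
    sc$score[1L]
  }, numeric(1))
  expect_true(all(vals == vals[1L]))
})

test_that("score_dataset validates geometry and degenerate LOO", {
  subs <- c(S1 = "AGKSAAAKVA")
  ann <- data.frame(protein_id = "S1", position = 3L, hat = "EP300",
                    species = "human", stringsAsFactors = FALSE)
  ds <- build_dataset(subs, ann, "EP300", 1, 1)
  model <- new_hat_model("EP300", 1, 1, ds$positives)
  expect_error(score_dataset(ds, model, loo = TRUE), "at least 2")
  ds2 <- build_dataset(subs, ann, "EP300", 2, 2)
  expect_error(score_dataset(ds2, model), "does not match model")
})

test_that("dataset scoring equals the brute-force oracle on random sets", {
  set.seed(9)
  for (rep in 1:5) {
    np <- sample(2:6, 1); nn <- sample(1:8, 1); len <- 5
    refs <- data.frame(protein_id = paste0("P", 1:np), position = 1L,
                       window = vapply(1:np, function(i)
                         paste0(random_window(2), "K",
                                substr(random_window(2), 1, 2)),
                         character(1)),
                       stringsAsFactors = FALSE)
    negs <- data.frame(protein_id = paste0("N", 1:nn), position = 2L,
                       window = vapply(1:nn, function(i)
                         paste0(random_window(2), "K",
                                substr(random_window(2), 1, 2)),
                         character(1)),
                       stringsAsFactors = FALSE)
    ds <- structure(list(hat = "EP300", m = 2L, n = 2L, positives = refs,
                         negatives = negs), class = "hat_dataset")
    w <- sample(0:2, len, replace = TRUE)
    model <- new_hat_model("EP300", 2, 2, refs, weights = w)
    sc <- score_dataset(ds, model, loo = TRUE)
    for (i in seq_len(np)) {
      others <- refs$window[-i]
      expected <- mean(vapply(others, oracle_similarity, numeric(1),
                              a = refs$window[i], w = w))
      expect_equal(sc$score[i], expected)
    }
    for (j in seq_len(nn)) {
      expected <- mean(vapply(refs$window, oracle_similarity, numeric(1),
                              a = negs$window[j], w = w))
      expect_equal(sc$score[np + j], expected)
    }
  }
})

test_that("the BLOSUM62 constant matches the published matrix", {
  skip_if_not_installed("Biostrings")
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  mine <- blosum62_matrix()
  std <- hatsite:::AA_STANDARD
  expect_equal(unname(mine[std, std]), unname(ref[std, std]))
})

test_that("model JSON serialization round-trips bit-exactly", {
  refs <- data.frame(protein_id = c("A", "B"), position = c(5L, 9L),
                     window = c("GKSAA", "AKVGG"), stringsAsFactors = FALSE)
  mat <- blosum62_matrix(); mat["G", "S"] <- mat["G", "S"] + 3L
  model <- new_hat_model("KAT2B", 2, 2, refs, matrix = mat,
                         weights = c(2L, 0L, 1L, 3L, 1L),
                         thresholds = c(high = 12.5, medium = 8, low = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_hat_model(model, path)
  back <- read_hat_model(path)
  expect_identical(back$matrix, model$matrix)
  expect_identical(as.integer(back$weights), as.integer(model$weights))
  expect_identical(back$positives, model$positives)
  expect_equal(back$thresholds, model$thresholds)
  # writing again gives identical bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hat_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
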