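ranked_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(spectrum_id = r[[1]], peptide_pair_id = r[[2]],
               xl_position_id = r[[3]], rank = as.integer(r[[4]]),
               score = as.numeric(r[[5]]))))
}

test_that("top-two extraction applies the position-duplicate promotion rule", {
  # ranks 1 and 2 share the peptide pair but differ in cross-link position:
  # rank 2 is dropped and rank 3 promoted
  recs <- ranked_df(list("sp1", "pairA", "pos1", 1, 10),
                    list("sp1", "pairA", "pos2", 2, 9),
                    list("sp1", "pairB", "pos1", 3, 7))
  ds <- extract_top_two(recs)
  expect_equal(ds$s1, 10)
  expect_equal(ds$s2, 7)

  # single candidate: second score missing
  ds <- extract_top_two(ranked_df(list("sp1", "pairA", "pos1", 1, 5)))
  expect_equal(ds$s1, 5)
  expect_true(is.na(ds$s2))

  # duplicate pair with no third candidate: second score missing
  ds <- extract_top_two(ranked_df(list("sp1", "pairA", "pos1", 1, 10),
                                  list("sp1", "pairA", "pos2", 2, 9)))
  expect_equal(ds$s1, 10)
  expect_true(is.na(ds$s2))

  # distinct pairs at ranks 1-2: plain top two
  ds <- extract_top_two(ranked_df(list("sp1", "pairA", "pos1", 1, 10),
                                  list("sp1", "pairB", "pos1", 2, 9)))
  expect_equal(ds$s2, 9)

  # same pair, same position at ranks 1-2 is not a position duplicate
  ds <- extract_top_two(ranked_df(list("sp1", "pairA", "pos1", 1, 10),
                                  list("sp1", "pairA", "pos1", 2, 10)))
  expect_equal(ds$s2, 10)
})

test_that("extraction agrees with a brute-force restatement of the rule", {
  brute <- function(g) {
    g <- g[order(g$rank), ]
    s1 <- g$score[1]
    rest <- g[-1, , drop = FALSE]
    if (nrow(rest) >= 1 &&
        rest$peptide_pair_id[1] == g$peptide_pair_id[1] &&
        rest$xl_position_id[1] != g$xl_position_id[1])
      rest <- rest[-1, , drop = FALSE]
    c(s1, if (nrow(rest)) rest$score[1] else NA_real_)
  }
  set.seed(7)
  for (rep in 1:30) {
    n_cand <- sample(1:4, 1)
    g <- data.frame(spectrum_id = "s",
                    peptide_pair_id = sample(c("pA", "pB"), n_cand,
                                             replace = TRUE),
                    xl_position_id = sample(c("x1", "x2"), n_cand,
                                            replace = TRUE),
                    rank = 1:n_cand,
                    score = sort(round(runif(n_cand, 0, 20), 3),
                                 decreasing = TRUE))
    ds <- extract_top_two(g)
    exp <- brute(g)
    expect_equal(ds$s1, exp[1])
    expect_equal(ds$s2, exp[2])
  }
})

test_that("extraction validates its input", {
  empty <- ranked_df(list("s", "p", "x", 1, 1))[0, ]
  expect_equal(nrow(extract_top_two(empty)), 0)
  expect_error(extract_top_two(
    ranked_df(list("sp1", "pA", "x1", 1, 5), list("sp1", "pB", "x1", 1, 4))),
    "duplicate")
  expect_error(extract_top_two(ranked_df(list("sp1", "pA", "x1", 2, 5))),
               "rank-1")
})

test_that("missing-second-score proportion is the exact fraction", {
  ds <- score_dataset(c(5, 4, 6, 7), c(3, NA, 2, NA))
  expect_equal(compute_v_phi(ds), 0.5)
  expect_equal(compute_v_phi(score_dataset(1:3, c(0, 1, 2))), 0)
  expect_equal(compute_v_phi(score_dataset(1:3)), 1)
  expect_error(compute_v_phi(score_dataset(numeric(0), numeric(0))), "empty")
})

test_that("wide-form TSV reads missing markers and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "10.5\t", "8\t7.25", "3\tNA"), f)
  ds <- read_scores_tsv(f)
  expect_equal(ds$s1, c(10.5, 8, 3))
  expect_equal(ds$s2, c(NA, 7.25, NA))
  expect_equal(compute_v_phi(ds), 2 / 3)

  writeLines(c("s1\ts2", "abc\t1"), f)
  expect_error(read_scores_tsv(f), "line 1")
  writeLines(c("a\tb", "1\t2"), f)
  expect_error(read_scores_tsv(f), "s1")
})

test_that("ranked TSV round-trips through extraction", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tpeptide_pair_id\txl_position_id\trank\tscore",
               "sp1\tpA\tx1\t1\t12.5",
               "sp1\tpB\tx1\t2\t9",
               "sp2\tpC\tx1\t1\t4"), f)
  recs <- read_ranked_tsv(f)
  ds <- extract_top_two(recs)
  expect_equal(ds$s1, c(12.5, 4))
  expect_equal(ds$s2, c(9, NA))
})

test_that("model JSON serialization is lossless", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".json")
  for (i in 1:5) {
    m <- random_model()
    write_model_json(m, f, meta = list(restarts = 24, seed = 1))
    m2 <- read_model_json(f)
    for (nm in names(m$theta)) {
      expect_equal(m2$theta[[nm]]$mu, m$theta[[nm]]$mu, tolerance = 1e-15)
      expect_equal(m2$theta[[nm]]$sigma, m$theta[[nm]]$sigma,
                   tolerance = 1e-15)
      expect_equal(m2$theta[[nm]]$lambda, m$theta[[nm]]$lambda,
                   tolerance = 1e-15)
    }
    expect_equal(m2$w, m$w, tolerance = 1e-15)
    expect_equal(m2$v, m$v, tolerance = 1e-15)
    expect_equal(m2$v_phi, m$v_phi, tolerance = 1e-15)
    expect_equal(attr(m2, "meta")$restarts, 24)
  }
  # one-sample model round trip
  m1 <- one_sample_model(toy_model()$theta[c("C", "J1", "I1")],
                         c(C = 0.3, J1 = 0.3, I1 = 0.4))
  write_model_json(m1, f)
  m2 <- read_model_json(f)
  expect_s3_class(m2, "one_sample_model")
  expect_equal(m2$w, m1$w, tolerance = 1e-15)
})

test_that("extraction is idempotent on already-paired data", {
  set.seed(12)
  ds <- random_dataset(40)
  # re-expand pairs to a ranked table and extract again
  obs <- !is.na(ds$s2)
  ids <- sprintf("sp%03d", seq_len(nrow(ds)))
  recs <- rbind(
    data.frame(spectrum_id = ids, peptide_pair_id = "p1",
               xl_position_id = "x1", rank = 1L, score = ds$s1),
    data.frame(spectrum_id = ids[obs], peptide_pair_id = "p2",
               xl_position_id = "x1", rank = 2L, score = ds$s2[obs]))
  ds2 <- extract_top_two(recs)
  expect_equal(ds2$s1, ds$s1)
  expect_equal(ds2$s2, ds$s2)
  expect_equal(compute_v_phi(ds2), compute_v_phi(ds))
})
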