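local_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- separable_dataset(30, seed = 51)
      cache <<- train_model(ds, train_config("linear", scheme = "AAC",
                                             seed = 1), threshold = 0)
    }
    cache
  }
})

test_that("window scans cover exactly L - w + 1 stride-1 windows", {
  antigen <- random_peptides(1, lengths = 30, seed = 52)
  hits <- scan_windows(antigen, local_bundle(), window = 20,
                       threshold = -Inf, full_profile = TRUE)
  prof <- attr(hits, "profile")
  expect_equal(nrow(prof), 11L)
  expect_equal(prof$start, 1:11)
  expect_equal(prof$end, 20:30)
  expect_equal(prof$window, substring(antigen, 1:11, 20:30))
  one <- scan_windows(random_peptides(1, lengths = 20, seed = 53),
                      local_bundle(), window = 20, threshold = -Inf)
  expect_equal(c(one$start, one$end), c(1, 20))
  expect_error(scan_windows(strrep("A", 10), local_bundle(), window = 20),
               "shorter")
})

test_that("multi-window scanning pools and ranks window lengths", {
  antigen <- random_peptides(1, lengths = 40, seed = 54)
  hits <- scan_windows_multi(antigen, local_bundle(), windows = c(10, 20),
                             threshold = -Inf)
  expect_equal(nrow(hits), (40 - 10 + 1) + (40 - 20 + 1))
  expect_true(all(diff(hits$score) <= 0))
})

test_that("exact epitope mapping reports all overlapping occurrences", {
  known <- peptide_set(c("ACDE", "AA", "WWWW"),
                       id = c("e1", "e2", "e3"),
                       label = c("IgG", "IgA", "IgE"))
  hits <- map_exact_epitopes("KKACDEKK", known)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(3, 6))
  expect_equal(hits$class, "IgG")
  multi <- map_exact_epitopes("AAAA", known)
  expect_equal(multi$start, 1:3)
  expect_equal(multi$end, 2:4)
  none <- map_exact_epitopes("KLMN", known)
  expect_equal(nrow(none), 0L)
})

test_that("alignment matches identity self-alignment and empty cases", {
  self <- smith_waterman("ACDEF", "ACDEF", match = 1)
  expect_equal(self$score, 5)
  expect_equal(c(self$a_start, self$a_end), c(1, 5))
  disjoint <- smith_waterman("AAAA", "CCCC")
  expect_equal(disjoint$score, 0)
  expect_true(is.na(disjoint$a_start))
  expect_error(smith_waterman("", "ACDE"))
})

test_that("alignment equals the full-DP oracle and is symmetric", {
  expect_equal(smith_waterman("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_sw("HEAGAWGHEE", "PAWHEAE"))
  withr::with_seed(55, {
    for (rep in 1:40) {
      a <- paste(sample(AA, sample(5:30, 1), replace = TRUE), collapse = "")
      b <- paste(sample(AA, sample(5:30, 1), replace = TRUE), collapse = "")
      ab <- smith_waterman(a, b)
      expect_equal(ab$score, oracle_sw(a, b))
      expect_equal(ab$score, smith_waterman(b, a)$score)
    }
  })
})

test_that("similarity search ranks known epitopes by alignment score", {
  antigen <- paste0("KKKK", "ACDEFGHIKL", "MMMM")
  known <- peptide_set(c("ACDEFGHIKL", "ACDEFGAIKL", "WWWWW"),
                       id = c("exact", "near", "far"),
                       label = c("IgG", "IgG", "IgE"))
  hits <- similarity_search(antigen, known, min_score = 1)
  expect_equal(hits$epitope_id[1], "exact")
  expect_equal(hits$score[1], 10 * 2)   # verbatim: length x match
  expect_equal(c(hits$start[1], hits$end[1]), c(5, 14))
  expect_true(all(diff(hits$score) <= 0))
  # rescoring oracle agreement
  for (i in seq_len(nrow(hits))) {
    k <- known[known$id == hits$epitope_id[i], ]
    expect_equal(hits$score[i], oracle_sw(k$seq, antigen))
  }
  empty <- similarity_search(antigen, known, min_score = 1e6)
  expect_equal(nrow(empty), 0L)
  # exact mapping hits are a superset of identity-threshold alignment hits
  exact <- map_exact_epitopes(antigen, known)
  ident <- similarity_search(antigen, known, match = 1, mismatch = -1,
                             min_score = nchar(known$seq[1]))
  expect_true(all(ident$epitope_id %in% exact$epitope_id))
})

test_that("implanted epitopes are recovered at their planted coordinates", {
  imp <- peptide_set(c("ACDEFGHIKLACDEFGHIKL"), id = "imp", label = "IgE")
  ag <- generate_antigen_with_implants(80, list(list(seq = imp$seq,
                                                     offset = 31)),
                                       seed = 56)
  hits <- map_exact_epitopes(ag, imp)
  expect_true(any(hits$start == 31 & hits$end == 50))
  expect_error(generate_antigen_with_implants(
    30, list(list(seq = imp$seq, offset = 20))), "fit")
  expect_error(generate_antigen_with_implants(
    80, list(list(seq = imp$seq, offset = 1),
             list(seq = imp$seq, offset = 10))), "overlap")
})
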