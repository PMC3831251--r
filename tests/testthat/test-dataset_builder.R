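test_that("deduplication keeps first occurrences in order", {
  peps <- peptide_set(c("ACDE", "ACDE", "KLMN"))
  expect_equal(deduplicate(peps)$seq, c("ACDE", "KLMN"))
  distinct <- peptide_set(c("ACDE", "KLMN", "PQRS"))
  expect_equal(deduplicate(distinct), distinct)
  s <- random_peptides(500, lengths = 4:6, seed = 9)
  planted <- peptide_set(c(s, sample(s, 500, replace = TRUE)))
  expect_equal(nrow(deduplicate(planted)), length(unique(planted$seq)))
})

test_that("length filter bounds are inclusive", {
  peps <- peptide_set(c(strrep("A", 3), strrep("C", 4),
                        strrep("D", 50), strrep("E", 51)))
  expect_equal(nchar(filter_length(peps)$seq), c(4, 50))
  expect_equal(nrow(filter_length(peptide_set("ACDE")[0, ])), 0L)
  s <- peptide_set(random_peptides(200, lengths = 2:60, seed = 10))
  expect_equal(nrow(filter_length(s, 10, 20)),
               sum(nchar(s$seq) >= 10 & nchar(s$seq) <= 20))
})

test_that("fix_length pads symmetrically and truncates centrally", {
  expect_equal(fix_length("ACDEFGHI"), "XXXXXXACDEFGHIXXXXXX")
  twenty <- strrep("K", 20)
  expect_equal(fix_length(twenty), twenty)
  # 25-mer: floor((25-20)/2) = 2 leading residues dropped
  s25 <- paste(rep(AA[1:5], 5), collapse = "")
  expect_equal(fix_length(s25), substr(s25, 3, 22))
  # odd deficit: extra pad at the C-terminus
  expect_equal(fix_length("ACD", 6), "XACDXX")
  # idempotent, and at least one non-pad residue always remains
  for (s in random_peptides(30, lengths = 4:50, seed = 11)) {
    f <- fix_length(s)
    expect_equal(fix_length(f), f)
    expect_true(grepl("[^X]", f))
    expect_equal(nchar(f), 20L)
  }
})

test_that("one-vs-rest negatives are the union of the other pools", {
  pools <- list(IgG = peptide_set(random_peptides(50, seed = 1),
                                  label = "IgG"),
                IgE = peptide_set(random_peptides(30, seed = 2),
                                  label = "IgE"),
                IgA = peptide_set(random_peptides(10, seed = 3),
                                  label = "IgA"),
                nonBCE = peptide_set(random_peptides(80, seed = 4),
                                     label = "nonBCE"))
  ds <- build_one_vs_rest(pools, "IgE")
  expect_equal(ds$class_name, "IgE")
  expect_equal(nrow(ds$positives), 30L)
  expect_equal(nrow(ds$negatives), 50 + 10 + 80)
  expect_length(intersect(ds$positives$seq, ds$negatives$seq), 0)
  # a sequence labeled in two classes is purged from the negatives
  pools$IgG$seq[1] <- pools$IgE$seq[1]
  expect_message(ds2 <- build_one_vs_rest(pools, "IgE"), "removed")
  expect_equal(nrow(ds2$negatives), 139L)
  # single epitope class: negatives are exactly the background pool
  ds3 <- build_one_vs_rest(pools[c("IgA", "nonBCE")], "IgA")
  expect_equal(nrow(ds3$negatives), 80L)
  expect_error(build_one_vs_rest(list(IgA = pools$IgA[0, ],
                                      nonBCE = pools$nonBCE), "IgA"),
               "empty")
})

test_that("balancing undersamples negatives reproducibly", {
  pools <- list(IgA = peptide_set(random_peptides(40, seed = 5),
                                  label = "IgA"),
                nonBCE = peptide_set(random_peptides(400, seed = 6),
                                     label = "nonBCE"))
  ds <- build_one_vs_rest(pools, "IgA")
  b1 <- balance(ds, seed = 7)
  expect_equal(nrow(b1$negatives), 40L)
  expect_equal(b1$design, "BalanceVar")
  expect_identical(balance(ds, seed = 7)$negatives, b1$negatives)
  expect_false(identical(balance(ds, seed = 8)$negatives$seq,
                         b1$negatives$seq))
  # pool smaller than positives: positives subsampled, flagged
  small <- build_one_vs_rest(
    list(IgA = pools$IgA, nonBCE = pools$nonBCE[1:10, ]), "IgA")
  bs <- balance(small, seed = 1)
  expect_equal(nrow(bs$positives), 10L)
  expect_true(attr(bs, "pool_limited"))
  # pool exactly equal: untouched
  eq <- build_one_vs_rest(
    list(IgA = pools$IgA, nonBCE = pools$nonBCE[1:40, ]), "IgA")
  expect_identical(balance(eq, seed = 1)$negatives, eq$negatives)
})

test_that("independent split is a stratified partition", {
  pools <- list(IgE = peptide_set(random_peptides(100, seed = 7),
                                  label = "IgE"),
                nonBCE = peptide_set(random_peptides(100, seed = 8),
                                     label = "nonBCE"))
  ds <- build_one_vs_rest(pools, "IgE")
  sp <- split_independent(ds, fraction = 0.2, seed = 3)
  expect_equal(nrow(sp$eval$positives), 20L)
  expect_equal(nrow(sp$eval$negatives), 20L)
  expect_setequal(c(sp$train$positives$seq, sp$eval$positives$seq),
                  ds$positives$seq)
  expect_length(intersect(sp$train$negatives$seq, sp$eval$negatives$seq), 0)
  sp2 <- split_independent(ds, fraction = 0.2, seed = 3)
  expect_identical(sp2$eval$positives, sp$eval$positives)
  expect_error(split_independent(ds, fraction = 0.001, seed = 1), "empty")
})

test_that("design dispatcher composes fixing, dedup and balancing", {
  pools <- list(IgE = peptide_set(random_peptides(60, seed = 12),
                                  label = "IgE"),
                nonBCE = peptide_set(random_peptides(200, seed = 13),
                                     label = "nonBCE"))
  fix <- build_dataset(pools, "IgE", "BalanceFix", seed = 2)
  expect_true(all(nchar(c(fix$positives$seq, fix$negatives$seq)) == 20L))
  expect_equal(nrow(fix$positives), nrow(fix$negatives))
  rv <- build_dataset(pools, "IgE", "RealVar")
  expect_equal(nrow(rv$negatives), 200L)
})
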