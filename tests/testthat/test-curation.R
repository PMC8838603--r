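# ES/HS labeling, diversity down-sampling, splits, unbalanced test.

test_that("labeling thresholds inclusively and drops unreachable entries", {
  tab <- tibble::tibble(key = c("a", "b", "c"), srp = c(1L, 3L, 4L))
  l3 <- label_compounds(tab, 3L)
  expect_equal(l3$label, c("ES", "ES", "HS"))
  l2 <- label_compounds(tab, 2L)
  expect_equal(l2$label, c("ES", "HS", "HS"))
  # boundary: srp == cutoff is ES
  expect_true(all(label_compounds(tibble::tibble(key = "x", srp = 3L), 3L)$label == "ES"))
  # unreachable dropped with a message
  expect_message(
    out <- label_compounds(tibble::tibble(key = c("a", "b"),
                                          srp = c(2L, NA)), 2L),
    "unreachable")
  expect_equal(out$key, "a")
  # pure function of (srp, cutoff): relabeling idempotent, order-free
  shuf <- tab[c(3, 1, 2), ]
  expect_equal(dplyr::arrange(label_compounds(shuf, 3L), key),
               dplyr::arrange(l3, key))
})

test_that("leader clustering collapses redundancy and keeps diversity", {
  # 100 copies of one molecule -> one representative
  dup <- tibble::tibble(key = rep(canonical_smiles("CCOC(C)=O"), 100L))
  expect_warning(reps <- diversity_downsample(dup, 0.615, 10L, seed = 1L),
                 "clusters")
  expect_equal(nrow(reps), 1L)
  # structurally distinct molecules all stay
  distinct <- tibble::tibble(key = canonical_smiles(c(
    "CCO", "c1ccccc1", "CC(=O)O", "CCN", "CCCC", "C1CCCCC1", "CC#N",
    "O=[N+]([O-])C", "CCBr", "CCS")))
  sims <- tanimoto_similarity(ecfp4_fingerprint(distinct$key))
  expect_lt(max(sims[lower.tri(sims)]), 0.35)
  reps2 <- diversity_downsample(distinct, 0.35, 10L, seed = 1L)
  expect_equal(nrow(reps2), 10L)
  # planted homolog families (chain-length variants of five distinct
  # scaffolds): one representative per family
  fams <- list(
    vapply(1:6, function(j) paste0("CCCC", strrep("C", j), "C(C)C(=O)O"), ""),
    vapply(1:6, function(j) paste0("c1ccccc1CC", strrep("C", j), "c1ccccc1"), ""),
    vapply(1:6, function(j)
      paste0("O=[N+]([O-])CCC", strrep("C", j), "C[N+](=O)[O-]"), ""),
    vapply(1:6, function(j) paste0("COCCOCCOCC", strrep("C", j), "OC"), ""),
    vapply(1:6, function(j) paste0("N#CCCC", strrep("C", j), "CC#N"), "")
  )
  comp <- tibble::tibble(key = canonical_smiles(unlist(fams)),
                         fam = rep(seq_along(fams), lengths(fams)))
  comp <- comp[!duplicated(comp$key), ]
  reps3 <- diversity_downsample(comp, 0.4, 5L, seed = 1L)
  expect_equal(nrow(reps3), 5L)
  expect_setequal(reps3$fam, 1:5)
  # target above the available count returns everything with a warning
  expect_warning(all_back <- diversity_downsample(distinct, 0.35, 50L, 1L),
                 "returning all")
  expect_equal(nrow(all_back), 10L)
})

test_that("down-sampling a 10x ES surplus restores a balanced ratio", {
  pool <- generate_model_fixture(400L, "fingerprint-bit", seed = 31L)
  es <- pool[pool$label == "ES", ][1:200, ]
  hs <- pool[pool$label == "HS", ][1:20, ]
  reps <- diversity_downsample(es, 0.615, nrow(hs), seed = 2L)
  ratio <- nrow(reps) / nrow(hs)
  expect_gte(ratio, 0.9); expect_lte(ratio, 1.1)
})

test_that("splits follow 8:1:1 with remainder to test and are stratified", {
  comp <- tibble::tibble(key = sprintf("m%03d", 1:100),
                         smiles = sprintf("m%03d", 1:100),
                         srp = rep(c(1L, 5L), 50L),
                         label = rep(c("ES", "HS"), 50L))
  sp <- split_dataset(comp, seed = 4L)
  expect_equal(as.integer(table(sp$split)[c("train", "validation", "test")]),
               c(80L, 10L, 10L))
  # 101 compounds: remainder goes to test
  comp101 <- dplyr::bind_rows(comp, tibble::tibble(
    key = "m101", smiles = "m101", srp = 1L, label = "ES"))
  sp101 <- split_dataset(comp101, seed = 4L)
  expect_equal(as.integer(table(sp101$split)[c("train", "validation", "test")]),
               c(80L, 10L, 11L))
  # stratification: ES fraction within 1 point of the whole
  overall <- mean(sp$label == "ES")
  for (s in c("train", "validation", "test")) {
    expect_lte(abs(mean(sp$label[sp$split == s] == "ES") - overall), 0.01)
  }
  # determinism and no leakage across 20 seeds
  for (seed in 1:20) {
    a <- split_dataset(comp, seed = seed)
    b <- split_dataset(comp, seed = seed)
    expect_identical(a$split, b$split)
    expect_equal(anyDuplicated(a$key), 0L)
    expect_equal(sum(table(a$key, a$split) > 0L), 100L)
  }
  expect_error(split_dataset(comp[1:9, ], seed = 1L), "at least 10")
})

test_that("unbalanced test adds leftover ES without leaking train data", {
  comp <- tibble::tibble(key = sprintf("m%03d", 1:100),
                         smiles = sprintf("m%03d", 1:100),
                         srp = rep(c(1L, 5L), 50L),
                         label = rep(c("ES", "HS"), 50L))
  sp <- split_dataset(comp, seed = 9L)
  rest <- tibble::tibble(key = sprintf("x%03d", 1:90),
                         smiles = sprintf("x%03d", 1:90),
                         srp = 1L, label = "ES")
  ub <- build_unbalanced_test(sp, rest)
  expect_equal(nrow(ub), sum(sp$split == "test") + 90L)
  expect_true(all(sp$key[sp$split == "test"] %in% ub$key))
  expect_equal(length(intersect(ub$key,
                                sp$key[sp$split != "test"])), 0L)
  # leakage guard
  bad <- rest
  bad$key[1L] <- sp$key[sp$split == "train"][1L]
  expect_error(build_unbalanced_test(sp, bad), "overlap")
  # empty remainder: unbalanced test equals the balanced test
  ub0 <- build_unbalanced_test(sp, rest[0L, ])
  expect_setequal(ub0$key, sp$key[sp$split == "test"])
})
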