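# Template extraction, inverse/forward application, role designation.

sn2_record <- function() {
  parse_reactions("Br[CH2:1][CH3:2].[NH2:3]C>CO>[CH3:2][CH2:1][NH:3]C",
                  id = "sn2")
}

ester_record <- function() {
  parse_reactions(paste0(
    "[CH3:1][C:2](=[O:3])O.[OH:4][CH2:5][CH3:6].OS(=O)(=O)O>>",
    "[CH3:1][C:2](=[O:3])[O:4][CH2:5][CH3:6]"), id = "est")
}

test_that("template centers are the atoms whose bond table changes", {
  t <- extract_reaction_template(sn2_record())
  # oracle: diff the mapped bond tables of the two sides
  expect_setequal(t$center, c(1L, 3L))
  # reactant side carries the C-Br motif and the amine motif
  expect_true("Br" %in% t$rside$elem)
  expect_true("N" %in% t$rside$elem)
  expect_false("Br" %in% t$pside$elem)
})

test_that("no bond change and broken maps raise the documented errors", {
  same <- parse_reactions("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3].O",
                          id = "x")
  expect_error(extract_reaction_template(same), "no_reaction_center")
  dup <- parse_reactions("[CH3:1][CH2:1]O>>[CH3:1][CH2:2]O", id = "y")
  expect_error(extract_reaction_template(dup), "bad_atom_map")
})

test_that("environment radius grows the pattern monotonically", {
  long <- parse_reactions(paste0(
    "Br[CH2:1][CH2:2][CH2:3][CH3:4].[NH2:5][CH2:6][CH3:7]>>",
    "[NH:5]([CH2:6][CH3:7])[CH2:1][CH2:2][CH2:3][CH3:4]"), id = "l")
  t0 <- extract_reaction_template(long, radius = 0L)
  t1 <- extract_reaction_template(long, radius = 1L)
  t2 <- extract_reaction_template(long, radius = 2L)
  expect_lte(t0$rside$n, t1$rside$n)
  expect_lte(t1$rside$n, t2$rside$n)
  expect_lte(t0$pside$n, t1$pside$n)
})

test_that("inverse application yields canonical deduplicated PR sets", {
  t <- extract_reaction_template(ester_record())
  # on the record's own product
  prs <- apply_reaction_template(t, t$product_smiles, "inverse")
  expect_equal(prs, list(sort(canonical_smiles(c("CC(=O)O", "CCO")))))
  # generalizes to methyl acetate -> acetic acid + methanol
  prs2 <- apply_reaction_template(t, "COC(C)=O", "inverse")
  expect_equal(prs2, list(sort(canonical_smiles(c("CC(=O)O", "CO")))))
  # no matching substructure -> empty list
  expect_equal(apply_reaction_template(t, "CCCC", "inverse"), list())
  # symmetric product: both embeddings give the same PR set, collapsed
  sym <- apply_reaction_template(t, "CCOC(=O)C(=O)OCC", "inverse")
  expect_equal(length(sym), 1L)
})

test_that("forward application regenerates the recorded product", {
  rec <- sn2_record()
  t <- extract_reaction_template(rec)
  fw <- apply_reaction_template(t, c("CCBr", "CN"), "forward")
  expect_true(any(vapply(fw, function(s)
    canonical_smiles("CCNC") %in% s, logical(1L))))
})

test_that("role designation consumes exact matches first, leftovers are reagents", {
  rec <- sn2_record()
  roles <- designate_roles(rec)
  expect_equal(roles$status, "ok")
  expect_setequal(roles$true_reactants, canonical_smiles(c("CCBr", "CN")))
  expect_equal(roles$reagents, canonical_smiles("CO"))
  expect_true(all(roles$match_trace$mode == "exact"))
  # conservation: reactants + reagents = ORs
  expect_equal(length(roles$true_reactants) + length(roles$reagents), 3L)
  # ORs equal to PRs exactly -> no reagents
  rec2 <- parse_reactions("Br[CH2:1][CH3:2].[NH2:3]C>>[CH3:2][CH2:1][NH:3]C",
                          id = "bare")
  expect_equal(designate_roles(rec2)$reagents, character())
})

test_that("similarity matching picks the structurally closest OR", {
  # the ester template from a clean record, applied to a record whose OR
  # list lacks the exact acid: the propanoate ester is the similar
  # candidate, Pd the dissimilar one
  t <- extract_reaction_template(ester_record())
  rec <- parse_reactions("CCOC(=O)CC.[Pd].CCO>>CC(=O)OCC", id = "sim")
  roles <- suppressWarnings(designate_roles(rec, t))
  expect_equal(roles$status, "ok")
  tr <- roles$match_trace
  sim_row <- tr[tr$mode == "similarity", ]
  expect_equal(nrow(sim_row), 1L)
  expect_equal(sim_row$matched, canonical_smiles("CCOC(=O)CC"))
  expect_true("[Pd]" %in% roles$reagents)
  # oracle: the chosen OR is the Tanimoto argmax
  ors <- c(canonical_smiles(c("CCOC(=O)CC", "[Pd]")))
  sims <- tanimoto_similarity(ecfp4_fingerprint(sim_row$pr),
                              ecfp4_fingerprint(ors))[1L, ]
  expect_equal(sim_row$matched, ors[which.max(sims)])
})

test_that("designation is deterministic", {
  rec <- ester_record()
  r1 <- designate_roles(rec)
  r2 <- designate_roles(rec)
  expect_identical(r1$true_reactants, r2$true_reactants)
  expect_identical(r1$match_trace, r2$match_trace)
})

test_that("roles on a noisy corpus recover the planted reactant sets", {
  corpus <- noisy_corpus()
  roles <- roles_on(corpus)
  acc <- vapply(seq_len(nrow(roles)), function(i) {
    planted <- corpus$truth$roles[[roles$id[i]]]
    setequal(roles$true_reactant_keys[[i]], planted$reactants) &&
      setequal(roles$reagent_keys[[i]], planted$reagents)
  }, logical(1L))
  expect_gte(mean(acc), 0.99)
})

test_that("forward round-trip holds on every fixture reaction", {
  corpus <- clean_corpus()
  recs <- parse_reactions(corpus$records)
  n <- min(nrow(recs), 15L)
  for (i in seq_len(n)) {
    rec <- recs[i, ]
    t <- extract_reaction_template(rec)
    roles <- designate_roles(rec, t)
    fw <- apply_reaction_template(t, roles$true_reactants, "forward")
    expect_true(any(vapply(fw, function(s)
      rec$product_keys[[1L]][1L] %in% s, logical(1L))), info = rec$id)
  }
})
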