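# Reaction graph construction, node typing, candidate filtering, SRP.

roles_tbl <- function(lines, ids = NULL, sources = NULL) {
  recs <- parse_reactions(lines, id = ids)
  if (!is.null(sources)) recs$source <- sources
  suppressWarnings(designate_reaction_roles(recs))
}

mapped <- function(...) vapply(list(...), identity, character(1L))

test_that("each record fans edges from true reactants to products", {
  recs <- roles_tbl(c(
    "[CH3:1][C:2](=[O:3])O.[NH2:4][CH2:5][CH3:6]>>[CH3:1][C:2](=[O:3])[NH:4][CH2:5][CH3:6]",
    "[CH3:1][C:2](=[O:3])[NH:4][CH2:5][CH3:6].Br[CH2:7][CH3:8]>>[CH3:1][C:2](=[O:3])[N:4]([CH2:7][CH3:8])[CH2:5][CH3:6]"
  ), ids = c("a", "b"))
  g <- build_reaction_graph(recs)
  expect_setequal(igraph::V(g)$name,
                  canonical_smiles(c("CC(=O)O", "CCN", "CC(=O)NCC", "CCBr",
                                     "CC(=O)N(CC)CC")))
  expect_equal(igraph::ecount(g), 4L)
  amide <- canonical_smiles("CC(=O)NCC")
  expect_equal(igraph::degree(g, amide, mode = "in"), c(2L) |> stats::setNames(amide))
  expect_equal(igraph::degree(g, amide, mode = "out"), c(1L) |> stats::setNames(amide))
})

test_that("parallel reactions aggregate distinct sources into the edge weight", {
  # same transformation recorded in two patents with different agents, so
  # deduplication keeps both
  recs <- roles_tbl(c(
    "[CH3:1][C:2](=[O:3])O.[OH:4][CH2:5][CH3:6]>O>[CH3:1][C:2](=[O:3])[O:4][CH2:5][CH3:6]",
    "[CH3:1][C:2](=[O:3])O.[OH:4][CH2:5][CH3:6]>ClCCl>[CH3:1][C:2](=[O:3])[O:4][CH2:5][CH3:6]"
  ), ids = c("p1", "p2"), sources = c("US1", "US2"))
  expect_equal(nrow(deduplicate_reactions(recs)), 2L)
  g <- build_reaction_graph(recs)
  acid <- canonical_smiles("CC(=O)O")
  ester <- canonical_smiles("CCOC(C)=O")
  eid <- igraph::get_edge_ids(g, c(acid, ester))
  expect_equal(igraph::E(g)$weight[eid], 2)
})

test_that("records without roles or with self-loops are skipped with warnings", {
  recs <- roles_tbl("CCO.CCN>>CCOCC")  # unmapped: role designation fails
  expect_equal(recs$role_status, "role_designation_failed")
  expect_warning(g <- build_reaction_graph(recs), "skipped")
  expect_equal(igraph::vcount(g), 0L)
})

test_that("node typing partitions terminal and normal nodes", {
  recs <- roles_tbl(c(
    "[CH3:1][CH2:2]Br.[NH2:3]C>>[CH3:1][CH2:2][NH:3]C",
    "[CH3:4][CH2:5][NH:6]C.Br[CH2:7][CH3:8]>>[CH3:4][CH2:5][N:6](C)[CH2:7][CH3:8]"
  ), ids = c("a", "b"))
  g <- build_reaction_graph(recs)
  ty <- classify_nodes(g, building_blocks = c("CCBr", "NC"))
  expect_equal(unname(sort(ty$type[ty$starting])), rep("terminal", 2L))
  expect_setequal(ty$key[ty$starting], canonical_smiles(c("CCBr", "CN")))
  expect_setequal(ty$key[ty$type == "normal"],
                  canonical_smiles(c("CCNC", "CCN(C)CC")))
  # terminal not in the list stays non-starting
  ty2 <- classify_nodes(g, building_blocks = "CCBr")
  expect_false(canonical_smiles("CN") %in% ty2$key[ty2$starting])
  # partition sizes
  expect_equal(sum(ty$type == "terminal") + sum(ty$type == "normal"),
               sum(ty$in_deg + ty$out_deg >= 1L))
  expect_equal(classify_nodes(igraph::make_empty_graph(), "CCO"),
               classify_nodes(igraph::make_empty_graph()))
})

test_that("candidate filtering is inclusive on property bounds", {
  keys <- canonical_smiles(c("c1ccccc1", "O=C(O)CCCCCCCCCC(=O)O"))
  ty <- tibble::tibble(key = keys, in_deg = 1L, out_deg = 0L,
                       type = "normal", starting = FALSE)
  d <- physchem_descriptors(keys)
  # benzene (MW 78) fails the default 200-500 window
  expect_false(keys[1L] %in% filter_candidates(ty))
  expect_true(d$mw[2L] >= 200 && d$mw[2L] <= 500)
  expect_true(keys[2L] %in% filter_candidates(ty))
  # boundary inclusivity: a bound equal to the computed property keeps it
  expect_true(keys[1L] %in%
                filter_candidates(ty, mw_range = c(d$mw[1L], 500),
                                  logp_range = c(0, d$logp[1L])))
})

test_that("SRP of a chain equals its length and unreachable is NA", {
  g <- igraph::graph_from_literal("S" -+ "A", "A" -+ "B", "B" -+ "C",
                                  "X" -+ "Y")
  ty <- tibble::tibble(key = igraph::V(g)$name,
                       in_deg = as.integer(igraph::degree(g, mode = "in")),
                       out_deg = as.integer(igraph::degree(g, mode = "out")),
                       type = ifelse(igraph::degree(g, mode = "in") == 0,
                                     "terminal", "normal"),
                       starting = igraph::V(g)$name == "S")
  srp <- compute_srp(g, ty)
  expect_equal(srp$srp[srp$key == "C"], 3L)
  expect_equal(srp$srp[srp$key == "A"], 1L)
  expect_true(is.na(srp$srp[srp$key == "Y"]))
})

test_that("a many-path product takes the minimum path length", {
  # 19 alternative routes of lengths 3..5 into the product; minimum 3
  edges <- c()
  mk <- function(...) edges <<- c(edges, ...)
  for (i in 1:19) {
    len <- 3L + (i %% 3L)
    prev <- sprintf("S%02d", i)
    for (st in seq_len(len - 1L)) {
      nxt <- sprintf("I%02d_%d", i, st)
      mk(prev, nxt); prev <- nxt
    }
    mk(prev, "P")
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE))
  starts <- grepl("^S", igraph::V(g)$name)
  ty <- tibble::tibble(key = igraph::V(g)$name,
                       in_deg = as.integer(igraph::degree(g, mode = "in")),
                       out_deg = as.integer(igraph::degree(g, mode = "out")),
                       type = ifelse(starts, "terminal", "normal"),
                       starting = starts)
  srp <- compute_srp(g, ty, targets = "P")
  expect_equal(srp$srp, 3L)
})

test_that("multi-source BFS agrees with brute-force path enumeration", {
  for (seed in 1:6) {
    fx <- generate_fixture_dag(n_nodes = 60L + 20L * seed, seed = seed)
    srp <- compute_srp(fx$graph, fx$typing)
    oracle <- brute_force_srp(fx$graph, fx$typing)
    got <- ifelse(is.na(srp$srp), Inf, srp$srp)
    expect_equal(unname(got), unname(oracle[srp$key]), info = seed)
  }
})

test_that("SRP satisfies the edge triangle inequality", {
  fx <- generate_fixture_dag(n_nodes = 150L, seed = 99L)
  srp <- compute_srp(fx$graph, fx$typing, targets = fx$typing$key)
  d <- stats::setNames(ifelse(is.na(srp$srp), Inf, srp$srp), srp$key)
  d[fx$typing$key[fx$typing$starting]] <- 0
  el <- igraph::as_edgelist(fx$graph)
  for (k in seq_len(nrow(el))) {
    expect_lte(d[el[k, 2L]], d[el[k, 1L]] + 1)
  }
})

test_that("removing a non-starting terminal node never shortens an SRP", {
  fx <- generate_fixture_dag(n_nodes = 120L, seed = 17L)
  srp0 <- compute_srp(fx$graph, fx$typing)
  victim <- fx$typing$key[fx$typing$type == "terminal" & !fx$typing$starting][1L]
  expect_false(is.na(victim))  # seed chosen so such a node exists
  g2 <- igraph::delete_vertices(fx$graph, victim)
  ty2 <- fx$typing[fx$typing$key != victim, ]
  srp1 <- compute_srp(g2, ty2, targets = srp0$key[srp0$key != victim])
  j <- dplyr::inner_join(srp0, srp1, by = "key")
  worse <- ifelse(is.na(j$srp.y), Inf, j$srp.y) >=
    ifelse(is.na(j$srp.x), Inf, j$srp.x)
  expect_true(all(worse))
})

test_that("GraphML round trip preserves nodes, edges and attributes", {
  corpus <- clean_corpus()
  roles <- roles_on(corpus)
  g <- build_reaction_graph(roles)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, path)
  g2 <- import_graphml(path)
  expect_setequal(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::ecount(g), igraph::ecount(g2))
  el1 <- apply(igraph::as_edgelist(g), 1L, paste, collapse = ">")
  el2 <- apply(igraph::as_edgelist(g2), 1L, paste, collapse = ">")
  expect_equal(sort(el1), sort(el2))
  expect_setequal(igraph::E(g2)$reaction_id, igraph::E(g)$reaction_id)
  # empty graph round trips too
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(igraph::make_empty_graph(directed = TRUE), p2)
  expect_equal(igraph::vcount(import_graphml(p2)), 0L)
})
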