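# Synthetic reaction corpora with known ground truth.
#
# The generator builds a layered synthesis network from a closed library of
# building blocks and four reliable coupling motifs (esterification, amide
# coupling, Williamson etherification, N-alkylation). Products are made by
# actual bond rewiring on the internal molecular graphs, so atom maps,
# true reactant/reagent roles and planted shortest reaction paths are exact
# by construction. Reagent injection reproduces the classic corpus flaw of
# solvents, metals and ions misplaced into the reactant field.

.FIXTURE_BLOCKS <- list(
  acid = c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O", "CCCCC(=O)O",
           "OC(=O)c1ccccc1", "OCC(=O)O", "OC(=O)CCC(=O)O"),
  amine = c("CCN", "CCCN", "CC(C)N", "CCCCN", "NCCN", "Nc1ccccc1", "NCC(C)C"),
  alcohol = c("CCO", "CCCO", "CC(C)O", "CCCCO", "OCCO", "OCc1ccccc1",
              "CC(C)CO"),
  halide = c("CCBr", "CCCBr", "CC(C)Br", "CCCCBr", "BrCc1ccccc1", "CCCCCBr")
)

# bifunctional anchors guarantee that every layer keeps reactive products
.FIXTURE_ANCHORS <- c("NCCO", "BrCCC(=O)O")

.FIXTURE_REAGENTS <- c("[Na+]", "[K+]", "[I-]", "[Cl-]", "[Pd]", "O",
                       "ClCCl", "CS(=O)C", "C1CCOC1", "Cl", "OS(=O)(=O)O",
                       "CCOCC")

.resample <- function(x) x[sample.int(length(x))]

# ---- functional-site detection on the internal graph ----------------------

.site_carboxyl <- function(mol) {
  adj <- mol_adjacency(mol)
  for (i in which(mol$elem == "C" & !mol$arom)) {
    nb <- adj[[i]]
    if (is.null(nb)) next
    od <- nb[mol$elem[nb[, 1L]] == "O" & nb[, 2L] == 2, 1L]
    oh <- nb[mol$elem[nb[, 1L]] == "O" & nb[, 2L] == 1, 1L]
    oh <- oh[mol$hyd[oh] >= 1L]
    if (length(od) && length(oh)) return(list(c = i, oh = oh[1L]))
  }
  NULL
}

.site_hydroxyl <- function(mol) {
  adj <- mol_adjacency(mol)
  carb <- .site_carboxyl(mol)
  for (i in which(mol$elem == "O" & !mol$arom & mol$hyd >= 1L &
                    mol$charge == 0L)) {
    if (!is.null(carb) && i == carb$oh) next
    nb <- adj[[i]]
    if (is.null(nb) || nrow(nb) != 1L) next
    if (mol$elem[nb[1L, 1L]] == "C" && nb[1L, 2L] == 1) return(list(o = i))
  }
  NULL
}

.site_amine <- function(mol) {
  adj <- mol_adjacency(mol)
  for (i in which(mol$elem == "N" & !mol$arom & mol$hyd >= 2L &
                    mol$charge == 0L)) {
    nb <- adj[[i]]
    if (is.null(nb) || nrow(nb) != 1L || any(nb[, 2L] != 1)) next
    return(list(n = i))
  }
  NULL
}

.site_halide <- function(mol) {
  adj <- mol_adjacency(mol)
  for (i in which(mol$elem == "Br")) {
    nb <- adj[[i]]
    if (is.null(nb) || nrow(nb) != 1L) next
    cc <- nb[1L, 1L]
    if (mol$elem[cc] == "C" && !mol$arom[cc]) return(list(br = i, c = cc))
  }
  NULL
}

.mol_sites <- function(mol) {
  list(acid = .site_carboxyl(mol), oh = .site_hydroxyl(mol),
       nh2 = .site_amine(mol), br = .site_halide(mol))
}

# Couple molecule a with molecule b under a motif. Returns the product and
# for each input atom its product index (NA for leaving atoms).
.couple <- function(ma, mb, motif) {
  sa <- .mol_sites(ma); sb <- .mol_sites(mb)
  u <- mol_union(list(ma, mb))
  off <- attr(u, "offsets")[2L]
  drop <- integer(); bond <- NULL
  if (motif == "ester") {
    if (is.null(sa$acid) || is.null(sb$oh)) return(NULL)
    drop <- sa$acid$oh
    bond <- c(sa$acid$c, sb$oh$o + off)
    u$hyd[sb$oh$o + off] <- 0L
  } else if (motif == "amide") {
    if (is.null(sa$acid) || is.null(sb$nh2)) return(NULL)
    drop <- sa$acid$oh
    bond <- c(sa$acid$c, sb$nh2$n + off)
    u$hyd[sb$nh2$n + off] <- u$hyd[sb$nh2$n + off] - 1L
  } else if (motif == "ether") {
    if (is.null(sa$br) || is.null(sb$oh)) return(NULL)
    drop <- sa$br$br
    bond <- c(sa$br$c, sb$oh$o + off)
    u$hyd[sb$oh$o + off] <- 0L
  } else if (motif == "amine") {
    if (is.null(sa$br) || is.null(sb$nh2)) return(NULL)
    drop <- sa$br$br
    bond <- c(sa$br$c, sb$nh2$n + off)
    u$hyd[sb$nh2$n + off] <- u$hyd[sb$nh2$n + off] - 1L
  } else stop("unknown motif ", motif)
  u <- mol_add_bond(u, bond[1L], bond[2L], 1)
  keep <- setdiff(seq_len(u$n), drop)
  prod <- mol_subgraph(u, keep)
  to_prod <- match(seq_len(u$n), keep)
  list(product = prod,
       map_a = to_prod[seq_len(ma$n)],
       map_b = to_prod[ma$n + seq_len(mb$n)])
}

# Emit an atom-mapped reaction SMILES for a coupling (leaving atoms stay
# unmapped on the reactant side, as in real mapped corpora).
.coupled_rsmi <- function(ma, mb, cp) {
  prod <- cp$product
  prod$map <- seq_len(prod$n)
  ma$map <- ifelse(is.na(cp$map_a), 0L, cp$map_a)
  mb$map <- ifelse(is.na(cp$map_b), 0L, cp$map_b)
  list(
    reactants = c(mol_to_smiles(ma), mol_to_smiles(mb)),
    product = mol_to_smiles(prod)
  )
}

.motifs_for <- function(sx, sy) {
  out <- character()
  if (!is.null(sx$acid) && !is.null(sy$oh)) out <- c(out, "ester")
  if (!is.null(sx$acid) && !is.null(sy$nh2)) out <- c(out, "amide")
  if (!is.null(sx$br) && !is.null(sy$oh)) out <- c(out, "ether")
  if (!is.null(sx$br) && !is.null(sy$nh2)) out <- c(out, "amine")
  out
}

#' Specification of a synthetic reaction corpus
#'
#' @param n_building_blocks Number of purchasable layer-0 substances
#'   (minimum 6; two bifunctional anchors are always included).
#' @param depth Maximum planted shortest reaction path.
#' @param branching Products attempted per substance and layer.
#' @param reagent_injection_rate Fraction of records whose reactant field
#'   receives misplaced reagents (solvents, metals, ions).
#' @param duplicate_rate Fraction of extra exact-duplicate records appended.
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   corpora.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_building_blocks = 10L, depth = 3L, branching = 2L,
                         reagent_injection_rate = 0, duplicate_rate = 0,
                         seed = 1L) {
  stopifnot(depth >= 1L, n_building_blocks >= 6L,
            reagent_injection_rate >= 0, reagent_injection_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  if (branching < 1L && depth > 1L) {
    stop("branching 0 cannot reach depth > 1")
  }
  structure(list(n_building_blocks = n_building_blocks, depth = depth,
                 branching = branching,
                 reagent_injection_rate = reagent_injection_rate,
                 duplicate_rate = duplicate_rate, seed = seed),
            class = "fixture_spec")
}

#' Generate a layered reaction corpus with known ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `srp_corpus`: `records` (tibble `id`, `source`,
#'   `rsmi` in the format [parse_reactions()] consumes), and `truth` with
#'   `building_blocks` (canonical keys), `srp` (tibble `key`, `srp`),
#'   `roles` (named list per record id: `reactants`, `reagents` key sets).
#' @export
generate_reaction_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    pool <- unlist(.FIXTURE_BLOCKS, use.names = FALSE)
    n_extra <- spec$n_building_blocks - length(.FIXTURE_ANCHORS)
    # round-robin over the categories so every role is represented
    picks <- character()
    cats <- rep(names(.FIXTURE_BLOCKS), length.out = n_extra)
    for (cat in names(.FIXTURE_BLOCKS)) {
      k <- sum(cats == cat)
      picks <- c(picks, sample(.FIXTURE_BLOCKS[[cat]],
                               min(k, length(.FIXTURE_BLOCKS[[cat]]))))
    }
    blocks <- unique(c(.FIXTURE_ANCHORS, picks))[seq_len(
      min(spec$n_building_blocks, length(.FIXTURE_ANCHORS) + length(picks)))]
    block_keys <- canonical_smiles(blocks)

    mols <- lapply(blocks, parse_smiles)
    keys <- block_keys
    layer <- rep(0L, length(blocks))
    exact <- lapply(0:spec$depth, function(i) integer())
    exact[[1L]] <- seq_along(blocks)

    rec_react <- list(); rec_prod <- character(); rec_truth <- list()
    mk_record <- function(ia, ib, motif) {
      cp <- .couple(mols[[ia]], mols[[ib]], motif)
      if (is.null(cp)) return(NULL)
      key <- canonical_smiles(mol_to_smiles(cp$product, keep_map = FALSE))
      if (is.na(key) || key %in% keys) return(NULL)
      rs <- .coupled_rsmi(mols[[ia]], mols[[ib]], cp)
      list(cp = cp, key = key, rs = rs, ia = ia, ib = ib)
    }

    for (d in seq_len(spec$depth)) {
      placed <- integer()
      # spine: couple two exact-(d-1) substances so a planted-SRP-d product
      # certainly exists
      spine_done <- 0L
      # only multi-functional substances can sustain arbitrarily deep chains
      nsites <- vapply(exact[[d]], function(i) {
        sum(!vapply(.mol_sites(mols[[i]]), is.null, logical(1L)))
      }, integer(1L))
      prev <- exact[[d]][nsites >= 2L]
      if (!length(prev)) prev <- exact[[d]]
      for (ia in .resample(prev)) {
        if (spine_done >= 2L) break
        for (ib in .resample(prev)) {
          ms <- c(.motifs_for(.mol_sites(mols[[ia]]), .mol_sites(mols[[ib]])))
          ok <- FALSE
          for (motif in .resample(ms)) {
            r <- mk_record(ia, ib, motif)
            if (is.null(r)) next
            mols[[length(mols) + 1L]] <- r$cp$product
            keys <- c(keys, r$key)
            layer <- c(layer, d)
            exact[[d + 1L]] <- c(exact[[d + 1L]], length(mols))
            rec_react[[length(rec_react) + 1L]] <- list(
              smiles = r$rs$reactants, keys = keys[c(ia, ib)])
            rec_prod <- c(rec_prod, r$rs$product)
            placed <- c(placed, length(mols))
            spine_done <- spine_done + 1L
            ok <- TRUE
            break
          }
          if (ok) break
        }
      }
      # branching: each previous-layer substance attempts `branching`
      # couplings with any shallower partner
      prev_all <- which(layer == d - 1L)
      shallower <- which(layer <= d - 1L)
      for (ia in prev_all) {
        made <- 0L
        tries <- 0L
        while (made < spec$branching && tries < 8L * spec$branching) {
          tries <- tries + 1L
          ib <- .resample(shallower)[1L]
          sa <- .mol_sites(mols[[ia]]); sb <- .mol_sites(mols[[ib]])
          cands <- rbind(
            if (length(m <- .motifs_for(sa, sb)))
              cbind(ia, ib, m) else NULL,
            if (length(m <- .motifs_for(sb, sa)))
              cbind(ib, ia, m) else NULL
          )
          if (is.null(cands) || !nrow(cands)) next
          pick <- cands[sample(nrow(cands), 1L), ]
          r <- mk_record(as.integer(pick[1L]), as.integer(pick[2L]), pick[3L])
          if (is.null(r)) next
          mols[[length(mols) + 1L]] <- r$cp$product
          keys <- c(keys, r$key)
          layer <- c(layer, d)
          rec_react[[length(rec_react) + 1L]] <- list(
            smiles = r$rs$reactants,
            keys = keys[c(as.integer(pick[1L]), as.integer(pick[2L]))])
          rec_prod <- c(rec_prod, r$rs$product)
          made <- made + 1L
        }
      }
    }

    n_rec <- length(rec_prod)
    sources <- sprintf("US%05d", sample.int(max(3L, n_rec %/% 3L), n_rec,
                                            replace = TRUE))
    ids <- sprintf("rxn%04d", seq_len(n_rec))
    lines <- character(n_rec)
    roles <- vector("list", n_rec)
    names(roles) <- ids
    for (i in seq_len(n_rec)) {
      comp <- rec_react[[i]]$smiles
      reag <- character()
      if (stats::runif(1L) < spec$reagent_injection_rate) {
        reag <- sample(.FIXTURE_REAGENTS, sample(1:2, 1L))
      }
      allc <- sample(c(comp, reag))  # reagents mixed into the reactant field
      lines[i] <- paste0(paste(allc, collapse = "."), ">>", rec_prod[i])
      roles[[i]] <- list(
        reactants = sort(unique(rec_react[[i]]$keys)),
        reagents = sort(unique(canonical_smiles(reag)))
      )
    }
    # exact duplicates (re-emitted records, shuffled component order)
    n_dup <- round(spec$duplicate_rate * n_rec)
    if (n_dup > 0L) {
      dup_of <- sample.int(n_rec, n_dup, replace = TRUE)
      for (j in seq_along(dup_of)) {
        i <- dup_of[j]
        parts <- strsplit(lines[i], ">>", fixed = TRUE)[[1L]]
        comps <- sample(strsplit(parts[1L], ".", fixed = TRUE)[[1L]])
        did <- sprintf("rxn%04d_dup%02d", i, j)
        lines <- c(lines, paste0(paste(comps, collapse = "."), ">>", parts[2L]))
        ids <- c(ids, did)
        sources <- c(sources, sources[i])
        roles[[did]] <- roles[[i]]
      }
    }

    # planted SRP: fixpoint relaxation over the true reactant sets
    srp <- stats::setNames(rep(NA_integer_, length(keys)), keys)
    srp[block_keys] <- 0L
    repeat {
      changed <- FALSE
      for (i in seq_len(n_rec)) {
        pk <- keys[length(block_keys) + i]
        rs <- srp[rec_react[[i]]$keys]
        if (all(!is.na(rs))) {
          cand <- 1L + min(rs)
          if (is.na(srp[pk]) || cand < srp[pk]) { srp[pk] <- cand; changed <- TRUE }
        }
      }
      if (!changed) break
    }

    structure(list(
      records = tibble::tibble(id = ids, source = sources, rsmi = lines),
      truth = list(
        building_blocks = block_keys,
        srp = tibble::tibble(key = keys, srp = unname(srp),
                             is_block = keys %in% block_keys),
        roles = roles
      ),
      spec = spec
    ), class = "srp_corpus")
  })
}

#' @export
print.srp_corpus <- function(x, ...) {
  cat("<srp_corpus> ", nrow(x$records), " records, ",
      length(x$truth$building_blocks), " building blocks, max planted SRP ",
      max(x$truth$srp$srp, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' Run the full pipeline on a corpus and compare with its ground truth
#'
#' Executes parsing, deduplication, validity filtering, role designation,
#' graph construction, node typing and SRP computation, then reports the
#' agreement with the planted truth.
#'
#' @param corpus An `srp_corpus` from [generate_reaction_corpus()].
#' @return A list: `n_records`, `n_deduplicated`, `n_kept`, `n_rejected`,
#'   `rejected_reasons`, `role_accuracy` (fraction of records whose
#'   recovered true-reactant key set equals the planted set),
#'   `srp_agreement` (fraction of products whose computed SRP equals the
#'   planted SRP), `typing_agreement` (Jaccard of recovered vs planted
#'   starting materials).
#' @export
verify_pipeline_against_truth <- function(corpus) {
  records <- parse_reactions(corpus$records)
  dd <- deduplicate_reactions(records)
  fl <- filter_reactions(dd)
  roles <- designate_reaction_roles(fl$kept)

  acc <- vapply(seq_len(nrow(roles)), function(i) {
    planted <- corpus$truth$roles[[roles$id[i]]]
    if (is.null(planted)) return(NA)
    setequal(roles$true_reactant_keys[[i]], planted$reactants) &&
      setequal(roles$reagent_keys[[i]], planted$reagents)
  }, logical(1L))

  g <- build_reaction_graph(roles)
  ty <- classify_nodes(g, corpus$truth$building_blocks)
  srp <- compute_srp(g, ty)
  truth_srp <- corpus$truth$srp[!corpus$truth$srp$is_block, , drop = FALSE]
  cmp <- dplyr::inner_join(srp, truth_srp, by = "key",
                           suffix = c("_got", "_true"))
  recovered <- ty$key[ty$starting]
  planted_sm <- intersect(corpus$truth$building_blocks, ty$key)
  list(
    n_records = nrow(records),
    n_deduplicated = nrow(dd),
    n_kept = nrow(fl$kept),
    n_rejected = nrow(fl$rejected),
    rejected_reasons = table(fl$rejected$reason),
    role_accuracy = mean(acc, na.rm = TRUE),
    srp_agreement = mean(!is.na(cmp$srp_got) & cmp$srp_got == cmp$srp_true),
    typing_agreement = length(intersect(recovered, planted_sm)) /
      max(1L, length(union(recovered, planted_sm)))
  )
}

# ---- molecule sampler and planted-signal model fixtures -------------------

.SUBSTITUENTS <- c("O", "N", "Cl", "C", "CC", "C(=O)O", "OC", "C#N")

.sample_molecule <- function(n_carbons, n_subs, nitro = FALSE) {
  toks <- rep("C", n_carbons)
  pos <- if (n_carbons > 2L) sample(2:(n_carbons - 1L), min(n_subs, n_carbons - 2L))
         else integer()
  for (p in pos) {
    toks[p] <- paste0("C(", sample(.SUBSTITUENTS, 1L), ")")
  }
  if (nitro) {
    toks[1L] <- "C([N+](=O)[O-])"
  }
  paste(toks, collapse = "")
}

#' Generate a labeled molecule set with a planted classification signal
#'
#' Three signal types: `"descriptor-threshold"` labels by molecular weight
#' with a clear gap (ES below 300, HS above 400 g/mol);
#' `"fingerprint-bit"` and `"substructure"` label by the presence of a
#' nitro group (which drives a reproducible set of ECFP4 bits). Classes
#' are balanced.
#'
#' @param n Total number of molecules (at least 40).
#' @param signal One of `"descriptor-threshold"`, `"fingerprint-bit"`,
#'   `"substructure"`.
#' @param seed Integer seed.
#' @return Tibble `smiles`, `key`, `label` (`"ES"`/`"HS"`), `signal`.
#' @export
generate_model_fixture <- function(n, signal = c("descriptor-threshold",
                                                 "fingerprint-bit",
                                                 "substructure"),
                                   seed = 1L) {
  signal <- match.arg(signal)
  if (n < 40L) stop("model fixtures need n >= 40")
  .with_seed(seed, {
    half <- n %/% 2L
    gen_class <- function(k, size, nitro) {
      out <- character()
      guard <- 0L
      while (length(out) < k && guard < 60L) {
        guard <- guard + 1L
        batch_n <- max(50L, 2L * (k - length(out)))
        big <- switch(size, small = rep(FALSE, batch_n),
                      large = rep(TRUE, batch_n),
                      mixed = stats::runif(batch_n) < 0.5)
        smi <- vapply(seq_len(batch_n), function(i) {
          if (big[i]) .sample_molecule(sample(28:38, 1L), sample(3:6, 1L), nitro)
          else .sample_molecule(sample(4:10, 1L), sample(0:2, 1L), nitro)
        }, character(1L))
        key <- canonical_smiles(smi)
        ok <- !is.na(key) & !duplicated(key) & !(key %in% out)
        key <- key[ok]; big <- big[ok]
        if (signal == "descriptor-threshold" && length(key)) {
          mw <- physchem_descriptors(key)$mw
          key <- key[!is.na(mw) & ifelse(big, mw > 400, mw < 300)]
        }
        need <- min(k - length(out), length(key))
        out <- c(out, key[seq_len(need)])
      }
      if (length(out) < k) stop("could not build a balanced fixture")
      out
    }
    if (signal == "descriptor-threshold") {
      es <- gen_class(half, size = "small", nitro = FALSE)
      hs <- gen_class(n - half, size = "large", nitro = FALSE)
    } else {
      # nitro carriers are the positive (ES) class; sizes mixed on both
      # sides so the substructure is the only reliable signal
      es <- gen_class(half, size = "mixed", nitro = TRUE)
      hs <- gen_class(n - half, size = "mixed", nitro = FALSE)
    }
    tibble::tibble(
      smiles = c(es, hs), key = c(es, hs),
      label = rep(c("ES", "HS"), c(length(es), length(hs))),
      signal = signal
    )
  })
}

#' Generate a random layered DAG fixture for shortest-path testing
#'
#' Vertices are arranged in layers with edges only from earlier to later
#' layers, a random subset of sources is marked as starting material, and
#' the graph is returned with a typing table, ready for [compute_srp()].
#'
#' @param n_nodes Number of vertices (at most 500 by convention).
#' @param edge_factor Average out-edges attempted per vertex.
#' @param seed Integer seed.
#' @return List `graph` (igraph), `typing` (tibble as from
#'   [classify_nodes()]).
#' @export
generate_fixture_dag <- function(n_nodes = 100L, edge_factor = 1.8,
                                 seed = 1L) {
  .with_seed(seed, {
    n_layers <- max(3L, round(sqrt(n_nodes)))
    layer <- sort(sample.int(n_layers, n_nodes, replace = TRUE))
    name <- sprintf("M%03d", seq_len(n_nodes))
    from <- integer(); to <- integer()
    for (v in which(layer > 1L)) {
      k <- stats::rpois(1L, edge_factor)
      cand <- which(layer < layer[v])
      if (!length(cand) || k == 0L) next
      src <- sample(cand, min(k, length(cand)))
      from <- c(from, src); to <- c(to, rep(v, length(src)))
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = name[from], to = name[to]),
      directed = TRUE,
      vertices = data.frame(name = name)
    )
    ind <- igraph::degree(g, mode = "in")
    outd <- igraph::degree(g, mode = "out")
    type <- ifelse(ind == 0L & outd >= 1L, "terminal",
                   ifelse(ind >= 1L, "normal", "isolated"))
    term <- which(type == "terminal")
    starting <- logical(n_nodes)
    if (length(term)) {
      starting[.resample(term)[seq_len(max(1L, round(0.7 * length(term))))]] <- TRUE
    }
    list(graph = g,
         typing = tibble::tibble(key = igraph::V(g)$name,
                                 in_deg = as.integer(ind),
                                 out_deg = as.integer(outd),
                                 type = type, starting = starting))
  })
}
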