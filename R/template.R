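# Reaction templates: radius-r subgraph rewrite patterns around the reaction
# center of an atom-mapped reaction, applied forward (reactants -> product)
# or inverse (product -> predicted reactants).
#
# The reaction center is the set of mapped atoms whose bonding environment,
# hydrogen count or formal charge changes between the reactant and product
# side. The pattern keeps the center, every atom within `radius` bonds of it,
# atoms multiply-bonded to anything already included (so carbonyls and nitro
# groups stay intact), and unmapped fragments hanging off included atoms
# (leaving groups). Unmapped atoms present on both sides are paired up by
# anchored breadth-first search and given shared negative pseudo-maps so the
# rewrite treats them as context rather than deleting and recreating them.

.side_env <- function(mol) {
  adj <- mol_adjacency(mol)
  lapply(seq_len(mol$n), function(i) {
    nb <- adj[[i]]
    mapped <- character(); unmapped <- character()
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1L]; o <- nb[r, 2L]
        if (mol$map[w] > 0L) {
          mapped <- c(mapped, paste0(mol$map[w], ":", o))
        } else {
          unmapped <- c(unmapped, paste0(mol$elem[w], ":", o))
        }
      }
    }
    list(mapped = sort(mapped), unmapped = sort(unmapped))
  })
}

.expand_pattern_atoms <- function(mol, seeds, radius) {
  adj <- mol_adjacency(mol)
  incl <- logical(mol$n)
  frontier <- seeds
  incl[seeds] <- TRUE
  for (d in seq_len(radius)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- adj[[v]]
      if (!is.null(nb)) for (w in nb[, 1L]) if (!incl[w]) {
        incl[w] <- TRUE; nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  repeat {
    grew <- FALSE
    for (v in which(incl)) {
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1L]; o <- nb[r, 2L]
        if (incl[w]) next
        # multiple bonds complete the functional group; unmapped neighbours
        # of unmapped included atoms complete leaving-group fragments
        if (o >= 2 || (mol$map[v] == 0L && mol$map[w] == 0L)) {
          incl[w] <- TRUE; grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  which(incl)
}

# Pair unmapped pattern atoms across sides via shared mapped anchors, then
# grow the pairing outward. Paired atoms receive the same negative pseudo-map.
.pair_unmapped <- function(rpat, ppat) {
  radj <- mol_adjacency(rpat); padj <- mol_adjacency(ppat)
  sig <- function(mol, i, o) paste(mol$elem[i], mol$arom[i], mol$charge[i], o)
  next_pm <- 0L
  queue <- list()
  for (m in intersect(rpat$map[rpat$map > 0L], ppat$map[ppat$map > 0L])) {
    queue[[length(queue) + 1L]] <- c(which(rpat$map == m), which(ppat$map == m))
  }
  qi <- 1L
  while (qi <= length(queue)) {
    ra <- queue[[qi]][1L]; pa <- queue[[qi]][2L]; qi <- qi + 1L
    rnb <- radj[[ra]]; pnb <- padj[[pa]]
    if (is.null(rnb) || is.null(pnb)) next
    rcand <- which(rpat$map[rnb[, 1L]] == 0L)
    pcand <- which(ppat$map[pnb[, 1L]] == 0L)
    for (ri in rcand) {
      if (!length(pcand)) break
      rv <- rnb[ri, 1L]
      if (rpat$map[rv] != 0L) next  # may have been paired meanwhile
      s <- sig(rpat, rv, rnb[ri, 2L])
      hit <- NA_integer_
      for (k in seq_along(pcand)) {
        pv <- pnb[pcand[k], 1L]
        if (ppat$map[pv] != 0L) next
        if (identical(sig(ppat, pv, pnb[pcand[k], 2L]), s)) { hit <- k; break }
      }
      if (!is.na(hit)) {
        pv <- pnb[pcand[hit], 1L]
        next_pm <- next_pm - 1L
        rpat$map[rv] <- next_pm; ppat$map[pv] <- next_pm
        pcand <- pcand[-hit]
        queue[[length(queue) + 1L]] <- c(rv, pv)
      }
    }
  }
  list(rpat = rpat, ppat = ppat)
}

#' Extract a reaction template
#'
#' Derives the forward (reactant side to product side) and inverse rewrite
#' patterns of an atom-mapped reaction record at the given environment
#' radius. All reactant-side species, agents included, form the reactant
#' side; the product side is the largest product by heavy-atom count.
#'
#' @param record A one-row reaction record tibble (see [parse_reactions()]).
#' @param radius Number of bonds around the reaction center to keep
#'   (default 1).
#' @return An object of class `srp_template`.
#' @export
extract_reaction_template <- function(record, radius = 1L) {
  stopifnot(nrow(record) == 1L, radius >= 0L)
  rsp <- c(record$reactants[[1L]], record$agents[[1L]])
  rmols <- lapply(rsp, parse_smiles)
  rside <- mol_union(rmols)
  pmols <- lapply(record$products[[1L]], parse_smiles)
  psize <- vapply(pmols, function(m) m$n, integer(1L))
  pside <- pmols[[which.max(psize)]]

  for (side in list(rside, pside)) {
    mm <- side$map[side$map > 0L]
    if (anyDuplicated(mm)) {
      stop("bad_atom_map: duplicated atom-map number in record ", record$id)
    }
  }
  shared <- intersect(rside$map[rside$map > 0L], pside$map[pside$map > 0L])
  if (!length(shared)) stop("bad_atom_map: no shared maps in record ", record$id)

  renv <- .side_env(rside); penv <- .side_env(pside)
  center <- shared[vapply(shared, function(m) {
    ri <- which(rside$map == m); pi <- which(pside$map == m)
    !identical(renv[[ri]]$mapped, penv[[pi]]$mapped) ||
      !identical(renv[[ri]]$unmapped, penv[[pi]]$unmapped) ||
      rside$hyd[ri] != pside$hyd[pi] ||
      rside$charge[ri] != pside$charge[pi]
  }, logical(1L))]
  if (!length(center)) stop("no_reaction_center: record ", record$id)

  # maps present on one side only behave like unmapped context
  rside$map[rside$map > 0L & !(rside$map %in% shared)] <- 0L
  pside$map[pside$map > 0L & !(pside$map %in% shared)] <- 0L

  ratoms <- .expand_pattern_atoms(rside, which(rside$map %in% center), radius)
  patoms <- .expand_pattern_atoms(pside, which(pside$map %in% center), radius)
  rpat <- mol_subgraph(rside, ratoms)
  ppat <- mol_subgraph(pside, patoms)
  paired <- .pair_unmapped(rpat, ppat)
  rpat <- paired$rpat; ppat <- paired$ppat

  structure(list(
    rside = rpat, pside = ppat, center = center, radius = as.integer(radius),
    record_id = record$id,
    product_smiles = record$products[[1L]][which.max(psize)]
  ), class = "srp_template")
}

#' @export
print.srp_template <- function(x, ...) {
  cat("<srp_template> radius ", x$radius, ", center maps {",
      paste(x$center, collapse = ","), "}\n  forward: ",
      format_template(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a template as a reaction-SMARTS-like string
#'
#' Pseudo-maps used internally for paired unmapped atoms are shifted into
#' the 900+ range so the string stays valid SMILES.
#'
#' @param template An `srp_template`.
#' @param direction `"forward"` (reactants>>product) or `"inverse"`.
#' @return A single string.
#' @export
format_template <- function(template, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  shift <- function(m) { m$map[m$map < 0L] <- 900L - m$map[m$map < 0L]; m }
  r <- mol_to_smiles(shift(template$rside))
  p <- mol_to_smiles(shift(template$pside))
  if (direction == "forward") paste0(r, ">>", p) else paste0(p, ">>", r)
}

# All disjoint embeddings of the (possibly multi-component) pattern into tgt.
.match_pattern <- function(pat, tgt, center_maps, cap = 32L) {
  comps <- mol_components(pat)
  tadj <- mol_adjacency(tgt)
  tdeg <- vapply(tadj, function(a) if (is.null(a)) 0L else nrow(a), integer(1L))
  padj <- mol_adjacency(pat)
  pdeg <- vapply(padj, function(a) if (is.null(a)) 0L else nrow(a), integer(1L))

  results <- list()
  rec <- function(ci, used, acc) {
    if (length(results) >= cap) return(invisible())
    if (ci > length(comps)) {
      results[[length(results) + 1L]] <<- acc
      return(invisible())
    }
    comp <- comps[[ci]]
    sub <- mol_subgraph(pat, comp)
    atom_ok <- function(pi, ti) {
      gi <- comp[pi]
      if (pat$elem[gi] != tgt$elem[ti]) return(FALSE)
      if (pat$arom[gi] != tgt$arom[ti]) return(FALSE)
      if (pat$charge[gi] != tgt$charge[ti]) return(FALSE)
      if (pat$map[gi] %in% center_maps) {
        if (pat$hyd[gi] != tgt$hyd[ti]) return(FALSE)
        if (pdeg[gi] != tdeg[ti]) return(FALSE)
      }
      TRUE
    }
    ms <- mol_match_component(sub, tgt, atom_ok, used = used, max_matches = cap)
    for (m in ms) {
      acc2 <- acc; acc2[comp] <- m
      used2 <- used; used2[m] <- TRUE
      rec(ci + 1L, used2, acc2)
      if (length(results) >= cap) return(invisible())
    }
  }
  rec(1L, logical(tgt$n), integer(pat$n))
  results
}

.bond_index <- function(mol) {
  if (!nrow(mol$bond)) return(character())
  apply(mol$bond[, 1:2, drop = FALSE], 1L, function(e) paste(sort(e), collapse = "|"))
}

# Rewrite one embedding: delete from-side bonds, rewrite matched atoms to
# the to-side state, instantiate to-side-only atoms, drop from-side-only ones.
.rewrite <- function(from_pat, to_pat, tgt, img, center_maps = integer()) {
  res <- tgt
  if (nrow(from_pat$bond)) {
    del <- apply(from_pat$bond[, 1:2, drop = FALSE], 1L, function(e) {
      paste(sort(img[e]), collapse = "|")
    })
    res$bond <- res$bond[!(.bond_index(res) %in% del), , drop = FALSE]
  }
  fmap <- from_pat$map
  new_idx <- integer(to_pat$n)
  for (j in seq_len(to_pat$n)) {
    m <- to_pat$map[j]
    k <- if (m != 0L) which(fmap == m) else integer()
    if (length(k) == 1L) {
      a <- img[k]
      new_idx[j] <- a
      if (m %in% center_maps) {
        # only reaction-center atoms change state; environment atoms keep
        # whatever the target molecule has
        res$hyd[a] <- to_pat$hyd[j]
        res$charge[a] <- to_pat$charge[j]
        res$arom[a] <- to_pat$arom[j]
        res$chir[a] <- to_pat$chir[j]
      }
    } else {
      res <- mol_add_atom(res, to_pat$elem[j], to_pat$arom[j], to_pat$charge[j],
                          to_pat$hyd[j], 0L, to_pat$chir[j])
      new_idx[j] <- res$n
    }
  }
  if (nrow(to_pat$bond)) {
    have <- .bond_index(res)
    for (r in seq_len(nrow(to_pat$bond))) {
      a <- new_idx[to_pat$bond[r, 1L]]; b <- new_idx[to_pat$bond[r, 2L]]
      key <- paste(sort(c(a, b)), collapse = "|")
      hit <- which(have == key)
      if (length(hit)) {
        res$bond[hit[1L], 3L] <- to_pat$bond[r, 3L]
      } else {
        res <- mol_add_bond(res, a, b, to_pat$bond[r, 3L])
        have <- c(have, key)
      }
    }
  }
  drop <- img[fmap == 0L | !(fmap %in% to_pat$map)]
  if (length(drop)) res <- mol_subgraph(res, setdiff(seq_len(res$n), drop))
  res
}

#' Apply a reaction template
#'
#' In the `"inverse"` direction the product-side pattern is embedded into a
#' product molecule and rewritten back to the reactant side, yielding
#' predicted-reactant (PR) sets; `"forward"` embeds the reactant-side
#' pattern into the supplied molecules and yields product sets. Every
#' distinct disjoint embedding gives one candidate set; sets are
#' canonicalized and deduplicated, and an empty list means the template
#' does not apply.
#'
#' @param template An `srp_template`.
#' @param smiles Character vector of molecule SMILES (one product for the
#'   inverse direction; one or more reactants for the forward direction).
#' @param direction `"inverse"` (default) or `"forward"`.
#' @param max_sets Cap on returned alternative sets.
#' @return A list of character vectors; each vector is one canonicalized,
#'   deduplicated precursor (or product) set.
#' @export
apply_reaction_template <- function(template, smiles,
                                    direction = c("inverse", "forward"),
                                    max_sets = 16L) {
  direction <- match.arg(direction)
  tgt <- mol_union(lapply(smiles, parse_smiles))
  from_pat <- if (direction == "inverse") template$pside else template$rside
  to_pat <- if (direction == "inverse") template$rside else template$pside
  embeds <- tryCatch(
    .match_pattern(from_pat, tgt, template$center, cap = 4L * max_sets),
    error = function(e) list()
  )
  out <- list()
  seen <- character()
  for (img in embeds) {
    mols <- tryCatch({
      res <- .rewrite(from_pat, to_pat, tgt, img, template$center)
      comps <- mol_components(res)
      vapply(comps, function(a) mol_to_smiles(mol_subgraph(res, a), keep_map = FALSE),
             character(1L))
    }, error = function(e) NULL)
    if (is.null(mols)) next
    can <- canonical_smiles(mols)
    if (anyNA(can)) next
    # multiplicity is kept: A + A -> P needs two precursor copies
    set <- sort(can)
    sig <- paste(set, collapse = ".")
    if (!(sig %in% seen)) {
      seen <- c(seen, sig)
      out[[length(out) + 1L]] <- set
    }
    if (length(out) >= max_sets) break
  }
  out
}
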