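# Internal atom-mapped molecular graph.
#
# Substance identity and descriptors are delegated to OpenBabel (see chem.R);
# this layer exists because template extraction needs per-atom map numbers and
# editable bond tables, which no installed toolkit exposes to R. It supports
# the SMILES subset used by reaction corpora: organic-subset atoms, aromatic
# lowercase atoms, bracket atoms with isotope/chirality/H-count/charge/map,
# bonds - = # : / \, branches, ring closures (incl. %nn), but not wildcard or
# recursive SMARTS.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

new_mol <- function(elem = character(), arom = logical(), charge = integer(),
                    hyd = integer(), map = integer(), chir = character(),
                    bond = matrix(numeric(), ncol = 3L)) {
  colnames(bond) <- c("a1", "a2", "order")
  structure(
    list(n = length(elem), elem = elem, arom = arom, charge = charge,
         hyd = hyd, map = map, chir = chir, bond = bond),
    class = "srp_mol"
  )
}

#' @export
print.srp_mol <- function(x, ...) {
  cat("<srp_mol> ", x$n, " atoms, ", nrow(x$bond), " bonds: ",
      mol_to_smiles(x), "\n", sep = "")
  invisible(x)
}

mol_add_atom <- function(mol, elem, arom = FALSE, charge = 0L, hyd = NA_integer_,
                         map = 0L, chir = "") {
  mol$n <- mol$n + 1L
  mol$elem <- c(mol$elem, elem)
  mol$arom <- c(mol$arom, arom)
  mol$charge <- c(mol$charge, charge)
  mol$hyd <- c(mol$hyd, hyd)
  mol$map <- c(mol$map, map)
  mol$chir <- c(mol$chir, chir)
  mol
}

mol_add_bond <- function(mol, a1, a2, order) {
  mol$bond <- rbind(mol$bond, c(a1, a2, order))
  mol
}

# Sum of bond orders per atom (aromatic bonds count 1.5).
mol_bond_sum <- function(mol) {
  bs <- numeric(mol$n)
  if (nrow(mol$bond)) {
    for (k in seq_len(nrow(mol$bond))) {
      bs[mol$bond[k, 1L]] <- bs[mol$bond[k, 1L]] + mol$bond[k, 3L]
      bs[mol$bond[k, 2L]] <- bs[mol$bond[k, 2L]] + mol$bond[k, 3L]
    }
  }
  bs
}

# Implicit hydrogen count an organic-subset atom receives from its valence.
.implicit_h <- function(elem, bsum) {
  vs <- .DEFAULT_VALENCE[[elem]]
  if (is.null(vs)) return(0L)
  need <- as.integer(ceiling(bsum - 0.5))
  v <- vs[vs >= need]
  if (!length(v)) return(0L)
  max(0L, as.integer(v[1L] - round(bsum)))
}

# Fill NA hydrogen counts (organic-subset atoms written without brackets).
mol_resolve_h <- function(mol) {
  todo <- which(is.na(mol$hyd))
  if (length(todo)) {
    bs <- mol_bond_sum(mol)
    for (i in todo) mol$hyd[i] <- .implicit_h(mol$elem[i], bs[i])
  }
  mol
}

parse_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  mol <- new_mol()
  prev <- 0L            # index of previous atom on the current chain
  stack <- integer()    # branch stack
  pend <- NA_real_      # pending explicit bond order
  rings <- list()       # ring-closure digit -> c(atom, order)
  i <- 1L
  n <- length(chars)

  add_atom_link <- function(elem, arom, charge, hyd, map, chir) {
    mol <<- mol_add_atom(mol, elem, arom, charge, hyd, map, chir)
    a <- mol$n
    if (prev > 0L) {
      o <- pend
      if (is.na(o)) o <- if (mol$arom[prev] && arom) 1.5 else 1
      mol <<- mol_add_bond(mol, prev, a, o)
    }
    pend <<- NA_real_
    prev <<- a
  }

  close_ring <- function(d) {
    if (!is.null(rings[[d]])) {
      r <- rings[[d]]
      o <- pend
      if (is.na(o)) o <- r[2L]
      if (is.na(o)) o <- if (mol$arom[r[1L]] && mol$arom[prev]) 1.5 else 1
      mol <<- mol_add_bond(mol, r[1L], prev, o)
      rings[[d]] <<- NULL
      pend <<- NA_real_
    } else {
      rings[[d]] <<- c(prev, pend)
      pend <<- NA_real_
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pend <- 1; i <- i + 1L
    } else if (ch == "=") {
      pend <- 2; i <- i + 1L
    } else if (ch == "#") {
      pend <- 3; i <- i + 1L
    } else if (ch == ":") {
      pend <- 1.5; i <- i + 1L
    } else if (ch == ".") {
      stop("dot-disconnected SMILES passed to parse_smiles: ", smiles)
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in ", smiles)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in ", smiles)
      spec <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(spec, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?((?:\\+{1,3}|-{1,3})|(?:[+-][0-9]+))?(?::([0-9]+))?$",
        spec))[[1L]]
      if (!length(m)) stop("cannot parse bracket atom [", spec, "] in ", smiles)
      sym <- m[3L]
      arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      elem <- if (arom) paste0(toupper(substr(sym, 1L, 1L)),
                               substring(sym, 2L)) else sym
      chir <- m[4L]
      hyd <- if (m[5L] == "") 0L else if (m[6L] == "") 1L else as.integer(m[6L])
      charge <- 0L
      if (m[7L] != "") {
        cs <- m[7L]
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- nchar(cs) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
        }
      }
      map <- if (is.na(m[8L]) || m[8L] == "") 0L else as.integer(m[8L])
      add_atom_link(elem, arom, charge, hyd, map, chir)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ch
      if (two %in% c("Cl", "Br")) {
        add_atom_link(two, FALSE, 0L, NA_integer_, 0L, ""); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom_link(ch, FALSE, 0L, NA_integer_, 0L, ""); i <- i + 1L
      } else {
        stop("atom '", ch, "' outside brackets in ", smiles)
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom_link(toupper(ch), TRUE, 0L, NA_integer_, 0L, ""); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", smiles)
  open <- !vapply(rings, is.null, logical(1L))
  if (length(rings) && any(open)) stop("unclosed ring bond in SMILES: ", smiles)
  mol_resolve_h(mol)
}

mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  if (nrow(mol$bond)) {
    for (k in seq_len(nrow(mol$bond))) {
      a <- mol$bond[k, 1L]; b <- mol$bond[k, 2L]; o <- mol$bond[k, 3L]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  adj
}

mol_components <- function(mol) {
  if (mol$n == 0L) return(list())
  adj <- mol_adjacency(mol)
  seen <- logical(mol$n)
  comps <- list()
  for (s in seq_len(mol$n)) {
    if (seen[s]) next
    q <- s; seen[s] <- TRUE; comp <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      nb <- adj[[v]]
      if (!is.null(nb)) for (w in nb[, 1L]) if (!seen[w]) {
        seen[w] <- TRUE; q <- c(q, w); comp <- c(comp, w)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Extract the sub-molecule induced by `atoms` (indices kept in given order).
mol_subgraph <- function(mol, atoms) {
  idx <- match(seq_len(mol$n), atoms)
  b <- mol$bond
  if (nrow(b)) {
    sel <- !is.na(idx[b[, 1L]]) & !is.na(idx[b[, 2L]])
    b <- b[sel, , drop = FALSE]
    b[, 1L] <- idx[b[, 1L]]
    b[, 2L] <- idx[b[, 2L]]
  }
  new_mol(mol$elem[atoms], mol$arom[atoms], mol$charge[atoms],
          mol$hyd[atoms], mol$map[atoms], mol$chir[atoms], b)
}

# Merge molecules into one disconnected graph; returns offsets invisibly.
mol_union <- function(mols) {
  out <- new_mol()
  offsets <- integer(length(mols))
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    offsets[i] <- out$n
    b <- m$bond
    if (nrow(b)) {
      b[, 1L] <- b[, 1L] + out$n
      b[, 2L] <- b[, 2L] + out$n
    }
    out$elem <- c(out$elem, m$elem); out$arom <- c(out$arom, m$arom)
    out$charge <- c(out$charge, m$charge); out$hyd <- c(out$hyd, m$hyd)
    out$map <- c(out$map, m$map); out$chir <- c(out$chir, m$chir)
    out$bond <- rbind(out$bond, b)
    out$n <- out$n + m$n
  }
  attr(out, "offsets") <- offsets
  out
}

# SMILES writer. Brackets are emitted only where the reader needs them to
# recover hydrogen count, charge, chirality or (optionally) atom maps.
mol_to_smiles <- function(mol, keep_map = TRUE) {
  if (mol$n == 0L) return("")
  adj <- mol_adjacency(mol)
  bs <- mol_bond_sum(mol)

  atom_token <- function(i) {
    elem <- mol$elem[i]
    sym <- if (mol$arom[i]) tolower(elem) else elem
    needs <- !(elem %in% .ORGANIC_SUBSET) ||
      mol$charge[i] != 0L ||
      (keep_map && mol$map[i] > 0L) ||
      mol$chir[i] != "" ||
      mol$hyd[i] != .implicit_h(elem, bs[i])
    if (!needs) return(sym)
    h <- mol$hyd[i]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- mol$charge[i]
    ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
            else sprintf("%+d", ch)
    mtok <- if (keep_map && mol$map[i] > 0L) paste0(":", mol$map[i]) else ""
    paste0("[", sym, mol$chir[i], htok, ctok, mtok, "]")
  }

  bond_token <- function(a, b, o) {
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) return(if (mol$arom[a] && mol$arom[b]) "" else ":")
    if (mol$arom[a] && mol$arom[b]) "-" else ""
  }

  # Pass 1: DFS spanning forest; back edges become ring closures with a
  # label recorded at both endpoints (bond symbol emitted at the closing end).
  visited <- logical(mol$n)
  tree_children <- vector("list", mol$n)
  ring_labels <- vector("list", mol$n)
  n_labels <- 0L
  back_seen <- character()

  dfs1 <- function(v, parent) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in order(nb[, 1L])) {
      w <- nb[r, 1L]; o <- nb[r, 2L]
      if (w == parent) next
      key <- paste(sort(c(v, w)), collapse = "|")
      if (visited[w]) {
        if (!(key %in% back_seen)) {
          back_seen <<- c(back_seen, key)
          n_labels <<- n_labels + 1L
          lab <- if (n_labels < 10L) as.character(n_labels) else paste0("%", n_labels)
          ring_labels[[w]] <<- c(ring_labels[[w]], list(list(lab = lab, o = o, peer = v, close = FALSE)))
          ring_labels[[v]] <<- c(ring_labels[[v]], list(list(lab = lab, o = o, peer = w, close = TRUE)))
        }
      } else {
        tree_children[[v]] <<- rbind(tree_children[[v]], c(w, o))
        dfs1(w, v)
      }
    }
  }

  dfs2 <- function(v) {
    s <- atom_token(v)
    for (rl in ring_labels[[v]]) {
      s <- paste0(s, if (rl$close) bond_token(v, rl$peer, rl$o) else "", rl$lab)
    }
    ch <- tree_children[[v]]
    if (!is.null(ch)) {
      for (ci in seq_len(nrow(ch))) {
        w <- ch[ci, 1L]; o <- ch[ci, 2L]
        sub <- paste0(bond_token(v, w, o), dfs2(w))
        if (ci < nrow(ch)) sub <- paste0("(", sub, ")")
        s <- paste0(s, sub)
      }
    }
    s
  }

  out <- character()
  for (comp in mol_components(mol)) {
    dfs1(comp[1L], 0L)
    out <- c(out, dfs2(comp[1L]))
  }
  paste(out, collapse = ".")
}

# ---------------------------------------------------------------------------
# Subgraph matching (connected pattern onto target), backtracking.

# atom_ok(pi, ti): may the pattern atom pi sit on target atom ti?
mol_match_component <- function(pat, tgt, atom_ok,
                                used = logical(tgt$n), max_matches = 64L) {
  if (pat$n == 0L) return(list())
  padj <- mol_adjacency(pat)
  tadj <- mol_adjacency(tgt)

  # visit order: BFS so every atom after the first has a matched neighbour
  ord <- integer(0); seen <- logical(pat$n); q <- 1L; seen[1L] <- TRUE
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]; ord <- c(ord, v)
    nb <- padj[[v]]
    if (!is.null(nb)) for (w in nb[, 1L]) if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
  }
  if (length(ord) < pat$n) stop("pattern component not connected")

  matches <- list()
  img <- integer(pat$n)

  consistent <- function(v, t) {
    nb <- padj[[v]]
    if (is.null(nb)) return(TRUE)
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1L]
      if (img[w] == 0L) next
      o <- nb[r, 2L]
      tn <- tadj[[t]]
      hit <- FALSE
      if (!is.null(tn)) {
        for (rr in seq_len(nrow(tn))) {
          if (tn[rr, 1L] == img[w] && tn[rr, 2L] == o) { hit <- TRUE; break }
        }
      }
      if (!hit) return(FALSE)
    }
    TRUE
  }

  recurse <- function(k) {
    if (length(matches) >= max_matches) return()
    if (k > pat$n) {
      matches[[length(matches) + 1L]] <<- img
      return()
    }
    v <- ord[k]
    cand <- if (k == 1L) seq_len(tgt$n) else {
      # neighbours of any already-matched pattern neighbour
      nb <- padj[[v]]
      anchors <- nb[img[nb[, 1L]] != 0L, , drop = FALSE]
      a <- anchors[1L, ]
      tn <- tadj[[img[a[1L]]]]
      if (is.null(tn)) integer() else tn[tn[, 2L] == a[2L], 1L]
    }
    for (t in cand) {
      if (used[t] || t %in% img) next
      if (!atom_ok(v, t)) next
      if (!consistent(v, t)) next
      img[v] <<- t
      recurse(k + 1L)
      img[v] <<- 0L
      if (length(matches) >= max_matches) return()
    }
  }
  recurse(1L)
  matches
}

# Ring atoms: endpoints of edges that lie on a cycle (non-bridge edges).
mol_ring_atoms <- function(mol) {
  if (nrow(mol$bond) == 0L) return(logical(mol$n))
  g <- igraph::graph_from_edgelist(mol$bond[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < mol$n) g <- igraph::add_vertices(g, mol$n - igraph::vcount(g))
  br <- igraph::bridges(g)
  ring <- logical(mol$n)
  es <- igraph::as_edgelist(g)
  nonbridge <- setdiff(seq_len(nrow(es)), as.integer(br))
  if (length(nonbridge)) {
    ring[as.integer(es[nonbridge, ])] <- TRUE
  }
  ring
}

.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29,
  Zn = 30, Br = 35, Pd = 46, I = 53
)

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Br = 79.904, Pd = 106.42, I = 126.904
)
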