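# Molecular featurization for the three classifier families: ECFP4 bits,
# the six physicochemical descriptors, and a per-atom/per-bond molecular
# graph representation for the message-passing network.

.ATOM_FEATURE_DIM <- 133L
.BOND_FEATURE_DIM <- 5L

.hybridization <- function(mol) {
  adj <- mol_adjacency(mol)
  vapply(seq_len(mol$n), function(i) {
    nb <- adj[[i]]
    if (is.null(nb)) return("sp3")
    orders <- nb[, 2L]
    if (any(orders == 3) || sum(orders == 2) >= 2L) return("sp")
    if (mol$arom[i] || any(orders == 2) || any(orders == 1.5)) return("sp2")
    "sp3"
  }, character(1L))
}

# 133-dim atom features: atomic number one-hot (100) + degree one-hot (6)
# + formal charge one-hot (-2..2, 5) + H-count one-hot (0..4, 5)
# + hybridization one-hot (sp/sp2/sp3/other/unknown, 5) + chiral tag one-hot
# (none/@/@@/other, 4) + aromatic (1) + ring membership (1) + mass/100 (1)
# + zero padding (5) = 133.
.atom_features <- function(mol) {
  n <- mol$n
  out <- matrix(0, n, .ATOM_FEATURE_DIM)
  adj <- mol_adjacency(mol)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1L))
  ring <- mol_ring_atoms(mol)
  hyb <- .hybridization(mol)
  for (i in seq_len(n)) {
    z <- .ATOMIC_NUMBER[[mol$elem[i]]]
    if (!is.null(z) && z >= 1 && z <= 100) out[i, z] <- 1
    out[i, 100L + min(deg[i], 5L) + 1L] <- 1
    ch <- max(-2L, min(2L, mol$charge[i]))
    out[i, 106L + ch + 3L] <- 1
    out[i, 111L + min(mol$hyd[i], 4L) + 1L] <- 1
    hslot <- match(hyb[i], c("sp", "sp2", "sp3", "other"), nomatch = 5L)
    out[i, 116L + hslot] <- 1
    cslot <- match(mol$chir[i], c("", "@", "@@"), nomatch = 4L)
    out[i, 121L + cslot] <- 1
    out[i, 126L] <- as.numeric(mol$arom[i])
    out[i, 127L] <- as.numeric(ring[i])
    m <- .ATOMIC_MASS[[mol$elem[i]]]
    out[i, 128L] <- if (is.null(m)) 0 else m / 100
  }
  out
}

# bond features: order one-hot (single/double/triple/aromatic) + ring flag
.bond_features <- function(mol) {
  nb <- nrow(mol$bond)
  out <- matrix(0, nb, .BOND_FEATURE_DIM)
  if (!nb) return(out)
  ring <- mol_ring_atoms(mol)
  for (k in seq_len(nb)) {
    o <- mol$bond[k, 3L]
    slot <- if (o == 1) 1L else if (o == 2) 2L else if (o == 3) 3L else 4L
    out[k, slot] <- 1
    out[k, 5L] <- as.numeric(ring[mol$bond[k, 1L]] && ring[mol$bond[k, 2L]])
  }
  out
}

#' Featurize molecules
#'
#' Computes, for each SMILES, the three representations used by the
#' synthetic-accessibility models: the folded 2048-bit ECFP4 fingerprint,
#' the six physicochemical descriptors (MW, TPSA, RTB, HBD, HBA, LogP), and
#' a molecular graph with 133-dimensional atom feature vectors plus a bond
#' list with bond features.
#'
#' @param smiles Character vector of valid SMILES.
#' @return A list of `srp_features` bundles (one per molecule), each with
#'   elements `smiles`, `ecfp`, `physchem`, `molgraph` (list `atom`:
#'   n_atoms x 133 matrix, `bond`: bond matrix `a1,a2,order`,
#'   `bond_features`: n_bonds x 5 matrix).
#' @export
#' @examples
#' f <- featurize("c1ccccc1")[[1]]
#' dim(f$molgraph$atom)
featurize <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("cannot featurize invalid SMILES: ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "))
  }
  fp <- ecfp4_fingerprint(smiles)
  pc <- physchem_descriptors(smiles)
  lapply(seq_along(smiles), function(i) {
    mol <- parse_smiles(smiles[i])
    structure(list(
      smiles = smiles[i],
      ecfp = fp[i, ],
      physchem = c(mw = pc$mw[i], tpsa = pc$tpsa[i], rtb = pc$rtb[i],
                   hbd = pc$hbd[i], hba = pc$hba[i], logp = pc$logp[i]),
      molgraph = list(
        atom = .atom_features(mol),
        bond = mol$bond,
        bond_features = .bond_features(mol)
      )
    ), class = "srp_features")
  })
}

#' @export
print.srp_features <- function(x, ...) {
  cat("<srp_features> ", x$smiles, ": ", nrow(x$molgraph$atom), " atoms, ",
      sum(x$ecfp), " ECFP bits on\n", sep = "")
  invisible(x)
}
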