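# OpenBabel-backed chemistry services: canonical SMILES (substance identity),
# physicochemical descriptors, ECFP4 fingerprints, Tanimoto similarity.
# Everything is vectorized over SMILES and memoised, because the pipeline
# re-canonicalizes the same substances constantly.

.chem_cache <- new.env(parent = emptyenv())
.chem_cache$canon <- new.env(parent = emptyenv())
.chem_cache$fp <- new.env(parent = emptyenv())
.chem_cache$desc <- new.env(parent = emptyenv())

.has_obabel <- function() nzchar(Sys.which("obabel"))

# batch canonicalization through one obabel process; invalid entries are
# skipped by -e and recognized by their missing title
.ob_can_cli <- function(smiles) {
  inp <- tempfile(fileext = ".smi"); outf <- tempfile(fileext = ".can")
  on.exit(unlink(c(inp, outf)), add = TRUE)
  writeLines(paste0(smiles, " t", seq_along(smiles)), inp)
  system2("obabel", c("-ismi", inp, "-ocan", "-e"), stdout = outf,
          stderr = FALSE)
  out <- rep(NA_character_, length(smiles))
  for (ln in readLines(outf, warn = FALSE)) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next
    i <- as.integer(sub("^t", "", parts[2L]))
    if (!is.na(i) && nzchar(parts[1L])) out[i] <- parts[1L]
  }
  out
}

# OpenBabel in-process conversion stops at the first invalid entry; convert
# the valid prefix, mark the offender NA, recurse on the rest. (Fallback
# when the obabel binary is unavailable.)
.ob_can_block <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  lo <- 1L
  while (lo <= length(smiles)) {
    idx <- lo:length(smiles)
    block <- paste0(smiles[idx], " t", idx, collapse = "\n")
    res <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(block, "\n")),
      error = function(e) ""
    ))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    k <- 0L
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) next
      i <- as.integer(sub("^t", "", parts[2L]))
      if (!is.na(i) && nzchar(parts[1L])) {
        out[i] <- parts[1L]
        k <- max(k, i - lo + 1L)
      }
    }
    # everything up to lo+k-1 processed; lo+k is the invalid line (skip it)
    lo <- lo + k + 1L
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical isomeric SMILES for each input, or `NA`
#' for unparseable strings. Atom-map numbers are stripped, so the result is
#' a stable substance identity: stereochemistry is kept, mapping is not.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where invalid).
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO", "not-a-molecule"))
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  keys <- smiles[ok]
  cached <- vapply(keys, function(s) {
    v <- .chem_cache$canon[[s]]
    if (is.null(v)) NA_character_ else v
  }, character(1L), USE.NAMES = FALSE)
  todo <- unique(keys[is.na(cached)])
  if (length(todo)) {
    fresh <- if (.has_obabel()) .ob_can_cli(todo) else .ob_can_block(todo)
    for (i in seq_along(todo)) {
      .chem_cache$canon[[todo[i]]] <-
        if (is.na(fresh[i])) "invalid" else fresh[i]
    }
  }
  res <- vapply(keys, function(s) .chem_cache$canon[[s]], character(1L),
                USE.NAMES = FALSE)
  res[res == "invalid"] <- NA_character_
  out[ok] <- res
  out
}

#' Test whether SMILES strings are parseable
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
smiles_is_valid <- function(smiles) !is.na(canonical_smiles(smiles))

#' Substance identity key
#'
#' The key of a substance is its canonical isomeric SMILES with atom maps
#' stripped; two substances are the same node of the reaction network iff
#' their keys are equal.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of keys (`NA` where invalid).
#' @export
substance_key <- function(smiles) canonical_smiles(smiles)

.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

# one obabel process for the whole batch: orders of magnitude faster than
# per-molecule property calls
.desc_obabel_batch <- function(keys) {
  inp <- tempfile(fileext = ".smi"); out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(paste0(keys, " t", seq_along(keys)), inp)
  system2("obabel", c("-ismi", inp, "-otxt", "--append",
                      shQuote("MW TPSA rotors HBD HBA1 logP")),
          stdout = out, stderr = FALSE)
  lines <- readLines(out, warn = FALSE)
  vals <- rep(list(c(mw = NA_real_, tpsa = NA_real_, rtb = NA_real_,
                     hbd = NA_real_, hba = NA_real_, logp = NA_real_)),
              length(keys))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) != 7L) next
    i <- as.integer(sub("^t", "", parts[1L]))
    if (is.na(i)) next
    v <- as.numeric(parts[2:7])
    vals[[i]] <- c(mw = v[1L], tpsa = v[2L], rtb = v[3L], hbd = v[4L],
                   hba = v[5L], logp = v[6L])
  }
  vals
}

.desc_chemmine <- function(keys) {
  block <- paste0(keys, " t", seq_along(keys), "\n", collapse = "")
  ChemmineOB::forEachMol("SMILES", block, function(m) {
    p <- ChemmineOB::prop_OB(m)
    rtb <- ChemmineOB::smartsSearch_OB(list(m), .ROTATABLE_SMARTS)[[1L]]
    c(mw = p$MW, tpsa = p$TPSA, rtb = as.numeric(rtb),
      hbd = p$HBD, hba = p$HBA1, logp = p$logP)
  })
}

#' Physicochemical descriptors
#'
#' Computes the six descriptors used by the property-based synthetic
#' accessibility models: molecular weight (MW, g/mol), topological polar
#' surface area (TPSA, A^2), number of rotatable bonds (RTB), H-bond donors
#' (HBD), H-bond acceptors (HBA, N+O count) and Crippen-type calculated LogP.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles`, `mw`, `tpsa`, `rtb`, `hbd`,
#'   `hba`, `logp`; one row per input, `NA` rows for invalid SMILES.
#' @export
#' @examples
#' physchem_descriptors(c("c1ccccc1", "CC(=O)O"))
physchem_descriptors <- function(smiles) {
  can <- canonical_smiles(smiles)
  uniq <- unique(can[!is.na(can)])
  todo <- uniq[!vapply(uniq, function(s) !is.null(.chem_cache$desc[[s]]),
                       logical(1L), USE.NAMES = FALSE)]
  if (length(todo)) {
    vals <- if (nzchar(Sys.which("obabel"))) .desc_obabel_batch(todo)
            else .desc_chemmine(todo)
    for (i in seq_along(todo)) .chem_cache$desc[[todo[i]]] <- vals[[i]]
  }
  rows <- lapply(can, function(s) {
    if (is.na(s)) return(c(mw = NA_real_, tpsa = NA_real_, rtb = NA_real_,
                           hbd = NA_real_, hba = NA_real_, logp = NA_real_))
    .chem_cache$desc[[s]]
  })
  m <- do.call(rbind, rows)
  tibble::tibble(smiles = smiles, mw = unname(m[, "mw"]),
                 tpsa = unname(m[, "tpsa"]), rtb = unname(m[, "rtb"]),
                 hbd = unname(m[, "hbd"]), hba = unname(m[, "hba"]),
                 logp = unname(m[, "logp"]))
}

# nibble -> 4 bits lookup for FPS hex decoding
.HEX_BITS <- {
  m <- matrix(0L, 16L, 4L)
  for (v in 0:15) m[v + 1L, ] <- as.integer(intToBits(v))[1:4]
  m
}

# batch ECFP4 through one obabel process (FPS text format: one hex line per
# molecule). The bit layout is deterministic, which is all Tanimoto and the
# classifiers need.
.fp_obabel_batch <- function(keys) {
  inp <- tempfile(fileext = ".smi"); outf <- tempfile(fileext = ".fps")
  on.exit(unlink(c(inp, outf)), add = TRUE)
  writeLines(paste0(keys, " t", seq_along(keys)), inp)
  system2("obabel", c("-ismi", inp, "-ofps", "-e", "-xfECFP4"),
          stdout = outf, stderr = FALSE)
  vals <- vector("list", length(keys))
  for (ln in readLines(outf, warn = FALSE)) {
    if (startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next
    i <- as.integer(sub("^t", "", parts[2L]))
    if (is.na(i)) next
    nib <- strtoi(strsplit(parts[1L], "")[[1L]], 16L)
    vals[[i]] <- as.numeric(t(.HEX_BITS[nib + 1L, , drop = FALSE]))
  }
  bad <- vapply(vals, is.null, logical(1L))
  if (any(bad)) {
    stop("fingerprint computation failed for: ",
         paste(utils::head(keys[bad], 3L), collapse = ", "))
  }
  vals
}

.fp_chemmine <- function(keys) {
  block <- paste0(keys, " t", seq_along(keys), "\n", collapse = "")
  ChemmineOB::forEachMol("SMILES", block, function(m) {
    as.numeric(ChemmineOB::fingerprint_OB(list(m), "ECFP4"))
  })
}

#' ECFP4 fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2), folded to a
#' fixed-length bit vector. Used for reactant/reagent similarity matching,
#' leader clustering and the fingerprint-based neural classifier.
#'
#' @param smiles Character vector of valid SMILES strings.
#' @param nbits Folded length (default 2048).
#' @return A 0/1 integer matrix with one row per input SMILES.
#' @export
ecfp4_fingerprint <- function(smiles, nbits = 2048L) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("invalid SMILES passed to ecfp4_fingerprint: ",
                       paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "))
  uniq <- unique(can)
  todo <- uniq[!vapply(uniq, function(s) !is.null(.chem_cache$fp[[s]]),
                       logical(1L), USE.NAMES = FALSE)]
  if (length(todo)) {
    vals <- if (.has_obabel()) .fp_obabel_batch(todo) else .fp_chemmine(todo)
    for (i in seq_along(todo)) .chem_cache$fp[[todo[i]]] <- vals[[i]]
  }
  full <- do.call(rbind, lapply(can, function(s) .chem_cache$fp[[s]]))
  wide <- ncol(full)
  if (wide %% nbits != 0L) stop("cannot fold ", wide, " bits into ", nbits)
  folds <- wide / nbits
  out <- matrix(0L, nrow(full), nbits)
  for (f in seq_len(folds)) {
    out <- out | full[, ((f - 1L) * nbits + 1L):(f * nbits), drop = FALSE]
  }
  storage.mode(out) <- "integer"
  rownames(out) <- smiles
  out
}

#' Tanimoto similarity between fingerprint matrices
#'
#' @param fp_a,fp_b 0/1 matrices with fingerprints in rows (`fp_b` defaults
#'   to `fp_a`).
#' @return Matrix of pairwise Tanimoto similarities, `nrow(fp_a)` by
#'   `nrow(fp_b)`. Two all-zero fingerprints have similarity 0.
#' @export
tanimoto_similarity <- function(fp_a, fp_b = fp_a) {
  fp_a <- as.matrix(fp_a); fp_b <- as.matrix(fp_b)
  common <- fp_a %*% t(fp_b)
  na <- rowSums(fp_a); nb <- rowSums(fp_b)
  denom <- outer(na, nb, "+") - common
  sim <- ifelse(denom > 0, common / denom, 0)
  sim
}
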