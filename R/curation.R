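# Dataset curation: ES/HS labeling at an SRP cut-off, diversity
# down-sampling of the surplus class by leader (sphere-exclusion)
# clustering, and stratified 8:1:1 splits with an optional unbalanced test.

#' Label compounds as easy- or hard-to-synthesize
#'
#' A compound is ES iff its shortest reaction path is less than or equal to
#' the cut-off, HS otherwise. Unreachable compounds (`NA` SRP) are dropped
#' and their count reported.
#'
#' @param srp_table Tibble `key`, `srp` from [compute_srp()].
#' @param cutoff Positive integer SRP cut-off (the study's defaults are
#'   2, 3 and 4).
#' @return Tibble `key`, `smiles`, `srp`, `label` (`"ES"`/`"HS"`).
#' @export
label_compounds <- function(srp_table, cutoff) {
  stopifnot(cutoff >= 1L)
  drop <- is.na(srp_table$srp)
  if (any(drop)) message(sum(drop), " unreachable compound(s) dropped")
  t <- srp_table[!drop, , drop = FALSE]
  tibble::tibble(
    key = t$key, smiles = t$key, srp = as.integer(t$srp),
    label = ifelse(t$srp <= cutoff, "ES", "HS")
  )
}

#' Diversity down-sampling by leader clustering
#'
#' Greedy sphere-exclusion clustering on ECFP4/Tanimoto: compounds are
#' scanned in input order; a compound joins the first existing cluster whose
#' leader is at least `similarity_threshold` similar, otherwise it founds a
#' new cluster. The cluster leaders are the diverse representatives; when
#' there are more leaders than `target_size`, a seeded uniform subsample is
#' returned.
#'
#' @param compounds Labeled compound tibble (any tibble with `key`).
#' @param similarity_threshold Tanimoto similarity above which two compounds
#'   share a cluster (per-cut-off defaults in the study: 0.35, 0.615, 0.655
#'   for SRP 2, 3, 4).
#' @param target_size Desired number of representatives.
#' @param seed Integer seed for the subsample.
#' @return Subset of `compounds` rows (the representatives), with a
#'   `cluster` column giving each leader's cluster id.
#' @export
diversity_downsample <- function(compounds, similarity_threshold,
                                 target_size, seed = 1L) {
  stopifnot(nrow(compounds) >= 1L,
            similarity_threshold > 0, similarity_threshold < 1)
  if (target_size > nrow(compounds)) {
    warning("target_size exceeds available compounds; returning all")
  }
  fp <- ecfp4_fingerprint(compounds$key)
  n <- nrow(compounds)
  leader_idx <- integer()
  assign <- integer(n)
  lead_fp <- NULL
  for (i in seq_len(n)) {
    if (length(leader_idx)) {
      sims <- tanimoto_similarity(fp[i, , drop = FALSE], lead_fp)[1L, ]
      hit <- which(sims >= similarity_threshold)
      if (length(hit)) { assign[i] <- hit[1L]; next }
    }
    leader_idx <- c(leader_idx, i)
    lead_fp <- rbind(lead_fp, fp[i, , drop = FALSE])
    assign[i] <- length(leader_idx)
  }
  reps <- compounds[leader_idx, , drop = FALSE]
  reps$cluster <- seq_along(leader_idx)
  if (nrow(reps) > target_size) {
    withr_seed <- .with_seed(seed, sample.int(nrow(reps), target_size))
    reps <- reps[sort(withr_seed), , drop = FALSE]
  } else if (nrow(reps) < target_size && target_size <= n) {
    warning("only ", nrow(reps), " clusters for target_size ", target_size)
  }
  reps
}

# evaluate expr under a local RNG seed without touching the global stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split labeled compounds into train/validation/test
#'
#' Seeded, stratified by label: within each label the compounds are
#' shuffled, the first 80% (floor) go to training, the next 10% (floor) to
#' validation, and the remainder to test, so each split's ES fraction stays
#' within a percentage point of the whole set's.
#'
#' @param compounds Labeled compound tibble from [label_compounds()].
#' @param seed Integer seed.
#' @param ratios Integer ratios (default `c(8, 1, 1)`).
#' @return `compounds` with an extra `split` column
#'   (`"train"`/`"validation"`/`"test"`); attributes `seed` and `ratios`.
#' @export
split_dataset <- function(compounds, seed = 1L, ratios = c(8L, 1L, 1L)) {
  if (nrow(compounds) < 10L) stop("need at least 10 compounds to honor 8:1:1")
  frac <- ratios / sum(ratios)
  compounds$split <- NA_character_
  for (lab in unique(compounds$label)) {
    idx <- which(compounds$label == lab)
    idx <- idx[.with_seed(seed + match(lab, sort(unique(compounds$label))),
                          sample.int(length(idx)))]
    n <- length(idx)
    ntr <- floor(frac[1L] * n); nva <- floor(frac[2L] * n)
    compounds$split[idx[seq_len(ntr)]] <- "train"
    compounds$split[idx[ntr + seq_len(nva)]] <- "validation"
    if (ntr + nva < n) compounds$split[idx[(ntr + nva + 1L):n]] <- "test"
  }
  attr(compounds, "seed") <- seed
  attr(compounds, "ratios") <- ratios
  compounds
}

#' Extend the balanced test set into an unbalanced test set
#'
#' The unbalanced test set is the balanced test set plus every remaining ES
#' compound that was removed by the diversity down-sampling; it must not
#' overlap the training or validation sets.
#'
#' @param split A split tibble from [split_dataset()].
#' @param remaining_es Labeled compound tibble of leftover ES compounds.
#' @return Tibble of unbalanced-test rows (superset of the `test` rows).
#' @export
build_unbalanced_test <- function(split, remaining_es) {
  trainval <- split$key[split$split %in% c("train", "validation")]
  bad <- intersect(remaining_es$key, trainval)
  if (length(bad)) {
    stop("remaining ES compounds overlap train/validation: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  test <- split[split$split == "test", , drop = FALSE]
  extra <- remaining_es[!(remaining_es$key %in% test$key), , drop = FALSE]
  cols <- intersect(names(test), names(extra))
  out <- dplyr::bind_rows(test[, cols, drop = FALSE], extra[, cols, drop = FALSE])
  out$split <- "unbalanced_test"
  out
}
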