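# Reactant/reagent role designation.
#
# All reactant-side species of a record, agents included, are pooled as
# "original reactants" (ORs). The inverse template applied to the product
# gives "predicted reactants" (PRs). Each PR consumes at most one OR: an
# exact canonical-key match if available, otherwise the unconsumed OR with
# the highest ECFP4 Tanimoto similarity. ORs left unconsumed are reagents.

.similarity_floor <- 0.2

.match_prs_to_ors <- function(prs, or_keys) {
  consumed <- logical(length(or_keys))
  trace <- vector("list", length(prs))
  total_sim <- 0
  fp_or <- NULL
  for (i in seq_along(prs)) {
    pr <- prs[i]
    free <- which(!consumed)
    if (!length(free)) break
    exact <- free[or_keys[free] == pr]
    if (length(exact)) {
      j <- exact[1L]
      consumed[j] <- TRUE
      total_sim <- total_sim + 1
      trace[[i]] <- tibble::tibble(pr = pr, matched = or_keys[j],
                                   mode = "exact", similarity = 1)
    } else {
      if (is.null(fp_or)) fp_or <- ecfp4_fingerprint(or_keys)
      sims <- tanimoto_similarity(ecfp4_fingerprint(pr),
                                  fp_or[free, , drop = FALSE])[1L, ]
      j <- free[which.max(sims)]
      s <- max(sims)
      consumed[j] <- TRUE
      total_sim <- total_sim + s
      trace[[i]] <- tibble::tibble(pr = pr, matched = or_keys[j],
                                   mode = "similarity", similarity = s)
    }
  }
  list(consumed = consumed, trace = dplyr::bind_rows(trace),
       n_exact = sum(vapply(trace, function(t) !is.null(t) && t$mode == "exact",
                            logical(1L))),
       total_sim = total_sim)
}

#' Designate reactant and reagent roles for one record
#'
#' Applies the record's inverse template to its largest product to obtain
#' predicted-reactant sets, picks the set that agrees best with the pooled
#' reactant-side species (most exact matches, then highest total Tanimoto,
#' then lexicographic order), and consumes one original reactant per PR.
#' Leftover species are reagents.
#'
#' @param record A one-row reaction record tibble.
#' @param template An `srp_template` for the record (extracted on the fly
#'   when `NULL`).
#' @return A list of class `srp_roles` with elements `true_reactants`,
#'   `reagents` (canonical keys), `status` (`"ok"` or
#'   `"role_designation_failed"`), and `match_trace` (a tibble with one row
#'   per PR: `pr`, `matched`, `mode`, `similarity`).
#' @export
designate_roles <- function(record, template = NULL) {
  stopifnot(nrow(record) == 1L)
  or_keys <- c(record$reactant_keys[[1L]], record$agent_keys[[1L]])
  fail <- function() {
    structure(list(
      true_reactants = record$reactant_keys[[1L]],
      reagents = record$agent_keys[[1L]],
      status = "role_designation_failed",
      match_trace = tibble::tibble(pr = character(), matched = character(),
                                   mode = character(), similarity = numeric())
    ), class = "srp_roles")
  }
  if (is.null(template)) {
    template <- tryCatch(extract_reaction_template(record),
                         error = function(e) NULL)
    if (is.null(template)) return(fail())
  }
  pr_sets <- apply_reaction_template(template, template$product_smiles,
                                     direction = "inverse")
  if (!length(pr_sets)) return(fail())

  scored <- lapply(pr_sets, .match_prs_to_ors, or_keys = or_keys)
  ord <- order(
    -vapply(scored, `[[`, numeric(1L), "n_exact"),
    -vapply(scored, `[[`, numeric(1L), "total_sim"),
    vapply(pr_sets, paste, character(1L), collapse = ".")
  )
  best <- scored[[ord[1L]]]
  low <- best$trace$similarity < .similarity_floor & best$trace$mode == "similarity"
  if (any(low)) {
    warning("best PR/OR similarity below ", .similarity_floor, " for PR ",
            paste(best$trace$pr[low], collapse = ", "), " in record ",
            record$id, call. = FALSE)
  }
  structure(list(
    true_reactants = or_keys[best$consumed],
    reagents = or_keys[!best$consumed],
    status = "ok",
    match_trace = best$trace
  ), class = "srp_roles")
}

#' @export
print.srp_roles <- function(x, ...) {
  cat("<srp_roles> ", x$status, "\n  reactants: ",
      paste(x$true_reactants, collapse = ", "), "\n  reagents:  ",
      paste(x$reagents, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Designate roles for a whole record table
#'
#' Runs [extract_reaction_template()] and [designate_roles()] over every
#' record and appends the results as columns. Records whose template cannot
#' be extracted or applied keep their as-parsed roles and are flagged.
#'
#' @param records A reaction record tibble.
#' @param radius Template radius (default 1).
#' @return `records` with extra columns `true_reactant_keys`,
#'   `reagent_keys` (list-columns of canonical keys), `role_status`
#'   (character) and `match_trace` (list-column of tibbles).
#' @export
designate_reaction_roles <- function(records, radius = 1L) {
  n <- nrow(records)
  tr <- vector("list", n); rg <- vector("list", n)
  st <- character(n); mt <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    tmpl <- tryCatch(extract_reaction_template(rec, radius = radius),
                     error = function(e) NULL)
    roles <- designate_roles(rec, tmpl)
    tr[[i]] <- roles$true_reactants
    rg[[i]] <- roles$reagents
    st[i] <- roles$status
    mt[[i]] <- roles$match_trace
  }
  records$true_reactant_keys <- tr
  records$reagent_keys <- rg
  records$role_status <- st
  records$match_trace <- mt
  records
}
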