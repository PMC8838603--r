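# Reaction record I/O: parse "reactants>agents>products" lines into a tidy
# record table, deduplicate, and apply the validity contract.

.smiles_maps <- function(smiles) {
  m <- gregexpr(":([0-9]+)\\]", smiles)[[1L]]
  if (m[1L] == -1L) return(integer())
  lens <- attr(m, "match.length")
  as.integer(substr(rep(smiles, length(m)), m + 1L, m + lens - 2L))
}

#' Read a reaction-SMILES file
#'
#' One reaction per line: the reaction SMILES, optionally followed by
#' tab-separated `id` and `source` columns. Lines starting with `#` and
#' blank lines are skipped. Records without an explicit id get `"r<line>"`.
#'
#' @param path Path to a UTF-8 text file.
#' @return A tibble with columns `id`, `source`, `rsmi`.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  tibble::tibble(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L && nzchar(parts[[i]][2L])) parts[[i]][2L]
      else paste0("r", lineno[i])
    }, character(1L)),
    source = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "",
                    character(1L)),
    rsmi = vapply(parts, `[[`, character(1L), 1L)
  )
}

#' Parse reaction SMILES into a record table
#'
#' Splits each `"reactants>agents>products"` string into dot-separated
#' species lists, validates every species, and attaches canonical substance
#' keys (atom maps stripped). The as-written SMILES (atom maps preserved)
#' are kept for template extraction.
#'
#' @param x A character vector of reaction SMILES, or a tibble from
#'   [read_reactions()] with columns `rsmi`, `id` and optionally `source`.
#' @param id Optional ids when `x` is a character vector.
#' @return A reaction record tibble with columns `id`, `source`, `reactants`,
#'   `agents`, `products` (list-columns of as-written SMILES) and
#'   `reactant_keys`, `agent_keys`, `product_keys` (list-columns of canonical
#'   keys).
#' @export
#' @examples
#' parse_reactions("CCBr.CN>CO>CCNC", id = "r1")
parse_reactions <- function(x, id = NULL) {
  if (is.character(x)) {
    x <- tibble::tibble(
      id = if (is.null(id)) paste0("r", seq_along(x)) else id,
      source = "", rsmi = x
    )
  }
  stopifnot(all(c("id", "rsmi") %in% names(x)))
  if (!"source" %in% names(x)) x$source <- ""
  if (anyDuplicated(x$id)) stop("duplicate reaction ids in input")

  fields <- strsplit(x$rsmi, ">", fixed = TRUE)
  nsep <- vapply(x$rsmi, function(s) sum(strsplit(s, "")[[1L]] == ">"),
                 integer(1L), USE.NAMES = FALSE)
  bad <- nsep != 2L
  if (any(bad)) {
    stop("malformed reaction SMILES (need exactly two '>'): ",
         paste(utils::head(x$id[bad], 5L), collapse = ", "))
  }

  split_side <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ".", fixed = TRUE)[[1L]]
  }
  side <- function(k) lapply(fields, function(f) split_side(if (length(f) >= k) f[k] else ""))
  reactants <- side(1L); agents <- side(2L); products <- side(3L)

  all_species <- unique(unlist(c(reactants, agents, products), use.names = FALSE))
  keys <- canonical_smiles(all_species)
  if (anyNA(keys)) {
    stop("unparseable species in reaction input: ",
         paste(utils::head(all_species[is.na(keys)], 5L), collapse = ", "))
  }
  keymap <- stats::setNames(keys, all_species)
  to_keys <- function(lst) lapply(lst, function(s) unname(keymap[s]))

  tibble::tibble(
    id = x$id, source = x$source,
    reactants = reactants, agents = agents, products = products,
    reactant_keys = to_keys(reactants),
    agent_keys = to_keys(agents),
    product_keys = to_keys(products)
  )
}

.dedup_signature <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    paste(
      paste(sort(records$reactant_keys[[i]]), collapse = "."),
      paste(sort(records$agent_keys[[i]]), collapse = "."),
      paste(sort(records$product_keys[[i]]), collapse = "."),
      sep = ">"
    )
  }, character(1L))
}

#' Remove duplicate reaction records
#'
#' Two records are duplicates iff their sorted reactant-, agent- and
#' product-key triples coincide (component order and atom maps are
#' irrelevant). The first occurrence is kept; input order is preserved.
#'
#' @param records A reaction record tibble from [parse_reactions()].
#' @return The deduplicated record tibble.
#' @export
deduplicate_reactions <- function(records) {
  if (!nrow(records)) return(records)
  records[!duplicated(.dedup_signature(records)), , drop = FALSE]
}

#' Apply the reaction validity contract
#'
#' Rejects records with no products, with neither reactants nor agents, with
#' a product identical to a reactant (self-loop), or whose products share no
#' atom-map number with any reactant (unmappable). Optionally also rejects
#' records on which radius-`radius` template extraction fails.
#'
#' @param records A reaction record tibble.
#' @param check_templates Also attempt template extraction and reject
#'   failures with reason `"template_failure"` (default `FALSE`).
#' @param radius Template radius used when `check_templates` is `TRUE`.
#' @return A list with elements `kept` (record tibble) and `rejected`
#'   (record tibble with an extra `reason` column).
#' @export
filter_reactions <- function(records, check_templates = FALSE, radius = 1L) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rk <- records$reactant_keys[[i]]
    ak <- records$agent_keys[[i]]
    pk <- records$product_keys[[i]]
    if (!length(pk)) {
      reason[i] <- "no_products"
    } else if (!length(rk) && !length(ak)) {
      reason[i] <- "no_reactants"
    } else if (any(pk %in% rk)) {
      reason[i] <- "product_equals_reactant"
    } else {
      rmaps <- unique(unlist(lapply(records$reactants[[i]], .smiles_maps)))
      pmaps <- unique(unlist(lapply(records$products[[i]], .smiles_maps)))
      if (!length(pmaps) || !length(intersect(rmaps, pmaps))) {
        reason[i] <- "unmappable_product"
      } else if (check_templates) {
        tmpl <- tryCatch(extract_reaction_template(records[i, ], radius = radius),
                         error = function(e) NULL)
        if (is.null(tmpl)) reason[i] <- "template_failure"
      }
    }
  }
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Write reaction records back to a reaction-SMILES file
#'
#' Inverse of [read_reactions()] + [parse_reactions()]: species are joined
#' with `.`, sides with `>`, and `id`/`source` become tab-separated columns.
#'
#' @param records A reaction record tibble.
#' @param path Output path.
#' @param rejected Optional rejected tibble (from [filter_reactions()]);
#'   written as a side-car TSV `<path>.rejected.tsv` with reason codes.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(records, path, rejected = NULL) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    paste(
      paste(
        paste(records$reactants[[i]], collapse = "."),
        paste(records$agents[[i]], collapse = "."),
        paste(records$products[[i]], collapse = "."),
        sep = ">"
      ),
      records$id[i], records$source[i], sep = "\t"
    )
  }, character(1L))
  writeLines(lines, path)
  if (!is.null(rejected) && nrow(rejected)) {
    side <- file.path(paste0(path, ".rejected.tsv"))
    utils::write.table(
      data.frame(id = rejected$id, reason = rejected$reason,
                 rsmi = vapply(seq_len(nrow(rejected)), function(i) {
                   paste(paste(rejected$reactants[[i]], collapse = "."),
                         paste(rejected$agents[[i]], collapse = "."),
                         paste(rejected$products[[i]], collapse = "."), sep = ">")
                 }, character(1L))),
      side, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
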