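# The reaction knowledge graph: a directed multigraph of substances.
# Vertices are canonical substance keys; each reaction contributes one edge
# from every true reactant to every product. Agents/reagents never become
# vertices. Edge weight of a (u, v) pair is the number of distinct source
# documents (patents) supporting the transformation.

#' Build the directed substance-level reaction graph
#'
#' @param records A reaction record tibble with designated roles
#'   (see [designate_reaction_roles()]); records whose `role_status` is not
#'   `"ok"` are skipped with a warning, as are would-be self-loop edges.
#' @return An `igraph` directed multigraph with vertex attribute `name`
#'   (the substance key) and edge attributes `reaction_id`, `source` and
#'   `weight` (distinct-source count of the parallel class).
#' @export
build_reaction_graph <- function(records) {
  if (!"true_reactant_keys" %in% names(records)) {
    stop("records lack designated roles; run designate_reaction_roles() first")
  }
  bad <- records$role_status != "ok"
  if (any(bad)) {
    warning(sum(bad), " record(s) without designated roles skipped: ",
            paste(utils::head(records$id[bad], 5L), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  edges <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    from <- unique(records$true_reactant_keys[[i]])
    to <- unique(records$product_keys[[i]])
    if (!length(from) || !length(to)) return(NULL)
    g <- tidyr::expand_grid(from = from, to = to)
    g$reaction_id <- records$id[i]
    g$source <- records$source[i]
    g
  })
  if (nrow(edges)) {
    loops <- edges$from == edges$to
    if (any(loops)) {
      warning("dropped ", sum(loops), " self-loop edge(s)")
      edges <- edges[!loops, , drop = FALSE]
    }
  }
  if (!nrow(edges)) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  # distinct-source support per (u, v) pair
  key <- paste(edges$from, edges$to, sep = " -> ")
  w <- tapply(edges$source, key, function(s) length(unique(s[nzchar(s)])) |>
                max(1L))
  igraph::E(g)$weight <- as.numeric(w[key])
  g
}

#' Classify reaction-graph nodes
#'
#' Terminal nodes have no incoming edge and at least one outgoing edge (they
#' only ever act as reactants); normal nodes have at least one incoming edge
#' (they have been made at least once). Terminal nodes whose key appears in
#' the purchasable building-block list are the starting materials.
#'
#' @param graph Reaction graph from [build_reaction_graph()].
#' @param building_blocks Character vector of building-block SMILES (any
#'   form; canonicalized before matching).
#' @return A tibble with columns `key`, `in_deg`, `out_deg`,
#'   `type` (`"terminal"`/`"normal"`), `starting` (logical).
#' @export
classify_nodes <- function(graph, building_blocks = character()) {
  if (igraph::vcount(graph) == 0L) {
    return(tibble::tibble(key = character(), in_deg = integer(),
                          out_deg = integer(), type = character(),
                          starting = logical()))
  }
  bb <- unique(stats::na.omit(canonical_smiles(building_blocks)))
  keys <- igraph::V(graph)$name
  ind <- igraph::degree(graph, mode = "in")
  outd <- igraph::degree(graph, mode = "out")
  type <- ifelse(ind == 0L & outd >= 1L, "terminal",
                 ifelse(ind >= 1L, "normal", "isolated"))
  tibble::tibble(
    key = keys, in_deg = as.integer(ind), out_deg = as.integer(outd),
    type = type, starting = type == "terminal" & keys %in% bb
  )
}

#' Select label candidates by physicochemical properties
#'
#' Returns the normal (product) nodes whose molecular weight and calculated
#' LogP lie within the given inclusive ranges. The graph itself is never
#' pruned: excluded substances still serve as path intermediates.
#'
#' @param typing Node typing from [classify_nodes()].
#' @param mw_range,logp_range Inclusive `[low, high]` bounds
#'   (defaults 200–500 g/mol and 0–5).
#' @return Character vector of candidate keys; nodes whose properties
#'   cannot be computed are excluded with a message.
#' @export
filter_candidates <- function(typing, mw_range = c(200, 500),
                              logp_range = c(0, 5)) {
  normal <- typing$key[typing$type == "normal"]
  if (!length(normal)) return(character())
  d <- physchem_descriptors(normal)
  bad <- is.na(d$mw) | is.na(d$logp)
  if (any(bad)) {
    message(sum(bad), " node(s) excluded: property computation failed")
  }
  ok <- !bad & d$mw >= mw_range[1L] & d$mw <= mw_range[2L] &
    d$logp >= logp_range[1L] & d$logp <= logp_range[2L]
  normal[ok]
}

#' Shortest reaction paths from starting materials
#'
#' Multi-source breadth-first search over the directed graph: the SRP of a
#' substance is the minimum number of reaction edges from any starting
#' material to it. Implemented by attaching a virtual super-source to every
#' starting material, so one BFS covers all sources. Edge multiplicity is
#' irrelevant to path length.
#'
#' @param graph Reaction graph.
#' @param typing Node typing from [classify_nodes()] (supplies the starting
#'   materials).
#' @param targets Keys to report (default: all normal nodes).
#' @return A tibble `key`, `srp` (positive integer steps; `NA` when no
#'   starting material reaches the substance).
#' @export
compute_srp <- function(graph, typing, targets = NULL) {
  if (is.null(targets)) targets <- typing$key[typing$type == "normal"]
  starts <- typing$key[typing$starting]
  if (!length(starts)) stop("no starting materials: SRP undefined")
  if (!length(targets)) return(tibble::tibble(key = character(), srp = integer()))
  g2 <- igraph::add_vertices(graph, 1L, name = "..source..")
  src <- igraph::vcount(g2)
  g2 <- igraph::add_edges(g2, rbind(rep(src, length(starts)),
                                    match(starts, igraph::V(graph)$name)))
  d <- igraph::distances(g2, v = src, to = match(targets, igraph::V(graph)$name),
                         mode = "out", weights = NA)[1L, ]
  reach <- is.finite(d)
  srp <- rep(NA_integer_, length(d))
  srp[reach] <- as.integer(d[reach]) - 1L
  tibble::tibble(key = targets, srp = srp)
}

#' Export / import the reaction graph as GraphML
#'
#' Round-trips the vertex keys and edge attributes through the standard
#' GraphML format so networks can be exchanged with other graph tools.
#'
#' @param graph Reaction graph.
#' @param path File path.
#' @return `path` (export) or an `igraph` (import).
#' @export
export_graphml <- function(graph, path) {
  # igraph refuses vertex attribute "name" clashes in GraphML readers that
  # reserve it; keep a plain "smiles" copy alongside
  if (igraph::vcount(graph) > 0L) {
    igraph::V(graph)$smiles <- igraph::V(graph)$name
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) > 0L && !is.null(igraph::vertex_attr(g, "smiles"))) {
    igraph::V(g)$name <- igraph::V(g)$smiles
  }
  g
}
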