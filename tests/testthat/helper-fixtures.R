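# Shared fixtures, generated once per test run and cached.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- force(expr)
  .test_cache[[name]]
}

clean_corpus <- function() {
  cached("clean_corpus", generate_reaction_corpus(
    fixture_spec(n_building_blocks = 10L, depth = 3L, branching = 2L,
                 reagent_injection_rate = 0, duplicate_rate = 0, seed = 101L)
  ))
}

noisy_corpus <- function() {
  cached("noisy_corpus", generate_reaction_corpus(
    fixture_spec(n_building_blocks = 10L, depth = 3L, branching = 2L,
                 reagent_injection_rate = 0.5, duplicate_rate = 0.2,
                 seed = 202L)
  ))
}

roles_on <- function(corpus) {
  cached(paste0("roles_", substr(digest_lines(corpus$records$rsmi), 1, 8)), {
    rec <- parse_reactions(corpus$records)
    fl <- filter_reactions(deduplicate_reactions(rec))
    suppressWarnings(designate_reaction_roles(fl$kept))
  })
}

digest_lines <- function(x) paste(substr(x[1], 1, 20), length(x))

# brute-force SRP oracle: minimum over all simple directed paths from any
# starting vertex, by depth-first enumeration (independent of the BFS code)
brute_force_srp <- function(graph, typing) {
  adj_out <- igraph::adjacent_vertices(graph, igraph::V(graph), mode = "out")
  names(adj_out) <- igraph::V(graph)$name
  starts <- typing$key[typing$starting]
  best <- stats::setNames(rep(Inf, igraph::vcount(graph)),
                          igraph::V(graph)$name)
  walk <- function(v, depth, seen) {
    # prune prefixes that arrive no earlier than a known one: every
    # continuation of a dominated prefix is dominated too, so all minima
    # are preserved while the enumeration stays finite-time
    if (depth >= best[[v]]) return(invisible())
    best[[v]] <<- depth
    for (w in names(adj_out[[v]])) {
      if (!(w %in% seen)) walk(w, depth + 1L, c(seen, w))
    }
  }
  for (s in starts) walk(s, 0L, s)
  best
}

# threshold-sweep trapezoid AUC oracle, independent of the rank formula
trapezoid_auc <- function(scores, labels) {
  pos <- labels == "ES"
  ths <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
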