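#' Extract the mechanism-of-action subgraph of a drug
#'
#' For each ensemble solution, enumerates simple directed paths of length
#' at most `steps` from any stimulus protein to any effector, keeping only
#' paths whose every edge carries |weight| >= `epsilon` in that solution.
#' An edge's support is the fraction of solutions in which it lies on at
#' least one such path. A path's score is the minimum edge support along
#' it; the union subgraph of the `k` best-scoring paths (ties broken
#' lexicographically by node sequence) is returned.
#'
#' @param net a [protein_network()].
#' @param ensemble a `moa_ensemble` (from [build_ensemble()]) or list of [solution_weights()].
#' @param stimulus_proteins character vector of path sources (drug
#'   targets).
#' @param effector_proteins character vector of path sinks (disease
#'   effectors).
#' @param k number of top paths to keep (>= 1).
#' @param epsilon minimum |weight| for an edge to carry mechanism signal.
#' @param steps maximum path length in edges (the propagation depth, so
#'   extracted mechanisms are realizable by the dynamics).
#' @return An object of class `moa_subgraph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `support`), and `paths` (data.frame `path`,
#'   `score`); empty (with a warning) when no qualifying path exists.
#' @export
extract_moa <- function(net, ensemble, stimulus_proteins, effector_proteins,
                        k = 5L, epsilon = 0.1, steps = 3L) {
  stopifnot(inherits(net, "protein_network"), k >= 1, epsilon > 0, steps >= 1)
  sols <- if (inherits(ensemble, "moa_ensemble")) ensemble$solutions else ensemble
  if (!length(sols)) stop("ensemble is empty")
  stimulus_proteins <- intersect(stimulus_proteins, net$nodes)
  effector_proteins <- intersect(effector_proteins, net$nodes)
  edge_key <- paste(net$edges$from, net$edges$to, sep = "\t")

  edge_count <- integer(nrow(net$edges))
  names(edge_count) <- edge_key
  path_seen <- character()

  for (sol in sols) {
    w <- if (inherits(sol, "solution_weights")) sol$weights else sol
    keep <- abs(w) >= epsilon
    if (!any(keep)) next
    sub <- net$edges[keep, c("from", "to"), drop = FALSE]
    g <- igraph::graph_from_data_frame(sub, directed = TRUE)
    present_src <- intersect(stimulus_proteins, igraph::V(g)$name)
    present_dst <- intersect(effector_proteins, igraph::V(g)$name)
    if (!length(present_src) || !length(present_dst)) next
    sol_edges <- character()
    for (src in present_src) {
      paths <- igraph::all_simple_paths(g, from = src, to = present_dst,
                                        mode = "out", cutoff = steps)
      for (p in paths) {
        nm <- igraph::V(g)$name[as.integer(p)]
        if (length(nm) < 2L) next
        ek <- paste(nm[-length(nm)], nm[-1L], sep = "\t")
        sol_edges <- c(sol_edges, ek)
        path_seen <- c(path_seen, paste(nm, collapse = "->"))
      }
    }
    sol_edges <- unique(sol_edges)
    edge_count[sol_edges] <- edge_count[sol_edges] + 1L
  }

  path_seen <- unique(path_seen)
  if (!length(path_seen)) {
    warning("no stimulus-to-effector path qualifies at |weight| >= ", epsilon)
    return(structure(list(nodes = character(),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             support = numeric()),
                          paths = data.frame(path = character(),
                                             score = numeric())),
                     class = "moa_subgraph"))
  }
  support <- edge_count / length(sols)
  score <- vapply(path_seen, function(pp) {
    nm <- strsplit(pp, "->", fixed = TRUE)[[1]]
    min(support[paste(nm[-length(nm)], nm[-1L], sep = "\t")])
  }, numeric(1))
  ord <- order(-score, path_seen)
  top <- head(ord, k)
  top_paths <- data.frame(path = path_seen[top], score = score[top],
                          stringsAsFactors = FALSE)
  top_edges <- unique(unlist(lapply(top_paths$path, function(pp) {
    nm <- strsplit(pp, "->", fixed = TRUE)[[1]]
    paste(nm[-length(nm)], nm[-1L], sep = "\t")
  })))
  parts <- strsplit(top_edges, "\t", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      support = as.numeric(support[top_edges]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = unique(c(edges$from, edges$to)),
                 edges = edges, paths = top_paths),
            class = "moa_subgraph")
}

#' @export
print.moa_subgraph <- function(x, ...) {
  cat("moa_subgraph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", nrow(x$paths), "path(s)\n")
  if (nrow(x$paths)) {
    for (i in seq_len(min(5L, nrow(x$paths))))
      cat(sprintf("  [%.2f] %s\n", x$paths$score[i], x$paths$path[i]))
  }
  invisible(x)
}

#' Write a MoA subgraph as SIF plus an edge-support TSV
#'
#' @param moa a `moa_subgraph` from [extract_moa()].
#' @param sif_path SIF output path (`source  moa  target`).
#' @param support_path TSV output path (`source`, `target`, `support`).
#' @return Character vector of the two paths, invisibly.
#' @export
write_moa <- function(moa, sif_path, support_path) {
  stopifnot(inherits(moa, "moa_subgraph"))
  writeLines(paste(moa$edges$from, "moa", moa$edges$to, sep = "\t"), sif_path)
  write.table(
    data.frame(source = moa$edges$from, target = moa$edges$to,
               support = moa$edges$support),
    support_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif_path, support_path))
}
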