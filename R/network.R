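#' Construct a directed protein network
#'
#' A `protein_network` is the substrate over which signal propagates: a set
#' of protein identifiers (nodes) and directed edges, each optionally
#' carrying a prior interaction sign (+1 activation, -1 inhibition, `NA`
#' unknown). Self-loops and duplicate edges are dropped with a warning.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `sign`
#'   (values in `-1`, `1`, `NA`).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of edge endpoints. Must cover all endpoints.
#' @return An object of class `protein_network` with elements `nodes`
#'   (character), `edges` (data.frame `from`, `to`, `sign`), and 1-based
#'   index vectors `from_idx`, `to_idx` into `nodes`.
#' @seealso [load_network()]
#' @export
protein_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$sign)) edges$sign <- rep(NA_integer_, nrow(edges))
  edges$sign <- as.integer(edges$sign)
  bad_sign <- !is.na(edges$sign) & !edges$sign %in% c(-1L, 1L)
  if (any(bad_sign)) {
    stop("edge sign must be -1, 1 or NA (rows: ",
         paste(which(bad_sign), collapse = ", "), ")")
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  dup <- duplicated(paste(edges$from, edges$to, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) dropped")
    edges <- edges[!dup, , drop = FALSE]
  }
  if (nrow(edges) == 0L && is.null(nodes)) stop("network has no edges")
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing)) {
      stop("edge endpoints absent from node set: ",
           paste(head(missing, 5), collapse = ", "))
    }
  }
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes,
         edges = edges[, c("from", "to", "sign")],
         from_idx = match(edges$from, nodes),
         to_idx = match(edges$to, nodes)),
    class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat("protein_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  n_signed <- sum(!is.na(x$edges$sign))
  if (n_signed) cat("  ", n_signed, "edges carry a prior sign\n")
  invisible(x)
}

#' Read a directed network from SIF or TSV edge lists
#'
#' SIF lines are `source<TAB>relation<TAB>target`; relations `act`/`inh`
#' become prior edge signs +1/-1, anything else an unsigned edge. Plain TSV
#' edge lists may have two columns (`from`, `to`) or three (`from`, `to`,
#' `sign` or `relation`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.sif` vs anything else), `"sif"`
#'   or `"tsv"`.
#' @return A [protein_network()].
#' @export
load_network <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty network file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) stop("malformed SIF line(s) in ", path)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1L),
      to = vapply(parts, `[`, "", 3L),
      relation = vapply(parts, `[`, "", 2L),
      stringsAsFactors = FALSE)
    edges$sign <- ifelse(edges$relation == "act", 1L,
                         ifelse(edges$relation == "inh", -1L, NA_integer_))
  } else {
    edges <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!nrow(edges)) stop("empty network file: ", path)
    if (ncol(edges) < 2L) stop("edge list needs at least two columns")
    names(edges)[1:2] <- c("from", "to")
    if (ncol(edges) >= 3L && !"sign" %in% names(edges)) {
      rel <- as.character(edges[[3L]])
      edges$sign <- ifelse(rel %in% c("act", "1"), 1L,
                           ifelse(rel %in% c("inh", "-1"), -1L, NA_integer_))
    }
  }
  net <- protein_network(edges)
  message("loaded network: ", length(net$nodes), " nodes, ",
          nrow(net$edges), " edges")
  net
}

#' Write a network as SIF
#'
#' Prior signs map back to `act`/`inh`; unsigned edges are written with
#' relation `int`.
#'
#' @param net a [protein_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "protein_network"))
  rel <- ifelse(is.na(net$edges$sign), "int",
                ifelse(net$edges$sign > 0, "act", "inh"))
  writeLines(paste(net$edges$from, rel, net$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Build a stimulus for propagation
#'
#' Clamped proteins (drug targets) hold their value at every propagation
#' step; basal proteins (the basal clinical motive) only set the initial
#' state and are then free to change. A protein appearing in both is kept
#' clamped and removed from the basal set, with a message.
#'
#' @param clamped named numeric vector of +1/-1 values.
#' @param basal named numeric vector of +1/-1 values (may be empty).
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(clamped = numeric(), basal = numeric()) {
  check_signed <- function(x, what) {
    if (length(x)) {
      if (is.null(names(x)) || any(!nzchar(names(x))))
        stop(what, " values must be named by protein")
      if (anyDuplicated(names(x))) stop("duplicate ", what, " protein")
      if (!all(x %in% c(-1, 1))) stop(what, " values must be +1 or -1")
    }
    x
  }
  clamped <- check_signed(clamped, "clamped")
  basal <- check_signed(basal, "basal")
  both <- intersect(names(clamped), names(basal))
  if (length(both)) {
    message("clamped value overrides basal for: ", paste(both, collapse = ", "))
    basal <- basal[setdiff(names(basal), both)]
  }
  structure(list(clamped = clamped, basal = basal), class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat("stimulus:", length(x$clamped), "clamped,", length(x$basal),
      "basal protein(s)\n")
  invisible(x)
}

#' Propagate a stimulus through one weight solution
#'
#' Synchronous update for `steps` iterations: each non-clamped node's next
#' activity is the saturating-linear clamp to \[-1, 1\] of the weighted sum
#' of its incoming neighbours' activities. Clamped nodes hold their
#' stimulus value at every step; basal nodes start at their basal value but
#' are free; all other nodes start at 0.
#'
#' @param net a [protein_network()].
#' @param weights a [solution_weights()] object or a bare numeric vector of
#'   per-edge weights in \[-1, 1\], ordered as `net$edges`.
#' @param stim a [stimulus()].
#' @param steps number of synchronous update steps (>= 1).
#' @return Named numeric vector of activities in \[-1, 1\], one per network
#'   node (an activity profile).
#' @export
propagate <- function(net, weights, stim, steps = 3L) {
  stopifnot(inherits(net, "protein_network"), inherits(stim, "stimulus"))
  w <- if (inherits(weights, "solution_weights")) weights$weights else weights
  if (length(w) != nrow(net$edges))
    stop("weights must cover all ", nrow(net$edges), " edges")
  if (any(abs(w) > 1)) stop("edge weights must lie in [-1, 1]")
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be >= 1")
  absent <- setdiff(c(names(stim$clamped), names(stim$basal)), net$nodes)
  if (length(absent)) {
    stop("stimulus protein(s) absent from network: ",
         paste(absent, collapse = ", "))
  }
  act <- propagate_core(
    length(net$nodes),
    net$from_idx - 1L, net$to_idx - 1L, as.numeric(w),
    match(names(stim$clamped), net$nodes) - 1L, as.numeric(stim$clamped),
    match(names(stim$basal), net$nodes) - 1L, as.numeric(stim$basal),
    steps)
  setNames(act, net$nodes)
}

#' Ensemble-averaged activity profile
#'
#' Propagates the stimulus through every retained solution and returns the
#' per-protein arithmetic mean of the activities.
#'
#' @inheritParams propagate
#' @param ensemble a `moa_ensemble` (from [build_ensemble()]) or a list of [solution_weights()].
#' @return Named numeric vector of mean activities in \[-1, 1\].
#' @export
ensemble_profile <- function(net, ensemble, stim, steps = 3L) {
  sols <- if (inherits(ensemble, "moa_ensemble")) ensemble$solutions else ensemble
  if (!length(sols)) stop("ensemble is empty")
  acc <- numeric(length(net$nodes))
  for (s in sols) acc <- acc + propagate(net, s, stim, steps)
  setNames(acc / length(sols), net$nodes)
}

#' Write an activity profile as TSV
#'
#' @param profile named numeric vector of activities.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(
    data.frame(protein = names(profile), activity = as.numeric(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
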