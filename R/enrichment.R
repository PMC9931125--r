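#' Annotation collection
#'
#' A named family of gene/protein sets (GO-like terms, KEGG-like pathways)
#' used for over-representation analysis.
#'
#' @param terms named list of character vectors (term id -> protein set);
#'   every set non-empty, ids unique.
#' @param source label of the source database family.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(terms, source = "custom") {
  if (!length(terms) && !is.list(terms)) terms <- as.list(terms)
  if (is.null(names(terms)) && length(terms)) stop("terms must be named")
  if (anyDuplicated(names(terms))) stop("duplicate term identifiers")
  if (any(lengths(terms) == 0L)) stop("every term set must be non-empty")
  terms <- lapply(terms, function(x) unique(as.character(x)))
  structure(list(terms = terms, source = source),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection '", x$source, "': ", length(x$terms),
      " terms (sizes ", if (length(x$terms)) min(lengths(x$terms)) else 0,
      "-", if (length(x$terms)) max(lengths(x$terms)) else 0, ")\n", sep = "")
  invisible(x)
}

#' Read an annotation collection from GMT
#'
#' @param path GMT file path (term, description, tab-separated members).
#' @param source source label; defaults to the file name.
#' @return An [annotation_collection()].
#' @export
read_gmt <- function(path, source = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (is.null(source)) source <- sub("\\.gmt$", "", basename(path))
  annotation_collection(fgsea::gmtPathways(path), source = source)
}

#' Write an annotation collection as GMT
#'
#' @param coll an [annotation_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "annotation_collection"))
  writeLines(vapply(names(coll$terms), function(id) {
    paste(c(id, coll$source, coll$terms[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Split a profile into up- and down-regulated protein sets
#'
#' Up: activity >= `thr`; down: activity <= -`thr`. The sets are disjoint;
#' the boundary is inclusive on both sides.
#'
#' @param profile named numeric activity profile.
#' @param thr threshold, > 0 (default 0.1).
#' @return List with character vectors `up` and `down`.
#' @export
split_up_down <- function(profile, thr = 0.1) {
  stopifnot(thr > 0)
  list(up = names(profile)[profile >= thr],
       down = names(profile)[profile <= -thr])
}

#' Drop large annotation terms
#'
#' Terms whose set size is `max_size` or larger are removed (so at the
#' default 500, sets of size 500 are excluded and 499 retained), filtering
#' unspecific results. Idempotent.
#'
#' @param coll an [annotation_collection()].
#' @param max_size exclusion boundary (default 500).
#' @return The filtered [annotation_collection()].
#' @export
filter_collection <- function(coll, max_size = 500L) {
  stopifnot(inherits(coll, "annotation_collection"), max_size >= 1)
  coll$terms <- coll$terms[lengths(coll$terms) < max_size]
  coll
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least the actual overlap when drawing
#' |query| proteins without replacement from the universe, of which |term|
#' are successes. An empty query gives p = 1.
#'
#' @param query character vector (must be a subset of `universe`).
#' @param term character vector (must be a subset of `universe`).
#' @param universe character vector of all proteins under consideration.
#' @return Numeric p-value in (0, 1\].
#' @export
hypergeom_test <- function(query, term, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  query <- unique(query)
  term <- unique(term)
  if (length(setdiff(query, universe)) || length(setdiff(term, universe)))
    stop("query and term must be subsets of the universe")
  overlap <- length(intersect(query, term))
  phyper(overlap - 1L, length(term), length(universe) - length(term),
         length(query), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotonicity enforcement, invariant under
#' input permutation.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Up/down over-representation analysis of an activity profile
#'
#' Splits the profile into up- and down-regulated sets, filters each
#' collection by term size, tests every surviving term with the upper-tail
#' hypergeometric, and adjusts p-values by BH independently within each
#' (direction x collection) family. Terms significant in both directions
#' are flagged `modulated`.
#'
#' @param profile named numeric activity profile.
#' @param collections list of [annotation_collection()] objects (a single
#'   collection is accepted).
#' @param universe character vector of all proteins in the model's world
#'   (typically the network nodes); must cover the queried proteins.
#' @param thr up/down split threshold (default 0.1).
#' @param max_size term-size exclusion boundary (default 500).
#' @param alpha significance level on the q-value (default 0.05).
#' @return data.frame with columns `collection`, `direction`, `term`,
#'   `overlap`, `query_size`, `term_size`, `universe_size`, `p_value`,
#'   `q_value`, `significant`, `modulated`.
#' @export
enrich <- function(profile, collections, universe, thr = 0.1,
                   max_size = 500L, alpha = 0.05) {
  if (inherits(collections, "annotation_collection"))
    collections <- list(collections)
  universe <- unique(universe)
  sets <- split_up_down(profile, thr)
  out <- list()
  for (coll in collections) {
    coll <- filter_collection(coll, max_size)
    for (dir in c("up", "down")) {
      query <- intersect(sets[[dir]], universe)
      if (!length(query) || !length(coll$terms)) next
      p <- vapply(coll$terms, function(tm) {
        hypergeom_test(query, intersect(tm, universe), universe)
      }, numeric(1))
      q <- bh_adjust(p)
      out[[length(out) + 1L]] <- data.frame(
        collection = coll$source,
        direction = dir,
        term = names(coll$terms),
        overlap = vapply(coll$terms,
                         function(tm) length(intersect(query, tm)),
                         integer(1)),
        query_size = length(query),
        term_size = lengths(coll$terms),
        universe_size = length(universe),
        p_value = as.numeric(p),
        q_value = as.numeric(q),
        significant = q < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(collection = character(), direction = character(),
                      term = character(), overlap = integer(),
                      query_size = integer(), term_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      modulated = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  sig_by_dir <- split(res$term[res$significant], res$direction[res$significant])
  both_dirs <- intersect(sig_by_dir[["up"]], sig_by_dir[["down"]])
  res$modulated <- res$term %in% both_dirs
  rownames(res) <- NULL
  res
}
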