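#' Disease characterization: motives of signed effector proteins
#'
#' A motive is a pathophysiological process (e.g. an inflammatory cytokine
#' storm) described as a set of effector proteins, each with a disease sign:
#' +1 if the protein is increased/overactivated in the disease, -1 if
#' reduced/inhibited. Motives have a role: `response` motives define the
#' model outputs scored against drug effects, the `basal` motive describes
#' the patient's baseline state (its effectors initialise propagation), and
#' `context` motives are carried but not scored by default.
#'
#' @param motives list of motives, each a list with elements `name`
#'   (string), `role` (`"response"`, `"basal"` or `"context"`) and
#'   `effectors` (data.frame with columns `protein`, `sign`).
#' @return An object of class `disease_characterization` with the validated
#'   motive list; each motive gains `bed_p`, its effector count (the
#'   denominator of the weighted intensity score).
#' @export
disease_characterization <- function(motives) {
  if (!length(motives)) stop("characterization needs at least one motive")
  roles <- character(length(motives))
  for (i in seq_along(motives)) {
    m <- motives[[i]]
    if (is.null(m$name) || !nzchar(m$name)) stop("motive ", i, " has no name")
    if (!m$role %in% c("response", "basal", "context"))
      stop("motive '", m$name, "': role must be response, basal or context")
    eff <- m$effectors
    if (!is.data.frame(eff) || !all(c("protein", "sign") %in% names(eff)) ||
        nrow(eff) == 0L)
      stop("motive '", m$name, "' needs a non-empty effector table")
    eff$protein <- as.character(eff$protein)
    eff$sign <- as.integer(eff$sign)
    if (any(!nzchar(eff$protein))) stop("motive '", m$name, "': empty protein id")
    bad <- !eff$sign %in% c(-1L, 1L)
    if (any(bad))
      stop("motive '", m$name, "': disease sign must be +1 or -1 (protein ",
           eff$protein[which(bad)[1]], ")")
    if (anyDuplicated(eff$protein))
      stop("motive '", m$name, "': duplicate effector protein")
    eff <- eff[, c("protein", "sign")]
    rownames(eff) <- NULL
    motives[[i]]$effectors <- eff
    motives[[i]]$bed_p <- nrow(eff)
    roles[i] <- m$role
  }
  if (anyDuplicated(vapply(motives, `[[`, "", "name")))
    stop("duplicate motive names")
  if (!any(roles == "response"))
    stop("characterization needs at least one response motive")
  structure(list(motives = motives), class = "disease_characterization")
}

#' @export
print.disease_characterization <- function(x, ...) {
  cat("disease_characterization:", length(x$motives), "motives,",
      length(unique_effectors(x)), "unique effectors\n")
  for (m in x$motives) {
    cat(sprintf("  %-40s %-8s %3d effectors\n", m$name, m$role, m$bed_p))
  }
  invisible(x)
}

#' Read a disease characterization from TSV or JSON
#'
#' The TSV dialect has one row per (motive, protein) with header columns
#' `motive`, `role`, `protein`, `sign`. A `.json` file with the same fields
#' (array of row objects) is accepted as an alternative.
#'
#' @param path file path.
#' @return A [disease_characterization()].
#' @export
load_characterization <- function(path) {
  if (!file.exists(path)) stop("characterization file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("motive", "role", "protein", "sign")
  if (!all(need %in% names(df)))
    stop("characterization needs columns: ", paste(need, collapse = ", "))
  sg <- suppressWarnings(as.integer(df$sign))
  bad <- is.na(sg) | !sg %in% c(-1L, 1L)
  if (any(bad))
    stop("invalid disease sign '", df$sign[which(bad)[1]], "' at row ",
         which(bad)[1])
  dup <- duplicated(paste(df$motive, df$protein, sep = "\r"))
  if (any(dup))
    stop("duplicate (motive, protein) pair at row ", which(dup)[1], ": ",
         df$motive[which(dup)[1]], " / ", df$protein[which(dup)[1]])
  motives <- lapply(split(seq_len(nrow(df)), df$motive)[unique(df$motive)],
    function(rows) {
      list(name = df$motive[rows[1]],
           role = unique(df$role[rows])[1],
           effectors = data.frame(protein = df$protein[rows],
                                  sign = sg[rows],
                                  stringsAsFactors = FALSE))
    })
  names(motives) <- NULL
  disease_characterization(motives)
}

#' Write a disease characterization as TSV
#'
#' Inverse of [load_characterization()]: one row per (motive, protein).
#'
#' @param char a [disease_characterization()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(char, path) {
  stopifnot(inherits(char, "disease_characterization"))
  rows <- do.call(rbind, lapply(char$motives, function(m) {
    data.frame(motive = m$name, role = m$role,
               protein = m$effectors$protein, sign = m$effectors$sign,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unique effector proteins across motives
#'
#' Deduplicated union of all motive effector proteins; effectors shared by
#' several motives are counted once.
#'
#' @param char a [disease_characterization()].
#' @return Sorted character vector of protein identifiers.
#' @export
unique_effectors <- function(char) {
  stopifnot(inherits(char, "disease_characterization"))
  sort(unique(unlist(lapply(char$motives,
                            function(m) m$effectors$protein))))
}

#' Basal stimulus values from the characterization
#'
#' Signed values of every effector in `basal` motives, used to initialise
#' propagation to the patient's baseline state. On conflict across basal
#' motives the first occurrence wins.
#'
#' @param char a [disease_characterization()].
#' @return Named numeric vector (possibly empty).
#' @export
basal_values <- function(char) {
  stopifnot(inherits(char, "disease_characterization"))
  out <- numeric()
  for (m in char$motives) {
    if (m$role != "basal") next
    new <- setdiff(m$effectors$protein, names(out))
    keep <- m$effectors$protein %in% new
    out <- c(out, setNames(as.numeric(m$effectors$sign[keep]),
                           m$effectors$protein[keep]))
  }
  out
}

#' Drug profile: targets and bioflags
#'
#' Targets are proteins the drug acts on directly, with effect +1
#' (activation) or -1 (inhibition); they are clamped as the propagation
#' stimulus. Bioflags are proteins the drug is known to modulate downstream
#' without targeting directly; they are used as extra training constraints.
#'
#' @param name drug name.
#' @param targets data.frame with columns `protein`, `sign` (+1/-1).
#' @param bioflags data.frame with columns `protein`, `sign`; may be empty.
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(name, targets,
                         bioflags = data.frame(protein = character(),
                                               sign = integer())) {
  if (!nzchar(name)) stop("drug needs a name")
  check <- function(df, what) {
    df$protein <- as.character(df$protein)
    df$sign <- as.integer(df$sign)
    if (any(!df$sign %in% c(-1L, 1L))) stop(what, " sign must be +1 or -1")
    if (anyDuplicated(df$protein)) stop("duplicate ", what, " protein")
    df[, c("protein", "sign")]
  }
  if (!is.data.frame(targets) || nrow(targets) == 0L)
    stop("drug '", name, "' needs at least one target")
  targets <- check(targets, "target")
  bioflags <- check(bioflags, "bioflag")
  clash <- intersect(targets$protein, bioflags$protein)
  if (length(clash))
    stop("protein(s) listed both as target and bioflag: ",
         paste(clash, collapse = ", "))
  structure(list(name = name, targets = targets, bioflags = bioflags),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("drug_profile '", x$name, "': ", nrow(x$targets), " target(s), ",
      nrow(x$bioflags), " bioflag(s)\n", sep = "")
  invisible(x)
}

#' Read a drug profile from TSV
#'
#' Columns `kind` (`target` or `bioflag`), `protein`, `effect` (`act` or
#' `inh`, mapped to +1/-1).
#'
#' @param path file path.
#' @param name drug name; defaults to the file name without extension.
#' @return A [drug_profile()].
#' @export
load_drug_profile <- function(path, name = NULL) {
  if (!file.exists(path)) stop("drug profile not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kind", "protein", "effect")
  if (!all(need %in% names(df)))
    stop("drug profile needs columns: ", paste(need, collapse = ", "))
  bad <- !df$effect %in% c("act", "inh")
  if (any(bad))
    stop("unknown effect keyword '", df$effect[which(bad)[1]],
         "' at row ", which(bad)[1], " (expected act or inh)")
  bad_kind <- !df$kind %in% c("target", "bioflag")
  if (any(bad_kind))
    stop("unknown kind '", df$kind[which(bad_kind)[1]], "' at row ",
         which(bad_kind)[1])
  sg <- ifelse(df$effect == "act", 1L, -1L)
  drug_profile(
    name,
    targets = data.frame(protein = df$protein[df$kind == "target"],
                         sign = sg[df$kind == "target"],
                         stringsAsFactors = FALSE),
    bioflags = data.frame(protein = df$protein[df$kind == "bioflag"],
                          sign = sg[df$kind == "bioflag"],
                          stringsAsFactors = FALSE))
}

#' Write a drug profile as TSV
#'
#' @param drug a [drug_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drug_profile <- function(drug, path) {
  stopifnot(inherits(drug, "drug_profile"))
  rows <- rbind(
    data.frame(kind = "target", protein = drug$targets$protein,
               effect = ifelse(drug$targets$sign > 0, "act", "inh")),
    data.frame(kind = "bioflag", protein = drug$bioflags$protein,
               effect = ifelse(drug$bioflags$sign > 0, "act", "inh")))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truth-table rule constructor
#'
#' One training constraint: clamping the stimulus proteins at their signs
#' must drive the response proteins to their expected signs. `relation`
#' records whether the rule encodes a drug reversing a condition
#' (`treats`) or a stimulus inducing a condition (`causes`); expected
#' response signs are stored already resolved to the sign propagation
#' should produce.
#'
#' @param id rule identifier.
#' @param stimulus named numeric vector of +1/-1 clamp values.
#' @param response named numeric vector of expected +1/-1 response signs.
#' @param relation `"treats"` or `"causes"`.
#' @return An object of class `truth_rule`.
#' @export
truth_rule <- function(id, stimulus, response, relation = "causes") {
  if (!length(stimulus) || !length(response))
    stop("rule '", id, "': stimulus and response must be non-empty")
  if (!all(stimulus %in% c(-1, 1)) || !all(response %in% c(-1, 1)))
    stop("rule '", id, "': signs must be +1 or -1")
  if (!relation %in% c("treats", "causes"))
    stop("rule '", id, "': relation must be treats or causes")
  structure(list(id = as.character(id), relation = relation,
                 stimulus = stimulus, response = response),
            class = "truth_rule")
}

#' Read a truth table from TSV
#'
#' Long format, one row per (rule, side, protein): columns `rule_id`,
#' `relation`, `side` (`stimulus` or `response`), `protein`, `sign`.
#' When a network is supplied, proteins absent from it are dropped from
#' the rule with a warning, and a rule whose stimulus or response becomes
#' empty is dropped entirely.
#'
#' @param path file path.
#' @param net optional [protein_network()] to reconcile rules against.
#' @return List of [truth_rule()] objects.
#' @export
load_truth_table <- function(path, net = NULL) {
  if (!file.exists(path)) stop("truth table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("rule_id", "relation", "side", "protein", "sign")
  if (!nrow(df)) stop("truth table is empty: training is impossible")
  if (!all(need %in% names(df)))
    stop("truth table needs columns: ", paste(need, collapse = ", "))
  if (any(!df$side %in% c("stimulus", "response")))
    stop("side must be stimulus or response")
  sg <- suppressWarnings(as.integer(df$sign))
  if (any(is.na(sg) | !sg %in% c(-1L, 1L)))
    stop("invalid sign at row ", which(is.na(sg) | !sg %in% c(-1L, 1L))[1])
  rules <- lapply(split(seq_len(nrow(df)), df$rule_id)[unique(df$rule_id)],
    function(rows) {
      st <- rows[df$side[rows] == "stimulus"]
      rs <- rows[df$side[rows] == "response"]
      if (!length(st) || !length(rs)) {
        stop("rule '", df$rule_id[rows[1]],
             "' needs both stimulus and response rows")
      }
      truth_rule(df$rule_id[rows[1]],
                 stimulus = setNames(as.numeric(sg[st]), df$protein[st]),
                 response = setNames(as.numeric(sg[rs]), df$protein[rs]),
                 relation = df$relation[rows[1]])
    })
  names(rules) <- NULL
  if (!is.null(net)) rules <- reconcile_rules(rules, net)
  if (!length(rules)) stop("no usable truth-table rules: training is impossible")
  rules
}

#' Reconcile truth-table rules with network coverage
#'
#' Drops proteins absent from the network from each rule; drops a rule
#' entirely (with a warning) if its stimulus or response becomes empty.
#'
#' @param rules list of [truth_rule()].
#' @param net a [protein_network()].
#' @return Filtered list of rules.
#' @export
reconcile_rules <- function(rules, net) {
  kept <- list()
  n_dropped_prot <- 0L
  for (r in rules) {
    s_in <- names(r$stimulus) %in% net$nodes
    p_in <- names(r$response) %in% net$nodes
    n_dropped_prot <- n_dropped_prot + sum(!s_in) + sum(!p_in)
    r$stimulus <- r$stimulus[s_in]
    r$response <- r$response[p_in]
    if (length(r$stimulus) && length(r$response)) {
      kept[[length(kept) + 1L]] <- r
    } else {
      warning("rule '", r$id, "' dropped: no network coverage")
    }
  }
  if (n_dropped_prot)
    message(n_dropped_prot,
            " rule protein(s) absent from the network were dropped")
  kept
}

#' Write a truth table as TSV
#'
#' @param rules list of [truth_rule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(rules, path) {
  rows <- do.call(rbind, lapply(rules, function(r) {
    rbind(
      data.frame(rule_id = r$id, relation = r$relation, side = "stimulus",
                 protein = names(r$stimulus), sign = as.integer(r$stimulus)),
      data.frame(rule_id = r$id, relation = r$relation, side = "response",
                 protein = names(r$response), sign = as.integer(r$response)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
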