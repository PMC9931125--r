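#' Specification of a synthetic fixture
#'
#' Describes the complete synthetic study: network size and topology,
#' motive/effector layout, drugs and their planted targets, truth-table
#' size and noise, and the annotation collection. Defaults are desk-scale
#' counterparts of a realistic modelling study: a 200-node scale-free
#' network, 4 motives (3 response + 1 basal) of 5 effectors each, 2 drugs
#' with 3 targets each, and a 20-rule truth table.
#'
#' @param n_nodes number of proteins (>= m + 1).
#' @param m attachment parameter; every node after the first `m` attaches
#'   `m` out-edges, so a scale-free fixture has `m * (n_nodes - m)` edges.
#' @param model `"scale_free"` (preferential attachment, edges oriented
#'   new -> existing) or `"erdos_renyi"`.
#' @param n_motives number of motives; the last one is the basal motive.
#' @param effectors_per_motive effectors per motive.
#' @param n_drugs number of drugs.
#' @param targets_per_drug targets clamped per drug.
#' @param n_bioflags downstream bioflag constraints per drug.
#' @param n_rules total truth-table rules (one per drug + distractors).
#' @param n_terms random annotation terms (planted terms are added on
#'   top).
#' @param term_size_range integer range of random term sizes.
#' @param noise fraction of truth-table response signs flipped (eta, in
#'   \[0, 0.5)).
#' @param steps propagation depth used for planting and analysis.
#' @param seed base RNG seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 200L, m = 2L,
                         model = c("scale_free", "erdos_renyi"),
                         n_motives = 4L, effectors_per_motive = 5L,
                         n_drugs = 2L, targets_per_drug = 3L,
                         n_bioflags = 2L,
                         n_rules = 20L, n_terms = 30L,
                         term_size_range = pmin(c(5L, 40L), n_nodes),
                         noise = 0, steps = 3L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_nodes >= m + 1, m >= 1, n_motives >= 1,
            effectors_per_motive >= 1, n_drugs >= 1, targets_per_drug >= 1,
            n_bioflags >= 0, n_rules >= n_drugs, n_terms >= 0,
            length(term_size_range) == 2, term_size_range[1] >= 1,
            term_size_range[2] <= n_nodes, noise >= 0, noise < 0.5,
            steps >= 1)
  structure(list(n_nodes = as.integer(n_nodes), m = as.integer(m),
                 model = model, n_motives = as.integer(n_motives),
                 effectors_per_motive = as.integer(effectors_per_motive),
                 n_drugs = as.integer(n_drugs),
                 targets_per_drug = as.integer(targets_per_drug),
                 n_bioflags = as.integer(n_bioflags),
                 n_rules = as.integer(n_rules),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 noise = noise, steps = as.integer(steps),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic directed protein network
#'
#' Scale-free topology by preferential attachment: the first `m` nodes
#' form an edgeless seed, and every later node attaches `m` out-edges to
#' distinct existing nodes chosen with probability proportional to
#' degree + 1, giving `m * (n_nodes - m)` edges oriented new -> existing.
#' The Erdos-Renyi alternative draws directed edges at the density that
#' matches the same expected edge count. Each edge carries a prior
#' activation/inhibition sign. Deterministic given `seed`.
#'
#' @param spec a [fixture_spec()] (only `n_nodes`, `m`, `model` are used).
#' @param seed RNG seed; `NULL` continues from the current RNG state.
#' @param p_act probability that an edge's prior sign is activating.
#' @return A [protein_network()].
#' @export
generate_network <- function(spec, seed = spec$seed, p_act = 0.6) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_nodes
  m <- spec$m
  nodes <- sprintf("P%0*d", nchar(n), seq_len(n))
  if (spec$model == "scale_free") {
    deg <- rep(0L, n)
    from <- integer(0)
    to <- integer(0)
    for (j in (m + 1L):n) {
      existing <- seq_len(j - 1L)
      picks <- sample(existing, m, prob = deg[existing] + 1)
      from <- c(from, rep(j, m))
      to <- c(to, picks)
      deg[j] <- deg[j] + m
      deg[picks] <- deg[picks] + 1L
    }
  } else {
    p <- (m * (n - m)) / (n * (n - 1L))
    pairs <- which(matrix(runif(n * n) < p, n, n) &
                     !diag(TRUE, n), arr.ind = TRUE)
    from <- pairs[, 1L]
    to <- pairs[, 2L]
  }
  sign <- ifelse(runif(length(from)) < p_act, 1L, -1L)
  protein_network(
    data.frame(from = nodes[from], to = nodes[to], sign = sign,
               stringsAsFactors = FALSE),
    nodes = nodes)
}

#' Plant ground-truth mechanisms into a network
#'
#' Assigns a true weight to every edge (magnitude in \[0.5, 1\], sign from
#' the edge's prior), clamps each drug's randomly signed targets, and
#' propagates. Nodes responding with |activity| >= `act_min` become that
#' drug's planted effectors and bioflags; effector disease signs are set
#' opposite to the drug-induced signs, so the drug reverses them by
#' construction. Effectors are interleaved across motives (the last motive
#' is basal), and one shortest target-to-effector path per effector is
#' recorded as the planted mechanism.
#'
#' @param net a [protein_network()].
#' @param spec a [fixture_spec()].
#' @param seed RNG seed; `NULL` continues from the current RNG state.
#' @param act_min minimum |activity| for a node to be eligible as planted
#'   effector or bioflag.
#' @return List with `ground_truth` (elements `weights`, a
#'   [solution_weights()]; `planted_paths`, per-drug character vectors
#'   "A->B->C"; `effectors`, data.frame `protein`, `sign`, `drug`),
#'   `characterization` (a [disease_characterization()]) and `drugs`
#'   (list of [drug_profile()]).
#' @export
plant_ground_truth <- function(net, spec, seed = spec$seed + 1L,
                               act_min = 0.2) {
  stopifnot(inherits(net, "protein_network"), inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_total_eff <- spec$n_motives * spec$effectors_per_motive
  eff_per_drug <- ceiling(n_total_eff / spec$n_drugs)

  sg <- net$edges$sign
  sg[is.na(sg)] <- sample(c(-1L, 1L), sum(is.na(sg)), replace = TRUE)
  w_true <- sg * runif(nrow(net$edges), 0.5, 1)

  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE, vertices = net$nodes)
  reach <- vapply(
    igraph::ego(g, order = spec$steps, mode = "out", mindist = 1),
    length, integer(1))
  candidates <- net$nodes[reach >= 4L]
  if (length(candidates) < spec$n_drugs * spec$targets_per_drug)
    stop("network too sparse to place drug targets; increase n_nodes or m")

  for (try in seq_len(25L)) {
    taken <- character()
    drugs <- list()
    eff_rows <- list()
    paths <- list()
    ok <- TRUE
    targets_pool <- sample(candidates)
    for (d in seq_len(spec$n_drugs)) {
      tg <- targets_pool[seq_len(spec$targets_per_drug) +
                           (d - 1L) * spec$targets_per_drug]
      tg_sign <- sample(c(-1, 1), length(tg), replace = TRUE)
      prof <- propagate(net, w_true,
                        stimulus(clamped = setNames(tg_sign, tg)),
                        steps = spec$steps)
      cand <- setdiff(names(prof)[abs(prof) >= act_min],
                      c(targets_pool[seq_len(spec$n_drugs *
                                               spec$targets_per_drug)], taken))
      if (length(cand) < eff_per_drug + spec$n_bioflags) { ok <- FALSE; break }
      cand <- cand[order(-abs(prof[cand]))]
      eff <- cand[seq_len(eff_per_drug)]
      flags <- if (spec$n_bioflags)
        cand[eff_per_drug + seq_len(spec$n_bioflags)] else character()
      taken <- c(taken, eff, flags)
      name <- sprintf("drug%02d", d)
      drugs[[d]] <- drug_profile(
        name,
        targets = data.frame(protein = tg, sign = as.integer(tg_sign)),
        bioflags = data.frame(protein = flags,
                              sign = as.integer(sign(prof[flags]))))
      eff_rows[[d]] <- data.frame(
        protein = eff,
        sign = as.integer(-sign(prof[eff])),  # disease sign opposes the drug
        drug = name, stringsAsFactors = FALSE)
      sub <- igraph::subgraph_from_edges(
        g, igraph::E(g)[abs(w_true) >= 0.1], delete.vertices = FALSE)
      paths[[name]] <- vapply(eff, function(e) {
        best <- NULL
        for (t in tg) {
          sp <- suppressWarnings(
            igraph::shortest_paths(sub, from = t, to = e, mode = "out"))
          v <- sp$vpath[[1]]
          if (length(v) > 1 && (is.null(best) || length(v) < length(best)))
            best <- igraph::V(sub)$name[as.integer(v)]
        }
        if (is.null(best)) NA_character_ else paste(best, collapse = "->")
      }, "")
    }
    if (ok) break
  }
  if (!ok)
    stop("insufficient reachable nodes to plant ", n_total_eff,
         " effectors; enlarge the network or raise targets_per_drug")

  effectors <- do.call(rbind, eff_rows)
  effectors <- effectors[seq_len(min(nrow(effectors), n_total_eff)), ]
  # interleave drugs across motives so every motive mixes mechanisms
  ord <- order(rep(seq_len(eff_per_drug), spec$n_drugs)[seq_len(nrow(effectors))])
  effectors <- effectors[ord, ]
  motive_id <- rep(seq_len(spec$n_motives),
                   each = spec$effectors_per_motive)[seq_len(nrow(effectors))]
  motives <- lapply(seq_len(spec$n_motives), function(i) {
    rows <- effectors[motive_id == i, , drop = FALSE]
    list(name = sprintf("motive_%02d", i),
         role = if (i == spec$n_motives && spec$n_motives > 1) "basal"
                else "response",
         effectors = rows[, c("protein", "sign")])
  })
  list(ground_truth = list(weights = solution_weights(w_true),
                           planted_paths = paths,
                           effectors = effectors),
       characterization = disease_characterization(motives),
       drugs = drugs)
}

#' Generate a truth table from planted ground truth
#'
#' One `treats` rule per drug (targets as stimulus, planted effectors at
#' their reversed signs as response) plus distractor `causes` rules built
#' by propagating random stimuli through the true weights and recording
#' strongly responding proteins, so that every noiseless rule is complied
#' by the true weights while random weights score near chance. Each
#' response sign is then flipped independently with probability
#' `spec$noise`.
#'
#' @param net a [protein_network()].
#' @param ground_truth the `ground_truth` element of
#'   [plant_ground_truth()] output.
#' @param drugs list of [drug_profile()] from the same planting.
#' @param spec a [fixture_spec()].
#' @param seed RNG seed; `NULL` continues from the current RNG state.
#' @return List of [truth_rule()].
#' @export
generate_truth_table <- function(net, ground_truth, drugs, spec,
                                 seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  rules <- list()
  for (d in drugs) {
    eff <- ground_truth$effectors[ground_truth$effectors$drug == d$name, ]
    rules[[length(rules) + 1L]] <- truth_rule(
      paste0("treat_", d$name),
      stimulus = setNames(as.numeric(d$targets$sign), d$targets$protein),
      response = setNames(as.numeric(-eff$sign), eff$protein),
      relation = "treats")
  }
  n_distract <- spec$n_rules - length(rules)
  w <- ground_truth$weights
  guard <- 0L
  while (n_distract > 0L && guard < 200L) {
    guard <- guard + 1L
    stim_p <- sample(net$nodes, 2L)
    stim <- setNames(sample(c(-1, 1), 2L, replace = TRUE), stim_p)
    prof <- propagate(net, w, stimulus(clamped = stim), steps = spec$steps)
    cand <- setdiff(names(prof)[abs(prof) >= 0.25], stim_p)
    if (length(cand) < 2L) next
    resp_p <- if (length(cand) > 3L) sample(cand, 3L) else cand
    rules[[length(rules) + 1L]] <- truth_rule(
      sprintf("rule_%02d", length(rules)),
      stimulus = stim,
      response = setNames(as.numeric(sign(prof[resp_p])), resp_p),
      relation = "causes")
    n_distract <- n_distract - 1L
  }
  if (n_distract > 0L)
    warning("only ", length(rules), " of ", spec$n_rules,
            " rules generated; distractor stimuli rarely reach any node")
  if (spec$noise > 0) {
    for (i in seq_along(rules)) {
      flip <- runif(length(rules[[i]]$response)) < spec$noise
      rules[[i]]$response[flip] <- -rules[[i]]$response[flip]
    }
  }
  rules
}

#' Generate a synthetic annotation collection
#'
#' One planted term per drug (its planted effector set) plus `n_terms`
#' random terms with sizes drawn from `term_size_range`; when the network
#' has at least 500 nodes an oversized 500-protein term is included to
#' exercise the size-exclusion filter.
#'
#' @param net a [protein_network()].
#' @param ground_truth the `ground_truth` element of
#'   [plant_ground_truth()] output.
#' @param spec a [fixture_spec()].
#' @param seed RNG seed; `NULL` continues from the current RNG state.
#' @return An [annotation_collection()] with source `"synthetic"`.
#' @export
generate_annotations <- function(net, ground_truth, spec,
                                 seed = spec$seed + 3L) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  terms <- list()
  for (d in unique(ground_truth$effectors$drug)) {
    terms[[paste0("PLANTED_", d)]] <-
      ground_truth$effectors$protein[ground_truth$effectors$drug == d]
  }
  if (spec$n_terms > 0) {
    sizes <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]),
                    spec$n_terms, replace = TRUE)
    for (i in seq_len(spec$n_terms)) {
      terms[[sprintf("TERM_%03d", i)]] <- sample(net$nodes, sizes[i])
    }
  }
  if (spec$n_nodes >= 500L) {
    terms[["OVERSIZED_TERM"]] <- sample(net$nodes, 500L)
  }
  annotation_collection(terms, source = "synthetic")
}

#' Generate a complete synthetic fixture
#'
#' Chains [generate_network()], [plant_ground_truth()],
#' [generate_truth_table()] and [generate_annotations()] with seeds
#' derived from `spec$seed`, and verifies the construction guarantee that
#' the true weights reverse every planted effector of every drug.
#'
#' @param spec a [fixture_spec()].
#' @return A list of class `moa_fixture` with elements `network`,
#'   `ground_truth`, `characterization`, `drugs`, `rules`, `annotations`,
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  net <- generate_network(spec)
  planted <- plant_ground_truth(net, spec)
  rules <- generate_truth_table(net, planted$ground_truth, planted$drugs, spec)
  ann <- generate_annotations(net, planted$ground_truth, spec)
  for (d in planted$drugs) {
    eff <- planted$ground_truth$effectors
    eff <- eff[eff$drug == d$name, ]
    prof <- propagate(net, planted$ground_truth$weights, drug_stimulus(d),
                      steps = spec$steps)
    if (!all(is_reversed(prof[eff$protein], eff$sign)))
      stop("internal error: planted effectors of ", d$name,
           " are not all reversed by the true weights")
  }
  structure(list(network = net,
                 ground_truth = planted$ground_truth,
                 characterization = planted$characterization,
                 drugs = planted$drugs,
                 rules = rules,
                 annotations = ann,
                 spec = spec),
            class = "moa_fixture")
}

#' Deterministic characterization at literature scale
#'
#' A synthetic stand-in for a manually curated disease characterization:
#' `n_motives` motives over `n_proteins` unique effector proteins, of
#' which `n_shared` appear in two motives (so the row count exceeds the
#' unique count by `n_shared`). Three quarters of the signs are +1
#' (overactivated), the rest -1. Defaults give 4 motives, 70 rows and 66
#' unique proteins.
#'
#' @param n_proteins unique effector proteins.
#' @param n_motives number of motives (last one basal).
#' @param n_shared proteins duplicated into a second motive.
#' @param seed RNG seed.
#' @return A [disease_characterization()].
#' @export
synthetic_characterization <- function(n_proteins = 66L, n_motives = 4L,
                                       n_shared = 4L, seed = 42L) {
  stopifnot(n_motives >= 2, n_shared < n_proteins)
  set.seed(seed)
  prots <- sprintf("EFF%03d", seq_len(n_proteins))
  signs <- ifelse(runif(n_proteins) < 0.75, 1L, -1L)
  motive_of <- rep(seq_len(n_motives), length.out = n_proteins)
  motives <- lapply(seq_len(n_motives), function(i) {
    own <- which(motive_of == i)
    list(name = sprintf("motive_%02d", i),
         role = if (i == n_motives) "basal" else "response",
         effectors = data.frame(protein = prots[own], sign = signs[own]))
  })
  # duplicate the first n_shared proteins into the next motive over
  shared <- seq_len(n_shared)
  for (j in shared) {
    i <- motive_of[j] %% n_motives + 1L
    motives[[i]]$effectors <- rbind(
      motives[[i]]$effectors,
      data.frame(protein = prots[j], sign = signs[j]))
  }
  disease_characterization(motives)
}

#' Write a fixture directory
#'
#' Emits the complete fixture as plain-text files: `network.sif`,
#' `characterization.tsv`, one `drug_<name>.tsv` per drug,
#' `truth_table.tsv`, `annotations.gmt`, `ground_truth.json` and a
#' `manifest.json` recording the spec and seed.
#'
#' @param fixture a `moa_fixture` from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "moa_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_sif(fixture$network, file.path(dir, "network.sif"))
  write_characterization(fixture$characterization,
                         file.path(dir, "characterization.tsv"))
  for (d in fixture$drugs)
    write_drug_profile(d, file.path(dir, paste0("drug_", d$name, ".tsv")))
  write_truth_table(fixture$rules, file.path(dir, "truth_table.tsv"))
  write_gmt(fixture$annotations, file.path(dir, "annotations.gmt"))
  gt <- fixture$ground_truth
  jsonlite::write_json(
    list(weights = data.frame(from = fixture$network$edges$from,
                              to = fixture$network$edges$to,
                              weight = gt$weights$weights),
         planted_paths = gt$planted_paths,
         effectors = gt$effectors),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = fixture$spec$seed, spec = unclass(fixture$spec),
         package = "netmoa",
         version = as.character(utils::packageVersion("netmoa"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back
#'
#' @param dir directory written by [write_fixture()].
#' @return A list with `network`, `characterization`, `drugs`, `rules`,
#'   `annotations`, `ground_truth`, `spec` (spec fields as a plain list).
#' @export
load_fixture <- function(dir) {
  net <- suppressMessages(load_network(file.path(dir, "network.sif")))
  drug_files <- list.files(dir, pattern = "^drug_.*\\.tsv$", full.names = TRUE)
  drugs <- lapply(drug_files, function(f)
    load_drug_profile(f, name = sub("^drug_", "", sub("\\.tsv$", "",
                                                      basename(f)))))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gt_path)) {
    raw <- jsonlite::fromJSON(gt_path)
    gt <- list(weights = solution_weights(raw$weights$weight),
               planted_paths = raw$planted_paths,
               effectors = raw$effectors)
  }
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  list(network = net,
       characterization = load_characterization(
         file.path(dir, "characterization.tsv")),
       drugs = drugs,
       rules = load_truth_table(file.path(dir, "truth_table.tsv"), net = net),
       annotations = read_gmt(file.path(dir, "annotations.gmt"),
                              source = "synthetic"),
       ground_truth = gt,
       spec = manifest$spec)
}
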