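#' Training configuration
#'
#' Bundles every knob of ensemble training. Retained solutions must have
#' accuracy strictly above `retention_threshold` (default 0.9, i.e. the
#' "higher than 90%" validity filter); `target_size` (default 250) is the
#' number of retained solutions that constitutes the final model.
#'
#' @param retention_threshold minimum accuracy (strict) for a solution to
#'   be retained, in (0, 1).
#' @param target_size number of retained solutions sought (>= 1).
#' @param max_attempts maximum number of annealing runs before giving up.
#' @param iterations annealing iterations per solution.
#' @param t_init initial annealing temperature (accuracy units).
#' @param cooling geometric cooling factor per iteration, in (0, 1].
#' @param steps propagation steps per rule evaluation.
#' @param f per-rule compliance fraction: strictly more than `f` of a
#'   rule's response proteins must match for the rule to count.
#' @param epsilon minimum activity magnitude for a response (and for the
#'   effector reversal calls downstream).
#' @param seed base RNG seed; attempt k uses `seed + k`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(retention_threshold = 0.9,
                            target_size = 250L,
                            max_attempts = 2000L,
                            iterations = 2000L,
                            t_init = 0.25,
                            cooling = 0.999,
                            steps = 3L,
                            f = 0.5,
                            epsilon = 0.1,
                            seed = 1L) {
  stopifnot(retention_threshold > 0, retention_threshold < 1,
            target_size >= 1, max_attempts >= 1, iterations >= 0,
            t_init >= 0, cooling > 0, cooling <= 1,
            steps >= 1, f > 0, f <= 1, epsilon > 0)
  structure(list(retention_threshold = retention_threshold,
                 target_size = as.integer(target_size),
                 max_attempts = as.integer(max_attempts),
                 iterations = as.integer(iterations),
                 t_init = t_init, cooling = cooling,
                 steps = as.integer(steps), f = f, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Read a training configuration from YAML
#'
#' Keys mirror the arguments of [training_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A [training_config()].
#' @export
load_training_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(training_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(training_config, vals)
}

#' One link-weight solution
#'
#' @param weights numeric vector of per-edge weights in \[-1, 1\], ordered
#'   as the network's edge table.
#' @param accuracy fraction of truth-table rules complied, or `NA` if not
#'   yet evaluated.
#' @return An object of class `solution_weights`.
#' @export
solution_weights <- function(weights, accuracy = NA_real_) {
  weights <- as.numeric(weights)
  if (any(abs(weights) > 1)) stop("weights must lie in [-1, 1]")
  if (!is.na(accuracy) && (accuracy < 0 || accuracy > 1))
    stop("accuracy must lie in [0, 1]")
  structure(list(weights = weights, accuracy = accuracy),
            class = "solution_weights")
}

#' Attach drug bioflags as extra rule constraints
#'
#' For every rule whose stimulus equals a drug's target stimulus, the
#' drug's bioflags are appended to the rule's response set, so they count
#' in that rule's compliance fraction during training.
#'
#' @param rules list of [truth_rule()].
#' @param drugs list of [drug_profile()].
#' @return The rule list with augmented responses.
#' @export
attach_bioflags <- function(rules, drugs) {
  for (d in drugs) {
    if (!nrow(d$bioflags)) next
    tgt <- setNames(as.numeric(d$targets$sign), d$targets$protein)
    tgt <- tgt[order(names(tgt))]
    for (i in seq_along(rules)) {
      st <- rules[[i]]$stimulus[order(names(rules[[i]]$stimulus))]
      if (identical(names(st), names(tgt)) && all(st == tgt)) {
        extra <- setdiff(d$bioflags$protein, names(rules[[i]]$response))
        keep <- d$bioflags$protein %in% extra
        rules[[i]]$response <- c(
          rules[[i]]$response,
          setNames(as.numeric(d$bioflags$sign[keep]),
                   d$bioflags$protein[keep]))
      }
    }
  }
  rules
}

# Flatten rules to 0-based index form for the compiled evaluators.
flatten_rules <- function(net, rules) {
  lapply(rules, function(r) {
    si <- match(names(r$stimulus), net$nodes)
    ri <- match(names(r$response), net$nodes)
    if (anyNA(si) || anyNA(ri))
      stop("rule '", r$id, "' references proteins absent from the network; ",
           "run reconcile_rules() first")
    list(stim_idx = si - 1L, stim_val = as.numeric(r$stimulus),
         resp_idx = ri - 1L, resp_sign = as.numeric(r$response))
  })
}

#' Per-rule compliance predicate
#'
#' A rule is complied when strictly more than fraction `f` of its response
#' proteins show activity of the expected sign with magnitude at least
#' `epsilon`.
#'
#' @param profile named numeric activity profile covering the rule's
#'   response proteins.
#' @param rule a [truth_rule()].
#' @param f compliance fraction (default 0.5: a strict majority).
#' @param epsilon minimum activity magnitude (default 0.1).
#' @return Logical scalar.
#' @export
rule_complied <- function(profile, rule, f = 0.5, epsilon = 0.1) {
  stopifnot(inherits(rule, "truth_rule"))
  if (!length(rule$response)) stop("rule '", rule$id, "' has empty response")
  a <- profile[names(rule$response)]
  if (anyNA(a))
    stop("profile does not cover all response proteins of rule '",
         rule$id, "'")
  ok <- abs(a) >= epsilon & a * rule$response > 0
  sum(ok) > f * length(ok)
}

#' Accuracy of one solution against the truth table
#'
#' Propagates each rule's own stimulus (no basal state) and returns the
#' fraction of rules complied per [rule_complied()].
#'
#' @param net a [protein_network()].
#' @param weights a [solution_weights()] or numeric weight vector.
#' @param rules list of [truth_rule()].
#' @param config a [training_config()] supplying `steps`, `f`, `epsilon`.
#' @return Numeric scalar in \[0, 1\].
#' @export
solution_accuracy <- function(net, weights, rules, config = training_config()) {
  if (!length(rules)) stop("no rules to evaluate")
  complied <- vapply(rules, function(r) {
    prof <- propagate(net, weights, stimulus(clamped = r$stimulus),
                      steps = config$steps)
    rule_complied(prof, r, f = config$f, epsilon = config$epsilon)
  }, logical(1))
  mean(complied)
}

#' Sample one weight solution by simulated annealing
#'
#' Weights start uniform in \[-1, 1\] (restricted to the prior sign where
#' the network edge carries one); each iteration redraws one edge weight
#' uniformly within its allowed range and accepts by the Metropolis rule on
#' truth-table accuracy with geometric cooling. The best weights seen are
#' returned. Deterministic given `seed`.
#'
#' @inheritParams solution_accuracy
#' @param config a [training_config()].
#' @param seed integer seed for this run.
#' @return A [solution_weights()] with its accuracy attached.
#' @export
sample_solution <- function(net, rules, config = training_config(),
                            seed = config$seed) {
  if (!length(rules)) stop("no rules to train against")
  flat <- flatten_rules(net, rules)
  prior <- net$edges$sign
  prior[is.na(prior)] <- 0L
  set.seed(seed)
  res <- anneal_core(length(net$nodes),
                     net$from_idx - 1L, net$to_idx - 1L,
                     as.integer(prior), flat,
                     config$f, config$epsilon, config$steps,
                     config$iterations, config$t_init, config$cooling)
  solution_weights(res$weights, res$accuracy)
}

#' Build the model ensemble
#'
#' Repeatedly samples solutions (attempt k with seed `config$seed + k`) and
#' retains those with accuracy strictly above the retention threshold,
#' until `target_size` solutions are retained or `max_attempts` runs are
#' exhausted. The ensemble's accuracy is the mean of the retained
#' solutions' accuracies.
#'
#' @inheritParams solution_accuracy
#' @param config a [training_config()].
#' @param verbose print progress every 25 attempts.
#' @return An object of class `moa_ensemble`: list with `solutions`,
#'   `accuracies`, `mean_accuracy`, `retention_threshold`, `target_size`,
#'   `seed`, `n_attempts`.
#' @export
build_ensemble <- function(net, rules, config = training_config(),
                           verbose = FALSE) {
  solutions <- vector("list", config$target_size)
  n_kept <- 0L
  attempt <- 0L
  while (n_kept < config$target_size && attempt < config$max_attempts) {
    attempt <- attempt + 1L
    sol <- sample_solution(net, rules, config, seed = config$seed + attempt)
    if (sol$accuracy > config$retention_threshold) {
      n_kept <- n_kept + 1L
      solutions[[n_kept]] <- sol
    }
    if (verbose && attempt %% 25L == 0L)
      message("attempt ", attempt, ": ", n_kept, "/", config$target_size,
              " retained")
  }
  if (n_kept == 0L)
    stop("no solution exceeded accuracy ", config$retention_threshold,
         " in ", attempt, " attempts; lower the threshold or extend the ",
         "annealing schedule")
  if (n_kept < config$target_size)
    warning("only ", n_kept, " of ", config$target_size,
            " solutions retained after ", attempt, " attempts")
  solutions <- solutions[seq_len(n_kept)]
  accs <- vapply(solutions, `[[`, numeric(1), "accuracy")
  structure(list(solutions = solutions,
                 accuracies = accs,
                 mean_accuracy = mean(accs),
                 retention_threshold = config$retention_threshold,
                 target_size = config$target_size,
                 seed = config$seed,
                 n_attempts = attempt),
            class = "moa_ensemble")
}

#' @export
print.moa_ensemble <- function(x, ...) {
  cat("moa_ensemble:", length(x$solutions), "retained solution(s) (target",
      paste0(x$target_size, ","), x$n_attempts, "attempts)\n")
  cat(sprintf("  mean accuracy %.3f (min %.3f, threshold > %.2f)\n",
              x$mean_accuracy, min(x$accuracies), x$retention_threshold))
  invisible(x)
}

#' Write ensemble accuracies and weights as TSV
#'
#' Writes two files: `<prefix>_accuracies.tsv` (`solution_id`, `accuracy`)
#' and `<prefix>_weights.tsv` in long format (`solution_id`, `source`,
#' `target`, `weight`).
#'
#' @param ensemble a `moa_ensemble` (from [build_ensemble()]).
#' @param net the [protein_network()] the ensemble was trained on.
#' @param prefix output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ensemble <- function(ensemble, net, prefix) {
  stopifnot(inherits(ensemble, "moa_ensemble"))
  acc_path <- paste0(prefix, "_accuracies.tsv")
  w_path <- paste0(prefix, "_weights.tsv")
  ids <- seq_along(ensemble$solutions)
  write.table(data.frame(solution_id = ids, accuracy = ensemble$accuracies),
              acc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  n_e <- nrow(net$edges)
  long <- data.frame(
    solution_id = rep(ids, each = n_e),
    source = rep(net$edges$from, length(ids)),
    target = rep(net$edges$to, length(ids)),
    weight = unlist(lapply(ensemble$solutions, `[[`, "weights")))
  write.table(long, w_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(acc_path, w_path))
}
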