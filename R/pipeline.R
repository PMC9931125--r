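#' Write a reproducibility manifest
#'
#' @param dir output directory.
#' @param stage pipeline stage name.
#' @param seed the seed in effect.
#' @param params named list of parameters to record.
#' @return The manifest path, invisibly.
#' @keywords internal
write_manifest <- function(dir, stage, seed, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(
    list(stage = stage, seed = seed, params = params,
         package = "netmoa",
         version = as.character(utils::packageVersion("netmoa"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline stage: generate and write a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory.
#' @return The fixture, invisibly.
#' @export
run_simulate <- function(spec = fixture_spec(), outdir) {
  fixture <- generate_fixture(spec)
  write_fixture(fixture, outdir)
  write_manifest(outdir, "simulate", spec$seed, unclass(spec))
  invisible(fixture)
}

#' Pipeline stage: train the model ensemble on a fixture directory
#'
#' Loads the network, truth table and drug profiles, attaches bioflag
#' constraints to the drug rules, builds the ensemble and writes
#' per-solution accuracies and long-format weights.
#'
#' @param fixture_dir directory written by [run_simulate()] /
#'   [write_fixture()].
#' @param config a [training_config()].
#' @param outdir output directory.
#' @param verbose passed to [build_ensemble()].
#' @return The [build_ensemble()] result, invisibly.
#' @export
run_train <- function(fixture_dir, config = training_config(), outdir,
                      verbose = FALSE) {
  fx <- load_fixture(fixture_dir)
  rules <- attach_bioflags(fx$rules, fx$drugs)
  ens <- build_ensemble(fx$network, rules, config, verbose = verbose)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_ensemble(ens, fx$network, file.path(outdir, "ensemble"))
  write_manifest(outdir, "train", config$seed, unclass(config))
  invisible(ens)
}

#' Pipeline stage: per-drug and combination analysis
#'
#' Computes ensemble activity profiles for every drug and for the first
#' drug pair's combination (all with the basal motive initialised), then
#' writes the motive impact table, the per-motive synergy calls, the
#' effector heatmap table and each treatment's MoA subgraph.
#'
#' @param fixture_dir fixture directory.
#' @param ensemble a `moa_ensemble` (e.g. from [run_train()]).
#' @param outdir output directory.
#' @param steps propagation depth.
#' @param epsilon reversal magnitude threshold.
#' @param moa_k number of top MoA paths per treatment.
#' @return List with `profiles` (named list of activity profiles),
#'   `impacts`, `synergy`, `heatmap`, `moa` (named list of subgraphs),
#'   invisibly.
#' @export
run_analyze <- function(fixture_dir, ensemble, outdir, steps = 3L,
                        epsilon = 0.1, moa_k = 10L) {
  fx <- load_fixture(fixture_dir)
  char <- fx$characterization
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  profiles <- list()
  impacts <- list()
  moas <- list()
  for (d in fx$drugs) {
    prof <- ensemble_profile(fx$network, ensemble, drug_stimulus(d, char),
                             steps = steps)
    profiles[[d$name]] <- prof
    write_profile(prof, file.path(outdir, paste0("profile_", d$name, ".tsv")))
    imp <- impact_table(prof, char, epsilon = epsilon)
    impacts[[d$name]] <- cbind(treatment = d$name, imp)
    moa <- extract_moa(fx$network, ensemble, d$targets$protein,
                       unique_effectors(char), k = moa_k,
                       epsilon = epsilon, steps = steps)
    moas[[d$name]] <- moa
    write_moa(moa, file.path(outdir, paste0("moa_", d$name, ".sif")),
              file.path(outdir, paste0("moa_", d$name, "_support.tsv")))
  }

  synergy <- NULL
  if (length(fx$drugs) >= 2L) {
    a <- fx$drugs[[1]]
    b <- fx$drugs[[2]]
    combo_name <- paste(a$name, b$name, sep = "+")
    stim_ab <- combination_stimulus(a, b, char)
    prof_ab <- ensemble_profile(fx$network, ensemble, stim_ab, steps = steps)
    profiles[[combo_name]] <- prof_ab
    write_profile(prof_ab,
                  file.path(outdir, paste0("profile_", combo_name, ".tsv")))
    impacts[[combo_name]] <- cbind(treatment = combo_name,
                                   impact_table(prof_ab, char,
                                                epsilon = epsilon))
    syn_rows <- lapply(Filter(function(m) m$role == "response", char$motives),
      function(m) {
        wa <- impacts[[a$name]]$w_signal[impacts[[a$name]]$motive == m$name]
        wb <- impacts[[b$name]]$w_signal[impacts[[b$name]]$motive == m$name]
        wab <- impacts[[combo_name]]$w_signal[
          impacts[[combo_name]]$motive == m$name]
        cbind(motive = m$name, assess_synergy(wa, wb, wab))
      })
    synergy <- do.call(rbind, syn_rows)
    write.table(synergy, file.path(outdir, "synergy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    heat <- effector_heatmap_table(profiles[[a$name]], profiles[[b$name]],
                                   char)
    write.table(heat, file.path(outdir, "effector_heatmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    heat <- NULL
  }
  all_impacts <- do.call(rbind, impacts)
  rownames(all_impacts) <- NULL
  write_impact_table(all_impacts, file.path(outdir, "motive_impacts.tsv"))
  write_manifest(outdir, "analyze", NA,
                 list(steps = steps, epsilon = epsilon, moa_k = moa_k))
  invisible(list(profiles = profiles, impacts = all_impacts,
                 synergy = synergy, heatmap = heat, moa = moas))
}

#' Pipeline stage: up/down enrichment of the drug profiles
#'
#' @param fixture_dir fixture directory (supplies the annotation
#'   collection and the network universe).
#' @param profiles named list of activity profiles (from [run_analyze()]).
#' @param outdir output directory.
#' @param thr up/down split threshold.
#' @param max_size term-size exclusion boundary.
#' @return Named list of enrichment data.frames, invisibly.
#' @export
run_enrich <- function(fixture_dir, profiles, outdir, thr = 0.1,
                       max_size = 500L) {
  fx <- load_fixture(fixture_dir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (nm in names(profiles)) {
    res <- enrich(profiles[[nm]], fx$annotations, fx$network$nodes,
                  thr = thr, max_size = max_size)
    out[[nm]] <- res
    write.table(res, file.path(outdir, paste0("enrichment_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(outdir, "enrich", NA,
                 list(thr = thr, max_size = max_size))
  invisible(out)
}

#' Run the whole pipeline: simulate, train, analyze, enrich
#'
#' @param spec a [fixture_spec()].
#' @param config a [training_config()].
#' @param outdir root output directory; stages write into
#'   `fixture/`, `train/`, `analyze/`, `enrich/` subdirectories.
#' @param verbose print training progress.
#' @return List with `fixture`, `ensemble`, `analysis`, `enrichment`,
#'   invisibly.
#' @export
run_all <- function(spec = fixture_spec(), config = training_config(),
                    outdir, verbose = FALSE) {
  fix_dir <- file.path(outdir, "fixture")
  fixture <- run_simulate(spec, fix_dir)
  ensemble <- run_train(fix_dir, config, file.path(outdir, "train"),
                        verbose = verbose)
  analysis <- run_analyze(fix_dir, ensemble, file.path(outdir, "analyze"),
                          steps = config$steps, epsilon = config$epsilon)
  enrichment <- run_enrich(fix_dir, analysis$profiles,
                           file.path(outdir, "enrich"))
  invisible(list(fixture = fixture, ensemble = ensemble,
                 analysis = analysis, enrichment = enrichment))
}
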