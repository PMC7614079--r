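# FNV-1a hash of a deparsed R object; a short stable fingerprint embedded in
# reports so outputs can be traced to the exact configuration that made them.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Nested list of every tunable of the analysis pipeline with its default.
#' Unknown keys are rejected by [run_pipeline()], so typos fail loudly
#' before any computation.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    fjc = list(kuhn_length_nm = 1.1, thermal_energy_pNnm = 4.11),
    simulate = list(enabled = TRUE, states = "i", duration_s = 200,
                    force_pN = 8.5, seed = 1L, sampling_rate_hz = 1000,
                    baseline_sd_nm = 0.85,
                    transition_path_duration_s = 0),
    input = list(trajectory_path = NULL),
    idealize = list(k_levels = 2L, min_dwell_samples = 3L,
                    max_fit_samples = 1e5),
    fluctuation = list(reference_label = "N", reference_lc_nm = NULL),
    kinetics = list(pu_window = 10L, high_cut = 0.8, low_cut = 0.6,
                    min_windows = 3L),
    landscape = list(enabled = TRUE, psf_sd_nm = 0.85, bin_width_nm = 0.25,
                     iterations = 500L, relaxation = 1.0, floor = 1e-8),
    structures = list(enabled = TRUE, n_residues = 110L,
                      nm_per_residue = 0.4)
  ), class = "pipeline_config")
}

.validate_config <- function(cfg, ref = default_config(), path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(cfg[[k]]) && is.list(cfg[[k]]))
      .validate_config(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

# deep-merge user keys onto the defaults
.merge_config <- function(user, ref = default_config()) {
  for (k in names(user)) {
    if (is.list(ref[[k]]) && is.list(user[[k]]))
      ref[[k]] <- .merge_config(user[[k]], ref[[k]])
    else ref[[k]] <- user[[k]]
  }
  ref
}

#' Build a pipeline configuration
#'
#' Merges user overrides onto [default_config()], rejecting unknown keys.
#'
#' @param ... Named top-level sections, each a list of overrides, e.g.
#'   `simulate = list(duration_s = 500)`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  .validate_config(user)
  structure(.merge_config(user), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides (same structure as
#'   [default_config()]); unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  .validate_config(user)
  structure(.merge_config(user), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> idealize -> fluctuation analysis ->
#' kinetics -> landscape -> structural hypotheses on one recording, and
#' writes the reports as tab-separated tables plus a JSON metadata block
#' (seed, configuration hash, per-stage counts). Every stage failure aborts
#' with the stage name.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory for the reports (created if missing);
#'   `NULL` skips writing and just returns the results.
#' @return Invisible list with `trajectory`, `idealization`, `fragments`,
#'   `summary`, `transition_table`, `pu_series`, `landscape`, `structures`,
#'   `metadata`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  .validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- fjc_params(config$fjc$kuhn_length_nm, config$fjc$thermal_energy_pNnm)

  traj <- stage("simulate/input", {
    if (isTRUE(config$simulate$enabled)) {
      net <- talin_network(config$simulate$states)
      path <- simulate_state_path(net, config$simulate$duration_s,
                                  force_pN = config$simulate$force_pN,
                                  initial = "F",
                                  seed = config$simulate$seed)
      render_trajectory(path, observation_spec(
        sampling_rate_hz = config$simulate$sampling_rate_hz,
        baseline_sd_nm = config$simulate$baseline_sd_nm,
        transition_path_duration_s = config$simulate$transition_path_duration_s),
        conformations = net$conformations,
        seed = config$simulate$seed + 1L)
    } else {
      if (is.null(config$input$trajectory_path))
        stop("no input trajectory and simulation disabled")
      read_trajectory(config$input$trajectory_path)
    }
  })

  ideal <- stage("idealize", {
    th <- estimate_levels(traj, k_levels = config$idealize$k_levels,
                          max_samples = config$idealize$max_fit_samples)
    label_and_excise(traj, th, min_dwell = config$idealize$min_dwell_samples)
  })

  force <- stats::median(traj$force_pN)
  frag <- stage("fluctuation", fragment_statistics(
    ideal, traj, reference_label = config$fluctuation$reference_label))
  summ <- stage("fluctuation", summarize_state(
    frag, force = force, params = params,
    reference_Lc = config$fluctuation$reference_lc_nm))

  tt <- stage("kinetics", build_transition_table(ideal))
  pu <- stage("kinetics", tryCatch(
    running_unfolded_fraction(ideal, n = config$kinetics$pu_window,
                              folded_label = config$fluctuation$reference_label),
    warning = function(w) NULL))

  ls <- NULL
  if (isTRUE(config$landscape$enabled)) {
    ls <- stage("landscape", reconstruct_landscape(
      traj$extension_nm, psf = config$landscape$psf_sd_nm,
      bin_width_nm = config$landscape$bin_width_nm,
      iterations = config$landscape$iterations,
      relaxation = config$landscape$relaxation,
      floor = config$landscape$floor))
  }

  st <- NULL
  if (isTRUE(config$structures$enabled)) {
    st <- stage("structures", {
      topo <- helix_topology(n_residues = config$structures$n_residues,
                             nm_per_residue = config$structures$nm_per_residue)
      cfgs <- enumerate_configs(topo, force = force, params = params)
      non_ref <- summ[summ$label != attr(summ, "reference_label") &
                        is.finite(summ$lc_nm), , drop = FALSE]
      ranked <- lapply(seq_len(nrow(non_ref)), function(i)
        cbind(conformation = non_ref$label[i],
              rank_against_measurement(cfgs, non_ref[i, ])))
      if (length(ranked)) do.call(rbind, ranked) else NULL
    })
  }

  meta <- list(seed = config$simulate$seed,
               config_hash = .config_hash(unclass(config)),
               n_samples = nrow(traj),
               n_dwells = sum(ideal$segments$label != "TP"),
               force_pN = force)

  out <- list(trajectory = traj, idealization = ideal, fragments = frag,
              summary = summ, transition_table = tt, pu_series = pu,
              landscape = ls, structures = st, metadata = meta)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) data.table::fwrite(
      as.data.frame(df), file.path(out_dir, name), sep = "\t")
    write_idealization(ideal, file.path(out_dir, "segments.tsv"))
    wr(summ, "state_summary.tsv")
    wr(tt, "transition_table.tsv")
    if (!is.null(pu) && nrow(pu)) wr(pu, "unfolded_fraction.tsv")
    if (!is.null(ls))
      wr(data.frame(z_nm = ls$grid_nm, G_kT = ls$free_energy_kT,
                    density = ls$density), "landscape.tsv")
    if (!is.null(st)) wr(st, "structure_hypotheses.tsv")
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
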