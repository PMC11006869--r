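#' Run a pipeline stage from a configuration
#'
#' Single entry point binding the analysis stages together: validates a
#' hierarchical configuration (unknown keys are rejected), dispatches to
#' the corresponding library function, writes the stage artifacts plus a
#' provenance record (config, package version, seed) into `output_dir`,
#' and returns the artifact paths. Every subcommand is a thin wrapper over
#' an exported function, so library calls behave identically.
#'
#' Subcommands and their parameter keys:
#' \describe{
#'   \item{`simulate-ta`}{`noise_sigma`, `time_start`, `time_end`,
#'     `linear_end`, `points_per_decade`, `wl_start`, `wl_end`, `wl_step`}
#'   \item{`patterns`}{`residues`, `n_orientations`, `max_protonated`}
#'   \item{`classify`}{`msa` (FASTA path), `reference_id`, `anchors`,
#'     `motif`, `subgroup_position`, `min_length`, `identity_threshold`}
#'   \item{`lda`}{`input` (transient CSV), `tau_start`, `tau_end`, `n_tau`,
#'     `alpha_min`, `alpha_max`, `n_alpha`, `mode`}
#'   \item{`fit-pka`}{`input` (CSV pH,observable), `n_transitions`}
#'   \item{`fit-hill`}{`input` (CSV conc,amplitude)}
#'   \item{`fit-toff`}{`input` (CSV time,current), `start_index`}
#'   \item{`iv60`}{`input` (CSV voltage,current), `v_target`}
#'   \item{`select-model`}{`table` (CSV), `experimental_ev`,
#'     `tolerance_ev`, `required_proton_count`}
#'   \item{`struct-dist`}{`model`, `sel_a`, `sel_b`}
#'   \item{`struct-rmsd`}{`a`, `b`, `atoms`}
#' }
#'
#' @param config Named list with `subcommand`, optional `seed` (default 1),
#'   optional `verbosity`, and `params` (stage parameters).
#' @param output_dir Directory for artifacts (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths) and `result` (the in-memory stage result).
#' @export
ndq_run <- function(config, output_dir = ".") {
  allowed_top <- c("subcommand", "seed", "verbosity", "params")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra)) abort(paste("unknown config keys:", paste(extra, collapse = ", ")))
  sub <- config$subcommand %||% abort("config$subcommand is required")
  seed <- as.integer(config$seed %||% 1L)
  params <- config$params %||% list()
  allowed <- list(
    "simulate-ta" = c("noise_sigma", "time_start", "time_end", "linear_end",
                      "points_per_decade", "wl_start", "wl_end", "wl_step"),
    "patterns" = c("residues", "n_orientations", "max_protonated"),
    "classify" = c("msa", "reference_id", "anchors", "motif",
                   "subgroup_position", "min_length", "identity_threshold"),
    "lda" = c("input", "tau_start", "tau_end", "n_tau", "alpha_min",
              "alpha_max", "n_alpha", "mode"),
    "fit-pka" = c("input", "n_transitions"),
    "fit-hill" = "input",
    "fit-toff" = c("input", "start_index"),
    "iv60" = c("input", "v_target"),
    "select-model" = c("table", "experimental_ev", "tolerance_ev",
                       "required_proton_count"),
    "struct-dist" = c("model", "sel_a", "sel_b"),
    "struct-rmsd" = c("a", "b", "atoms"))
  if (!sub %in% names(allowed)) abort(paste("unknown subcommand:", sub))
  extra <- setdiff(names(params), allowed[[sub]])
  if (length(extra)) abort(paste0("unknown keys for '", sub, "': ",
                                  paste(extra, collapse = ", ")))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  art <- function(f) file.path(output_dir, f)
  artifacts <- character(0)

  result <- switch(sub,
    "simulate-ta" = {
      cfg <- do.call(simulation_config, c(list(seed = seed), params))
      ds <- simulate_transient_dataset(default_photocycle(), cfg)
      write_transient_csv(ds, art("transient.csv"))
      artifacts <- c(art("transient.csv"), art("transient.csv.json"))
      ds
    },
    "patterns" = {
      pats <- do.call(enumerate_patterns, params)
      utils::write.csv(pats, art("patterns.csv"), row.names = FALSE)
      artifacts <- art("patterns.csv")
      pats
    },
    "classify" = {
      recs <- read_fasta(params$msa)
      aln <- ref_alignment(recs, reference_id = params$reference_id %||% "REF")
      spec <- motif_spec(positions = params$anchors %||% c(109, 112, 116, 123, 251, 216),
                         allowed_letters = params$motif %||% "RNDQDK")
      rep_ <- classify_ndq(aln, spec,
                           subgroup_position = params$subgroup_position %||% 74,
                           min_length = params$min_length %||% 250,
                           identity_threshold = params$identity_threshold %||% 0.9)
      utils::write.table(rep_, art("report.tsv"), sep = "\t", row.names = FALSE,
                         quote = FALSE)
      artifacts <- art("report.tsv")
      rep_
    },
    "lda" = {
      ds <- read_transient_csv(params$input)
      grid <- if (!is.null(params$tau_start)) {
        end <- params$tau_end %||% (3 * max(ds$times))
        build_lifetime_grid(params$tau_start, end, n = params$n_tau %||% 200)
      } else NULL
      ldm <- compute_ldm(ds, grid = grid,
                         alpha_min = params$alpha_min %||% 0.01,
                         alpha_max = params$alpha_max %||% 5,
                         n_alpha = params$n_alpha %||% 200,
                         mode = params$mode %||% "per-wavelength")
      write_ldm_csv(ldm, art("ldm.csv"))
      artifacts <- c(art("ldm.csv"), art("ldm.csv.json"))
      ldm
    },
    "fit-pka" = {
      df <- as_tibble(utils::read.csv(params$input))
      f <- fit_multi_pka(df, n_transitions = params$n_transitions %||% 2)
      jsonlite::write_json(list(converged = f$converged,
                                coefficients = if (f$converged) f$coefficients,
                                residual_rms = if (f$converged) f$residual_rms),
                           art("pka_fit.json"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      artifacts <- art("pka_fit.json")
      f
    },
    "fit-hill" = {
      df <- as_tibble(utils::read.csv(params$input))
      f <- fit_hill(df)
      jsonlite::write_json(list(K_half = f$K_half, n_hill = f$n_hill,
                                y_max = f$y_max, residual_rms = f$residual_rms),
                           art("hill_fit.json"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      artifacts <- art("hill_fit.json")
      f
    },
    "fit-toff" = {
      df <- utils::read.csv(params$input)
      f <- fit_monoexp(df[[1]], df[[2]], start_index = params$start_index %||% 1)
      jsonlite::write_json(list(converged = f$converged,
                                t_off = if (f$converged) f$t_off,
                                amplitude = if (f$converged) f$amplitude,
                                offset = if (f$converged) f$offset),
                           art("toff_fit.json"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      artifacts <- art("toff_fit.json")
      f
    },
    "iv60" = {
      df <- utils::read.csv(params$input)
      val <- extract_current_at(df[[1]], df[[2]], v_target = params$v_target %||% 60)
      jsonlite::write_json(list(v_target = params$v_target %||% 60, current = val),
                           art("iv.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- art("iv.json")
      val
    },
    "select-model" = {
      tab <- as_tibble(utils::read.csv(params$table))
      sel <- select_consistent_model(tab, params$experimental_ev,
                                     tolerance_ev = params$tolerance_ev %||% 0.3,
                                     required_proton_count = params$required_proton_count)
      jsonlite::write_json(list(consistent = sel$consistent, chosen = sel$chosen,
                                shortlist = sel$shortlist),
                           art("model_selection.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      artifacts <- art("model_selection.json")
      sel
    },
    "struct-dist" = {
      m <- read_structure(params$model)
      d <- min_distance(m, params$sel_a, params$sel_b)
      jsonlite::write_json(as.list(d), art("distance.json"), auto_unbox = TRUE,
                           digits = NA)
      artifacts <- art("distance.json")
      d
    },
    "struct-rmsd" = {
      sp <- kabsch_rmsd(read_structure(params$a), read_structure(params$b),
                        selection = list(elety = params$atoms %||% "CA"))
      jsonlite::write_json(list(rmsd = sp$rmsd, n_atoms = sp$n_atoms),
                           art("rmsd.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- art("rmsd.json")
      sp
    })

  prov <- list(subcommand = sub, seed = seed, params = params,
               package_version = as.character(utils::packageVersion("ndqkit")))
  jsonlite::write_json(prov, art("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, art("provenance.json"))
  if (isTRUE(config$verbosity %||% FALSE)) {
    message(sprintf("[ndqkit] %s -> %s", sub, paste(artifacts, collapse = ", ")))
  }
  invisible(list(status = 0L, artifacts = artifacts, result = result))
}

#' @rdname ndq_run
#' @param path YAML configuration file.
#' @param overrides Named list merged over the file values.
#' @export
ndq_run_file <- function(path, overrides = list(), output_dir = ".") {
  config <- yaml::read_yaml(path)
  config[names(overrides)] <- overrides
  ndq_run(config, output_dir = output_dir)
}
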