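# Serialization of the pipeline's inputs and outputs: parameter-spec CSV,
# constraint CSV/YAML, condition YAML, evaluation JSON, GA-run artifacts and
# run manifests.  CSV dialect: comma-separated, UTF-8, "." decimal, header
# row mandatory.

#' Read a parameter specification CSV
#'
#' Columns \code{name,reference,class,lower,upper}; empty bounds are filled
#' with the class defaults.
#'
#' @param path file path.
#' @return A \code{\link{param_spec}} table.
#' @export
read_param_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "reference", "class")
  if (!all(need %in% names(df)))
    stop("parameter spec CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lower <- if ("lower" %in% names(df)) df$lower else NA_real_
  upper <- if ("upper" %in% names(df)) df$upper else NA_real_
  param_spec(df$name, df$reference, df$class, lower, upper)
}

#' Write a parameter specification CSV
#' @param specs a \code{\link{param_spec}} table; an optional
#'   \code{estimated} column is preserved.
#' @param path file path.
#' @export
write_param_specs <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

collapse_num <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = ";")

#' Read training constraints from CSV or YAML
#'
#' CSV columns: \code{constraint_id,condition_id,variable,kind,times,values,
#' epsilon} with semicolon-separated \code{times}/\code{values}.  A YAML
#' file holds a list of mappings with the same fields.
#'
#' @param path file path (.csv or .yaml/.yml).
#' @return List of \code{\link{training_constraint}}s.
#' @export
read_constraints <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(times = "character",
                                         values = "character"))
    entries <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  lapply(entries, function(e) {
    times <- e$times
    values <- e$values
    if (is.character(times)) times <- parse_times(times)
    if (is.character(values)) values <- parse_times(values)
    training_constraint(e$constraint_id, e$condition_id, e$variable, e$kind,
                        times = times, values = values,
                        epsilon = as.numeric(e$epsilon))
  })
}

#' Write training constraints to CSV
#' @param constraints list of \code{\link{training_constraint}}s.
#' @param path file path.
#' @export
write_constraints <- function(constraints, path) {
  df <- do.call(rbind, lapply(constraints, function(cn) {
    data.frame(constraint_id = cn$constraint_id,
               condition_id = cn$condition_id, variable = cn$variable,
               kind = cn$kind, times = collapse_num(cn$times),
               values = collapse_num(cn$values), epsilon = cn$epsilon)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experimental condition from YAML
#'
#' Schema: \code{condition_id}; \code{physics} block with \code{mode},
#' \code{delta_psi_mV}, \code{temperature_K}, \code{ph_ext}, \code{ph_int};
#' \code{nhx_ext} as scalar or list of \code{[t, value]} steps; \code{pka};
#' \code{initial_state} map; \code{tau0}; optional \code{glnk_present}.
#'
#' @param path file path.
#' @return A \code{\link{toy_condition}}.
#' @export
read_condition <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$physics
  phys <- transport_physics(mode = ph$mode,
                            delta_psi = ph$delta_psi_mV %||% -150,
                            temperature = ph$temperature_K %||% 310,
                            ph_ext = ph$ph_ext %||% 7.0,
                            ph_int = ph$ph_int %||% 7.6)
  nhx <- y$nhx_ext
  if (is.list(nhx)) nhx <- do.call(rbind, lapply(nhx, as.numeric))
  toy_condition(y$condition_id, phys, nhx, pka = y$pka %||% 9.25,
                initial_state = unlist(y$initial_state),
                tau0 = y$tau0 %||% 60,
                glnk_present = y$glnk_present %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experimental condition to YAML
#' @param condition a \code{\link{toy_condition}}.
#' @param path file path.
#' @export
write_condition <- function(condition, path) {
  nhx <- condition$nhx_ext
  if (is.matrix(nhx)) nhx <- lapply(seq_len(nrow(nhx)), function(i) nhx[i, ])
  y <- list(condition_id = condition$condition_id,
            physics = list(mode = condition$physics$mode,
                           delta_psi_mV = condition$physics$delta_psi,
                           temperature_K = condition$physics$temperature,
                           ph_ext = condition$physics$ph_ext,
                           ph_int = condition$physics$ph_int),
            nhx_ext = nhx, pka = condition$pka,
            initial_state = as.list(condition$initial_state),
            tau0 = condition$tau0, glnk_present = condition$glnk_present)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Serialize an evaluation result to JSON
#' @param result an \code{\link{evaluation_result}}.
#' @param path file path.
#' @export
write_evaluation <- function(result, path) {
  jsonlite::write_json(list(f = result$f, g = as.list(result$g),
                            gamma = result$gamma, mp = result$mp),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an evaluation result from JSON
#' @param path file path.
#' @return An \code{\link{evaluation_result}}.
#' @export
read_evaluation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  evaluation_result(j$f, unlist(j$g))
}

# Run manifest: inputs are hashed so that identical manifests imply
# identical numeric outputs (all commands are pure functions of
# inputs + seed).
write_manifest <- function(outdir, command, input_files, seed, outputs) {
  hashes <- tools::md5sum(normalizePath(input_files))
  combined <- paste(hashes, collapse = "")
  tmp <- tempfile(); writeLines(combined, tmp)
  manifest <- list(command = command,
                   config_hash = unname(tools::md5sum(tmp)),
                   input_hashes = as.list(stats::setNames(unname(hashes),
                                                          basename(input_files))),
                   seed = seed,
                   tool_version = as.character(utils::packageVersion("rubberband")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Materialize a synthetic scenario to disk
#'
#' Writes the parameter-spec CSV, the constraints CSV and one condition YAML
#' per condition, plus a run manifest — exactly the artifact set
#' \code{\link{cmd_fit}} consumes.
#'
#' @param scenario_file YAML with fields \code{scenario} (\code{"default"}),
#'   \code{seed} (mandatory) and optional \code{noise_cv}.
#' @param outdir output directory (created).
#' @return Invisibly, the realized scenario.
#' @export
cmd_synth <- function(scenario_file, outdir) {
  y <- yaml::read_yaml(scenario_file)
  if (is.null(y$seed))
    stop("scenario file must contain a seed: unseeded generation is refused",
         call. = FALSE)
  name <- y$scenario %||% "default"
  if (name != "default")
    stop("unknown scenario '", name, "'; available: default", call. = FALSE)
  scen <- default_scenario(seed = y$seed, noise_cv = y$noise_cv %||% 0.03)
  real <- realize_scenario(scen)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "conditions"), showWarnings = FALSE)
  write_param_specs(real$specs, file.path(outdir, "specs.csv"))
  write_constraints(real$constraints, file.path(outdir, "constraints.csv"))
  for (cond in real$conditions)
    write_condition(cond, file.path(outdir, "conditions",
                                    paste0(cond$condition_id, ".yaml")))
  write_manifest(outdir, "synth", scenario_file, y$seed,
                 list(specs = "specs.csv", constraints = "constraints.csv",
                      conditions = "conditions/"))
  invisible(real)
}

#' Fit a model to training constraints (pipeline command)
#'
#' Reads the artifact set, pre-flights the condition and variable bindings,
#' runs the constrained GA and writes the best parameters, the per-generation
#' history, the evaluation JSON and a manifest.
#'
#' @param specs_file parameter-spec CSV.
#' @param constraints_file constraints CSV or YAML.
#' @param conditions_dir directory of condition YAMLs.
#' @param ga_file optional YAML of \code{\link{ga_config}} overrides
#'   (fields named as the arguments; \code{seed} mandatory there or via
#'   \code{seed}).
#' @param outdir output directory.
#' @param seed GA seed (overrides the ga_file).
#' @return Invisibly, the \code{ga_run}.
#' @export
cmd_fit <- function(specs_file, constraints_file, conditions_dir,
                    ga_file = NULL, outdir, seed = NULL) {
  specs <- read_param_specs(specs_file)
  constraints <- read_constraints(constraints_file)
  if (length(constraints) == 0)
    stop("empty constraint list: nothing to fit", call. = FALSE)
  cond_files <- list.files(conditions_dir, pattern = "\\.ya?ml$",
                           full.names = TRUE)
  conditions <- lapply(cond_files, read_condition)
  names(conditions) <- vapply(conditions, `[[`, character(1), "condition_id")

  problem <- fitting_problem(specs, constraints, conditions)
  opts <- if (!is.null(ga_file)) yaml::read_yaml(ga_file) else list()
  if (!is.null(seed)) opts$seed <- seed
  if (is.null(opts$seed)) stop("a GA seed is required", call. = FALSE)
  opts$d <- length(problem$lower)
  config <- do.call(ga_config, opts)

  run <- ga_optimize(problem, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  est <- as.data.frame(specs)
  est$estimated <- run$best$values[est$name]
  utils::write.csv(est, file.path(outdir, "best_params.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$history, file.path(outdir, "history.csv"),
                   row.names = FALSE, quote = FALSE)
  write_evaluation(evaluation_result(run$best$f, run$best$g),
                   file.path(outdir, "evaluation.json"))
  write_manifest(outdir, "fit",
                 c(specs_file, constraints_file, cond_files,
                   if (!is.null(ga_file)) ga_file),
                 config$seed,
                 list(best_params = "best_params.csv",
                      history = "history.csv",
                      evaluation = "evaluation.json"))
  if (!isTRUE(run$best$feasible))
    warning("optimization ended infeasible (gamma = ",
            format(run$best$gamma), ")", call. = FALSE)
  invisible(run)
}

#' Compare fitted runs of two model variants (pipeline command)
#'
#' Reads \code{evaluation.json} from each run directory and writes the
#' model-comparison JSON (representative f per side, MP ratio, rank-sum p).
#'
#' @param dirs_a,dirs_b character vectors of run directories for models A
#'   and B.
#' @param outfile path of the comparison JSON.
#' @return Invisibly, the \code{\link{compare_models}} result.
#' @export
cmd_compare <- function(dirs_a, dirs_b, outfile) {
  load_side <- function(dirs) lapply(dirs, function(d) {
    ev <- read_evaluation(file.path(d, "evaluation.json"))
    structure(list(best = list(f = ev$f, gamma = ev$gamma,
                               feasible = ev$gamma == 0)),
              class = "ga_run")
  })
  cmp <- compare_models(load_side(dirs_a), load_side(dirs_b))
  jsonlite::write_json(
    list(f_a = cmp$f_a, f_b = cmp$f_b, mp_a = cmp$mp_a, mp_b = cmp$mp_b,
         mp_ratio = cmp$mp_ratio, rank_sum_p = cmp$rank_sum_p,
         f_samples_a = cmp$f_samples_a, f_samples_b = cmp$f_samples_b),
    outfile, auto_unbox = TRUE, digits = NA)
  invisible(cmp)
}

#' Simulate a condition with a fitted parameter set (pipeline command)
#'
#' Writes a tidy trajectory CSV (time, variable, value), a flux CSV
#' (time, v_amtb, v_diff, v_net) and a steady-state summary JSON including
#' the futile-cycle ATP-equivalent drain.
#'
#' @param params_file parameter CSV (uses the \code{estimated} column when
#'   present, else \code{reference}).
#' @param condition_file condition YAML.
#' @param t_end simulation end time (min).
#' @param outdir output directory.
#' @param knockout simulate with GlnK removed.
#' @return Invisibly, the trajectory data frame.
#' @export
cmd_simulate <- function(params_file, condition_file, t_end = 20, outdir,
                         knockout = FALSE) {
  df <- utils::read.csv(params_file, stringsAsFactors = FALSE)
  vals <- stats::setNames(
    if ("estimated" %in% names(df) && !all(is.na(df$estimated)))
      df$estimated else df$reference, df$name)
  params <- toy_params_from_values(vals)
  if (knockout) params <- glnk_knockout(params)
  condition <- read_condition(condition_file)
  traj <- simulate_toy(params, condition, t_end = t_end)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tidy <- do.call(rbind, lapply(setdiff(names(traj), "time"), function(v)
    data.frame(time = traj$time, variable = v, value = traj[[v]])))
  utils::write.csv(tidy, file.path(outdir, "trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(traj[, c("time", "v_amtb", "v_diff", "v_net")],
                   file.path(outdir, "fluxes.csv"),
                   row.names = FALSE, quote = FALSE)
  ss <- steady_state_toy(params, condition)
  back <- max(0, -ss$fluxes[["v_diff"]])
  jsonlite::write_json(
    list(state = as.list(ss$state), fluxes = as.list(ss$fluxes),
         back_diffusion = back,
         futile_cycle_atp_equivalent = futile_cycle_atp_equivalent(back)),
    file.path(outdir, "steady_state.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "simulate", c(params_file, condition_file),
                 NA, list(trajectory = "trajectory.csv",
                          fluxes = "fluxes.csv",
                          steady_state = "steady_state.json"))
  invisible(traj)
}
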