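#' Derive a child seed from a master seed
#'
#' Counter-based fan-out so that inserting a stage (or window) does not
#' perturb the seeds of the others.  Results stay inside the 32-bit integer
#' range.
#'
#' @param seed master integer seed.
#' @param index stage/window counter (>= 1).
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647L)
}

#' Read a two-column time/derivative table
#'
#' Parses the plain-text dialect common MD engines emit for Hamiltonian
#' derivatives: whitespace-separated `time dH/dlambda` rows, with comment
#' lines starting with `#` or `@` skipped.  The window's lambda is taken
#' from the `lam` argument or, failing that, from a header comment of the
#' form `# lambda = 0.25`.
#'
#' @param path input file.
#' @param lam lambda for the series; `NULL` to read it from the header.
#' @param burn_in burn-in span attached to the series, ps.
#' @return A [derivative_series()].
#' @export
read_dhdl_table <- function(path, lam = NULL, burn_in = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  if (is.null(lam)) {
    hit <- regmatches(lines[is_comment],
                      regexpr("lambda\\s*=\\s*[0-9.eE+-]+", lines[is_comment]))
    hit <- unlist(hit)
    if (length(hit) > 0)
      lam <- as.numeric(sub("lambda\\s*=\\s*", "", hit[1]))
    else stop("lambda not given and no 'lambda = ...' header comment found")
  }
  data_idx <- which(!is_comment)
  if (length(data_idx) == 0)
    stop("no data rows in ", path, " (comments only)")
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop("malformed numeric row at line ", i, " of ", path)
    v[1:2]
  }
  rows <- t(vapply(data_idx, parse_row, numeric(2)))
  dt <- if (nrow(rows) > 1) rows[2, 1] - rows[1, 1] else 1
  if (!is.finite(dt) || dt <= 0) dt <- 1
  derivative_series(values = rows[, 2], lam = lam, dt = dt, burn_in = burn_in)
}

#' Write a derivative series as a two-column table
#'
#' Emits a `# lambda = ...` header so [read_dhdl_table()] can round-trip the
#' file without external metadata.
#'
#' @param series a [derivative_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dhdl_table <- function(series, path) {
  stopifnot(inherits(series, "derivative_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lambda = %.10g", series$lam),
               "@ time_ps dHdlambda_kJ_per_mol"), con)
  times <- seq_along(series$values) * series$dt
  writeLines(sprintf("%.10g %.17g", times, series$values), con)
  invisible(path)
}

#' Write a TI result (or any result list) as JSON
#' @param x a list or `ti_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Check a pipeline result list against the shipped schema
#'
#' Light-weight structural validation: verifies that the required fields of
#' the result document (as listed in `inst/extdata/results_schema.json`)
#' are present and of the right basic type.
#'
#' @param x a result list as produced by [run_pipeline()].
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_result <- function(x) {
  schema <- jsonlite::read_json(system.file("extdata", "results_schema.json",
                                            package = "densassign"))
  for (f in schema$required) {
    if (is.null(x[[f]])) stop("result is missing required field: ", f)
  }
  if (!is.character(x$package_version) && !inherits(x$package_version,
                                                    "numeric_version"))
    stop("package_version must be a string")
  if (!is.numeric(x$seed)) stop("seed must be numeric")
  invisible(TRUE)
}

#' Load the packaged toy system definitions
#'
#' Reads species and site definitions from a structured YAML config.  The
#' packaged default defines a water-like particle, a fluoride-like anion and
#' a sodium-like cation, together with a 3-donor pocket (aromatic-cage-like
#' site), a tetrahedral 4-dipole cage (carbonyl-cage-like site) and a
#' featureless solvated bulk box.  Parameter values are illustrative, not
#' fitted.
#'
#' @param path YAML file; defaults to the packaged `toy_system.yaml`.
#' @return list with `species` and `sites`, each a named list of objects.
#' @export
toy_system <- function(path = system.file("extdata", "toy_system.yaml",
                                          package = "densassign")) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  sp <- lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    species(name = nm, charge = s$charge, lj_epsilon = s$lj_epsilon,
            lj_sigma = s$lj_sigma, mass = s$mass,
            solvation = if (is.null(s$solvation)) 0 else s$solvation)
  })
  names(sp) <- names(cfg$species)
  st <- lapply(names(cfg$sites), function(nm) {
    s <- cfg$sites[[nm]]
    centers <- if (is.null(s$centers)) NULL else
      do.call(rbind, lapply(s$centers, as.data.frame))
    site_model(centers = centers, dielectric = s$dielectric,
               cage_k = if (is.null(s$cage_k)) 0 else s$cage_k,
               site_center = if (is.null(s$site_center)) c(0, 0, 0)
                             else unlist(s$site_center),
               escape_radius = s$escape_radius,
               box_halfwidth = s$box_halfwidth,
               solvation_scale = if (is.null(s$solvation_scale)) 0
                                 else s$solvation_scale,
               name = nm)
  })
  names(st) <- names(cfg$sites)
  list(species = sp, sites = st)
}

#' Read a pipeline run configuration
#'
#' @param path YAML run config (see the packaged `demo_config.yaml`).
#' @return the config as a named list, with the system file resolved.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("seed", "site", "ion", "water")) {
    if (is.null(cfg[[f]])) stop("run config is missing field: ", f)
  }
  if (is.null(cfg$system_file)) {
    cfg$system_file <- system.file("extdata", "toy_system.yaml",
                                   package = "densassign")
  } else if (!file.exists(cfg$system_file)) {
    # allow paths relative to the config file
    cand <- file.path(dirname(path), cfg$system_file)
    if (!file.exists(cand))
      stop("system_file does not exist: ", cfg$system_file)
    cfg$system_file <- cand
  }
  cfg
}

#' Run the full assignment pipeline on the toy model
#'
#' Orchestrates the package end to end for one candidate site: free
#' simulations with escape detection and lifetime estimation for both
#' candidate species, the relative transformation (site and bulk legs), the
#' absolute binding cycle for water, and the final three-criterion verdict.
#' Per-stage artifacts (event CSVs, per-window derivative tables, JSON leg
#' results) are written under `output_dir`; the run is reproducible given
#' the config seed, which is fanned out to the stages with [child_seed()].
#'
#' @param config a config list from [read_run_config()], or a path to one.
#' @param output_dir output directory (created if needed); defaults to the
#'   config's `output_dir` or a temporary directory.
#' @return the result list (also written to `assignment.json`), containing
#'   the lifetimes, free energies, verdict and provenance metadata.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(output_dir))
    output_dir <- if (!is.null(config$output_dir)) config$output_dir
                  else tempfile("densassign_run_")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sys <- stage("load_system", {
    s <- toy_system(config$system_file)
    list(site = s$sites[[config$site]], bulk = s$sites[[config$bulk %||% "bulk"]],
         ion = s$species[[config$ion]], water = s$species[[config$water]])
  })
  if (is.null(sys$site) || is.null(sys$bulk))
    stop("pipeline stage 'load_system' failed: unknown site or bulk name")

  seed0 <- as.integer(config$seed)
  stab_cfg <- config$stability
  taus <- stage("stability", {
    out <- list()
    for (who in c("water", "ion")) {
      sp <- sys[[who]]
      events <- lapply(seq_len(stab_cfg$n_replicas), function(r) {
        p <- simulation_params(
          temperature = config$temperature %||% 300,
          friction = stab_cfg$friction %||% 10,
          dt = stab_cfg$dt %||% 0.002,
          n_steps = stab_cfg$n_steps,
          seed = child_seed(seed0, 100 * match(who, c("water", "ion")) + r),
          sample_stride = stab_cfg$sample_stride %||% 10)
        traj <- simulate_langevin(sys$site, sp, p)
        detect_escape(traj, persistence = stab_cfg$persistence %||% 5,
                      molecule_id = sprintf("%s_rep%02d", sp$name, r))
      })
      surv <- events_to_survival(events)
      write_survival_csv(surv, file.path(output_dir,
                                         paste0("events_", who, ".csv")))
      out[[who]] <- tau_ml(surv)
    }
    out
  })

  ti_cfg <- config$ti
  mk_params <- function(idx, n_steps) {
    simulation_params(temperature = config$temperature %||% 300,
                      friction = ti_cfg$friction %||% 10,
                      dt = ti_cfg$dt %||% 0.002, n_steps = n_steps,
                      burn_in_steps = ti_cfg$burn_in_steps %||% 0,
                      seed = child_seed(seed0, 1000 + idx),
                      sample_stride = ti_cfg$sample_stride %||% 10)
  }
  sc <- soft_core_params()

  rel <- stage("relative_ti", {
    n_rel <- ti_cfg$n_windows_relative %||% 21
    a_site <- alchemical_hamiltonian(
      "relative", state_A = list(site = sys$site, species = sys$ion),
      state_B = list(site = sys$site, species = sys$water), softcore = sc)
    a_bulk <- alchemical_hamiltonian(
      "relative", state_A = list(site = sys$bulk, species = sys$ion),
      state_B = list(site = sys$bulk, species = sys$water), softcore = sc)
    g3 <- ti_leg(a_site, lambda_schedule(n = n_rel), mk_params(1, ti_cfg$n_steps),
                 "g3_site")
    g2 <- ti_leg(a_bulk, lambda_schedule(n = n_rel), mk_params(2, ti_cfg$n_steps),
                 "g2_bulk")
    for (leg in list(g3, g2)) {
      for (i in seq_along(leg$series))
        write_dhdl_table(leg$series[[i]],
                         file.path(output_dir, sprintf("dhdl_%s_w%02d.xvg",
                                                       leg$leg$name, i)))
    }
    relative_ddg(relative_cycle(leg_g3 = g3$leg, leg_g2 = g2$leg))
  })

  rspec <- restraint_spec(k_x = config$restraint_k %||% 200,
                          temperature = config$temperature %||% 300,
                          v_standard = config$v_standard %||% 0.02992)
  abs_water <- stage("absolute_ti", {
    absolute_binding_toy(sys$site, sys$bulk, sys$water, rspec,
                         n_steps = ti_cfg$n_steps,
                         base_seed = child_seed(seed0, 2000),
                         temperature = config$temperature %||% 300,
                         dt = ti_cfg$dt %||% 0.002,
                         burn_in_steps = ti_cfg$burn_in_steps %||% 0,
                         sample_stride = ti_cfg$sample_stride %||% 10,
                         friction = ti_cfg$friction %||% 10)
  })

  result <- stage("verdict", {
    thr <- do.call(assignment_thresholds,
                   config$thresholds %||% list())
    v <- verdict(site_assessment(
      ddg = rel$ddg, ddg_stderr = rel$stderr,
      dg_bind_water = abs_water$delta_g, dg_bind_stderr = abs_water$stderr,
      tau_water = taus$water, tau_ion = taus$ion, thresholds = thr))
    list(package_version = as.character(packageVersion("densassign")),
         seed = seed0,
         config_hash = unname(tools::md5sum(config$system_file)),
         site = config$site,
         lifetimes = list(
           water = list(tau_ns = taus$water$tau,
                        lower_bound = taus$water$is_lower_bound),
           ion = list(tau_ns = taus$ion$tau,
                      lower_bound = taus$ion$is_lower_bound)),
         relative = rel,
         absolute_water = abs_water[c("delta_g", "stderr", "dg1", "dg2",
                                      "restraint_release")],
         verdict = list(call = v$call, rationale = v$rationale,
                        evidence = lapply(v$evidence, function(e) e$label)))
  })
  validate_result(result)
  write_result_json(result, file.path(output_dir, "assignment.json"))
  result
}

#' Absolute binding free energy of a species on the toy model
#'
#' Runs the five-sub-step absolute cycle: restraint switch-on at the site,
#' Coulomb decoupling, Lennard-Jones decoupling (site legs, restrained),
#' the corresponding decoupling legs in bulk (restrained), the zero-cost
#' translation of the ghost particle, and the analytic restraint release at
#' the standard volume, assembled by [assemble_absolute()].
#'
#' @param site,bulk [site_model()]s for the binding site and bulk solvent.
#' @param sp the [species()] to bind.
#' @param spec a [restraint_spec()].
#' @param n_steps steps per lambda window.
#' @param base_seed seed fanned out over the legs/windows.
#' @param temperature,dt,burn_in_steps,sample_stride,friction simulation
#'   settings shared by all windows.
#' @param n_coul,n_lj,n_posre window counts for the Coulomb, LJ and
#'   restraint legs.
#' @return the [assemble_absolute()] result, with the legs attached.
#' @export
absolute_binding_toy <- function(site, bulk, sp, spec,
                                 n_steps = 20000, base_seed = 1,
                                 temperature = 300, dt = 0.002,
                                 burn_in_steps = 0, sample_stride = 10,
                                 friction = 10,
                                 n_coul = 11, n_lj = 21, n_posre = 11) {
  sc <- soft_core_params()
  restr <- list(k = spec$k_x, center = site$site_center)
  restr_bulk <- list(k = spec$k_x, center = bulk$site_center)
  mk <- function(idx) simulation_params(
    temperature = temperature, friction = friction, dt = dt,
    n_steps = n_steps, burn_in_steps = burn_in_steps,
    seed = child_seed(base_seed, idx), sample_stride = sample_stride)

  # uncharged ghost intermediate for the LJ legs
  sp_q0 <- sp; sp_q0$charge <- 0; sp_q0$solvation <- 0

  legs_site <- list(
    ti_leg(alchemical_hamiltonian("restraint_on",
                                  state_A = list(site = site, species = sp),
                                  softcore = sc, restraint = restr),
           lambda_schedule(n = n_posre), mk(1), "posre_on")$leg,
    ti_leg(alchemical_hamiltonian("decouple_coulomb",
                                  state_A = list(site = site, species = sp),
                                  softcore = sc, restraint = restr),
           lambda_schedule(n = n_coul), mk(2), "coulomb_off")$leg,
    ti_leg(alchemical_hamiltonian("decouple_lj",
                                  state_A = list(site = site, species = sp_q0),
                                  softcore = sc, restraint = restr),
           lambda_schedule(n = n_lj), mk(3), "lj_off")$leg)

  legs_bulk <- list(
    ti_leg(alchemical_hamiltonian("decouple_coulomb",
                                  state_A = list(site = bulk, species = sp),
                                  softcore = sc, restraint = restr_bulk),
           lambda_schedule(n = n_coul), mk(4), "coulomb_off")$leg,
    ti_leg(alchemical_hamiltonian("decouple_lj",
                                  state_A = list(site = bulk, species = sp_q0),
                                  softcore = sc, restraint = restr_bulk),
           lambda_schedule(n = n_lj), mk(5), "lj_off")$leg)

  out <- assemble_absolute(absolute_cycle(legs_site, legs_bulk), spec)
  out$legs_site <- legs_site
  out$legs_bulk <- legs_bulk
  out
}

#' Relative-vs-absolute cycle-closure study on the toy system
#'
#' Computes the relative binding free energy difference (water vs ion) by
#' direct alchemical transformation at the site and in bulk, and the two
#' absolute binding free energies through the restraint/decoupling cycle,
#' on the packaged toy system.  Thermodynamic consistency requires
#' \deqn{\Delta\Delta G_{bind} = \Delta G_{bind}(water) -
#'   \Delta G_{bind}(ion)} up to statistical error; the returned `closure`
#' is the left side minus the right side with its combined standard error.
#'
#' The default protocol (41-window relative/LJ/restraint schedules,
#' 11-window Coulomb legs, dt = 0.5 fs, 0.3 ns per window with 30 ps
#' burn-in, friction 2 ps^-1) was chosen by deterministic quadrature
#' analysis of the exact integrands and a time-step sensitivity study so
#' that the remaining systematic error is well below the statistical one.
#'
#' @param seed master seed; all windows derive from it.
#' @param system a [toy_system()] list.
#' @param site_name,bulk_name,ion_name,water_name names within `system`.
#' @param n_steps,dt,burn_in_steps,friction per-window simulation settings.
#' @param n_rel,n_posre,n_lj,n_coul lambda-window counts.
#' @return list with `relative` (ddg, stderr), `absolute_water`,
#'   `absolute_ion`, `closure`, `closure_stderr`.
#' @export
run_closure_study <- function(seed = 1, system = toy_system(),
                              site_name = "f_site", bulk_name = "bulk",
                              ion_name = "fluoride", water_name = "water",
                              n_steps = 6e5, dt = 5e-4, burn_in_steps = 6e4,
                              friction = 2, n_rel = 41, n_posre = 41,
                              n_lj = 41, n_coul = 11) {
  site <- system$sites[[site_name]]
  bulk <- system$sites[[bulk_name]]
  ion <- system$species[[ion_name]]
  wat <- system$species[[water_name]]
  sc <- soft_core_params()
  rspec <- restraint_spec()
  pp <- function(idx) simulation_params(
    n_steps = n_steps, burn_in_steps = burn_in_steps, friction = friction,
    dt = dt, seed = child_seed(seed, idx), sample_stride = 10)
  a_site <- alchemical_hamiltonian(
    "relative", state_A = list(site = site, species = ion),
    state_B = list(site = site, species = wat), softcore = sc)
  a_bulk <- alchemical_hamiltonian(
    "relative", state_A = list(site = bulk, species = ion),
    state_B = list(site = bulk, species = wat), softcore = sc)
  g3 <- ti_leg(a_site, lambda_schedule(n = n_rel), pp(1), "g3_site")
  g2 <- ti_leg(a_bulk, lambda_schedule(n = n_rel), pp(2), "g2_bulk")
  rel <- relative_ddg(relative_cycle(leg_g3 = g3$leg, leg_g2 = g2$leg))
  aw <- absolute_binding_toy(site, bulk, wat, rspec, n_steps = n_steps,
                             base_seed = child_seed(seed, 3), dt = dt,
                             burn_in_steps = burn_in_steps,
                             friction = friction, n_coul = n_coul,
                             n_lj = n_lj, n_posre = n_posre)
  ai <- absolute_binding_toy(site, bulk, ion, rspec, n_steps = n_steps,
                             base_seed = child_seed(seed, 4), dt = dt,
                             burn_in_steps = burn_in_steps,
                             friction = friction, n_coul = n_coul,
                             n_lj = n_lj, n_posre = n_posre)
  closure <- rel$ddg - (aw$delta_g - ai$delta_g)
  list(relative = rel, absolute_water = aw, absolute_ion = ai,
       closure = closure,
       closure_stderr = sqrt(rel$stderr^2 + aw$stderr^2 + ai$stderr^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
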