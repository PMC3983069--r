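# Run configuration: defaults, validation, (de)serialisation and the
# single-run simulation driver.

#' Default run configuration
#'
#' All defaults reproduce the baseline system: monolayer thickness 2 nm,
#' bending modulus 10 kT, insertion radius 0.5 nm, embedding depth 0.8 nm,
#' insertion length 2 nm.  The configuration round-trips losslessly
#' through YAML ([read_run_config()] / [write_run_config()]); every
#' computation is deterministic (no randomness anywhere).
#'
#' @param ... named overrides of nested fields, e.g.
#'   `insertion = list(d = 0.6)`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    membrane = list(h = 2, kappa = 10, nu = 0.49, z0_frac = 2 / 3,
                    z_break_frac = 0.5, zeta_table = NA),
    profile = list(head_center = NA, head_width = 0.6,
                   interface_width = 0.5, chain_center = NA,
                   chain_width = 1.2, w_head = 1, frustration_amp = 0),
    insertion = list(r = 0.5, d = 0.8, L_ins = 2),
    scenario = list(kind = "symmetric_Js", magnitude = 0,
                    coupling = "uncoupled"),
    vesicle = list(R = Inf, correction = "offset"),
    mesh = list(L_dom = 20, dz_fine = 0.1, aspect_max = 2.4,
                min_elements = 1908, min_elements_refined = 5514,
                refine_fraction = 0.25, max_refine_passes = 8),
    output = list(dir = NA, write_vtk = FALSE, prefix = "membrins")
  )
  ov <- list(...)
  for (sec in names(ov)) {
    if (!sec %in% names(cfg))
      stop("unknown configuration section '", sec, "'")
    for (key in names(ov[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown configuration field '", sec, "$", key, "'")
      cfg[[sec]][[key]] <- ov[[sec]][[key]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a [run_config()].
#' @return `cfg`, invisibly; errors name the offending field path.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(cond, path, msg) {
    if (!cond) stop("config field ", path, ": ", msg)
  }
  chk(cfg$membrane$h > 0, "membrane$h", "must be positive")
  chk(cfg$membrane$kappa > 0, "membrane$kappa", "must be positive")
  chk(cfg$membrane$nu < 0.5, "membrane$nu", "must be < 0.5")
  chk(cfg$insertion$r > 0, "insertion$r", "must be positive")
  chk(cfg$insertion$d >= 0, "insertion$d", "must be non-negative")
  chk(cfg$insertion$d <= cfg$membrane$h, "insertion$d",
      "must not exceed the monolayer thickness")
  chk(cfg$insertion$L_ins > 0, "insertion$L_ins", "must be positive")
  chk(cfg$scenario$kind %in% c("outer_Js", "inner_Js", "symmetric_Js",
                               "external_torque", "stretch"),
      "scenario$kind", "unknown scenario kind")
  chk(cfg$scenario$coupling %in% c("coupled", "uncoupled"),
      "scenario$coupling", "must be 'coupled' or 'uncoupled'")
  chk(is.infinite(cfg$vesicle$R) || cfg$vesicle$R > cfg$membrane$h,
      "vesicle$R", "must exceed the monolayer thickness (or be Inf)")
  chk(cfg$mesh$L_dom > 0, "mesh$L_dom", "must be positive")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file.
#' @return [read_run_config()]: a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$vesicle$R) && identical(raw$vesicle$R, "Inf"))
    raw$vesicle$R <- Inf
  cfg <- do.call(run_config, raw)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configuration files")
  out <- unclass(cfg)
  if (is.infinite(out$vesicle$R)) out$vesicle$R <- "Inf"
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# assemble model objects from a config
.config_objects <- function(cfg) {
  validate_run_config(cfg)
  h <- cfg$membrane$h
  membrane <- monolayer_spec(h = h, kappa = cfg$membrane$kappa,
                             z0 = cfg$membrane$z0_frac * h)
  moduli <- moduli_profile(membrane, nu = cfg$membrane$nu,
                           z_break = cfg$membrane$z_break_frac * h)
  na_null <- function(x) if (length(x) != 1L || is.na(x)) NULL else x
  shape <- profile_shape(head_center = na_null(cfg$profile$head_center),
                         head_width = cfg$profile$head_width,
                         interface_width = cfg$profile$interface_width,
                         chain_center = na_null(cfg$profile$chain_center),
                         chain_width = cfg$profile$chain_width,
                         w_head = cfg$profile$w_head,
                         frustration_amp = cfg$profile$frustration_amp)
  geom <- insertion_geometry(r = cfg$insertion$r, d = cfg$insertion$d,
                             L_ins = cfg$insertion$L_ins)
  control <- mesh_control(L_dom = cfg$mesh$L_dom,
                          dz_fine = cfg$mesh$dz_fine,
                          aspect_max = cfg$mesh$aspect_max,
                          min_elements = cfg$mesh$min_elements,
                          min_elements_refined = cfg$mesh$min_elements_refined,
                          refine_fraction = cfg$mesh$refine_fraction,
                          max_refine_passes = cfg$mesh$max_refine_passes)
  list(membrane = membrane, moduli = moduli, shape = shape, geom = geom,
       control = control)
}

# short deterministic hash of the scientific part of a configuration
# (output paths excluded, so reruns into different directories match)
.config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$output <- NULL
  s <- paste(deparse(core), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Run one embedding simulation from a configuration
#'
#' Prepares the scenario state, runs the two-step embedding, converts the
#' energies to a relative binding constant, and (optionally) writes the
#' budget/binding CSVs and the displacement/stress fields as VTK.
#'
#' @param cfg a [run_config()].
#' @param verbose log mesh sizes and the energy budget.
#' @return list with `budget` ([energy_budget()]), `eps_el0` (unstressed
#'   baseline, kT), `K_rel`, the scenario `state`, and the paths written.
#' @export
run_simulation <- function(cfg = run_config(), verbose = TRUE) {
  obj <- .config_objects(cfg)
  st <- scenario_state(scenario_spec(cfg$scenario$kind,
                                     cfg$scenario$magnitude,
                                     cfg$scenario$coupling),
                       obj$membrane, obj$moduli, obj$shape)
  solver <- embedding_solver(obj$geom, obj$membrane, obj$moduli,
                             cfg$scenario$coupling, obj$control,
                             verbose = verbose)
  em0 <- embed_state(solver, NULL)
  em <- embed_state(solver, st)
  model <- binding_model(delta = obj$membrane$h,
                         correction = cfg$vesicle$correction)
  K_rel <- relative_binding_constant(em$budget$eps_el, em0$budget$eps_el,
                                     R = cfg$vesicle$R, model = model)
  if (verbose) {
    message(sprintf(
      "mesh: %d elements; budget (kT): eps_V0 = %.4f, delta_eps_V = %.4f, eps_R = %.4f, eps_el = %.4f; eps_el0 = %.4f; K_rel = %.4f",
      nrow(solver$mesh$triangles), em$budget$eps_V0,
      em$budget$delta_eps_V, em$budget$eps_R, em$budget$eps_el,
      em0$budget$eps_el, K_rel))
  }
  paths <- character(0)
  out_dir <- cfg$output$dir
  if (!is.null(out_dir) && length(out_dir) == 1L && !is.na(out_dir)) {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(cfg$output$dir, cfg$output$prefix)
    hdr <- c(sprintf("# membrins %s", as.character(utils::packageVersion("membrins"))),
             sprintf("# config_hash: %s", .config_hash(cfg)))
    bpath <- paste0(pre, "_budget.csv")
    con <- file(bpath, "w")
    writeLines(hdr, con)
    utils::write.csv(data.frame(
      scenario = cfg$scenario$kind, magnitude = cfg$scenario$magnitude,
      coupling = cfg$scenario$coupling, J = st$J,
      eps_V0 = em$budget$eps_V0, delta_eps_V = em$budget$delta_eps_V,
      eps_R = em$budget$eps_R, eps_el = em$budget$eps_el,
      eps_el0 = em0$budget$eps_el, K_rel = K_rel), con,
      row.names = FALSE)
    close(con)
    paths <- bpath
    if (isTRUE(cfg$output$write_vtk)) {
      ef <- element_fields(em$state, st$profiles)
      asm <- solver$asm
      nv <- nrow(solver$mesh$nodes)
      vpath <- paste0(pre, "_fields.vtk")
      write_mesh_vtk(solver$mesh, vpath,
                     point_data = list(u_x = em$state$u[asm$dof_x[seq_len(nv)]],
                                       u_z = em$state$u[asm$dof_z[seq_len(nv)]]),
                     cell_data = list(sigma_xx = ef$sxx,
                                      sigma_zz = ef$szz,
                                      sigma_xz = ef$sxz))
      paths <- c(paths, vpath)
    }
  }
  list(budget = em$budget, eps_el0 = em0$budget$eps_el, K_rel = K_rel,
       state = st, dJ = em$dJ, mesh_elements = nrow(solver$mesh$triangles),
       paths = paths)
}
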