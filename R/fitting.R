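# Fitting insertion geometry (length, embedding depth) to measured
# relative binding constants of ALPS amphipathic helices.
#
# Size experiments: liposomes of different radii, curvature generated by
# external torque (extrusion/sonication), laterally coupled monolayers.
# Composition experiments: flat liposomes whose monolayer spontaneous
# curvature is varied symmetrically, coupled monolayers.
#
# The elastic binding energy is exactly linear in the insertion length, so
# all fits factorise into per-unit-length energies (computed once per
# embedding depth) times L.

#' Experiment table of relative binding constants
#'
#' @param data data.frame; for `kind = "size"` columns `R1`, `R2`, `ratio`
#'   (the measured `K_B(R1)/K_B(R2)`), for `kind = "composition"` columns
#'   `Js`, `ratio` (measured `K_B(Js)/K_B(Js_baseline)`).
#' @param kind `"size"` or `"composition"`.
#' @param motif label of the amphipathic helix.
#' @param baseline_Js baseline monolayer spontaneous curvature, nm^-1
#'   (composition tables).
#' @param delta monolayer thickness used for validity checks, nm.
#' @return Object of class `experiment_table`.
#' @export
experiment_table <- function(data, kind = c("size", "composition"),
                             motif = "", baseline_Js = NULL, delta = 2) {
  kind <- match.arg(kind)
  if (any(data$ratio <= 0)) stop("measured ratios must be positive")
  if (kind == "size") {
    stopifnot(all(c("R1", "R2", "ratio") %in% names(data)))
    if (any(c(data$R1, data$R2) <= delta))
      stop("all radii must exceed the monolayer thickness")
    base <- data$R1 == data$R2
    if (any(base) && any(data$ratio[base] != 1))
      stop("baseline rows (R1 == R2) must have ratio exactly 1")
  } else {
    stopifnot(all(c("Js", "ratio") %in% names(data)))
    if (is.null(baseline_Js)) stop("composition tables need baseline_Js")
    base <- abs(data$Js - baseline_Js) < 1e-12
    if (any(base) && any(data$ratio[base] != 1))
      stop("the baseline-composition row must have ratio exactly 1")
  }
  structure(list(data = data, kind = kind, motif = motif,
                 baseline_Js = baseline_Js, delta = delta),
            class = "experiment_table")
}

#' Measured size dependence of ALPS binding
#'
#' Relative binding constants of the ArfGAP1 ALPS1 and ALPS2 amphipathic
#' helices to extruded/sonicated liposomes of 34, 42 and 90 nm radius
#' (ratios relative to the 90 nm liposomes).
#'
#' @param motif `"ALPS1"` or `"ALPS2"`.
#' @return An [experiment_table()] of kind `"size"`.
#' @export
alps_size_table <- function(motif = c("ALPS1", "ALPS2")) {
  motif <- match.arg(motif)
  ratios <- if (motif == "ALPS1") c(46.75, 11.51) else c(5.33, 2.25)
  experiment_table(data.frame(R1 = c(34, 42, 90), R2 = 90,
                              ratio = c(ratios, 1)),
                   kind = "size", motif = motif)
}

#' Measured composition dependence of ArfGAP1 binding
#'
#' Relative binding constants of ArfGAP1 to flat liposomes of varying
#' DOPC:DOPE:DOPS:DAG composition, expressed against the 70:0:30:0
#' baseline, together with the monolayer spontaneous curvature of each
#' mixture (area-fraction weighted sum of the lipid contributions).
#'
#' @return An [experiment_table()] of kind `"composition"`.
#' @export
arfgap1_composition_table <- function() {
  tab <- data.frame(
    composition = c("70:0:30:0", "60:0:30:10", "40:30:30:0",
                    "30:30:30:10", "20:50:30:0", "10:50:30:10"),
    Js = c(-0.060, -0.147, -0.125, -0.213, -0.169, -0.256),
    ratio = c(1, 3.76, 1.17, 12.82, 2.02, 23.67))
  experiment_table(tab, kind = "composition", motif = "ArfGAP1",
                   baseline_Js = -0.060)
}

#' Read an experiment table from CSV
#'
#' @param path CSV with the columns of [experiment_table()].
#' @param kind `"size"` or `"composition"`.
#' @param ... passed to [experiment_table()].
#' @return An `experiment_table`.
#' @export
read_experiment_csv <- function(path, kind, ...) {
  experiment_table(utils::read.csv(path), kind = kind, ...)
}

# torque-scenario state whose pre-insertion curvature is 1/R (coupled
# monolayers; torque chosen accordingly)
.torque_state_for_radius <- function(R, membrane, moduli, shape) {
  z0 <- membrane$z0; h <- membrane$h
  gA <- .stretch_modulus(moduli)
  keff <- membrane$kappa + z0 * gA * (z0 - h / 2)
  scenario_state(scenario_spec("external_torque", 2 * keff / R, "coupled"),
                 membrane, moduli, shape)
}

# memoised per-depth, per-condition unit-length elastic binding energies
.energy_cache <- function(kind, r, radii_or_Js, membrane, moduli, shape,
                          control, verbose = FALSE) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  conds <- radii_or_Js
  function(d) {
    key <- sprintf("%.6f", d)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    geom <- insertion_geometry(r = r, d = d, L_ins = 1)
    solver <- embedding_solver(geom, membrane, moduli, "coupled", control)
    e <- vapply(conds, function(v) {
      st <- if (kind == "size")
        .torque_state_for_radius(v, membrane, moduli, shape)
      else
        scenario_state(scenario_spec("symmetric_Js", v, "coupled"),
                       membrane, moduli, shape)
      embed_state(solver, st)$budget$eps_el
    }, numeric(1))
    if (verbose) message("  d = ", key, ": e_unit = ",
                         paste(sprintf("%.4f", e), collapse = ", "))
    cache[[key]] <- e
    e
  }
}

#' Predicted size dependence of the relative binding constant
#'
#' `K_B(R)/K_B(R_ref)` for liposomes bent by an external torque with
#' laterally coupled monolayers, via the full embedding computation at
#' each radius.
#'
#' @param L_ins insertion length, nm.
#' @param d embedding depth, nm.
#' @param radii liposome mid-plane radii, nm.
#' @param ref reference radius (default: the largest).
#' @param r insertion cross-section radius, nm.
#' @param membrane,moduli,shape membrane description.
#' @param model a [binding_model()].
#' @param control mesh controls.
#' @return data.frame with `R`, `eps_el` and `ratio`; an attribute
#'   `validity_warnings` lists radii below the small-curvature validity
#'   bound (`R < 5 * delta`).
#' @export
predict_size_ratios <- function(L_ins, d, radii, ref = max(radii),
                                r = 0.5,
                                membrane = monolayer_spec(),
                                moduli = moduli_profile(membrane),
                                shape = profile_shape(),
                                model = binding_model(),
                                control = mesh_control()) {
  efun <- .energy_cache("size", r, c(radii, ref), membrane, moduli, shape,
                        control)
  e <- efun(d)
  n <- length(radii)
  e_ref <- e[n + 1L]
  ratio <- vapply(seq_len(n), function(i)
    ratio_between_radii(L_ins * e[i], L_ins * e_ref, radii[i], ref, model),
    numeric(1))
  out <- data.frame(R = radii, eps_el = L_ins * e[seq_len(n)],
                    ratio = ratio)
  warnR <- radii[radii < 5 * model$delta]
  attr(out, "validity_warnings") <-
    if (length(warnR)) sprintf("radius %g nm below validity bound %g nm",
                               warnR, 5 * model$delta) else character(0)
  out
}

#' Predicted composition dependence of the relative binding constant
#'
#' `K_B(J_s)/K_B(J_s_baseline)` for flat membranes with symmetrically
#' generated monolayer spontaneous curvature, coupled monolayers.
#'
#' @param L_ins insertion length, nm.
#' @param d embedding depth, nm.
#' @param Js_list monolayer spontaneous curvatures, nm^-1.
#' @param baseline_Js baseline spontaneous curvature, nm^-1.
#' @inheritParams predict_size_ratios
#' @return data.frame with `Js`, `eps_el` and `ratio`.
#' @export
predict_composition_ratios <- function(L_ins, d, Js_list,
                                       baseline_Js = -0.060,
                                       r = 0.5,
                                       membrane = monolayer_spec(),
                                       moduli = moduli_profile(membrane),
                                       shape = profile_shape(),
                                       model = binding_model(),
                                       control = mesh_control()) {
  efun <- .energy_cache("composition", r, c(Js_list, baseline_Js),
                        membrane, moduli, shape, control)
  e <- efun(d)
  n <- length(Js_list)
  ratio <- exp(-(L_ins * e[seq_len(n)] - L_ins * e[n + 1L]) / model$kT)
  data.frame(Js = Js_list, eps_el = L_ins * e[seq_len(n)], ratio = ratio)
}

# log-ratio predictions for an experiment table from unit-length energies
.log_pred <- function(table, e, conds, L, model) {
  d <- table$data
  if (table$kind == "size") {
    i1 <- match(d$R1, conds); i2 <- match(d$R2, conds)
    -L * (e[i1] - e[i2]) +
      log(size_correction(d$R1, model) / size_correction(d$R2, model))
  } else {
    ib <- match(table$baseline_Js, conds)
    ii <- match(d$Js, conds)
    -L * (e[ii] - e[ib])
  }
}

#' Fit insertion length and embedding depth to measured binding ratios
#'
#' Minimises the sum of squared log-ratio errors over a grid of insertion
#' lengths and embedding depths (exhaustive grid search followed by
#' golden-section refinement along the depth at the best length).  Also
#' returns the ridge of best depth as a function of length.
#'
#' @param table an [experiment_table()].
#' @param L_grid insertion lengths to scan, nm (a single value fixes L).
#' @param d_grid embedding depths to scan, nm.
#' @param r insertion cross-section radius, nm.
#' @param membrane,moduli,shape membrane description.
#' @param model a [binding_model()].
#' @param control mesh controls.
#' @param golden_tol depth tolerance of the golden-section refinement, nm
#'   (`NULL` skips refinement).
#' @param energies optional energy function from a previous fit on the
#'   same table kind/conditions (as returned in `$energies`), reused to
#'   avoid recomputation.
#' @param verbose print progress.
#' @return Object of class `fit_result`: `L`, `d`, `objective`,
#'   `predicted` (ratios at the optimum), `ridge` (best `d` and objective
#'   per `L`), `surface` (full objective grid) and `energies` (the energy
#'   cache function).
#' @export
fit_geometry <- function(table,
                         L_grid = seq(2, 8, by = 0.1),
                         d_grid = seq(0.1, 1.2, by = 0.05),
                         r = 0.5,
                         membrane = monolayer_spec(),
                         moduli = moduli_profile(membrane),
                         shape = profile_shape(),
                         model = binding_model(),
                         control = mesh_control(),
                         golden_tol = 0.005,
                         energies = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(table, "experiment_table"))
  conds <- if (table$kind == "size") {
    sort(unique(c(table$data$R1, table$data$R2)))
  } else {
    sort(unique(c(table$data$Js, table$baseline_Js)))
  }
  efun <- if (is.null(energies))
    .energy_cache(table$kind, r, conds, membrane, moduli, shape, control,
                  verbose)
  else energies
  yobs <- log(table$data$ratio)

  obj_Ld <- function(L, e) sum((.log_pred(table, e, conds, L, model) - yobs)^2)

  surface <- matrix(NA_real_, length(d_grid), length(L_grid),
                    dimnames = list(d = sprintf("%.3f", d_grid),
                                    L = sprintf("%.2f", L_grid)))
  for (i in seq_along(d_grid)) {
    e <- efun(d_grid[i])
    surface[i, ] <- vapply(L_grid, obj_Ld, numeric(1), e = e)
    if (verbose) message("d = ", d_grid[i], " done")
  }
  if (max(surface) - min(surface) < 1e-10) {
    stop("flat objective surface: the geometry is unidentifiable from ",
         "this table (objective range ",
         format(max(surface) - min(surface)), ")")
  }
  best <- which(surface == min(surface), arr.ind = TRUE)[1, ]
  d_best <- d_grid[best[1]]; L_best <- L_grid[best[2]]

  ridge <- data.frame(
    L = L_grid,
    d = d_grid[apply(surface, 2, which.min)],
    objective = apply(surface, 2, min))

  ## golden-section refinement along d at the best L
  if (!is.null(golden_tol)) {
    lo <- max(min(d_grid), d_best - 0.05)
    hi <- min(max(d_grid), d_best + 0.05)
    g <- (sqrt(5) - 1) / 2
    x1 <- hi - g * (hi - lo); x2 <- lo + g * (hi - lo)
    f1 <- obj_Ld(L_best, efun(x1)); f2 <- obj_Ld(L_best, efun(x2))
    while (hi - lo > golden_tol) {
      if (f1 < f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - g * (hi - lo); f1 <- obj_Ld(L_best, efun(x1))
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + g * (hi - lo); f2 <- obj_Ld(L_best, efun(x2))
      }
    }
    d_ref <- (lo + hi) / 2
    f_ref <- obj_Ld(L_best, efun(d_ref))
    if (f_ref < min(surface)) d_best <- d_ref
  }

  e_best <- efun(d_best)
  predicted <- exp(.log_pred(table, e_best, conds, L_best, model))
  structure(list(L = L_best, d = d_best,
                 objective = obj_Ld(L_best, e_best),
                 predicted = data.frame(table$data,
                                        predicted = predicted),
                 ridge = ridge, surface = surface,
                 motif = table$motif, kind = table$kind,
                 energies = efun),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Geometry fit [%s, %s]: L = %.2f nm, d = %.3f nm, objective = %.4g\n",
    x$motif, x$kind, x$L, x$d, x$objective))
  print(x$predicted, digits = 4)
  invisible(x)
}

#' Write a fit result (and its objective surface) as CSV
#'
#' @param fit a `fit_result`.
#' @param path output CSV for the fit summary and predictions.
#' @param surface_path optional CSV for the objective surface.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path, surface_path = NULL) {
  hdr <- sprintf("# motif: %s; kind: %s; L: %.3f; d: %.4f; objective: %.6g",
                 fit$motif, fit$kind, fit$L, fit$d, fit$objective)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(fit$predicted, con, row.names = FALSE)
  close(con)
  if (!is.null(surface_path)) {
    utils::write.csv(cbind(d = rownames(fit$surface),
                           as.data.frame(fit$surface)),
                     surface_path, row.names = FALSE)
  }
  invisible(path)
}
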