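# Plane-strain finite element solver for the bilayer cross-section.
#
# Quadratic (P2) triangles; isotropic linear elasticity with a
# depth-dependent Young's modulus (constant per element, mesh lines are
# aligned with the moduli zone breaks) and near-incompressible Poisson
# ratio.  The pre-insertion stress state enters as an initial lateral
# stress sigma0(z) whose work against the strain is part of the energy
# functional,
#
#   F[u] = 1/2 int eps:C:eps dA + int sigma0(z) eps_xx dA - W_ext ,
#
# per unit length along the insertion axis, on the mirror half of the
# domain.  The monolayer interface (z = 0) transmits normal displacement
# but is traction-free tangentially (monolayers slide).  The right
# boundary stays straight; its rotation and translations are either frozen
# (void-creation step) or determined by energy minimisation (relaxation
# step), with per-monolayer lateral translations governed by the coupling
# mode.

.qp3 <- list(l = rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3)),
             w = rep(1 / 3, 3))

.qp7 <- local({
  a <- 0.059715871789770; b <- 0.470142064105115
  c1 <- 0.797426985353087; d <- 0.101286507323456
  list(l = rbind(c(1/3, 1/3, 1/3),
                 c(a, b, b), c(b, a, b), c(b, b, a),
                 c(c1, d, d), c(d, c1, d), c(d, d, c1)),
       w = c(0.225, rep(0.132394152788506, 3),
             rep(0.125939180544827, 3)))
})

# P2 shape-function gradients at one barycentric point, given the constant
# P1 gradients gl1, gl2, gl3 (each ntri x 2).  Returns list of two
# ntri x 6 matrices (d/dx, d/dz).
.p2_grads <- function(l, glx, glz) {
  l1 <- l[1]; l2 <- l[2]; l3 <- l[3]
  dx <- cbind((4 * l1 - 1) * glx[, 1],
              (4 * l2 - 1) * glx[, 2],
              (4 * l3 - 1) * glx[, 3],
              4 * (l2 * glx[, 1] + l1 * glx[, 2]),
              4 * (l3 * glx[, 2] + l2 * glx[, 3]),
              4 * (l1 * glx[, 3] + l3 * glx[, 1]))
  dz <- cbind((4 * l1 - 1) * glz[, 1],
              (4 * l2 - 1) * glz[, 2],
              (4 * l3 - 1) * glz[, 3],
              4 * (l2 * glz[, 1] + l1 * glz[, 2]),
              4 * (l3 * glz[, 2] + l2 * glz[, 3]),
              4 * (l1 * glz[, 3] + l3 * glz[, 1]))
  list(dx = dx, dz = dz)
}

#' Assemble the finite element operator on a mesh
#'
#' Builds the P2 node set, the degree-of-freedom map (with duplicated
#' lateral displacements along the sliding monolayer interface), and the
#' stiffness matrix for the given depth-dependent moduli.
#'
#' @param mesh a `tri_mesh`.
#' @param moduli a [moduli_profile()]; its Young's modulus is evaluated at
#'   element centroids (elements never straddle a moduli zone).
#' @param interface `"slip"` (default: the monolayers slide freely on each
#'   other, transmitting only normal displacement at the midplane) or
#'   `"bonded"` (continuous displacement; used by homogeneous-slab
#'   verification fixtures).
#' @return Object of class `fem_assembly`.
#' @export
fem_assemble <- function(mesh, moduli, interface = c("slip", "bonded")) {
  interface <- match.arg(interface)
  p <- mesh$nodes; tri <- mesh$triangles
  nv <- nrow(p); nt <- nrow(tri)

  ## P2 edge nodes
  eall <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(eall[, 1], eall[, 2]), pmax(eall[, 1], eall[, 2]))
  ukey <- unique(ekey)
  eidx <- match(ekey, ukey)
  ne <- length(ukey)
  first <- match(ukey, ekey)
  emat <- eall[first, , drop = FALSE]
  ecoord <- (p[emat[, 1], , drop = FALSE] + p[emat[, 2], , drop = FALSE]) / 2
  coords <- rbind(p, ecoord)                 # P2 node coords, n_p2 x 2
  np2 <- nv + ne
  # local P2 connectivity: v1 v2 v3, m12 m23 m31
  conn <- cbind(tri,
                nv + eidx[seq_len(nt)],
                nv + eidx[nt + seq_len(nt)],
                nv + eidx[2L * nt + seq_len(nt)])

  tol <- 1e-9
  ifn <- if (interface == "slip") which(abs(coords[, 2]) < tol)
         else integer(0)                     # interface P2 nodes
  ndof_base <- 2L * np2
  lower_x <- integer(np2)
  lower_x[ifn] <- ndof_base + seq_along(ifn)
  ndof <- ndof_base + length(ifn)
  dof_x <- seq_len(np2)
  dof_z <- np2 + seq_len(np2)

  ## element geometry
  x1 <- p[tri[, 1], 1]; z1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; z2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; z3 <- p[tri[, 3], 2]
  A2 <- (x2 - x1) * (z3 - z1) - (x3 - x1) * (z2 - z1)
  if (any(A2 <= 0)) stop("mesh contains inverted triangles")
  area <- A2 / 2
  glx <- cbind(z2 - z3, z3 - z1, z1 - z2) / A2
  glz <- cbind(x3 - x2, x1 - x3, x2 - x1) / A2
  zc <- (z1 + z2 + z3) / 3
  xc <- (x1 + x2 + x3) / 3
  upper <- zc > 0

  ## element dof map (ntri x 12): ux(1..6), uz(1..6)
  gdof <- matrix(0L, nt, 12L)
  for (a in 1:6) {
    nd <- conn[, a]
    dx <- dof_x[nd]
    low <- lower_x[nd]
    swap <- (!upper) & (low > 0L)
    dx[swap] <- low[swap]
    gdof[, a] <- dx
    gdof[, 6L + a] <- dof_z[nd]
  }

  ## moduli per element
  E_e <- moduli_at(moduli, zc)
  nu <- moduli$poisson
  fac <- E_e / ((1 + nu) * (1 - 2 * nu))
  c11 <- fac * (1 - nu); c12 <- fac * nu
  c33 <- E_e / (2 * (1 + nu))

  ## stiffness accumulation over the 3-point rule (exact for P2)
  Ke <- matrix(0, nt, 144L)                  # column (a-1)*12 + b
  for (q in seq_along(.qp3$w)) {
    g <- .p2_grads(.qp3$l[q, ], glx, glz)
    wA <- .qp3$w[q] * area
    for (a in 1:6) {
      for (b in a:6) {
        kxx <- wA * (c11 * g$dx[, a] * g$dx[, b] + c33 * g$dz[, a] * g$dz[, b])
        kzz <- wA * (c11 * g$dz[, a] * g$dz[, b] + c33 * g$dx[, a] * g$dx[, b])
        kxz <- wA * (c12 * g$dx[, a] * g$dz[, b] + c33 * g$dz[, a] * g$dx[, b])
        kzx <- wA * (c12 * g$dz[, a] * g$dx[, b] + c33 * g$dx[, a] * g$dz[, b])
        Ke[, (a - 1L) * 12L + b] <- Ke[, (a - 1L) * 12L + b] + kxx
        Ke[, (a - 1L) * 12L + 6L + b] <- Ke[, (a - 1L) * 12L + 6L + b] + kxz
        Ke[, (6L + a - 1L) * 12L + b] <- Ke[, (6L + a - 1L) * 12L + b] + kzx
        Ke[, (6L + a - 1L) * 12L + 6L + b] <- Ke[, (6L + a - 1L) * 12L + 6L + b] + kzz
        if (b > a) {
          Ke[, (b - 1L) * 12L + a] <- Ke[, (b - 1L) * 12L + a] + kxx
          Ke[, (b - 1L) * 12L + 6L + a] <- Ke[, (b - 1L) * 12L + 6L + a] + kzx
          Ke[, (6L + b - 1L) * 12L + a] <- Ke[, (6L + b - 1L) * 12L + a] + kxz
          Ke[, (6L + b - 1L) * 12L + 6L + a] <- Ke[, (6L + b - 1L) * 12L + 6L + a] + kzz
        }
      }
    }
  }
  ii <- matrix(0L, nt, 144L); jj <- matrix(0L, nt, 144L)
  for (a in 1:12) for (b in 1:12) {
    col <- (a - 1L) * 12L + b
    ii[, col] <- gdof[, a]; jj[, col] <- gdof[, b]
  }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(Ke), dims = c(ndof, ndof))

  ## quadrature caches for pre-stress load assembly (7-point rule)
  qcache <- vector("list", length(.qp7$w))
  for (q in seq_along(.qp7$w)) {
    l <- .qp7$l[q, ]
    g <- .p2_grads(l, glx, glz)
    zq <- l[1] * z1 + l[2] * z2 + l[3] * z3
    xq <- l[1] * x1 + l[2] * x2 + l[3] * x3
    qcache[[q]] <- list(z = zq, x = xq, wA = .qp7$w[q] * area,
                        dx = g$dx, dz = g$dz)
  }

  structure(list(mesh = mesh, moduli = moduli, interface = interface,
                 coords = coords, conn = conn, np2 = np2, ndof = ndof,
                 dof_x = dof_x, dof_z = dof_z, lower_x = lower_x,
                 gdof = gdof, area = area, upper = upper, zc = zc, xc = xc,
                 glx = glx, glz = glz,
                 E_e = E_e, c11 = c11, c12 = c12, c33 = c33,
                 K = K, qcache = qcache),
            class = "fem_assembly")
}

#' Rigid-insertion boundary condition
#'
#' The insertion is far more rigid than the bilayer and imposes, on the
#' mirror boundary, the horizontal displacement that carves its half
#' cross-section out of the membrane: `u_x(0, z) = scale * w(z)` with
#' `w(z)` the half-chord of the rod's circular cross-section below the
#' outer surface, and `u_x = 0` elsewhere on the mirror boundary.
#'
#' @param asm a [fem_assemble()] result.
#' @param geom an [insertion_geometry()].
#' @param scale amplitude multiplier of the imposed displacement (1 = full
#'   insertion; used for continuity checks).
#' @return Object of class `insertion_bc`: P2 node indices on the mirror
#'   boundary, their imposed `u_x` values, and the half-void influx area.
#' @export
impose_insertion <- function(asm, geom, scale = 1) {
  h <- asm$mesh$h
  vc <- void_cross_section(geom, h)
  tol <- 1e-9
  left <- which(abs(asm$coords[, 1]) < tol)
  zs <- asm$coords[left, 2]
  ord <- order(zs)
  left <- left[ord]; zs <- zs[ord]
  vals <- scale * vc$half_width(zs)
  if (geom$d > 0 && !any(vc$half_width(zs) > 0))
    stop("no mesh nodes on the insertion arc; refine the mesh vertically")
  # discrete influx: integral of the P2 interpolant of the imposed
  # displacement along the boundary (Simpson on vertex/mid/vertex triples),
  # so that the coupled-mode conservation constraint is exact
  n <- length(left)
  if (n %% 2L != 1L)
    stop("mirror boundary node pattern is not vertex/midpoint alternating")
  iv <- seq(1L, n - 2L, by = 2L)
  influx <- sum((zs[iv + 2L] - zs[iv]) / 6 *
                  (vals[iv] + 4 * vals[iv + 1L] + vals[iv + 2L]))
  structure(list(nodes = left, values = vals, scale = scale,
                 influx = influx, geom = geom),
            class = "insertion_bc")
}

#' External load specification
#'
#' @param torque external bending moment per unit length applied at the far
#'   boundary, kT nm^-1 (conjugate to the boundary rotation).
#' @param force_out,force_in lateral stretching force per unit length
#'   applied to the outer/inner monolayer at the far boundary, kT nm^-2.
#' @param maintain if `TRUE` (default), the loads that maintain the
#'   pre-insertion stress state (the lab-frame moment and per-monolayer
#'   tensions of the initial stress profiles) are added automatically, so
#'   that the pre-insertion configuration is an equilibrium of the model.
#' @return Object of class `load_spec`.
#' @export
load_spec <- function(torque = 0, force_out = 0, force_in = 0,
                      maintain = TRUE) {
  stopifnot(is.finite(torque), is.finite(force_out), is.finite(force_in))
  structure(list(torque = torque, force_out = force_out,
                 force_in = force_in, maintain = maintain),
            class = "load_spec")
}

# maintaining loads of a prestress pair (list(outer=, inner=) of
# stress_profile or NULL)
.maintain_loads <- function(prestress) {
  if (is.null(prestress)) return(list(M = 0, F_out = 0, F_in = 0))
  mo <- profile_moments(prestress$outer)
  mi <- profile_moments(prestress$inner)
  zo <- prestress$outer; zi <- prestress$inner
  Mlab <- .moment1(zo$z_grid, zo$sigma, 0) -
    .moment1(zi$z_grid, zi$sigma, 0)
  list(M = Mlab, F_out = unname(mo["gamma"]), F_in = unname(mi["gamma"]))
}

#' Reduce the operator under boundary conditions and solve-mode flags
#'
#' Eliminates the constrained degrees of freedom: imposed `u_x` on the
#' mirror boundary, the straight far boundary tied to the scalar rotation
#' and translation variables, the monolayer-coupling constraint, and one
#' pinned vertical displacement that removes the rigid vertical mode.
#'
#' @param asm a [fem_assemble()] result.
#' @param bcs an [impose_insertion()] result, or `NULL` for no insertion.
#' @param coupling `"uncoupled"` (each monolayer exchanges lipid with a
#'   reservoir: independent lateral boundary translations) or `"coupled"`
#'   (each monolayer's integrated lateral strain is conserved).
#' @param relax_rotation if `TRUE` the far boundary may rotate (its angle is
#'   an energy-minimisation variable); `FALSE` freezes the membrane shape
#'   (void-creation step).  The boundary stays a straight symmetry plane in
#'   both cases: its lateral displacement is affine in depth while material
#'   slides freely along it.
#' @return Object of class `fem_operator` with the reduction and the
#'   factorised reduced stiffness.
#' @export
fem_reduce <- function(asm, bcs = NULL, coupling = c("uncoupled", "coupled"),
                       relax_rotation = TRUE) {
  coupling <- match.arg(coupling)
  rotate <- isTRUE(relax_rotation)
  h <- asm$mesh$h; L <- asm$mesh$L_dom
  tol <- 1e-9
  ndof <- asm$ndof
  coords <- asm$coords
  influx <- if (is.null(bcs)) 0 else bcs$influx

  g0 <- numeric(ndof)
  fixed <- logical(ndof)

  ## mirror boundary u_x (includes the insertion arc)
  left <- which(abs(coords[, 1]) < tol)
  fixed[asm$dof_x[left]] <- TRUE
  lowl <- asm$lower_x[left]
  fixed[lowl[lowl > 0L]] <- TRUE             # lower interface copy at x=0
  if (!is.null(bcs)) {
    g0[asm$dof_x[bcs$nodes]] <- bcs$values
    low <- asm$lower_x[bcs$nodes]
    has <- low > 0L
    g0[low[has]] <- bcs$values[has]          # arc never reaches z<=0; zero anyway
  }

  ## pin one vertical dof (mirror-boundary bottom corner)
  pin <- left[which.min(coords[left, 2])]
  fixed[asm$dof_z[pin]] <- TRUE

  ## far boundary: u_x affine in z (straight symmetry plane), u_z free
  right <- which(abs(coords[, 1] - L) < tol)
  rz <- coords[right, 2]
  rdx_up <- asm$dof_x[right]
  rlow <- asm$lower_x[right]
  fixed[rdx_up] <- TRUE
  fixed[rlow[rlow > 0L]] <- TRUE

  ## scalar variables; a bonded interface admits only one lateral
  ## translation (no displacement jump at the midplane)
  two_trans <- asm$interface == "slip"
  if (coupling == "coupled" && !two_trans)
    stop("coupled mode requires the sliding monolayer interface")
  scal <- character(0)
  if (rotate) scal <- c(scal, "theta")
  if (coupling == "uncoupled")
    scal <- c(scal, if (two_trans) c("Ux_out", "Ux_in") else "Ux")
  free <- which(!fixed)
  nfree <- length(free)
  nq <- nfree + length(scal)
  scol <- stats::setNames(nfree + seq_along(scal), scal)

  ti <- free; tj <- seq_len(nfree); tx <- rep(1, nfree)
  addG <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }

  # far-boundary u_x rows: value = Ux_m + theta * z (uncoupled)
  #                        value = influx_m/h + theta * (z -/+ h/2) (coupled)
  up_is_outer <- rep(TRUE, length(right))    # upper ux copy serves z >= 0 side
  for (k in seq_along(right)) {
    z <- rz[k]
    # upper copy: outer monolayer if z > 0, z == 0 boundary row belongs to outer
    dof_up <- rdx_up[k]
    dof_lo <- rlow[k]
    side_up <- if (z >= -tol) "out" else "in"
    rows <- c(dof_up, if (dof_lo > 0L) dof_lo)
    sides <- c(side_up, if (dof_lo > 0L) "in")
    for (m in seq_along(rows)) {
      dd <- rows[m]; sd <- sides[m]
      if (coupling == "uncoupled") {
        ucol <- if (two_trans) scol[[paste0("Ux_", sd)]] else scol[["Ux"]]
        addG(dd, ucol, 1)
        if (rotate) addG(dd, scol[["theta"]], z)
      } else {
        if (sd == "out") {
          g0[dd] <- influx / h
          if (rotate) addG(dd, scol[["theta"]], z - h / 2)
        } else {
          if (rotate) addG(dd, scol[["theta"]], z + h / 2)
        }
      }
    }
  }
  G <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nq))
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(G, asm$K %*% G))
  fac <- tryCatch(Matrix::Cholesky(Kr, LDL = FALSE, perm = TRUE),
                  error = function(e)
                    stop("singular reduced system (unconstrained rigid ",
                         "mode?): ", conditionMessage(e)))
  structure(list(asm = asm, bcs = bcs, coupling = coupling,
                 relax_rotation = rotate,
                 G = G, g0 = g0, free = free, scol = as.list(scol),
                 Kr = Kr, factor = fac, influx = influx, h = h),
            class = "fem_operator")
}

# pre-stress load vector: f[i] = int sigma0(z) dN_i/dx dA over the half
# domain, using the upper/lower monolayer profiles.
.prestress_load <- function(asm, prestress) {
  f <- numeric(asm$ndof)
  if (is.null(prestress)) return(f)
  for (q in asm$qcache) {
    zq <- q$z
    sig <- numeric(length(zq))
    up <- zq > 0
    sig[up] <- profile_at(prestress$outer, zq[up])
    sig[!up] <- profile_at(prestress$inner, -zq[!up])
    coef <- q$wA * sig
    idx <- as.vector(asm$gdof[, 1:6])
    val <- as.vector(coef * q$dx)
    agg <- rowsum(val, idx)
    f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
  }
  f
}

#' Solve the displacement equilibrium for one load case
#'
#' Minimises the quadratic energy functional (elastic energy + work against
#' the initial stress - external work) over the admissible displacement
#' space of the operator.
#'
#' @param op a [fem_reduce()] result.
#' @param prestress `NULL`, or `list(outer =, inner =)` of
#'   [build_stress_profile()] objects (each in its monolayer's own frame).
#' @param loads a [load_spec()].
#' @return Object of class `elastic_state`: displacement vector, scalar
#'   boundary variables, energy components (per unit insertion length, half
#'   domain) and accessors used by the energy bookkeeping.
#' @export
solve_equilibrium <- function(op, prestress = NULL, loads = load_spec()) {
  asm <- op$asm
  f <- .prestress_load(asm, prestress)
  mnt <- if (isTRUE(loads$maintain)) .maintain_loads(prestress)
         else list(M = 0, F_out = 0, F_in = 0)

  h <- op$h
  ## External work, expressed on the reduced coordinates: W = wq' q + w0.
  ## Maintaining loads are the boundary flux of the pre-insertion stress
  ## profile against the (affine) boundary motion: per-monolayer tensions
  ## referenced to z = 0 plus the lab-frame moment of sigma0.  User loads:
  ## the torque acts about z = 0; stretching forces act at each monolayer's
  ## mid-height (+-h/2), so they exert no moment by themselves.
  nq <- ncol(op$G)
  wq <- numeric(nq); w0 <- 0
  sc <- op$scol
  if (op$coupling == "uncoupled") {
    if (!is.null(sc$Ux_out)) wq[sc$Ux_out] <- loads$force_out + mnt$F_out
    if (!is.null(sc$Ux_in)) wq[sc$Ux_in] <- loads$force_in + mnt$F_in
    if (!is.null(sc$Ux))
      wq[sc$Ux] <- loads$force_out + loads$force_in + mnt$F_out + mnt$F_in
    if (!is.null(sc$theta))
      wq[sc$theta] <- loads$torque + mnt$M +
        loads$force_out * h / 2 - loads$force_in * h / 2
  } else {
    if (!is.null(sc$theta))
      wq[sc$theta] <- loads$torque + mnt$M -
        mnt$F_out * h / 2 + mnt$F_in * h / 2
    w0 <- (loads$force_out + mnt$F_out) * op$influx / h
  }

  Kg0 <- asm$K %*% op$g0
  b <- as.numeric(Matrix::crossprod(op$G, Kg0 + f)) - wq
  q <- as.numeric(Matrix::solve(op$factor, -b, system = "A"))
  u <- as.numeric(op$G %*% q) + op$g0

  E_strain <- 0.5 * sum(u * as.numeric(asm$K %*% u))
  E_pre <- sum(f * u)
  theta <- if (!is.null(sc$theta)) q[sc$theta] else 0
  if (op$coupling == "uncoupled") {
    if (!is.null(sc$Ux)) {
      Ux_out <- Ux_in <- q[sc$Ux]
    } else {
      Ux_out <- if (!is.null(sc$Ux_out)) q[sc$Ux_out] else 0
      Ux_in <- if (!is.null(sc$Ux_in)) q[sc$Ux_in] else 0
    }
  } else {
    Ux_out <- op$influx / h - theta * h / 2
    Ux_in <- theta * h / 2
  }
  W_ext <- sum(wq * q) + w0
  structure(list(op = op, u = u, q = q,
                 theta = theta, Ux_out = Ux_out, Ux_in = Ux_in,
                 loads = list(M = loads$torque + mnt$M,
                              F_out = loads$force_out + mnt$F_out,
                              F_in = loads$force_in + mnt$F_in),
                 E_strain = E_strain, E_pre = E_pre, W_ext = W_ext,
                 energy_half = E_strain + E_pre - W_ext),
            class = "elastic_state")
}

#' Total energy of a solved state
#'
#' The energy change of the full (mirror-symmetric) membrane element per
#' insertion, in kT: elastic strain energy plus the work against the
#' initial stresses minus the work of the external loads, doubled for the
#' mirror half and multiplied by the insertion length.
#'
#' @param state an `elastic_state`.
#' @param L_ins insertion length, nm (defaults to the mesh geometry's).
#' @return energy, kT.
#' @export
total_energy <- function(state, L_ins = NULL) {
  if (is.null(L_ins)) L_ins <- state$op$asm$mesh$geom$L_ins
  2 * state$energy_half * L_ins
}

#' Per-element strain and stress fields of a solved state
#'
#' Centroid values of the strain and total stress (elastic plus initial
#' lateral stress) on each triangle.
#'
#' @param state an `elastic_state`.
#' @param prestress the prestress pair used in the solve (optional; adds
#'   `sigma0` to the lateral stress).
#' @return data.frame with element centroid coordinates, strains, stresses
#'   and strain-energy density.
#' @export
element_fields <- function(state, prestress = NULL) {
  asm <- state$op$asm
  l <- c(1, 1, 1) / 3
  g <- .p2_grads(l, asm$glx, asm$glz)
  U <- matrix(state$u[asm$gdof], nrow = nrow(asm$gdof))
  exx <- rowSums(U[, 1:6] * g$dx)
  ezz <- rowSums(U[, 7:12] * g$dz)
  gxz <- rowSums(U[, 1:6] * g$dz) + rowSums(U[, 7:12] * g$dx)
  s0 <- numeric(length(exx))
  if (!is.null(prestress)) {
    up <- asm$zc > 0
    s0[up] <- profile_at(prestress$outer, asm$zc[up])
    s0[!up] <- profile_at(prestress$inner, -asm$zc[!up])
  }
  sxx <- asm$c11 * exx + asm$c12 * ezz + s0
  szz <- asm$c12 * exx + asm$c11 * ezz
  sxz <- asm$c33 * gxz
  edens <- 0.5 * ((asm$c11 * exx + asm$c12 * ezz) * exx +
                    (asm$c12 * exx + asm$c11 * ezz) * ezz + sxz * gxz)
  data.frame(x = asm$xc, z = asm$zc, area = asm$area,
             exx = exx, ezz = ezz, gxz = gxz,
             sxx = sxx, szz = szz, sxz = sxz,
             energy_density = edens)
}

#' Integrated lateral strain per monolayer
#'
#' @param state an `elastic_state`.
#' @return named vector `c(outer =, inner =)`, the integral of `eps_xx`
#'   over each monolayer of the half domain, nm^2.
#' @export
monolayer_lateral_strain <- function(state) {
  asm <- state$op$asm
  exx_int <- numeric(2)
  for (q in asm$qcache) {
    U <- matrix(state$u[asm$gdof[, 1:6]], nrow = nrow(asm$gdof))
    e <- rowSums(U * q$dx) * q$wA
    exx_int[1] <- exx_int[1] + sum(e[asm$upper])
    exx_int[2] <- exx_int[2] + sum(e[!asm$upper])
  }
  c(outer = exx_int[1], inner = exx_int[2])
}

#' Residual tractions on the free surfaces
#'
#' Ratio of the mean traction magnitude on the outer/inner surfaces
#' (computed from adjacent element centroid stresses) to the peak interior
#' stress norm; a weak-form check that the free surfaces are stress-free.
#'
#' @param state an `elastic_state`.
#' @param prestress optional prestress pair (its lateral component exerts
#'   no traction on horizontal surfaces).
#' @return dimensionless residual ratio.
#' @export
surface_traction_residual <- function(state, prestress = NULL) {
  ef <- element_fields(state, prestress)
  asm <- state$op$asm
  h <- asm$mesh$h
  hmean <- sqrt(mean(asm$area))
  near <- abs(abs(ef$z) - h) < 3 * hmean
  tr <- sqrt(ef$szz[near]^2 + ef$sxz[near]^2)
  peak <- max(sqrt(ef$sxx^2 + ef$szz^2 + 2 * ef$sxz^2))
  if (peak == 0) return(0)
  mean(tr) / peak
}
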