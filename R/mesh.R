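# Cross-section geometry of the bilayer and triangular meshing.
#
# The computational domain is the right half of a membrane element of
# length 2*L_dom and thickness 2h: x in [0, L_dom], z in [-h, h].  The left
# boundary (x = 0) is the mirror plane through the insertion axis; the
# insertion imposes its half cross-section there as a horizontal
# displacement.  The right boundary is the far, straight boundary where the
# relaxation degrees of freedom (rotation, translations) live.

#' Insertion geometry
#'
#' A rigid cylindrical rod of circular cross-section lying parallel to the
#' membrane plane, partially embedded into the outer monolayer.
#'
#' @param r cross-sectional radius, nm.
#' @param d embedding depth of the rod's lowest point below the outer
#'   surface, nm.
#' @param L_ins insertion length along the membrane plane, nm.
#' @return Object of class `insertion_geometry`.
#' @export
insertion_geometry <- function(r = 0.5, d = 0.8, L_ins = 2) {
  stopifnot(is.numeric(r), r > 0, is.numeric(d), is.numeric(L_ins),
            L_ins > 0)
  structure(list(r = r, d = d, L_ins = L_ins), class = "insertion_geometry")
}

#' Void cross-section of an embedded insertion
#'
#' The void is the part of the rod's circular cross-section (radius `r`,
#' center at `z = h - d + r`) lying below the outer surface `z = h`.  Its
#' area follows the circular-segment closed form.
#'
#' @param geom an [insertion_geometry()].
#' @param h monolayer thickness, nm.
#' @return list with `area` (nm^2), `z_center`, `z_lo`, `z_hi` (the vertical
#'   extent of the void) and `half_width(z)`, the half-chord function used
#'   as the imposed boundary displacement.
#' @export
void_cross_section <- function(geom, h = 2) {
  r <- geom$r; d <- geom$d
  if (d > h)
    stop("embedding depth d = ", d, " exceeds the monolayer thickness h = ",
         h, "; the void would pierce beyond the model's validity")
  if (d <= 0) {
    return(list(area = 0, z_center = h + r, z_lo = h, z_hi = h,
                half_width = function(z) numeric(length(z))))
  }
  zc <- h - d + r
  z_lo <- h - d
  z_hi <- min(h, zc + r)
  if (d >= 2 * r) {
    area <- pi * r^2
  } else {
    t <- h - zc                              # = d - r, in (-r, r)
    seg_above <- r^2 * acos(t / r) - t * sqrt(r^2 - t^2)
    area <- pi * r^2 - seg_above
  }
  half_width <- function(z) {
    w <- r^2 - (z - zc)^2
    w[w < 0] <- 0
    out <- sqrt(w)
    out[z > h | z < z_lo] <- 0
    out
  }
  list(area = area, z_center = zc, z_lo = z_lo, z_hi = z_hi,
       half_width = half_width)
}

#' Mesh generation controls
#'
#' @param L_dom half-domain length along the membrane plane, nm.  The
#'   modelled membrane element has total length `2 * L_dom`.
#' @param dz_fine vertical element size in the outer headgroup region
#'   (upper half of the outer monolayer), nm.
#' @param aspect_max maximum element aspect ratio (horizontal over vertical
#'   size); keeps the minimum triangle angle above ~20 degrees.
#' @param min_elements minimum number of triangles of the initial mesh.
#' @param min_elements_refined element count the adaptive refinement must
#'   reach.
#' @param refine_fraction fraction of elements (largest error indicators)
#'   marked in one adaptive pass.
#' @param max_refine_passes cap on adaptive passes.
#' @return list of controls.
#' @export
mesh_control <- function(L_dom = 20, dz_fine = 0.1, aspect_max = 2.4,
                         min_elements = 1908, min_elements_refined = 5514,
                         refine_fraction = 0.25, max_refine_passes = 8) {
  list(L_dom = L_dom, dz_fine = dz_fine, aspect_max = aspect_max,
       min_elements = min_elements,
       min_elements_refined = min_elements_refined,
       refine_fraction = refine_fraction,
       max_refine_passes = max_refine_passes)
}

# Vertical grid lines of the cross-section: finest in the upper half of the
# outer monolayer (insertion zone), moderate elsewhere; always includes the
# midplane, the moduli zone breaks (+-h/2) and the void bottom (h - d).
.z_lines <- function(h, dz_fine, z_extra = numeric(0)) {
  seg <- function(a, b, dz) seq(a, b, length.out = max(2L, ceiling((b - a) / dz) + 1L))
  z <- sort(unique(c(
    seg(-h, -h / 2, 2.5 * dz_fine),
    seg(-h / 2, 0, 2 * dz_fine),
    seg(0, h / 2, 2 * dz_fine),
    seg(h / 2, h, dz_fine)
  )))
  for (ze in z_extra) {
    if (ze > -h && ze < h && min(abs(z - ze)) > 0.25 * dz_fine)
      z <- sort(c(z, ze))
  }
  z
}

#' Build the triangular mesh of the bilayer cross-section
#'
#' Structured, graded triangulation of the rectangle
#' `[0, L_dom] x [-h, h]`, vertically refined in the insertion zone, with
#' grid lines at the midplane, the moduli zone breaks and the void bottom.
#' Use [refine_adaptive()] (or [embed_insertion()], which does it
#' automatically) to refine towards the insertion.
#'
#' @param geom an [insertion_geometry()].
#' @param h monolayer thickness, nm.
#' @param control a [mesh_control()] list.
#' @return Object of class `tri_mesh`: `nodes` (n x 2), `triangles`
#'   (m x 3, counter-clockwise), plus the domain parameters.
#' @export
build_mesh <- function(geom = insertion_geometry(), h = 2,
                       control = mesh_control()) {
  L <- control$L_dom
  zl <- .z_lines(h, control$dz_fine,
                 z_extra = if (geom$d > 0) h - geom$d else numeric(0))
  dz_min <- min(diff(zl))
  dx <- control$aspect_max * dz_min
  nx <- max(4L, ceiling(L / dx))
  # honour the minimum element count
  while (2L * nx * (length(zl) - 1L) < control$min_elements) nx <- nx + 1L
  xl <- seq(0, L, length.out = nx + 1L)
  nzl <- length(zl)
  nodes <- cbind(x = rep(xl, each = nzl), z = rep(zl, times = nx + 1L))
  idx <- function(i, j) (i - 1L) * nzl + j    # column i (x), row j (z)
  tris <- matrix(0L, nrow = 2L * nx * (nzl - 1L), ncol = 3L)
  k <- 0L
  for (i in seq_len(nx)) {
    j <- seq_len(nzl - 1L)
    n00 <- idx(i, j); n10 <- idx(i + 1L, j)
    n01 <- idx(i, j + 1L); n11 <- idx(i + 1L, j + 1L)
    m <- length(j)
    tris[k + seq_len(m), ] <- cbind(n00, n10, n11)
    tris[k + m + seq_len(m), ] <- cbind(n00, n11, n01)
    k <- k + 2L * m
  }
  mesh <- structure(list(nodes = nodes, triangles = tris,
                         h = h, L_dom = L, geom = geom,
                         refine_level = 0L),
                    class = "tri_mesh")
  mesh
}

#' Signed areas of all triangles
#' @param mesh a `tri_mesh`.
#' @return numeric vector of signed areas (positive for counter-clockwise).
#' @export
triangle_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  x1 <- p[t[, 1], 1]; z1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; z2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; z3 <- p[t[, 3], 2]
  ((x2 - x1) * (z3 - z1) - (x3 - x1) * (z2 - z1)) / 2
}

#' Minimum interior angle of each triangle (degrees)
#' @param mesh a `tri_mesh`.
#' @return numeric vector of minimum angles.
#' @export
triangle_min_angles <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  a <- sqrt(rowSums((p[t[, 2], ] - p[t[, 3], ])^2))
  b <- sqrt(rowSums((p[t[, 1], ] - p[t[, 3], ])^2))
  cc <- sqrt(rowSums((p[t[, 1], ] - p[t[, 2], ])^2))
  A <- acos(pmin(1, pmax(-1, (b^2 + cc^2 - a^2) / (2 * b * cc))))
  B <- acos(pmin(1, pmax(-1, (a^2 + cc^2 - b^2) / (2 * a * cc))))
  C <- pi - A - B
  pmin(A, pmin(B, C)) * 180 / pi
}

# Boundary edges (appearing in exactly one triangle) with tags derived from
# the domain geometry.  Returns a data.frame with node indices and tag.
.boundary_edges <- function(mesh) {
  t <- mesh$triangles
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  eb <- e[match(bkey, key), , drop = FALSE]
  p <- mesh$nodes
  mx <- (p[eb[, 1], 1] + p[eb[, 2], 1]) / 2
  mz <- (p[eb[, 1], 2] + p[eb[, 2], 2]) / 2
  tol <- 1e-9
  vc <- void_cross_section(mesh$geom, mesh$h)
  tag <- character(nrow(eb))
  tag[abs(mz - mesh$h) < tol] <- "outer_surface"
  tag[abs(mz + mesh$h) < tol] <- "inner_surface"
  tag[abs(mx - mesh$L_dom) < tol] <- "right_relax"
  left <- abs(mx) < tol
  tag[left] <- ifelse(mz[left] > vc$z_lo + tol & mz[left] < vc$z_hi - tol &
                        mesh$geom$d > 0,
                      "insertion_arc", "left_symmetry")
  if (any(tag == "")) stop("untagged boundary edge; corrupt mesh")
  data.frame(n1 = eb[, 1], n2 = eb[, 2], tag = tag,
             stringsAsFactors = FALSE)
}

#' Boundary edges and their tags
#'
#' @param mesh a `tri_mesh`.
#' @return data.frame with columns `n1`, `n2` (node indices) and `tag`, one
#'   of `insertion_arc`, `outer_surface`, `inner_surface`, `left_symmetry`,
#'   `right_relax`.
#' @export
boundary_tags <- function(mesh) .boundary_edges(mesh)

#' Adaptive mesh refinement by longest-edge bisection
#'
#' Marks the elements with the largest error indicators and refines them by
#' recursive longest-edge (Rivara) bisection, propagating to neighbours as
#' needed to keep the mesh conforming.  The refined finite-element space
#' nests the coarse one, so energies cannot increase under refinement.
#'
#' @param mesh a `tri_mesh`.
#' @param field per-element error indicator (numeric, one value per
#'   triangle); `NULL` refines uniformly.
#' @param fraction fraction of elements to mark.
#' @return The refined `tri_mesh`.
#' @export
refine_adaptive <- function(mesh, field = NULL, fraction = 0.25) {
  nt <- nrow(mesh$triangles)
  if (is.null(field)) {
    marked <- rep(TRUE, nt)
  } else {
    stopifnot(length(field) == nt)
    thr <- stats::quantile(field, probs = 1 - fraction, names = FALSE,
                           type = 1)
    marked <- field >= thr
    if (!any(marked)) marked[which.max(field)] <- TRUE
  }

  nodes <- mesh$nodes
  tris <- mesh$triangles
  midmap <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))

  get_mid <- function(i, j) {
    k <- ekey(i, j)
    m <- midmap[[k]]
    if (!is.null(m)) return(m)
    nodes <<- rbind(nodes, (nodes[i, ] + nodes[j, ]) / 2)
    m <- nrow(nodes)
    midmap[[k]] <- m
    m
  }

  # rotate each triangle so its longest edge is (v1, v2)
  longest_rot <- function(tr) {
    p1 <- nodes[tr[1], ]; p2 <- nodes[tr[2], ]; p3 <- nodes[tr[3], ]
    l12 <- sum((p2 - p1)^2); l23 <- sum((p3 - p2)^2); l31 <- sum((p1 - p3)^2)
    w <- which.max(c(l12, l23, l31))
    if (w == 1L) tr else if (w == 2L) tr[c(2L, 3L, 1L)] else tr[c(3L, 1L, 2L)]
  }

  pending <- new.env(hash = TRUE, parent = emptyenv())  # edge keys to split
  for (ti in which(marked)) {
    tr <- longest_rot(tris[ti, ])
    pending[[ekey(tr[1], tr[2])]] <- TRUE
  }

  repeat {
    if (length(ls(pending)) == 0L) break
    keys1 <- paste(pmin(tris[, 1], tris[, 2]), pmax(tris[, 1], tris[, 2]))
    keys2 <- paste(pmin(tris[, 2], tris[, 3]), pmax(tris[, 2], tris[, 3]))
    keys3 <- paste(pmin(tris[, 3], tris[, 1]), pmax(tris[, 3], tris[, 1]))
    pset <- ls(pending)
    touch <- (keys1 %in% pset) | (keys2 %in% pset) | (keys3 %in% pset)
    if (!any(touch)) break                    # all pending edges consumed
    keep <- list(); add <- list()
    progressed <- FALSE
    for (ti in which(touch)) {
      tr <- longest_rot(tris[ti, ])
      lk <- ekey(tr[1], tr[2])
      if (lk %in% pset) {
        m <- get_mid(tr[1], tr[2])
        add[[length(add) + 1L]] <- rbind(c(tr[1], m, tr[3]),
                                         c(m, tr[2], tr[3]))
        progressed <- TRUE
      } else {
        pending[[lk]] <- TRUE                 # propagate, split next round
        add[[length(add) + 1L]] <- rbind(tr)
      }
    }
    tris <- rbind(tris[!touch, , drop = FALSE], do.call(rbind, add))
    # drop pending edges that no longer exist in the mesh
    keys1 <- paste(pmin(tris[, 1], tris[, 2]), pmax(tris[, 1], tris[, 2]))
    keys2 <- paste(pmin(tris[, 2], tris[, 3]), pmax(tris[, 2], tris[, 3]))
    keys3 <- paste(pmin(tris[, 3], tris[, 1]), pmax(tris[, 3], tris[, 1]))
    alive <- unique(c(keys1, keys2, keys3))
    for (k in ls(pending)) if (!(k %in% alive)) rm(list = k, envir = pending)
    if (!progressed && length(ls(pending)) == 0L) break
  }

  out <- mesh
  out$nodes <- nodes
  rownames(out$nodes) <- NULL
  out$triangles <- tris
  out$refine_level <- mesh$refine_level + 1L
  out
}

#' Euler characteristic check of a simply connected mesh
#'
#' @param mesh a `tri_mesh`.
#' @return `V - E + F` where `F` counts triangles (1 for a triangulated
#'   disk).
#' @export
euler_characteristic <- function(mesh) {
  t <- mesh$triangles
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nv <- length(unique(as.vector(t)))
  nv - length(key) + nrow(t)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("Bilayer cross-section mesh: ", nrow(x$triangles), " triangles, ",
      nrow(x$nodes), " vertices (refine level ", x$refine_level, ")\n",
      sep = "")
  cat("  domain [0, ", x$L_dom, "] x [", -x$h, ", ", x$h, "] nm; insertion r = ",
      x$geom$r, ", d = ", x$geom$d, " nm\n", sep = "")
  invisible(x)
}

#' Export a mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh a `tri_mesh`.
#' @param path output `.vtk` file.
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-triangle numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- mesh$nodes; t <- mesh$triangles
  writeLines(c("# vtk DataFile Version 3.0",
               "bilayer cross-section", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(p), "double")), con)
  writeLines(sprintf("%.9g %.9g 0", p[, 1], p[, 2]), con)
  writeLines(paste("CELLS", nrow(t), 4 * nrow(t)), con)
  writeLines(sprintf("3 %d %d %d", t[, 1] - 1L, t[, 2] - 1L, t[, 3] - 1L),
             con)
  writeLines(paste("CELL_TYPES", nrow(t)), con)
  writeLines(rep("5", nrow(t)), con)
  wr <- function(dat, hdr) {
    writeLines(hdr, con)
    for (nm in names(dat)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", dat[[nm]]), con)
    }
  }
  if (length(point_data)) wr(point_data, paste("POINT_DATA", nrow(p)))
  if (length(cell_data)) wr(cell_data, paste("CELL_DATA", nrow(t)))
  invisible(path)
}

#' Export mesh node and element tables as CSV
#'
#' @param mesh a `tri_mesh`.
#' @param node_path,element_path output files.
#' @return invisibly, the two paths.
#' @export
write_mesh_csv <- function(mesh, node_path, element_path) {
  utils::write.csv(data.frame(x = mesh$nodes[, 1], z = mesh$nodes[, 2]),
                   node_path, row.names = FALSE)
  utils::write.csv(data.frame(n1 = mesh$triangles[, 1],
                              n2 = mesh$triangles[, 2],
                              n3 = mesh$triangles[, 3]),
                   element_path, row.names = FALSE)
  invisible(c(node_path, element_path))
}
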