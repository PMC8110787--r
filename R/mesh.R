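#' Two-layer turgid pollen-wall model
#'
#' Parameterizes the unpressurized pollen grain: an ellipsoid of
#' revolution about the major axis carrying a two-layer wall (inner
#' intine, outer exine) with the exine absent over the colpus band.
#' Defaults follow average lily pollen geometry: unpressurized axes
#' 128 x 97 um, intine 1.5 um, exine 0.5 um thick.
#'
#' @param major_axis_0,minor_axis_0 unpressurized full axes (um).
#' @param t_intine,t_exine layer thicknesses (um).
#' @param E_i,E_e Young's moduli of intine and exine (MPa).
#' @param nu Poisson's ratio (both layers).
#' @param P turgor pressure (MPa).
#' @param colpus_half_width angular half-width of the colpus band
#'   (degrees) measured around the major axis; 0 removes the colpus.
#' @param colpus_axial_extent fraction of the major semi-axis covered by
#'   the colpus band, so the furrow terminates before the grain tips.
#' @return an object of class `pollen_model`.
#' @export
pollen_model <- function(major_axis_0 = 128, minor_axis_0 = 97,
                         t_intine = 1.5, t_exine = 0.5,
                         E_i = 10, E_e = 20, nu = 0.3, P = 0.2,
                         colpus_half_width = 25,
                         colpus_axial_extent = 0.85) {
  stopifnot(major_axis_0 > 0, minor_axis_0 > 0, t_intine > 0, t_exine > 0,
            E_i > 0, E_e > 0, nu > 0, nu < 0.5, P >= 0,
            colpus_half_width >= 0, colpus_axial_extent > 0,
            colpus_axial_extent < 1)
  if (colpus_half_width >= 90)
    stop("colpus band must cover less than half of the surface")
  structure(list(major_axis_0 = major_axis_0, minor_axis_0 = minor_axis_0,
                 t_intine = t_intine, t_exine = t_exine,
                 E_i = E_i, E_e = E_e, nu = nu, P = P,
                 colpus_half_width = colpus_half_width,
                 colpus_axial_extent = colpus_axial_extent),
            class = "pollen_model")
}

#' @export
print.pollen_model <- function(x, ...) {
  cat("Two-layer turgid pollen-wall model\n")
  cat(sprintf("  unpressurized axes : %.1f x %.1f um\n",
              x$major_axis_0, x$minor_axis_0))
  cat(sprintf("  wall               : intine %.2f um (E_i = %g MPa), exine %.2f um (E_e = %g MPa)\n",
              x$t_intine, x$E_i, x$t_exine, x$E_e))
  cat(sprintf("  nu = %.2f, turgor P = %g MPa, colpus half-width %g deg\n",
              x$nu, x$P, x$colpus_half_width))
  invisible(x)
}

#' Reduced spherical-shell model
#'
#' Single-layer sphere used to study the bending-to-stretching
#' transition of the indentation response.  The `solid_wedge` variant
#' discretizes the wall with one prism element through the thickness;
#' the `membrane` variant uses surface elements with no bending
#' resistance.
#'
#' @param diameter mid-surface diameter (um).
#' @param thickness wall thickness (um).
#' @param element_kind `"solid_wedge"` or `"membrane"`.
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param P internal pressure (MPa).
#' @return an object of class `sphere_shell_model`.
#' @export
sphere_shell_model <- function(diameter = 100, thickness = 0.5,
                               element_kind = c("solid_wedge", "membrane"),
                               E = 10, nu = 0.3, P = 0) {
  element_kind <- match.arg(element_kind)
  stopifnot(diameter > 0, thickness > 0, E > 0, nu > 0, nu < 0.5, P >= 0)
  if (thickness > diameter / 10)
    stop("shell thickness must be small compared to the diameter")
  structure(list(diameter = diameter, thickness = thickness,
                 element_kind = element_kind, E = E, nu = nu, P = P),
            class = "sphere_shell_model")
}

# graded breakpoints: node positions on [lo, hi] distributed with local
# density `dens(x)` (more nodes where dens is large)
graded_breaks <- function(n, lo, hi, dens) {
  xs <- seq(lo, hi, length.out = 4001)
  d <- dens(xs)
  cdf <- cumsum(d) - d[1]
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, xs, xout = seq(0, 1, length.out = n), ties = "ordered")$y
}

# flat-top refinement bumps: uniform fine spacing inside each patch,
# quartic roll-off at its edge; `amp`/`sigma` may be vectors to overlay
# several refinement scales (bending boundary layer + contact patch)
refine_bump <- function(arc, amp, sigma) {
  out <- 0
  for (k in seq_along(amp)) out <- out + amp[k] * exp(-(arc / sigma[k])^4)
  out
}

# symmetric azimuthal grid on [0, 2*pi) containing exactly 0 and pi,
# refined near both (the two indentation meridians)
phi_grid <- function(n_half, b, amp, sigma) {
  dens <- function(phi) {
    arc0 <- b * pmin(phi, 2 * pi - phi) # distance to phi = 0
    arcp <- b * abs(phi - pi)
    1 + refine_bump(arc0, amp, sigma) + refine_bump(arcp, amp, sigma)
  }
  half <- graded_breaks(n_half + 1, 0, pi, dens) # includes 0 and pi
  c(half, 2 * pi - rev(half[-c(1, n_half + 1)]))
}

# polar-angle grid on (0, pi), symmetric about pi/2 and refined there
alpha_grid <- function(n_rows, b, amp, sigma) {
  dens <- function(al) 1 + refine_bump((al - pi / 2) * b, amp, sigma)
  # n_rows interior rows; build on [0, pi] then drop the poles
  g <- graded_breaks(n_rows + 2, 0, pi, dens)
  g[-c(1, n_rows + 2)]
}

# Triangulate an ellipsoid of revolution about the x-axis with semi-axes
# (a, b, b).  Returns vertices (S x 3), outward-oriented triangles, and
# the (alpha, phi) parameters of each vertex (NA at the poles).
triangulate_spheroid <- function(a, b, resolution, refine_amp = c(12, 60),
                                 refine_sigma = c(8, 2.5)) {
  stopifnot(resolution >= 500)
  # split the triangle budget between meridian and azimuth by arc length
  L_mer <- pi / 2 * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))) / 2
  L_az <- 2 * pi * b
  n_rows <- max(8, round(sqrt(resolution / 2 * L_mer / L_az)))
  n_half <- max(8, round(resolution / (4 * n_rows)))
  n_phi <- 2 * n_half

  al <- alpha_grid(n_rows, b, refine_amp, refine_sigma)
  ph <- phi_grid(n_half, b, refine_amp, refine_sigma)

  nv <- n_rows * n_phi + 2
  verts <- matrix(0, nv, 3)
  alpha_of <- rep(NA_real_, nv)
  phi_of <- rep(NA_real_, nv)
  vid <- function(j, i) (j - 1L) * n_phi + ((i - 1L) %% n_phi) + 1L
  for (j in seq_len(n_rows)) {
    sa <- sin(al[j]); ca <- cos(al[j])
    idx <- vid(j, seq_len(n_phi))
    verts[idx, 1] <- a * ca
    verts[idx, 2] <- b * sa * sin(ph)
    verts[idx, 3] <- b * sa * cos(ph)
    alpha_of[idx] <- al[j]
    phi_of[idx] <- ph
  }
  pole_p <- n_rows * n_phi + 1L # alpha = 0, x = +a
  pole_m <- n_rows * n_phi + 2L
  verts[pole_p, ] <- c(a, 0, 0)
  verts[pole_m, ] <- c(-a, 0, 0)

  tris <- matrix(0L, 2L * (n_rows - 1L) * n_phi + 2L * n_phi, 3L)
  k <- 0L
  for (j in seq_len(n_rows - 1L)) {
    for (i in seq_len(n_phi)) {
      v00 <- vid(j, i); v01 <- vid(j, i + 1L)
      v10 <- vid(j + 1L, i); v11 <- vid(j + 1L, i + 1L)
      # pick the shorter diagonal for better-shaped triangles
      d1 <- sum((verts[v00, ] - verts[v11, ])^2)
      d2 <- sum((verts[v01, ] - verts[v10, ])^2)
      if (d1 <= d2) {
        tris[k + 1L, ] <- c(v00, v10, v11)
        tris[k + 2L, ] <- c(v00, v11, v01)
      } else {
        tris[k + 1L, ] <- c(v00, v10, v01)
        tris[k + 2L, ] <- c(v01, v10, v11)
      }
      k <- k + 2L
    }
  }
  for (i in seq_len(n_phi)) { # pole caps
    tris[k + 1L, ] <- c(pole_p, vid(1L, i), vid(1L, i + 1L))
    tris[k + 2L, ] <- c(pole_m, vid(n_rows, i + 1L), vid(n_rows, i))
    k <- k + 2L
  }

  # enforce outward orientation (positive enclosed volume)
  v6 <- fem_enclosed_volume(verts, matrix(0, nrow(verts), 3), tris)
  if (v6 < 0) tris <- tris[, c(1L, 3L, 2L)]
  list(verts = verts, tris = tris, alpha = alpha_of, phi = phi_of,
       n_rows = n_rows, n_phi = n_phi)
}

spheroid_normals <- function(verts, a, b) {
  n <- cbind(verts[, 1] / a^2, verts[, 2] / b^2, verts[, 3] / b^2)
  n / sqrt(rowSums(n^2))
}

#' Build the layered wedge mesh of a pollen model
#'
#' Triangulates the unpressurized outer surface, offsets it inward along
#' the surface normal to form the exine/intine interface and the inner
#' wall surface, and stacks one 6-node wedge (prism) element per layer
#' on every surface triangle.  Over the colpus band only the intine
#' wedge is kept.  The grid is graded so that both indentation sites
#' (colpus center and its antipode) are resolved at sub-micrometre
#' element size.
#'
#' @param model a [pollen_model()].
#' @param resolution approximate number of surface triangles (>= 500).
#' @param refine_amp,refine_sigma grading amplitude and length scale
#'   (um) of the refinement around the indentation sites.
#' @return an object of class `shell_mesh`.
#' @export
build_pollen_mesh <- function(model, resolution = 3000, refine_amp = c(12, 60),
                              refine_sigma = c(8, 2.5)) {
  stopifnot(inherits(model, "pollen_model"))
  a <- model$major_axis_0 / 2
  b <- model$minor_axis_0 / 2
  if (b >= a) stop("degenerate axes: major axis must exceed minor axis")
  surf <- triangulate_spheroid(a, b, resolution, refine_amp, refine_sigma)
  nrm <- spheroid_normals(surf$verts, a, b)
  S <- nrow(surf$verts)

  # colpus: band around the +z meridian (phi = 0), terminated before the tips
  cphi <- surf$phi
  cx <- surf$verts[, 1]
  tri_phi <- apply(matrix(cphi[surf$tris], ncol = 3), 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    # circular mean around 0
    atan2(mean(sin(p)), mean(cos(p)))
  })
  tri_x <- rowMeans(matrix(cx[surf$tris], ncol = 3))
  half_w <- model$colpus_half_width * pi / 180
  colpus_mask <- !is.na(tri_phi) & abs(tri_phi) < half_w &
    abs(tri_x) < model$colpus_axial_extent * a
  if (model$colpus_half_width == 0) colpus_mask[] <- FALSE
  if (mean(colpus_mask) >= 0.5)
    stop("colpus band covers half or more of the surface")

  # node sheets: outer (template), mid (exine/intine interface), inner
  outer_ids <- seq_len(S)
  mid_ids <- S + seq_len(S)
  inner_ids <- 2L * S + seq_len(S)
  nodes <- rbind(surf$verts,
                 surf$verts - model$t_exine * nrm,
                 surf$verts - (model$t_exine + model$t_intine) * nrm)

  tri <- surf$tris
  intine_w <- cbind(inner_ids[tri[, 1]], inner_ids[tri[, 2]], inner_ids[tri[, 3]],
                    mid_ids[tri[, 1]], mid_ids[tri[, 2]], mid_ids[tri[, 3]])
  exine_tris <- tri[!colpus_mask, , drop = FALSE]
  exine_w <- cbind(mid_ids[exine_tris[, 1]], mid_ids[exine_tris[, 2]],
                   mid_ids[exine_tris[, 3]], outer_ids[exine_tris[, 1]],
                   outer_ids[exine_tris[, 2]], outer_ids[exine_tris[, 3]])
  wedges <- rbind(intine_w, exine_w)
  layer <- c(rep("intine", nrow(intine_w)), rep("exine", nrow(exine_w)))

  # drop outer-sheet nodes that no exine wedge references
  used <- sort(unique(as.integer(wedges)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  wedges <- matrix(remap[wedges], ncol = 6)
  pressure_tris <- matrix(remap[cbind(inner_ids[tri[, 1]], inner_ids[tri[, 2]],
                                      inner_ids[tri[, 3]])], ncol = 3)

  # exposed node per surface vertex: outer sheet where an exine wedge
  # touches the vertex, otherwise the interface sheet (bare intine)
  on_exine <- rep(FALSE, S)
  on_exine[unique(as.integer(exine_tris))] <- TRUE
  exposed <- ifelse(on_exine, remap[outer_ids], remap[mid_ids])

  site_vertex <- function(target) {
    d2 <- rowSums(sweep(surf$verts, 2, target)^2)
    which.min(d2)
  }
  v_col <- site_vertex(c(0, 0, b))
  v_ant <- site_vertex(c(0, 0, -b))

  eq_y_p <- site_vertex(c(0, b, 0)); eq_y_m <- site_vertex(c(0, -b, 0))
  pole_p <- which.max(surf$verts[, 1]); pole_m <- which.min(surf$verts[, 1])

  structure(list(
    nodes = nodes, wedges = wedges, layer = layer,
    membrane_tris = NULL,
    pressure_tris = pressure_tris,
    surface = surf, colpus_mask = colpus_mask,
    exposed_node = exposed,
    sites = list(
      colpus_center = list(vertex = v_col, dir = c(0, 0, 1)),
      antipode = list(vertex = v_ant, dir = c(0, 0, -1))),
    landmarks = list(
      major = remap[outer_ids[c(pole_p, pole_m)]],
      minor = remap[outer_ids[c(eq_y_p, eq_y_m)]]),
    kind = "pollen", a = a, b = b,
    thickness = c(intine = model$t_intine, exine = model$t_exine),
    resolution = resolution), class = "shell_mesh")
}

#' Build the mesh of a reduced spherical-shell model
#'
#' The `solid_wedge` variant extrudes the mid-surface sphere half a
#' thickness in- and outward into a single sheet of wedge elements; the
#' `membrane` variant keeps the surface triangles themselves as
#' (bending-free) membrane elements.
#'
#' @param spec a [sphere_shell_model()].
#' @inheritParams build_pollen_mesh
#' @return an object of class `shell_mesh`.
#' @export
build_sphere_model <- function(spec, resolution = 2000, refine_amp = c(12, 60),
                               refine_sigma = c(8, 2.5)) {
  stopifnot(inherits(spec, "sphere_shell_model"))
  R <- spec$diameter / 2
  # reuse the spheroid machinery with a slightly prolate surrogate is
  # unnecessary: a == b is handled fine by the parametrization
  surf <- triangulate_spheroid(R * (1 + 1e-9), R, resolution, refine_amp,
                               refine_sigma)
  nrm <- spheroid_normals(surf$verts, R, R)
  S <- nrow(surf$verts)
  v_col <- which.min(rowSums(sweep(surf$verts, 2, c(0, 0, R))^2))
  v_ant <- which.min(rowSums(sweep(surf$verts, 2, c(0, 0, -R))^2))
  eq_y_p <- which.min(rowSums(sweep(surf$verts, 2, c(0, R, 0))^2))
  eq_y_m <- which.min(rowSums(sweep(surf$verts, 2, c(0, -R, 0))^2))
  pole_p <- which.max(surf$verts[, 1]); pole_m <- which.min(surf$verts[, 1])

  if (spec$element_kind == "membrane") {
    mesh <- list(nodes = surf$verts, wedges = NULL, layer = character(0),
                 membrane_tris = surf$tris,
                 pressure_tris = surf$tris,
                 surface = surf, colpus_mask = rep(FALSE, nrow(surf$tris)),
                 exposed_node = seq_len(S),
                 sites = list(
                   colpus_center = list(vertex = v_col, dir = c(0, 0, 1)),
                   antipode = list(vertex = v_ant, dir = c(0, 0, -1))),
                 landmarks = list(major = c(pole_p, pole_m),
                                  minor = c(eq_y_p, eq_y_m)),
                 kind = "sphere_membrane", a = R, b = R,
                 thickness = c(wall = spec$thickness),
                 resolution = resolution)
    return(structure(mesh, class = "shell_mesh"))
  }

  outer_ids <- seq_len(S)
  inner_ids <- S + seq_len(S)
  nodes <- rbind(surf$verts + (spec$thickness / 2) * nrm,
                 surf$verts - (spec$thickness / 2) * nrm)
  tri <- surf$tris
  wedges <- cbind(inner_ids[tri[, 1]], inner_ids[tri[, 2]], inner_ids[tri[, 3]],
                  outer_ids[tri[, 1]], outer_ids[tri[, 2]], outer_ids[tri[, 3]])
  pressure_tris <- cbind(inner_ids[tri[, 1]], inner_ids[tri[, 2]],
                         inner_ids[tri[, 3]])

  structure(list(nodes = nodes, wedges = wedges,
                 layer = rep("wall", nrow(wedges)),
                 membrane_tris = NULL, pressure_tris = pressure_tris,
                 surface = surf, colpus_mask = rep(FALSE, nrow(tri)),
                 exposed_node = outer_ids,
                 sites = list(
                   colpus_center = list(vertex = v_col, dir = c(0, 0, 1)),
                   antipode = list(vertex = v_ant, dir = c(0, 0, -1))),
                 landmarks = list(major = outer_ids[c(pole_p, pole_m)],
                                  minor = outer_ids[c(eq_y_p, eq_y_m)]),
                 kind = "sphere_wedge", a = R, b = R,
                 thickness = c(wall = spec$thickness),
                 resolution = resolution), class = "shell_mesh")
}

#' @export
print.shell_mesh <- function(x, ...) {
  cat("shell_mesh (", x$kind, ")\n", sep = "")
  cat(sprintf("  %d nodes, %d surface triangles\n", nrow(x$nodes),
              nrow(x$surface$tris)))
  if (!is.null(x$wedges))
    cat(sprintf("  %d wedge elements (%s)\n", nrow(x$wedges),
                paste(sprintf("%s: %d", names(table(x$layer)),
                              as.integer(table(x$layer))), collapse = ", ")))
  if (!is.null(x$membrane_tris))
    cat(sprintf("  %d membrane elements\n", nrow(x$membrane_tris)))
  if (any(x$colpus_mask))
    cat(sprintf("  colpus: %d of %d surface triangles\n",
                sum(x$colpus_mask), length(x$colpus_mask)))
  invisible(x)
}

#' Euler characteristic of the surface triangulation
#'
#' A closed genus-0 surface has Euler characteristic 2; this is the
#' basic watertightness check for generated meshes.
#'
#' @param mesh a `shell_mesh`.
#' @return integer Euler characteristic V - E + F.
#' @export
euler_characteristic <- function(mesh) {
  tri <- mesh$surface$tris
  v <- length(unique(as.integer(tri)))
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- unique(t(apply(ed, 1, sort)))
  v - nrow(ed) + nrow(tri)
}

#' Total area of the surface triangulation
#' @param mesh a `shell_mesh`.
#' @return area in um^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$surface$verts
  tri <- mesh$surface$tris
  e1 <- v[tri[, 2], ] - v[tri[, 1], ]
  e2 <- v[tri[, 3], ] - v[tri[, 1], ]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cx^2))) / 2
}

#' Export a mesh surface to an OFF file
#'
#' Writes the (optionally deformed) surface triangulation in the plain
#' OFF text format readable by common mesh viewers.
#'
#' @param mesh a `shell_mesh`.
#' @param file output path.
#' @param state optional `fem_state`; if supplied the deformed surface
#'   is written.
#' @return `file`, invisibly.
#' @export
write_mesh_off <- function(mesh, file, state = NULL) {
  v <- mesh$surface$verts
  if (!is.null(state)) {
    ex <- mesh$exposed_node
    v <- mesh$nodes[ex, , drop = FALSE] + state$U[ex, , drop = FALSE]
  }
  tri <- mesh$surface$tris
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(tri)), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L,
                     tri[, 3] - 1L), con)
  invisible(file)
}
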