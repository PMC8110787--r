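# Nonlinear solver driving the element kernels: follower-pressure
# inflation and displacement-controlled rigid-sphere indentation.

wedge_matprops <- function(mesh, model) {
  if (inherits(model, "pollen_model")) {
    E <- ifelse(mesh$layer == "intine", model$E_i, model$E_e)
    list(E = E, nu = rep(model$nu, length(E)))
  } else {
    list(E = rep(model$E, length(mesh$layer)),
         nu = rep(model$nu, length(mesh$layer)))
  }
}

law_code <- function(law) {
  law <- match.arg(law, c("shell", "stvk3d"))
  if (law == "shell") 0L else 1L
}

# one full assembly: internal force, external (pressure + contact) force
# and the Jacobian triplets of the residual r(u) = f_int - f_ext
fem_assemble <- function(mesh, model, U, P, contact = NULL,
                         law = 0L, want_stress = FALSE) {
  n <- nrow(mesh$nodes)
  f_int <- numeric(3 * n)
  f_ext <- numeric(3 * n)
  ti <- list(); tj <- list(); tv <- list()
  stress <- NULL

  if (!is.null(mesh$wedges) && nrow(mesh$wedges) > 0) {
    mp <- wedge_matprops(mesh, model)
    w <- fem_wedge_assemble(mesh$nodes, U, mesh$wedges, mp$E, mp$nu,
                            law, want_stress)
    f_int <- f_int + w$f
    ti <- c(ti, list(w$i)); tj <- c(tj, list(w$j)); tv <- c(tv, list(w$v))
    if (want_stress) stress <- w$stress
  }
  if (!is.null(mesh$membrane_tris) && nrow(mesh$membrane_tris) > 0) {
    m <- fem_membrane_assemble(mesh$nodes, U, mesh$membrane_tris,
                               mesh$thickness[[1]], model$E, model$nu)
    f_int <- f_int + m$f
    ti <- c(ti, list(m$i)); tj <- c(tj, list(m$j)); tv <- c(tv, list(m$v))
  }
  if (P > 0) {
    p <- fem_pressure_assemble(mesh$nodes, U, mesh$pressure_tris, P)
    f_ext <- f_ext + p$f
    ti <- c(ti, list(p$i)); tj <- c(tj, list(p$j)); tv <- c(tv, list(-p$v))
  }
  if (!is.null(contact)) {
    ct <- contact(U)
    f_ext <- f_ext + ct$f
    if (length(ct$i)) {
      ti <- c(ti, list(ct$i)); tj <- c(tj, list(ct$j)); tv <- c(tv, list(-ct$v))
    }
  }
  list(f_int = f_int, f_ext = f_ext,
       i = unlist(ti), j = unlist(tj), v = unlist(tv), stress = stress)
}

# Newton iteration at fixed load with a backtracking line search on the
# residual norm; U is n x 3, fixed is a logical dof mask
newton_solve <- function(mesh, model, U, P, fixed, contact = NULL,
                         law = 0L, tol = 1e-6, max_iter = 30) {
  n <- nrow(mesh$nodes)
  free <- which(!fixed)
  resid_norm <- function(asm) sqrt(sum((asm$f_int - asm$f_ext)[free]^2))
  asm <- fem_assemble(mesh, model, U, P, contact, law)
  rn <- resid_norm(asm)
  fails <- 0L
  for (it in seq_len(max_iter)) {
    ref <- max(sqrt(sum(asm$f_ext[free]^2)), sqrt(sum(asm$f_int[free]^2)),
               1e-8)
    if (rn <= tol * ref)
      return(list(U = U, converged = TRUE, iters = it - 1L, res = rn / ref))
    if (!is.finite(rn) || rn > 1e8 * ref)
      return(list(U = U, converged = FALSE, iters = it, res = rn / ref))
    r <- asm$f_int - asm$f_ext
    sel <- !fixed[asm$i] & !fixed[asm$j]
    map <- integer(3 * n); map[free] <- seq_along(free)
    J <- Matrix::sparseMatrix(i = map[asm$i[sel]], j = map[asm$j[sel]],
                              x = asm$v[sel],
                              dims = c(length(free), length(free)))
    # the discrete follower-pressure load of a closed surface is
    # conservative, so the Jacobian is symmetric up to round-off;
    # symmetrize and try a sparse Cholesky first, fall back to LU
    Js <- Matrix::forceSymmetric((J + Matrix::t(J)) / 2)
    du <- tryCatch(suppressWarnings(
      as.numeric(Matrix::solve(Matrix::Cholesky(Js, LDL = FALSE,
                                                perm = TRUE),
                               -r[free]))),
      error = function(e) NULL)
    if (is.null(du))
      du <- tryCatch(as.numeric(Matrix::solve(J, -r[free])),
                     error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(U = U, converged = FALSE, iters = it, res = rn / ref))
    dU <- matrix(0, n, 3)
    dU[cbind(((free - 1L) %/% 3L) + 1L, ((free - 1L) %% 3L) + 1L)] <- du
    accepted <- FALSE
    for (s in c(1, 0.5, 0.25, 0.1, 0.03)) {
      asm_try <- fem_assemble(mesh, model, U + s * dU, P, contact, law)
      rn_try <- resid_norm(asm_try)
      if (is.finite(rn_try) && (rn_try < rn || rn_try <= tol * ref)) {
        U <- U + s * dU; asm <- asm_try; rn <- rn_try
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # accept a heavily damped step once; repeated failure aborts
      fails <- fails + 1L
      if (fails > 2L)
        return(list(U = U, converged = FALSE, iters = it, res = rn / ref))
      U <- U + 0.03 * dU
      asm <- fem_assemble(mesh, model, U, P, contact, law)
      rn <- resid_norm(asm)
    } else fails <- 0L
  }
  list(U = U, converged = FALSE, iters = max_iter, res = rn / ref)
}

dof_index <- function(node, comp) 3L * (node - 1L) + comp

rigid_body_fixes <- function(mesh) {
  n <- nrow(mesh$nodes)
  fixed <- rep(FALSE, 3L * n)
  n1 <- mesh$landmarks$major[1]; n2 <- mesh$landmarks$major[2]
  n3 <- mesh$landmarks$minor[1]
  fixed[dof_index(n1, 1:3)] <- TRUE
  fixed[dof_index(n2, 2:3)] <- TRUE
  fixed[dof_index(n3, 3)] <- TRUE
  fixed
}

#' Inflate a shell mesh to its turgor pressure
#'
#' Solves for the large-deformation equilibrium of the wall under a
#' follower pressure load acting on the inner surface, ramped in load
#' steps with Newton iteration at each step (step halving on
#' divergence).  Rigid-body motion is removed by a minimal 3-2-1 nodal
#' constraint; the structural Dirichlet support of the indentation stage
#' is applied afterwards, in [indent()].
#'
#' @param mesh a `shell_mesh` from [build_pollen_mesh()] or
#'   [build_sphere_model()].
#' @param model the matching `pollen_model` or `sphere_shell_model`.
#' @param n_steps number of pressure load steps.
#' @param tol relative residual tolerance for Newton convergence.
#' @param law constitutive option: `"shell"` (plane-stress-consistent
#'   in-plane response with uncoupled thickness modulus, the default) or
#'   `"stvk3d"` (fully coupled isotropic St. Venant-Kirchhoff).
#' @param verbose print per-step convergence.
#' @return an object of class `fem_state` with the displacement field
#'   (um), per-element Cauchy stress (MPa), enclosed volume and the
#'   convergence history.
#' @export
inflate <- function(mesh, model, n_steps = 10, tol = 1e-6,
                    law = c("shell", "stvk3d"), verbose = FALSE) {
  stopifnot(inherits(mesh, "shell_mesh"))
  lc <- law_code(law)
  n <- nrow(mesh$nodes)
  P <- model$P
  U <- matrix(0, n, 3)
  vol0 <- fem_enclosed_volume(mesh$nodes, U, mesh$pressure_tris)
  hist <- list()
  if (P > 0) {
    fixed <- rigid_body_fixes(mesh)
    lam <- 0; dl <- 1 / n_steps; dl_min <- dl / 16
    dU_pred <- matrix(0, n, 3)
    while (lam < 1 - 1e-12) {
      dl_try <- min(dl, 1 - lam)
      sol <- newton_solve(mesh, model, U + dU_pred * (dl_try / dl),
                          P * (lam + dl_try), fixed, law = lc, tol = tol)
      if (!sol$converged) {
        dl <- dl / 2
        dU_pred <- dU_pred / 2
        if (dl < dl_min)
          stop("inflation diverged (load step below floor); history: ",
               paste(vapply(hist, function(h)
                 sprintf("P=%.4g res=%.3g", h$P, h$res), ""), collapse = "; "))
        next
      }
      dU_pred <- sol$U - U
      U <- sol$U
      lam <- lam + dl_try
      hist[[length(hist) + 1]] <- list(P = P * lam, iters = sol$iters,
                                       res = sol$res)
      if (verbose)
        message(sprintf("  inflate: P = %.4g MPa, %d iterations", P * lam,
                        sol$iters))
    }
  }
  asm <- fem_assemble(mesh, model, U, P, law = lc, want_stress = TRUE)
  hist <- do.call(rbind, lapply(hist, as.data.frame))
  structure(list(U = U, P = P, stress = asm$stress,
                 volume0 = vol0,
                 volume = fem_enclosed_volume(mesh$nodes, U, mesh$pressure_tris),
                 history = hist, law = lc, tol = tol,
                 converged = TRUE), class = "fem_state")
}

#' @export
print.fem_state <- function(x, ...) {
  cat("fem_state: inflated equilibrium\n")
  cat(sprintf("  P = %g MPa, max displacement %.3f um\n", x$P,
              max(abs(x$U))))
  cat(sprintf("  enclosed volume %.0f -> %.0f um^3 (%+.2f%%)\n", x$volume0,
              x$volume, 100 * (x$volume / x$volume0 - 1)))
  if (!is.null(x$stress))
    cat(sprintf("  von Mises Cauchy stress: median %.3f, max %.3f MPa\n",
                stats::median(x$stress[, 7]), max(x$stress[, 7])))
  invisible(x)
}

#' Deformed axes of an inflated mesh
#'
#' Tip-to-tip distances between the landmark node pairs on the outer
#' surface: the two major-axis poles and an equatorial pair on the
#' minor axis.
#'
#' @param mesh a `shell_mesh`.
#' @param state a `fem_state` from [inflate()].
#' @return named vector `c(major = , minor = )` in um.
#' @export
deformed_axes <- function(mesh, state) {
  xy <- mesh$nodes + state$U
  mj <- mesh$landmarks$major; mn <- mesh$landmarks$minor
  c(major = sqrt(sum((xy[mj[1], ] - xy[mj[2], ])^2)),
    minor = sqrt(sum((xy[mn[1], ] - xy[mn[2], ])^2)))
}

# Penalty contact of exposed surface nodes against the rigid probe: a
# sphere-capped cylinder (tip radius `radius`, shaft extending along
# +axis, i.e. away from the sample).  The normal force is
# C1-regularized over a small gap g0 so that nodes entering or leaving
# contact do not destabilize the Newton iteration.
make_contact <- function(mesh, center, radius, kp, cand_ids, axis = NULL,
                         g0 = 0.02) {
  X <- mesh$nodes
  function(U) {
    n <- nrow(X)
    x <- X[cand_ids, , drop = FALSE] + U[cand_ids, , drop = FALSE]
    d <- sweep(x, 2, center)
    if (!is.null(axis)) {
      s <- as.numeric(d %*% axis)
      shaft <- s > 0
      # shaft side: measure distance to the probe axis instead
      d[shaft, ] <- d[shaft, , drop = FALSE] -
        outer(s[shaft], axis)
    }
    r <- sqrt(rowSums(d^2))
    g <- radius - r
    act <- which(g > 0 & r > 1e-9)
    f <- numeric(3 * n)
    if (!length(act))
      return(list(f = f, i = integer(0), j = integer(0), v = numeric(0),
                  force = numeric(3), active = integer(0)))
    ii <- integer(9 * length(act)); jj <- integer(9 * length(act))
    vv <- numeric(9 * length(act))
    ftot <- numeric(3)
    for (q in seq_along(act)) {
      aq <- act[q]
      id <- cand_ids[aq]
      dh <- d[aq, ] / r[aq]
      gq <- g[aq]
      if (gq < g0) {
        fn <- kp * gq^2 / (2 * g0)
        dfn <- kp * gq / g0
      } else {
        fn <- kp * (gq - g0 / 2)
        dfn <- kp
      }
      fq <- fn * dh
      f[dof_index(id, 1:3)] <- f[dof_index(id, 1:3)] + fq
      ftot <- ftot + fq
      # normal-gap stiffness only: the tangential curvature ("rolling")
      # term is omitted from the Jacobian so the tangent stays positive
      # definite under large penalty forces; the residual is exact and
      # the line-searched Newton absorbs the approximation
      Jq <- -dfn * outer(dh, dh)
      for (a in 1:3) for (b in 1:3) {
        pos <- 9 * (q - 1) + (a - 1) * 3 + b
        ii[pos] <- dof_index(id, a)
        jj[pos] <- dof_index(id, b)
        vv[pos] <- Jq[a, b]
      }
    }
    list(f = f, i = ii, j = jj, v = vv, force = ftot, active = cand_ids[act])
  }
}

#' Simulate rigid-sphere indentation of an inflated shell
#'
#' Advances a rigid spherical indenter along the inward surface normal
#' at an indentation site under displacement control, with frictionless
#' node-to-sphere penalty contact.  The half of the mesh opposite the
#' indenter (relative to the equatorial plane normal to the indentation
#' axis) is clamped at its inflated position.  Depth is measured as
#' indenter advance past first contact with the deformed surface; the
#' reaction force is the contact force resultant projected on the
#' indentation axis.
#'
#' @param mesh a `shell_mesh`.
#' @param state converged `fem_state` from [inflate()].
#' @param model the model that produced `state`.
#' @param site `"colpus_center"` or `"antipode"` (for spheres the two
#'   poles of the z-axis).
#' @param max_depth maximum indentation depth (um).
#' @param n_steps indentation steps (step halving on divergence).
#' @param indenter_radius rigid sphere radius (um); the instrument tip
#'   diameter is below 2 um, hence the 1 um default.
#' @param penalty_factor contact penalty in units of the largest layer
#'   membrane stiffness E*t.
#' @param tol,law as in [inflate()].
#' @param verbose print per-step convergence.
#' @return an object of class `indent_result` with `depth` and `force`
#'   samples (um, uN), convergence record and site metadata.
#' @export
indent <- function(mesh, state, model, site = c("colpus_center", "antipode"),
                   max_depth = 1.8, n_steps = 24, indenter_radius = 1,
                   penalty_factor = 100, tol = 1e-6,
                   law = c("shell", "stvk3d"), verbose = FALSE) {
  site <- match.arg(site)
  stopifnot(inherits(state, "fem_state"), state$converged)
  lc <- law_code(law)
  n <- nrow(mesh$nodes)
  si <- mesh$sites[[site]]
  dir_out <- si$dir / sqrt(sum(si$dir^2))

  # structural support: clamp the half away from the indenter
  fixed <- rep(FALSE, 3L * n)
  below <- which(as.numeric(mesh$nodes %*% dir_out) < 0)
  fixed[as.vector(vapply(1:3, function(k) dof_index(below, k),
                         integer(length(below))))] <- TRUE

  # contact candidates: exposed-surface nodes near the site
  ex <- mesh$exposed_node
  xdef <- mesh$nodes + state$U
  site_node <- ex[si$vertex]
  xs <- xdef[site_node, ]
  rel <- sweep(xdef[ex, , drop = FALSE], 2, xs)
  axial <- as.numeric(rel %*% dir_out)
  lat2 <- rowSums(rel^2) - axial^2
  cand <- ex[sqrt(pmax(lat2, 0)) < (3 * indenter_radius + max_depth + 2)]

  # first-touch position of the sphere center along the axis
  relc <- sweep(xdef[cand, , drop = FALSE], 2, xs)
  ax <- as.numeric(relc %*% dir_out)
  l2 <- pmax(rowSums(relc^2) - ax^2, 0)
  inside <- l2 < indenter_radius^2
  if (!any(inside)) stop("no surface nodes under the indenter footprint")
  o_touch <- max(ax[inside] + sqrt(indenter_radius^2 - l2[inside]))

  Et <- if (inherits(model, "pollen_model")) {
    max(model$E_i * model$t_intine, model$E_e * model$t_exine)
  } else model$E * mesh$thickness[[1]]
  kp <- penalty_factor * Et

  depths <- c(0)
  forces <- c(0)
  U <- state$U
  hist <- list()
  truncated <- FALSE
  if (max_depth > 0) {
    d_cur <- 0; dd <- max_depth / n_steps; dd_min <- dd / 16
    while (d_cur < max_depth - 1e-12) {
      dd_try <- min(dd, max_depth - d_cur)
      dtar <- d_cur + dd_try
      center <- xs + (o_touch - dtar) * dir_out
      cfun <- make_contact(mesh, center, indenter_radius, kp, cand,
                           axis = dir_out)
      sol <- newton_solve(mesh, model, U, state$P, fixed, contact = cfun,
                          law = lc, tol = tol)
      if (!sol$converged) {
        dd <- dd / 2
        if (dd < dd_min) {
          truncated <- TRUE
          warning("indentation truncated at depth ", signif(d_cur, 4),
                  " um (loss of convergence)")
          break
        }
        next
      }
      U <- sol$U
      d_cur <- dtar
      ct <- cfun(U)
      Fz <- -sum(ct$force * dir_out)
      depths <- c(depths, d_cur)
      forces <- c(forces, Fz)
      hist[[length(hist) + 1]] <- list(depth = d_cur, force = Fz,
                                       iters = sol$iters, res = sol$res,
                                       n_contact = length(ct$active))
      if (verbose)
        message(sprintf("  indent %s: depth %.3f um, F = %.3f uN (%d it)",
                        site, d_cur, Fz, sol$iters))
    }
  }
  structure(list(site = site, depth = depths, force = forces,
                 U = U, truncated = truncated,
                 indenter_radius = indenter_radius,
                 history = do.call(rbind, lapply(hist, as.data.frame)),
                 model = model, P = state$P), class = "indent_result")
}

#' @export
print.indent_result <- function(x, ...) {
  cat(sprintf("indent_result: site %s, %d samples to depth %.3f um\n",
              x$site, length(x$depth), max(x$depth)))
  cat(sprintf("  peak force %.3f uN%s\n", max(x$force),
              if (x$truncated) " [truncated run]" else ""))
  invisible(x)
}

#' @export
plot.indent_result <- function(x, ...) {
  graphics::plot(x$depth, x$force, type = "b", pch = 16, cex = 0.6,
                 xlab = "indentation depth (um)", ylab = "force (uN)",
                 main = paste("simulated indentation,", x$site), ...)
  invisible(x)
}

#' Apparent stiffness of a simulated indentation curve
#'
#' Local tangent slope of the force-depth curve, evaluated by central
#' finite difference over +/- `half_window` around the requested depth
#' on a monotone spline interpolant.  A secant mode (force over depth)
#' is also available.
#'
#' @param result an `indent_result`.
#' @param depth evaluation depth (um).
#' @param half_window finite-difference half width (um).
#' @param mode `"tangent"` (default) or `"secant"`.
#' @return apparent stiffness in N/m (= uN/um).
#' @export
apparent_stiffness_at <- function(result, depth, half_window = 0.1,
                                  mode = c("tangent", "secant")) {
  mode <- match.arg(mode)
  d <- result$depth; f <- result$force
  if (mode == "secant") {
    if (depth <= 0 || depth > max(d) + 1e-9)
      stop("depth outside sampled range")
    sf <- stats::splinefun(d, f, method = "monoH.FC")
    return(sf(depth) / depth)
  }
  if (depth - half_window < min(d) - 1e-9 ||
      depth + half_window > max(d) + 1e-9)
    stop("depth outside sampled range (needs +/- ", half_window,
         " um margin)")
  sf <- stats::splinefun(d, f, method = "monoH.FC")
  (sf(depth + half_window) - sf(depth - half_window)) / (2 * half_window)
}

#' Classify the linearity of an indentation curve
#'
#' Fits a straight line over `fit_range` and classifies the curve by the
#' sign of the mean residual beyond the midpoint of the range: force
#' above the line is superlinear (stretching-dominated), below is
#' sublinear (bending/pressure-dominated); residuals within `deadband`
#' (relative) count as linear.
#'
#' @param result an `indent_result` (or any list with `depth`/`force`).
#' @param fit_range depth interval (um) for the linear fit.
#' @param deadband relative mean-residual threshold for "linear".
#' @return `"sublinear"`, `"superlinear"` or `"linear"`.
#' @export
classify_linearity <- function(result, fit_range = c(0.1, 0.5),
                               deadband = 0.01) {
  d <- result$depth; f <- result$force
  if (fit_range[1] < min(d) - 1e-9 || fit_range[2] > max(d) + 1e-9)
    stop("fit range outside sampled depths")
  sf <- stats::splinefun(d, f, method = "monoH.FC")
  dd <- seq(fit_range[1], fit_range[2], length.out = 50)
  fit <- stats::lm(y ~ x, data = data.frame(x = dd, y = sf(dd)))
  mid <- mean(fit_range)
  beyond <- d[d > mid]
  if (!length(beyond)) stop("no samples beyond the fit-range midpoint")
  resid <- sf(beyond) - stats::predict(fit, data.frame(x = beyond))
  rel <- mean(resid) / mean(abs(sf(beyond)))
  if (abs(rel) < deadband) "linear" else if (rel > 0) "superlinear" else "sublinear"
}

#' Small-load tangent stiffness under a point load
#'
#' Linearizes the model about a converged state (or the reference
#' configuration) and applies an infinitesimal inward point load at an
#' indentation site; the ratio of force to site deflection is the
#' tangent stiffness in the limit of vanishing indentation depth.  This
#' is the quantity the closed-form thin-shell result of
#' [reissner_stiffness()] predicts for an unpressurized sphere.
#'
#' @param mesh a `shell_mesh`.
#' @param model the matching model object.
#' @param state optional `fem_state` to linearize about (defaults to
#'   the reference configuration, valid for P = 0).
#' @param site `"colpus_center"` or `"antipode"`.
#' @param patch_radius radius (um) over which the load is spread and
#'   the deflection averaged (cosine weighting).  A genuinely nodal
#'   load on a solid-element mesh has a mesh-divergent local
#'   compliance, so the "point" load is applied over a small patch of
#'   the order of the probe tip instead.
#' @return tangent stiffness in N/m.
#' @export
point_load_stiffness <- function(mesh, model, state = NULL,
                                 site = "colpus_center",
                                 patch_radius = 0.5) {
  n <- nrow(mesh$nodes)
  U <- if (is.null(state)) matrix(0, n, 3) else state$U
  P <- if (is.null(state)) 0 else state$P
  si <- mesh$sites[[site]]
  dir_out <- si$dir / sqrt(sum(si$dir^2))
  fixed <- rep(FALSE, 3L * n)
  below <- which(as.numeric(mesh$nodes %*% dir_out) < 0)
  fixed[as.vector(vapply(1:3, function(k) dof_index(below, k),
                         integer(length(below))))] <- TRUE
  free <- which(!fixed)
  asm <- fem_assemble(mesh, model, U, P,
                      law = if (is.null(state)) 0L else state$law)
  map <- integer(3 * n); map[free] <- seq_along(free)
  sel <- !fixed[asm$i] & !fixed[asm$j]
  J <- Matrix::sparseMatrix(i = map[asm$i[sel]], j = map[asm$j[sel]],
                            x = asm$v[sel],
                            dims = c(length(free), length(free)))
  site_node <- mesh$exposed_node[si$vertex]
  ex <- mesh$exposed_node
  xs <- (mesh$nodes + U)[site_node, ]
  d <- sqrt(rowSums(sweep(mesh$nodes[ex, , drop = FALSE] + U[ex, , drop = FALSE],
                          2, xs)^2))
  in_patch <- ex[d < patch_radius]
  wgt <- cos(pi / 2 * d[d < patch_radius] / patch_radius)^2
  wgt <- wgt / sum(wgt)
  f <- numeric(3 * n)
  f0 <- 1e-4
  for (q in seq_along(in_patch))
    f[dof_index(in_patch[q], 1:3)] <- -f0 * wgt[q] * dir_out
  u <- as.numeric(Matrix::solve(J, f[free]))
  uu <- numeric(3 * n); uu[free] <- u
  w <- -sum(vapply(seq_along(in_patch), function(q)
    wgt[q] * sum(uu[dof_index(in_patch[q], 1:3)] * dir_out), numeric(1)))
  f0 / w
}

#' Closed-form point-load stiffness of a thin spherical shell
#'
#' The classical shallow-shell result for a concentrated load on an
#' unpressurized thin elastic sphere,
#' \deqn{k = \frac{4 E t^2}{R \sqrt{3 (1 - \nu^2)}},}
#' used as the analytic oracle for the solid-shell elements in the
#' small-depth, zero-pressure limit.
#'
#' @param E Young's modulus (MPa).
#' @param t wall thickness (um).
#' @param R mid-surface radius (um).
#' @param nu Poisson's ratio.
#' @return stiffness in N/m.
#' @export
reissner_stiffness <- function(E, t, R, nu = 0.3) {
  stopifnot(E > 0, t > 0, R > 0, nu > 0, nu < 0.5)
  if (t / R >= 0.05) stop("thin-shell formula requires t/R < 0.05")
  4 * E * t^2 / (R * sqrt(3 * (1 - nu^2)))
}

#' Parameter sweep over pressure and layer moduli
#'
#' Runs inflation plus indentation at one or both sites for every
#' combination of turgor pressure and layer moduli, evaluating the
#' apparent tangent stiffness at the site-specific depths (1.6 um at the
#' colpus, 0.6 um at the antipodal exine site by default).  Diverged
#' runs are recorded with a reason and the sweep continues.
#'
#' @param model base `pollen_model` (geometry and Poisson ratio).
#' @param P_values,E_i_values,E_e_values sweep grids.
#' @param sites which indentation sites to run.
#' @param eval_depth named evaluation depths per site (um).
#' @param max_depth named maximum indentation depths per site (um).
#' @param resolution surface triangles of the shared mesh.
#' @param n_steps_indent,n_steps_inflate load-stepping resolution.
#' @param verbose print progress.
#' @return data.frame with one row per (P, E_i, E_e, site).
#' @export
run_parameter_sweep <- function(model, P_values, E_i_values, E_e_values,
                                sites = c("colpus_center", "antipode"),
                                eval_depth = c(colpus_center = 1.6,
                                               antipode = 0.6),
                                max_depth = c(colpus_center = 1.8,
                                              antipode = 0.8),
                                resolution = 3000,
                                n_steps_indent = 20, n_steps_inflate = 10,
                                verbose = FALSE) {
  stopifnot(inherits(model, "pollen_model"))
  mesh <- build_pollen_mesh(model, resolution)
  grid <- expand.grid(P = P_values, E_i = E_i_values, E_e = E_e_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    m <- model
    m$P <- grid$P[g]; m$E_i <- grid$E_i[g]; m$E_e <- grid$E_e[g]
    st <- tryCatch(inflate(mesh, m, n_steps = n_steps_inflate,
                           verbose = verbose),
                   error = function(e) e)
    for (s in sites) {
      row <- data.frame(P = m$P, E_i = m$E_i, E_e = m$E_e, site = s,
                        eval_depth = eval_depth[[s]], k_apparent = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
      if (inherits(st, "error")) {
        row$status <- paste("inflation failed:", conditionMessage(st))
      } else {
        res <- tryCatch({
          r <- indent(mesh, st, m, site = s, max_depth = max_depth[[s]],
                      n_steps = n_steps_indent, verbose = verbose)
          apparent_stiffness_at(r, eval_depth[[s]])
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$status <- paste("indentation failed:", conditionMessage(res))
        } else row$k_apparent <- res
      }
      rows[[length(rows) + 1]] <- row
      if (verbose)
        message(sprintf("sweep: P=%g E_i=%g E_e=%g %s -> %s", m$P, m$E_i,
                        m$E_e, s,
                        if (is.na(row$k_apparent)) row$status
                        else sprintf("k = %.3f N/m", row$k_apparent)))
    }
  }
  do.call(rbind, rows)
}
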