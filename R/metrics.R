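# Quantification of stenotic flow disturbances: per-section maximum
# velocity, reverse-flow (separation) area, jet asymmetry and asymmetric
# leaflet bending.

cell_speed <- function(solver, state) {
  cv <- center_velocity(solver, state)
  sqrt(cv$u^2 + cv$v^2)
}

#' Maximum-velocity profile along the vessel
#'
#' For each grid column the maximum flow speed over the lumen cells of
#' that cross-section.
#'
#' @param solver a [new_flow_solver()].
#' @param state a [flow_state][initialize_state()].
#' @return object of class `max_velocity_profile`: data frame with columns
#'   `x` (m) and `vmax` (m/s); the snapshot time is kept in
#'   `attr(, "time")`.
#' @export
max_velocity_vs_x <- function(solver, state) {
  sp <- cell_speed(solver, state)
  sp[solver$mask] <- NA
  prof <- apply(sp, 1, max, na.rm = TRUE)
  out <- data.frame(x = solver$grid$xc, vmax = prof)
  attr(out, "time") <- state$t
  class(out) <- c("max_velocity_profile", class(out))
  out
}

# label 4-connected regions of a logical matrix; returns integer matrix
label_regions <- function(flag) {
  nx <- nrow(flag); ny <- ncol(flag)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (start in which(flag)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (s - 1L) %% nx + 1L; j <- (s - 1L) %/% nx + 1L
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny) {
          s2 <- ii + (jj - 1L) * nx
          if (flag[s2] && lab[s2] == 0L) { lab[s2] <- cur; stack <- c(stack, s2) }
        }
      }
    }
  }
  lab
}

#' Reverse-flow (separation) report
#'
#' Area of the lumen where the axial velocity is negative beyond a small
#' threshold `eps_rev = eps_frac * U_max` (with `U_max` the maximum speed
#' in the domain at this snapshot), with 4-connected recirculation regions
#' labelled and summarized.
#'
#' @param solver a [new_flow_solver()].
#' @param state a [flow_state][initialize_state()].
#' @param xlim optional axial window `c(x0, x1)` (m) restricting the
#'   region of interest, e.g. downstream of the stenosis.
#' @param eps_frac reverse-flow threshold as a fraction of `U_max`.
#' @return object of class `separation_report`: list with `area` (m^2),
#'   `n_regions`, and a per-region data frame `regions`
#'   (bounding boxes, areas, mean reverse speed).
#' @export
reverse_flow_area <- function(solver, state, xlim = NULL, eps_frac = 1e-3) {
  g <- solver$grid
  cv <- center_velocity(solver, state)
  umax <- max(cell_speed(solver, state))
  eps <- eps_frac * umax
  flag <- (cv$u < -eps) & solver$fluid
  if (!is.null(xlim))
    flag <- flag & (g$xc >= xlim[1] & g$xc <= xlim[2])
  cellA <- g$hx * g$hy
  lab <- label_regions(flag)
  nreg <- max(lab)
  regions <- if (nreg > 0) {
    do.call(rbind, lapply(seq_len(nreg), function(r) {
      w <- which(lab == r, arr.ind = TRUE)
      data.frame(region = r, area = nrow(w) * cellA,
                 x_min = g$xc[min(w[, 1])], x_max = g$xc[max(w[, 1])],
                 y_min = g$yc[min(w[, 2])], y_max = g$yc[max(w[, 2])],
                 mean_reverse_speed = mean(-cv$u[lab == r]))
    }))
  } else {
    data.frame(region = integer(), area = numeric(), x_min = numeric(),
               x_max = numeric(), y_min = numeric(), y_max = numeric(),
               mean_reverse_speed = numeric())
  }
  structure(list(area = sum(flag) * cellA, n_regions = nreg,
                 threshold = eps, regions = regions, time = state$t),
            class = "separation_report")
}

#' Relative velocity dip just downstream of the stenosis throat
#'
#' From a maximum-velocity profile, the relative drop from the throat
#' peak to the profile minimum within a window just downstream of the
#' stenosis exit: `1 - min(post) / max(throat)`.  A coherent laminar jet
#' gives a value near zero; separation-driven momentum exchange behind a
#' severe stenosis gives a pronounced positive dip.
#'
#' @param profile a [max_velocity_profile][max_velocity_vs_x()] or any
#'   data frame with columns `x` and `vmax`.
#' @param geometry a [vessel_geometry()] with `f > 0`.
#' @param window axial extent (m) of the post-throat search window.
#' @return relative dip (dimensionless; can be negative if the velocity
#'   keeps rising downstream).
#' @export
post_throat_dip <- function(profile, geometry, window = 0.03) {
  if (geometry$f <= 0)
    stop_ijv("post-throat dip needs a stenosed geometry (f > 0)")
  x1 <- geometry$xs + geometry$ls / 2
  thr <- profile$x >= geometry$xs - geometry$ls / 2 & profile$x <= x1
  post <- profile$x > x1 & profile$x <= x1 + window
  if (!any(thr) || !any(post))
    stop_ijv("profile does not cover the throat and post-throat window")
  1 - min(profile$vmax[post], na.rm = TRUE) /
    max(profile$vmax[thr], na.rm = TRUE)
}

#' Mirror-asymmetry index of the velocity field
#'
#' `sum(|q - M(q)|) / sum(|q| + |M(q)|)` over the lumen, where `M` mirrors
#' the field about the channel midline `y = D/2` (the transverse component
#' changes sign under mirroring).  0 for a mirror-symmetric field, 1 for a
#' purely antisymmetric one; invariant under uniform rescaling; defined as
#' 0 for a quiescent field.
#'
#' @inheritParams reverse_flow_area
#' @return asymmetry index in `[0, 1]`.
#' @export
asymmetry_index <- function(solver, state, xlim = NULL) {
  g <- solver$grid
  cv <- center_velocity(solver, state)
  keep <- solver$fluid
  if (!is.null(xlim)) keep <- keep & (g$xc >= xlim[1] & g$xc <= xlim[2])
  jr <- rev(seq_len(g$ny))
  um <- cv$u[, jr]; vm <- -cv$v[, jr]
  keep <- keep & keep[, jr]
  num <- sum(abs(cv$u - um)[keep]) + sum(abs(cv$v - vm)[keep])
  den <- sum((abs(cv$u) + abs(um))[keep]) + sum((abs(cv$v) + abs(vm))[keep])
  if (den == 0) 0 else num / den
}

#' Transverse offset of the velocity maximum at a cross-section
#'
#' Position of the per-column speed maximum relative to the midline
#' `y = D/2`, refined to sub-cell accuracy by a parabolic fit through the
#' maximum and its neighbours.
#'
#' @inheritParams reverse_flow_area
#' @param x axial position (m) of the cross-section.
#' @return offset (m); positive toward the upper wall.
#' @export
centerline_offset <- function(solver, state, x) {
  g <- solver$grid
  i <- which.min(abs(g$xc - x))
  sp <- cell_speed(solver, state)[i, ]
  sp[solver$mask[i, ]] <- -Inf
  j <- which.max(sp)
  y <- g$yc[j]
  if (j > 1 && j < g$ny && is.finite(sp[j - 1]) && is.finite(sp[j + 1])) {
    a <- sp[j - 1]; b <- sp[j]; cc <- sp[j + 1]
    den <- a - 2 * b + cc
    if (den < 0) y <- y + 0.5 * g$hy * (a - cc) / den
  }
  y - g$D / 2
}

#' Difference in leaflet tip displacement magnitudes
#'
#' `| |d_tip(upper)| - |d_tip(lower)| |` -- zero for mirror-symmetric
#' deformation, positive when the flow bends the two leaflets unequally.
#'
#' @param upper,lower [leaflet_state()] objects with equal node counts.
#' @return displacement difference (m).
#' @export
leaflet_asymmetry <- function(upper, lower) {
  if (length(upper$x) != length(lower$x))
    stop_ijv("leaflet discretizations do not match")
  abs(leaflet_tip_displacement(upper) - leaflet_tip_displacement(lower))
}
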