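#' Parametric 2D vessel geometry with an upstream stenosis
#'
#' Builds the planar channel model of the internal jugular vein: a rectangle
#' of length `L` and width `D` whose lumen is narrowed by a fraction `f`
#' over an axial span `ls` centred at `xs`.  The open gap at the throat is
#' `d1 = (1 - f) * D`.  By default the contraction is a bilateral step
#' (an abrupt, nozzle-like narrowing from both walls); a smooth cosine bump
#' and a one-sided variant are available.
#'
#' @param L vessel length (m), default 0.2.
#' @param D vessel width (m), default 0.015.
#' @param f stenosis fraction in `[0, 1)`: fraction of the width occluded.
#' @param xs axial centre of the stenosis (m).
#' @param ls axial length of the stenosis (m).
#' @param profile `"step"` (abrupt contraction, default) or `"cosine"`.
#' @param one_sided if `TRUE` the full occlusion comes from the lower wall
#'   only; default `FALSE` (symmetric narrowing from both walls).
#' @return an object of class `vessel_geometry` with fields
#'   `L, D, f, xs, ls, d1, profile, one_sided`.
#' @examples
#' g <- vessel_geometry(f = 0.6)
#' g$d1  # 6 mm open gap
#' @export
vessel_geometry <- function(L = 0.2, D = 0.015, f = 0, xs = 0.02, ls = 0.005,
                            profile = c("step", "cosine"),
                            one_sided = FALSE) {
  profile <- match.arg(profile)
  if (L <= 0 || D <= 0) stop_ijv("L and D must be positive")
  if (f < 0 || f >= 1) stop_ijv("stenosis fraction f must lie in [0, 1)")
  if (f > 0 && (xs - ls / 2 <= 0 || xs + ls / 2 >= L))
    stop_ijv("stenosis [%g, %g] must lie strictly inside (0, %g)",
             xs - ls / 2, xs + ls / 2, L)
  structure(list(L = as.numeric(L), D = as.numeric(D), f = as.numeric(f),
                 xs = as.numeric(xs), ls = as.numeric(ls),
                 d1 = as.numeric((1 - f) * D), profile = profile,
                 one_sided = isTRUE(one_sided)),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> L = %g mm, D = %g mm, stenosis f = %g (gap d1 = %g mm, %s)\n",
    x$L * 1e3, x$D * 1e3, x$f, x$d1 * 1e3, x$profile))
  invisible(x)
}

# half-occlusion depth from each wall at axial position x (m); vector in x
stenosis_depth <- function(geom, x) {
  if (geom$f == 0) return(rep(0, length(x)))
  half <- geom$f * geom$D / 2
  inside <- abs(x - geom$xs) <= geom$ls / 2
  if (geom$profile == "step") {
    d <- ifelse(inside, half, 0)
  } else {
    d <- ifelse(inside,
                half * 0.5 * (1 + cos(2 * pi * (x - geom$xs) / geom$ls)),
                0)
  }
  d
}

#' Two-leaflet valve specification
#'
#' Geometry of the symmetric two-leaflet venous valve: each leaflet is a
#' thin flexible flap anchored on one wall at `anchor_x` (lower leaflet at
#' `y = 0`, upper at `y = D`), reaching toward the centreline so that the
#' resting tip-to-tip gap is `d2`.
#'
#' @param anchor_x axial position of the wall anchors (m).
#' @param leaflet_length leaflet arclength (m).
#' @param thickness leaflet thickness `h` (m), sets fiber stiffness
#'   `E*h` (stretch) and `E*h^3/12` (bend) per unit depth.
#' @param d2 resting gap between the leaflet tips (m).
#' @param n_nodes Lagrangian nodes per leaflet.
#' @return an object of class `valve_spec`.
#' @export
valve_spec <- function(anchor_x = 0.110, leaflet_length = 0.010,
                       thickness = 0.001, d2 = 0.003, n_nodes = 32L) {
  if (n_nodes < 3) stop_ijv("need at least 3 nodes per leaflet")
  if (d2 <= 0) stop_ijv("tip gap d2 must be positive")
  structure(list(anchor_x = as.numeric(anchor_x),
                 leaflet_length = as.numeric(leaflet_length),
                 thickness = as.numeric(thickness), d2 = as.numeric(d2),
                 n_nodes = as.integer(n_nodes)),
            class = "valve_spec")
}

#' Uniform staggered flow grid over the vessel rectangle
#'
#' @param nx,ny number of cells along x and y.
#' @param L,D domain extents (m); usually taken from a [vessel_geometry()].
#' @return an object of class `flow_grid` with cell sizes `hx, hy`, cell
#'   centres `xc, yc` and face coordinates `xf, yf`.
#' @export
flow_grid <- function(nx, ny, L = 0.2, D = 0.015) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4 || ny < 4) stop_ijv("grid must have at least 4x4 cells")
  hx <- L / nx; hy <- D / ny
  structure(list(nx = nx, ny = ny, L = L, D = D, hx = hx, hy = hy,
                 xc = (seq_len(nx) - 0.5) * hx, yc = (seq_len(ny) - 0.5) * hy,
                 xf = (0:nx) * hx, yf = (0:ny) * hy),
            class = "flow_grid")
}

#' Rasterize the vessel walls onto a flow grid
#'
#' Marks grid cells occluded by the stenosis.  The outer channel walls at
#' `y = 0` and `y = D` are handled by the solver's boundary conditions, not
#' by the mask, so for an unstenosed vessel the mask is all-`FALSE`.
#' A cell is solid when its centre lies inside the occluded band.  The
#' number of blocked rows is computed per column by counting cell centres,
#' which makes the bilateral mask exactly mirror-symmetric.
#'
#' @param geom a [vessel_geometry()].
#' @param grid a [flow_grid()]; must cover `[0,L] x [0,D]`.
#' @return logical `nx x ny` matrix, `TRUE` at solid cells.
#' @export
wall_mask <- function(geom, grid) {
  if (abs(grid$L - geom$L) > 1e-12 || abs(grid$D - geom$D) > 1e-12)
    stop_ijv("grid extents do not match the geometry")
  mask <- matrix(FALSE, grid$nx, grid$ny)
  depth <- stenosis_depth(geom, grid$xc)
  for (i in which(depth > 0)) {
    if (geom$one_sided) {
      nb <- sum(grid$yc < 2 * depth[i])
      if (nb > 0) mask[i, seq_len(nb)] <- TRUE
    } else {
      nb <- sum(grid$yc < depth[i])
      if (nb > 0) {
        mask[i, seq_len(nb)] <- TRUE
        mask[i, grid$ny + 1L - seq_len(nb)] <- TRUE
      }
    }
  }
  open_throat <- min(grid$ny - rowSums(mask))
  if (geom$f > 0 && open_throat < 4L)
    stop_ijv(paste0("grid too coarse: only %d fluid cells across the ",
                    "throat (need at least 4)"), open_throat)
  if (!lumen_connected(mask))
    stop_ijv("rasterized lumen is not a single connected region")
  mask
}

# 4-connectivity flood fill over fluid cells
lumen_connected <- function(mask) {
  fluid <- !mask
  n <- sum(fluid)
  if (n == 0L) return(FALSE)
  nx <- nrow(mask); ny <- ncol(mask)
  visited <- matrix(FALSE, nx, ny)
  start <- which(fluid, arr.ind = TRUE)[1, ]
  stack <- matrix(start, ncol = 2)
  visited[start[1], start[2]] <- TRUE
  count <- 0L
  while (nrow(stack) > 0L) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    count <- count + 1L
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i >= 1L && i <= nx && j >= 1L && j <= ny &&
          fluid[i, j] && !visited[i, j]) {
        visited[i, j] <- TRUE
        stack <- rbind(stack, c(i, j))
      }
    }
  }
  count == n
}

#' Build the resting valve: two mirror-symmetric leaflets
#'
#' Each leaflet is a straight fiber of `n_nodes` nodes from its wall anchor
#' toward the centreline, inclined downstream so that the resting tip
#' separation equals `d2`.
#'
#' @param D vessel width (m).
#' @param spec a [valve_spec()].
#' @return list with elements `spec`, `lower` and `upper`
#'   ([leaflet_state()] objects).
#' @export
build_valve <- function(D, spec) {
  if (spec$d2 >= D) stop_ijv("tip gap d2 must be smaller than the width D")
  reach <- (D - spec$d2) / 2          # transverse extent of each leaflet
  if (spec$leaflet_length <= reach)
    stop_ijv("leaflet_length %g must exceed the transverse reach %g",
             spec$leaflet_length, reach)
  ax <- sqrt(spec$leaflet_length^2 - reach^2)  # axial extent (leans downstream)
  s <- seq(0, 1, length.out = spec$n_nodes)
  lower <- leaflet_state(x = spec$anchor_x + s * ax, y = s * reach,
                         anchored = c(TRUE, rep(FALSE, spec$n_nodes - 1L)))
  upper <- leaflet_state(x = spec$anchor_x + s * ax, y = D - s * reach,
                         anchored = c(TRUE, rep(FALSE, spec$n_nodes - 1L)))
  list(spec = spec, lower = lower, upper = upper)
}
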