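# Internal array helpers for the staggered-grid solver.  Matrices are
# indexed [i, j] with i the axial (x) index and j the transverse (y) index.

# shift rows down by one (value at i becomes previous value at i-1),
# replicating the first row
shift_xm <- function(A) A[c(1L, seq_len(nrow(A) - 1L)), , drop = FALSE]

# shift rows up by one, replicating the last row
shift_xp <- function(A) A[c(seq_len(nrow(A))[-1L], nrow(A)), , drop = FALSE]

shift_ym <- function(A) A[, c(1L, seq_len(ncol(A) - 1L)), drop = FALSE]

shift_yp <- function(A) A[, c(seq_len(ncol(A))[-1L], ncol(A)), drop = FALSE]

# upwind-biased derivative along x (rows).  Second-order one-sided stencils
# in the interior, first-order at the two rows nearest each edge.  `gm1/gm2`
# and `gp1/gp2` optionally supply ghost rows beyond the first/last row;
# without them edge rows fall back to one-sided first-order differences.
upwind_ddx <- function(q, vel, h) {
  n <- nrow(q)
  stopifnot(n >= 4L)
  i <- seq_len(n)
  qm1 <- q[pmax(i - 1L, 1L), , drop = FALSE]
  qm2 <- q[pmax(i - 2L, 1L), , drop = FALSE]
  qp1 <- q[pmin(i + 1L, n), , drop = FALSE]
  qp2 <- q[pmin(i + 2L, n), , drop = FALSE]
  back <- (3 * q - 4 * qm1 + qm2) / (2 * h)
  fwd  <- (-3 * q + 4 * qp1 - qp2) / (2 * h)
  back[1:2, ] <- ((q - qm1) / h)[1:2, ]
  back[1, ]   <- ((qp1 - q) / h)[1, ]        # nothing upstream of row 1
  fwd[(n - 1L):n, ] <- ((qp1 - q) / h)[(n - 1L):n, ]
  fwd[n, ]          <- ((q - qm1) / h)[n, ]
  ifelse(vel >= 0, back, fwd)
}

# upwind-biased derivative along y (columns) with explicit ghost columns.
# ghosts: list(m1, m2, p1, p2) are the column vectors just below / above the
# physical range (m1 adjacent), encoding the wall condition.
upwind_ddy <- function(q, vel, h, ghosts) {
  n <- ncol(q)
  qq <- cbind(ghosts$m2, ghosts$m1, q, ghosts$p1, ghosts$p2)
  j <- seq_len(n) + 2L
  back <- (3 * qq[, j] - 4 * qq[, j - 1L] + qq[, j - 2L]) / (2 * h)
  fwd  <- (-3 * qq[, j] + 4 * qq[, j + 1L] - qq[, j + 2L]) / (2 * h)
  ifelse(vel >= 0, back, fwd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ijv <- function(...) stop(sprintf(...), call. = FALSE)
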