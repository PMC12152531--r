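#' Physical binding parameters and the derived distance threshold
#'
#' A gold particle is counted as antibody-bound to a fibril when the distance
#' between the particle centre and the fibril axis does not exceed
#' \eqn{r + a + d/2}: the particle can sit at most one antibody-complex
#' length beyond its own radius from the fibril surface, which itself lies
#' half a fibril width from the annotated axis.
#'
#' The defaults correspond to 10 nm colloidal gold (radius `r = 5` nm), a
#' primary plus secondary IgG complex spanning `a = 30` nm, and a fibril
#' width of `d = 17` nm, giving a threshold of 43.5 nm.
#'
#' @param r Gold particle radius in nm (non-negative).
#' @param a Length of the primary + secondary antibody complex in nm.
#' @param d Fibril width in nm.
#'
#' @return An object of class `binding_params`: a list with elements `r`,
#'   `a`, `d` and the derived `threshold` (all nm).
#'
#' @examples
#' p <- binding_params()          # r = 5, a = 30, d = 17
#' binding_threshold(p)           # 43.5 nm
#' binding_params(r = 5, a = 30, d = 17)$threshold
#' @export
binding_params <- function(r = 5, a = 30, d = 17) {
  vals <- c(r = r, a = a, d = d)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals))) {
    stop("binding parameters r, a, d must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("binding parameters r, a, d must be non-negative, got r=", r,
         ", a=", a, ", d=", d, call. = FALSE)
  }
  structure(
    list(r = r, a = a, d = d, threshold = r + a + d / 2),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Immunogold binding parameters (nm):\n")
  cat(sprintf("  particle radius r      : %g\n", x$r))
  cat(sprintf("  antibody complex a     : %g\n", x$a))
  cat(sprintf("  fibril width d         : %g\n", x$d))
  cat(sprintf("  threshold r + a + d/2  : %g\n", x$threshold))
  invisible(x)
}

#' Binding distance threshold
#'
#' Returns the maximum centre-to-axis distance, in nm, at which a particle is
#' counted as bound: \eqn{r + a + d/2}.
#'
#' @param params A [binding_params()] object.
#' @return Threshold in nm.
#' @examples
#' binding_threshold(binding_params(r = 5, a = 30, d = 17))  # 43.5
#' @export
binding_threshold <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  params$threshold
}

## Vectorised scalar kernel: distance from (px, py) to segment
## (x1, y1)-(x2, y2). All arguments recycled to a common length.
## The projection parameter is clamped to [0, 1], so a point whose foot falls
## beyond an endpoint gets the plain Euclidean distance to that endpoint.
psd_kernel <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Shortest distance from a point to a fibril segment
#'
#' Computes the standard point-to-line-segment distance: the perpendicular
#' distance to the fibril axis when the orthogonal projection of the point
#' falls within the segment, and otherwise the Euclidean distance to the
#' nearer endpoint. Particles beyond the fibril ends therefore get the
#' end-point distance without a separate code path.
#'
#' @param px,py Point coordinates in nm; vectors are accepted and recycled
#'   against the fibril rows.
#' @param fibril A fibril: either a data frame with columns `x1`, `y1`,
#'   `x2`, `y2` (one or more rows) or a named numeric vector with those
#'   elements. Coordinates in nm.
#'
#' @return Numeric vector of distances in nm.
#' @examples
#' f <- c(x1 = 0, y1 = 0, x2 = 10, y2 = 0)
#' point_segment_distance(5, 7, f)    # 7 (foot inside the segment)
#' point_segment_distance(13, 4, f)   # 5 (beyond the end: sqrt(3^2 + 4^2))
#' @export
point_segment_distance <- function(px, py, fibril) {
  if (is.data.frame(fibril)) {
    need <- c("x1", "y1", "x2", "y2")
    if (!all(need %in% names(fibril))) {
      stop("fibril data frame must have columns x1, y1, x2, y2", call. = FALSE)
    }
    x1 <- fibril$x1; y1 <- fibril$y1; x2 <- fibril$x2; y2 <- fibril$y2
  } else {
    x1 <- fibril[["x1"]]; y1 <- fibril[["y1"]]
    x2 <- fibril[["x2"]]; y2 <- fibril[["y2"]]
  }
  if (any((x2 - x1)^2 + (y2 - y1)^2 == 0)) {
    stop("zero-length fibril: start and end points coincide", call. = FALSE)
  }
  psd_kernel(px, py, x1, y1, x2, y2)
}

## Distance matrix between n particles and m fibril segments (n x m).
## Broadcast by building n x m coordinate matrices; fine for the sizes a
## micrograph produces (hundreds by hundreds).
particle_fibril_distances <- function(particles, fibrils) {
  n <- nrow(particles)
  m <- nrow(fibrils)
  if (n == 0L || m == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = m))
  }
  PX <- matrix(particles$x, nrow = n, ncol = m)
  PY <- matrix(particles$y, nrow = n, ncol = m)
  X1 <- matrix(fibrils$x1, nrow = n, ncol = m, byrow = TRUE)
  Y1 <- matrix(fibrils$y1, nrow = n, ncol = m, byrow = TRUE)
  X2 <- matrix(fibrils$x2, nrow = n, ncol = m, byrow = TRUE)
  Y2 <- matrix(fibrils$y2, nrow = n, ncol = m, byrow = TRUE)
  D <- psd_kernel(PX, PY, X1, Y1, X2, Y2)
  dim(D) <- c(n, m)
  D
}

## counter-clockwise orientation test for segment intersection
.ccw <- function(ax, ay, bx, by, cx, cy) {
  (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
}

segments_intersect <- function(p1, p2, q1, q2) {
  .ccw(p1[1], p1[2], q1[1], q1[2], q2[1], q2[2]) !=
    .ccw(p2[1], p2[2], q1[1], q1[2], q2[1], q2[2]) &&
  .ccw(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2]) !=
    .ccw(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
}

#' Minimum distance between two fibril segments
#'
#' Zero when the segments intersect; otherwise the minimum over the four
#' endpoint-to-opposite-segment distances, which is the exact
#' segment-to-segment distance for non-intersecting segments.
#'
#' @param f1,f2 Fibrils as in [point_segment_distance()] (single segments).
#' @return Distance in nm.
#' @export
segment_segment_distance <- function(f1, f2) {
  g <- function(f) {
    if (is.data.frame(f)) f <- unlist(f[1, c("x1", "y1", "x2", "y2")])
    as.numeric(f[c("x1", "y1", "x2", "y2")])
  }
  a <- g(f1); b <- g(f2)
  if (segments_intersect(a[1:2], a[3:4], b[1:2], b[3:4])) return(0)
  min(
    psd_kernel(a[1], a[2], b[1], b[2], b[3], b[4]),
    psd_kernel(a[3], a[4], b[1], b[2], b[3], b[4]),
    psd_kernel(b[1], b[2], a[1], a[2], a[3], a[4]),
    psd_kernel(b[3], b[4], a[1], a[2], a[3], a[4])
  )
}

## One segment against many: vectorised over the rows of `fibrils`
## (anything with numeric elements x1, y1, x2, y2 of equal length).
## Used by the crowding filter and the synthetic-field placement loop.
seg_to_segs_distance <- function(x1, y1, x2, y2, fibrils) {
  m <- length(fibrils$x1)
  if (m == 0L) return(numeric(0))
  d <- pmin(
    psd_kernel(x1, y1, fibrils$x1, fibrils$y1, fibrils$x2, fibrils$y2),
    psd_kernel(x2, y2, fibrils$x1, fibrils$y1, fibrils$x2, fibrils$y2),
    psd_kernel(fibrils$x1, fibrils$y1, x1, y1, x2, y2),
    psd_kernel(fibrils$x2, fibrils$y2, x1, y1, x2, y2)
  )
  ## zero where the segments actually cross (vectorised orientation test)
  crosses <-
    (.ccw(x1, y1, fibrils$x1, fibrils$y1, fibrils$x2, fibrils$y2) !=
     .ccw(x2, y2, fibrils$x1, fibrils$y1, fibrils$x2, fibrils$y2)) &
    (.ccw(x1, y1, x2, y2, fibrils$x1, fibrils$y1) !=
     .ccw(x1, y1, x2, y2, fibrils$x2, fibrils$y2))
  d[crosses] <- 0
  d
}
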