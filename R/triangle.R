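# Symmetric triangle coordinates: the (drop, short side, signed angle)
# parametrisation of triangle shape in which vertex order is irrelevant and
# mirroring is a sign flip of the angle.
#
# Construction (sides a, b, c opposite vertices A, B, C; b shortest):
#  * drop vector  a_v = (3^(3/4)/sqrt(2)) * (O - B), O the centroid - a
#    rescaled median from the vertex opposite the shortest side;
#  * short vector a_w = (3^(1/4)/sqrt(2)) * (oriented shortest side), the
#    orientation pointing toward the endpoint whose other leg is longest;
#  * theta = signed angle between a_v and a_w (positive when a_v leads a_w
#    in the clockwise sense), always in [-pi/2, pi/2].
# The scale factors are the ones under which the closed-form rotationally
# averaged three-point function of a Gaussian mixture becomes a product of
# two one-dimensional Gaussians of common width 3^(1/4) R centred at
# (a_v, a_w) times an angular factor (see rabs_closed_form.R); they also
# make the equilateral triangle the symmetric point a_v = a_w.

DROP_SCALE <- 3^(3 / 4) / sqrt(2)
SHORT_SCALE <- 3^(1 / 4) / sqrt(2)

#' Symmetric triangle coordinates of three points
#'
#' Computes the (drop, short side, signed angle) coordinates of the triangle
#' spanned by three 2D points. The result does not depend on the order in
#' which the vertices are given; translating or rotating the triangle leaves
#' it unchanged, and mirroring negates `theta` only.
#'
#' @param p1,p2,p3 numeric 2-vectors (finite).
#' @return object of class `triangle_coord`: `drop` (scaled median length),
#'   `short` (scaled shortest-side length), `theta` (signed angle in
#'   `[-pi/2, pi/2]`), `degenerate` (collinear or coincident), `tie`
#'   (ambiguous shortest side or leg), and the two coordinate vectors
#'   `a_v`, `a_w`.
#' @examples
#' triangle_coordinates(c(0, 0), c(2, 0), c(0, 1))
#' @export
triangle_coordinates <- function(p1, p2, p3) {
  P <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3))
  if (!all(is.finite(P)) || ncol(P) != 2L) {
    stop("triangle_coordinates: need three finite 2D points")
  }
  O <- colMeans(P)
  # side i is opposite vertex i
  side_len <- c(sqrt(sum((P[2, ] - P[3, ])^2)),
                sqrt(sum((P[3, ] - P[1, ])^2)),
                sqrt(sum((P[1, ] - P[2, ])^2)))
  scale0 <- max(side_len)
  degenerate <- FALSE
  if (scale0 == 0) {
    # coincident points
    return(structure(list(drop = 0, short = 0, theta = 0, degenerate = TRUE,
                          tie = TRUE, a_v = c(0, 0), a_w = c(0, 0)),
                     class = "triangle_coord"))
  }
  cr <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
    (P[2, 2] - P[1, 2]) * (P[3, 1] - P[1, 1])
  if (abs(cr) < 1e-12 * scale0^2) degenerate <- TRUE
  reltol <- 1e-9
  shortest <- which(side_len <= min(side_len) * (1 + reltol))
  tie <- length(shortest) > 1L
  best <- NULL
  for (bidx in shortest) {
    ends <- setdiff(1:3, bidx)
    legs <- side_len[ends]      # leg at ends[i] is the side opposite it
    if (abs(legs[1] - legs[2]) <= reltol * scale0) {
      # isoceles with shortest base: orient toward lexicographically larger
      to <- ends[order(P[ends, 1], P[ends, 2])[2]]
      tie <- TRUE
    } else {
      # toward the endpoint belonging to the longest leg: the leg through
      # vertex `ends[i]` is the side opposite the *other* endpoint
      to <- ends[which.min(legs)]
    }
    from <- setdiff(ends, to)
    a_w <- SHORT_SCALE * (P[to, ] - P[from, ])
    a_v <- DROP_SCALE * (O - P[bidx, ])
    theta <- signed_angle(a_w, a_v)
    if (degenerate) theta <- 0
    cand <- list(drop = sqrt(sum(a_v^2)), short = sqrt(sum(a_w^2)),
                 theta = theta, a_v = a_v, a_w = a_w)
    if (is.null(best) ||
        abs(cand$theta) < abs(best$theta) - 1e-12 ||
        (abs(abs(cand$theta) - abs(best$theta)) <= 1e-12 &&
           cand$theta > best$theta)) {
      best <- cand
    }
  }
  structure(list(drop = best$drop, short = best$short, theta = best$theta,
                 degenerate = degenerate, tie = tie,
                 a_v = best$a_v, a_w = best$a_w),
            class = "triangle_coord")
}

#' @export
print.triangle_coord <- function(x, ...) {
  cat(sprintf("triangle_coord: drop %.4g, short %.4g, theta %.4g rad%s%s\n",
              x$drop, x$short, x$theta,
              if (x$degenerate) " [degenerate]" else "",
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Enumerate the triangles of a point pattern
#'
#' One [triangle_coordinates()] row per unordered vertex triple: a pattern
#' of N points yields choose(N, 3) triangles (10 for N = 5). The table of
#' triangle coordinates is a third-order shape summary of the pattern;
#' the mirrored pattern gives the same table with `theta` negated, while
#' the pairwise-distance multiset (hence the RPS) cannot tell the two apart.
#'
#' @param p a 2D [point_pattern()] with at least 3 points.
#' @return data frame with columns `i, j, k` (vertex indices), `drop`,
#'   `short`, `theta`, `degenerate`, `tie`.
#' @export
enumerate_triangles <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  if (p$dim != 2L) stop("enumerate_triangles: implemented for 2D patterns")
  N <- nrow(p$centers)
  if (N < 3L) stop("enumerate_triangles: need at least 3 points")
  trip <- utils::combn(N, 3L)
  rows <- lapply(seq_len(ncol(trip)), function(c0) {
    tc <- triangle_coordinates(p$centers[trip[1, c0], ],
                               p$centers[trip[2, c0], ],
                               p$centers[trip[3, c0], ])
    data.frame(i = trip[1, c0], j = trip[2, c0], k = trip[3, c0],
               drop = tc$drop, short = tc$short, theta = tc$theta,
               degenerate = tc$degenerate, tie = tc$tie)
  })
  do.call(rbind, rows)
}

#' Empirical boundary of the triangle-coordinate asymmetric unit
#'
#' Every triangle shape has exactly one representative with
#' `|theta| <= pi/2` and a bounded short/drop ratio. The ratio bound is
#' computed here by a dense deterministic scan of shape space (third vertex
#' on a grid over the half plane above a fixed base, which covers all shapes
#' up to similarity), recording the largest `short/drop` seen in each
#' `|theta|` bin. Under the package scalings the equilateral triangle is the
#' extremal shape, with ratio 1 at `|theta| = pi/2`.
#'
#' @param n_theta number of bins over `[0, pi/2]`.
#' @param n_grid resolution of the shape-space scan per axis.
#' @return data frame with columns `theta` (bin centres) and `max_ratio`.
#' @export
asymmetric_unit_bound <- function(n_theta = 45L, n_grid = 200L) {
  xs <- seq(-2.5, 2.5, length.out = n_grid)
  ys <- seq(1e-3, 3, length.out = n_grid)
  edges <- seq(0, pi / 2, length.out = n_theta + 1L)
  mx <- numeric(n_theta)
  for (x in xs) {
    for (y in ys) {
      tc <- triangle_coordinates(c(0, 0), c(1, 0), c(x, y))
      if (tc$drop <= 0) next
      b <- min(findInterval(abs(tc$theta), edges,
                            rightmost.closed = TRUE), n_theta)
      ratio <- tc$short / tc$drop
      if (ratio > mx[b]) mx[b] <- ratio
    }
  }
  data.frame(theta = (edges[-1] + edges[-(n_theta + 1L)]) / 2, max_ratio = mx)
}

#' Check a triangle coordinate against the asymmetric unit
#'
#' Verifies `|theta| <= pi/2` and that the short/drop ratio lies below the
#' empirical boundary curve (interpolated from [asymmetric_unit_bound()]).
#'
#' @param tc a `triangle_coord`.
#' @param bound a boundary table from [asymmetric_unit_bound()]; computed on
#'   demand (and cached for the session) when omitted.
#' @param tol relative slack applied to the boundary.
#' @return logical; diagnostics (`theta_ok`, `ratio`, `ratio_bound`) are
#'   attached as attributes.
#' @export
asymmetric_unit_check <- function(tc, bound = NULL, tol = 0.05) {
  stopifnot(inherits(tc, "triangle_coord"))
  if (tc$degenerate && tc$drop == 0) {
    out <- TRUE
    attr(out, "theta_ok") <- TRUE
    return(out)
  }
  if (is.null(bound)) bound <- cached_asym_bound()
  theta_ok <- abs(tc$theta) <= pi / 2 + 1e-12
  ratio <- if (tc$drop > 0) tc$short / tc$drop else Inf
  rb <- stats::approx(bound$theta, bound$max_ratio, xout = abs(tc$theta),
                      rule = 2)$y
  out <- theta_ok && ratio <= rb * (1 + tol)
  attr(out, "theta_ok") <- theta_ok
  attr(out, "ratio") <- ratio
  attr(out, "ratio_bound") <- rb
  out
}

.motinv_cache <- new.env(parent = emptyenv())

cached_asym_bound <- function() {
  if (is.null(.motinv_cache$asym_bound)) {
    .motinv_cache$asym_bound <- asymmetric_unit_bound()
  }
  .motinv_cache$asym_bound
}

#' Quiver-style plot of a triangle table
#'
#' Draws each triangle of an [enumerate_triangles()] table as a point at
#' (short, drop) with an arrow whose direction encodes the signed angle -
#' the standard way to display the three-coordinate table in two dimensions.
#' Mirrored patterns show up as the same points with arrows reflected
#' across the horizontal.
#'
#' @param tab a data frame from [enumerate_triangles()].
#' @param arrow_len arrow length in plot units.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `tab`.
#' @export
plot_triangle_table <- function(tab, arrow_len = NULL, ...) {
  if (is.null(arrow_len)) {
    arrow_len <- 0.05 * max(tab$short, tab$drop)
  }
  graphics::plot(tab$short, tab$drop, pch = 19,
                 xlab = "short side", ylab = "drop", ...)
  graphics::arrows(tab$short, tab$drop,
                   tab$short + arrow_len * cos(tab$theta),
                   tab$drop + arrow_len * sin(tab$theta),
                   length = 0.06)
  invisible(tab)
}
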