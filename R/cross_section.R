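#' Intersect a mesh with a plane
#'
#' Computes the polygonal intersection of a triangulated surface with a
#' plane. Each triangle crossing the plane contributes one segment; segments
#' are chained by their shared mesh edges, so closure is exact (no
#' coordinate tolerance is involved). Chains that end on an open mesh
#' boundary are returned as open polylines and flagged.
#'
#' @param mesh a [surface_mesh].
#' @param origin a point on the plane (nm).
#' @param normal the plane normal (any length; normalised internally).
#' @return a list of loops; each loop is a list with `points` (k x 2 planar
#'   coordinates in the plane basis), `points3d` (k x 3), `closed` (logical)
#'   and `basis` (the in-plane unit vectors and normal). An empty list if
#'   the plane misses the mesh.
#' @export
slice_plane <- function(mesh, origin, normal) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0) return(list())
  b <- orthobasis(normal)
  d <- as.vector(V %*% b$n) - sum(origin * b$n)
  # vertices exactly on the plane are nudged to the positive side so every
  # crossing is a strict sign change (deterministic symbolic perturbation)
  scale <- max(abs(d), 1)
  d[abs(d) < 1e-12 * scale] <- 1e-12 * scale
  pos <- d > 0
  s1 <- pos[F[, 1]]; s2 <- pos[F[, 2]]; s3 <- pos[F[, 3]]
  cross_f <- which((s1 != s2) | (s2 != s3))
  if (length(cross_f) == 0) return(list())

  edge_key <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    lo * (nrow(V) + 1) + hi
  }
  fa <- F[cross_f, 1]; fb <- F[cross_f, 2]; fc <- F[cross_f, 3]
  sa <- pos[fa]; sb <- pos[fb]; sc <- pos[fc]
  # per face, the two edges whose endpoints differ in sign
  e_ab <- sa != sb; e_bc <- sb != sc; e_ca <- sc != sa
  keys <- cbind(
    ifelse(e_ab, edge_key(fa, fb), edge_key(fb, fc)),
    ifelse(e_ca, edge_key(fc, fa), edge_key(fb, fc))
  )
  uk <- unique(as.vector(keys))
  # intersection point for each unique crossing edge
  lo <- floor(uk / (nrow(V) + 1)); hi <- uk - lo * (nrow(V) + 1)
  t <- d[lo] / (d[lo] - d[hi])
  P <- V[lo, , drop = FALSE] + t * (V[hi, , drop = FALSE] - V[lo, , drop = FALSE])
  k1 <- match(keys[, 1], uk); k2 <- match(keys[, 2], uk)

  # chain segments (k1[i] -- k2[i]) into paths/cycles over edge-key nodes
  nseg <- length(k1)
  deg <- tabulate(c(k1, k2), nbins = length(uk))
  # adjacency: up to 2 incident segments per node on a manifold slice;
  # allow more and pick unused deterministically
  inc <- vector("list", length(uk))
  for (i in seq_len(nseg)) {
    inc[[k1[i]]] <- c(inc[[k1[i]]], i)
    inc[[k2[i]]] <- c(inc[[k2[i]]], i)
  }
  used <- logical(nseg)
  loops <- list()
  walk <- function(start_seg, start_node) {
    path <- integer(0)
    node <- start_node
    seg <- start_seg
    repeat {
      used[seg] <<- TRUE
      nxt <- if (k1[seg] == node) k2[seg] else k1[seg]
      path <- c(path, node)
      node <- nxt
      cand <- inc[[node]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      seg <- cand[1]
    }
    c(path, node)
  }
  # open chains first (start at degree-1 nodes), then cycles
  for (start in order(deg)) {
    cand <- inc[[start]]
    cand <- cand[!used[cand]]
    while (length(cand) > 0) {
      nodes <- walk(cand[1], start)
      closed <- nodes[1] == nodes[length(nodes)]
      if (closed) nodes <- nodes[-length(nodes)]
      pts3 <- P[nodes, , drop = FALSE]
      rel <- sweep(pts3, 2, origin)
      pts2 <- cbind(rel %*% b$u, rel %*% b$v)
      loops[[length(loops) + 1]] <- list(points = pts2, points3d = pts3,
                                         closed = closed, basis = b)
      cand <- inc[[start]]
      cand <- cand[!used[cand]]
    }
  }
  loops
}

#' Signed-area-free polygon area (shoelace magnitude)
#'
#' @param loop a k x 2 matrix of ordered polygon vertices, or a loop as
#'   returned by [slice_plane].
#' @return area in nm^2, independent of vertex orientation.
#' @export
polygon_area <- function(loop) {
  P <- loop_points(loop)
  abs(signed_area2d(P))
}

loop_points <- function(loop) {
  if (is.list(loop) && !is.null(loop$points)) loop$points
  else as.matrix(loop)
}

polygon_centroid2d <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(P))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

loop_centroid3d <- function(loop) {
  c2 <- polygon_centroid2d(loop$points)
  b <- loop$basis
  orig3 <- loop$points3d[1, ] -
    (loop$points[1, 1] * b$u + loop$points[1, 2] * b$v)
  orig3 + c2[1] * b$u + c2[2] * b$v
}

# ray-crossing point-in-polygon; P is k x 2, q length-2
point_in_polygon <- function(q, P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > q[2]) != (yn > q[2])) &
    (q[1] < (xn - x) * (q[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

# 2D coordinates of a 3D point in a loop's plane basis
project_to_loop_plane <- function(loop, p) {
  b <- loop$basis
  off_u <- sum(loop$points3d[1, ] * b$u) - loop$points[1, 1]
  off_v <- sum(loop$points3d[1, ] * b$v) - loop$points[1, 2]
  c(sum(p * b$u) - off_u, sum(p * b$v) - off_v)
}

#' Pick the section loop belonging to the structure under study
#'
#' A plane may cut a mesh in several places (neighbouring structures,
#' tracing-noise islands); the analysis follows one structure, so the loop
#' whose centroid is nearest a reference point (the current centreline
#' point) is selected. Ties are broken toward the loop of smaller area.
#' With `must_contain = TRUE` only loops that enclose the reference point's
#' in-plane projection qualify, which is what a junction cross-section must
#' do around its own centreline.
#'
#' @param loops list of loops from [slice_plane].
#' @param reference_point length-3 point in nm.
#' @param closed_only consider only closed loops (default `TRUE`).
#' @param must_contain require the loop to enclose the reference point's
#'   projection (default `FALSE`).
#' @return the selected loop, or `NULL` if none qualifies.
#' @export
select_loop <- function(loops, reference_point, closed_only = TRUE,
                        must_contain = FALSE) {
  if (closed_only) loops <- Filter(function(l) isTRUE(l$closed), loops)
  if (must_contain)
    loops <- Filter(function(l)
      point_in_polygon(project_to_loop_plane(l, reference_point), l$points),
      loops)
  if (length(loops) == 0) return(NULL)
  cent <- t(vapply(loops, loop_centroid3d, numeric(3)))
  d <- sqrt(colSums((t(cent) - reference_point)^2))
  best <- which(d - min(d) < 1e-9 * max(1, min(d)))
  if (length(best) > 1) {
    ar <- vapply(loops[best], polygon_area, numeric(1))
    best <- best[which.min(ar)]
  }
  loops[[best[1]]]
}

#' Minimum-area rotated bounding rectangle
#'
#' Rotating-calipers rectangle of the convex hull of a planar polygon: the
#' smallest-area enclosing rectangle over all rotations, so tilted profiles
#' are measured without axis-alignment bias.
#'
#' @param loop a k x 2 polygon matrix or a loop from [slice_plane].
#' @return list with `major`, `minor` (side lengths, nm, `major >= minor`)
#'   and `angle` (orientation of the major side, radians in `[0, pi)`).
#' @export
min_area_rect <- function(loop) {
  P <- loop_points(loop)
  if (nrow(P) < 3) stop("min_area_rect needs >= 3 points")
  h <- grDevices::chull(P[, 1], P[, 2])
  H <- P[h, , drop = FALSE]
  if (nrow(H) < 3) stop("degenerate (collinear) polygon: no bounding rectangle")
  E <- rbind(H[-1, , drop = FALSE], H[1, , drop = FALSE]) - H
  elen <- sqrt(rowSums(E^2))
  keep <- elen > 1e-12
  if (!any(keep)) stop("degenerate polygon: zero-length hull edges")
  ang <- atan2(E[keep, 2], E[keep, 1])
  best <- NULL
  for (a in ang) {
    ca <- cos(-a); sa <- sin(-a)
    xr <- H[, 1] * ca - H[, 2] * sa
    yr <- H[, 1] * sa + H[, 2] * ca
    w <- max(xr) - min(xr)
    hgt <- max(yr) - min(yr)
    area <- w * hgt
    if (is.null(best) || area < best$area - 1e-15) {
      major <- max(w, hgt); minor <- min(w, hgt)
      th <- if (w >= hgt) a else a + pi / 2
      best <- list(area = area, major = major, minor = minor,
                   angle = th %% pi)
    }
  }
  if (best$minor <= 1e-9 * best$major)
    stop("degenerate (collinear) polygon: no bounding rectangle")
  list(major = best$major, minor = best$minor, angle = best$angle)
}

# circular (closed) or reflective (open) moving average along a loop; the
# window is capped at 1/8 of the vertex count so short loops keep their
# shape. For closed loops the averaging gain on the fundamental harmonic
# (the radius of a circular loop) is compensated by rescaling about the
# centroid, so smoothing suppresses vertex noise without shrinking the loop.
smooth_loop <- function(P, window, closed = TRUE) {
  window <- min(window, nrow(P) %/% 8)
  if (window <= 1) return(P)
  if (window %% 2 == 0) window <- window - 1
  half <- (window - 1) / 2
  n <- nrow(P)
  idx <- if (closed) {
    function(i) ((i - 1) %% n) + 1
  } else {
    function(i) pmin(pmax(i, 1), n)
  }
  out <- P
  for (j in seq_len(ncol(P))) {
    acc <- numeric(n)
    for (o in -half:half) acc <- acc + P[idx(seq_len(n) + o), j]
    out[, j] <- acc / window
  }
  if (closed) {
    gain <- mean(cos(2 * pi * (-half:half) / n))
    ctr <- colMeans(out)
    out <- sweep(sweep(out, 2, ctr), 2, rep(gain, ncol(P)), "/")
    out <- sweep(out, 2, ctr, "+")
  }
  out
}

new_cross_sections <- function(tab, loops) {
  structure(list(table = tab, loops = loops), class = "cross_sections")
}

#' @export
print.cross_sections <- function(x, ...) {
  cat(sprintf("<cross_sections> %d sections, stations %.3g..%.3g nm\n",
              nrow(x$table), min(x$table$station_s), max(x$table$station_s)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.cross_sections <- function(x, ...) x$table

#' Series of cross-sections along a junction centreline
#'
#' Sections a mesh at fixed arc-length intervals from a base point along a
#' centreline. In `"adaptive"` mode the next plane origin is the previous
#' section's centroid advanced along the current axis, and the axis is
#' re-estimated from the smoothed centroid track with the per-step tilt
#' capped at 15 degrees, so the series follows bent necks. In `"fixed"` mode
#' the planes stay perpendicular to the given axis. Stations where the plane
#' meets no closed loop before any section has been found (e.g. the base
#' plane itself, coplanar with the envelope sheet) are skipped; once the
#' series has started, the first lost station ends it.
#'
#' @param mesh a [surface_mesh].
#' @param base base point of the junction (nm) on the envelope plane.
#' @param axis unit vector pointing from the envelope into the junction.
#' @param step station spacing in nm, in (0, 5].
#' @param range maximum station in nm (> 0).
#' @param mode `"adaptive"` (default) or `"fixed"`.
#' @param min_range if the series ends (section lost) before this station,
#'   raise an error naming the last valid station; default 0 (never).
#' @param smooth_window odd moving-average window (in vertices) applied to
#'   each loop before area/rectangle metrics; 1 disables smoothing.
#' @param max_tilt_deg adaptive-mode cap on the per-step axis tilt.
#' @param min_convexity minimum ratio of loop area to bounding-rectangle
#'   area for a loop to count as a cross-section. A true transversal
#'   profile is convex-ish (ratio near pi/4); self-crossing chains produced
#'   where a plane grazes a noisy, nearly coplanar sheet have large
#'   rectangles but tiny (cancelling) shoelace areas and are rejected.
#' @return a `cross_sections` object: `$table` is a data.frame with columns
#'   `station_s`, `area`, `rect_major`, `rect_minor`, `rect_angle`,
#'   `centroid_x/y/z`; `$loops` holds the section polygons.
#' @export
section_series <- function(mesh, base, axis, step = 0.5, range,
                           mode = c("adaptive", "fixed"), min_range = 0,
                           smooth_window = 1, max_tilt_deg = 15,
                           min_convexity = 0.3) {
  mode <- match.arg(mode)
  if (!(step > 0 && step <= 5)) stop("step must be in (0, 5] nm")
  if (range <= 0) stop("range must be > 0")
  axis <- unitize(axis)
  stations <- seq(0, range, by = step)
  rows <- list(); loops <- list()
  cur_axis <- axis
  prev_centroid <- NULL
  centroid_track <- list()
  station_arc <- 0
  started <- FALSE
  for (s in stations) {
    origin <- if (mode == "fixed" || is.null(prev_centroid)) base + s * axis
              else prev_centroid + step * cur_axis
    ref <- origin
    ls <- slice_plane(mesh, origin, cur_axis)
    ls <- Filter(function(l) {
      if (!isTRUE(l$closed) || nrow(l$points) < 3) return(FALSE)
      r <- tryCatch(min_area_rect(l$points), error = function(e) NULL)
      !is.null(r) && polygon_area(l$points) >= min_convexity * r$major * r$minor
    }, ls)
    loop <- select_loop(ls, ref, closed_only = FALSE, must_contain = TRUE)
    if (is.null(loop)) {
      if (!started) next  # degenerate base station(s)
      last_s <- rows[[length(rows)]]$station_s
      if (last_s < min_range)
        stop(sprintf("section lost at station %.3g nm before minimum range %.3g nm; last valid station %.3g nm",
                     s, min_range, last_s))
      break
    }
    Ps <- smooth_loop(loop$points, smooth_window, closed = TRUE)
    sm_loop <- loop
    sm_loop$points <- Ps
    cen <- loop_centroid3d(loop)
    st <- if (mode == "fixed") {
      s
    } else {
      if (is.null(prev_centroid)) station_arc <- vnorm(cen - base)
      else station_arc <- station_arc + vnorm(cen - prev_centroid)
      station_arc
    }
    rect <- tryCatch(min_area_rect(Ps), error = function(e) NULL)
    if (is.null(rect)) { if (!started) next else break }
    rows[[length(rows) + 1]] <- data.frame(
      station_s = st, area = polygon_area(Ps),
      rect_major = rect$major, rect_minor = rect$minor,
      rect_angle = rect$angle,
      centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3])
    loops[[length(loops) + 1]] <- sm_loop
    started <- TRUE
    if (mode == "adaptive") {
      centroid_track[[length(centroid_track) + 1]] <- cen
      k <- length(centroid_track)
      if (k >= 6) {
        # direction smoothed over a 5-section centroid baseline: a
        # single-step difference feeds centroid noise and plane-tilt
        # feedback into the next section and oscillates on steep flares.
        # The low-gain update (30% of the residual angle per step, capped)
        # keeps centroid noise from tilting the plane while persistent
        # bends are still followed.
        dir <- cen - centroid_track[[k - 5]]
        if (vnorm(dir) > 1e-9) {
          ang <- acos(max(-1, min(1, sum(cur_axis * unitize(dir)))))
          gain_deg <- min(0.3 * ang * 180 / pi, max_tilt_deg)
          cur_axis <- rotate_toward(cur_axis, unitize(dir), gain_deg)
        }
      }
      prev_centroid <- cen
    }
  }
  if (length(rows) == 0)
    stop("no cross-sections found: plane series misses the mesh")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new_cross_sections(tab, loops)
}

#' Export a section series as CSV
#'
#' Writes the per-station profile table (station, area, rectangle sides,
#' centroid) used for width/length profiles.
#'
#' @param sections a `cross_sections` object.
#' @param path output CSV path.
#' @export
write_sections <- function(sections, path) {
  stopifnot(inherits(sections, "cross_sections"))
  utils::write.csv(sections$table, path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.cross_sections <- function(x, ...) {
  graphics::plot(x$table$station_s, x$table$area, type = "b", pch = 16,
                 xlab = "station s (nm)", ylab = "cross-section area (nm^2)",
                 ...)
  invisible(x)
}
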