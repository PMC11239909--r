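#' Locate the junction neck as the minimum-area cross-section
#'
#' The neck is the cross-section of smallest area within a window (default
#' 25 nm) of arc-length stations from the junction base. Ties go to the
#' station nearer the base. If the minimum sits at the first sampled station
#' and the areas increase monotonically through the window, the junction has
#' no interior constriction and is flagged `non_constricted` (the geometry
#' of a wide cone-shaped base rather than an hourglass).
#'
#' @param sections a `cross_sections` object from [section_series].
#' @param window neck search window in nm from the base (default 25).
#' @return a list of class `neck_section`: `station_s`, `area`,
#'   `rect_major`, `rect_minor`, `rect_angle`, `centroid`, `loop`,
#'   `non_constricted`, and `index` into the series.
#' @export
find_neck <- function(sections, window = 25) {
  stopifnot(inherits(sections, "cross_sections"))
  tab <- sections$table
  in_win <- which(tab$station_s >= 0 & tab$station_s <= window)
  if (length(in_win) < 2)
    stop(sprintf("need >= 2 cross-sections within %g nm of the base; found %d",
                 window, length(in_win)))
  a <- tab$area[in_win]
  j <- in_win[which.min(a)]  # ties: first index = smallest station
  tol <- 1e-9 * max(a)
  non_constricted <- (j == in_win[1]) && all(diff(a) >= -tol)
  structure(list(
    station_s = tab$station_s[j], area = tab$area[j],
    rect_major = tab$rect_major[j], rect_minor = tab$rect_minor[j],
    rect_angle = tab$rect_angle[j],
    centroid = c(tab$centroid_x[j], tab$centroid_y[j], tab$centroid_z[j]),
    loop = sections$loops[[j]], non_constricted = non_constricted,
    index = j), class = "neck_section")
}

#' @export
print.neck_section <- function(x, ...) {
  cat(sprintf("<neck_section> station %.3g nm, area %.4g nm^2, rect %.3g x %.3g nm%s\n",
              x$station_s, x$area, x$rect_major, x$rect_minor,
              if (x$non_constricted) " [non_constricted]" else ""))
  invisible(x)
}

#' Junction width from the neck's bounding rectangle
#'
#' Width is the average of the longest and shortest side of the
#' minimum-area rotated bounding rectangle around the neck's top profile,
#' in nm.
#'
#' @param neck a `neck_section` from [find_neck].
#' @return width in nm.
#' @export
junction_width <- function(neck) {
  stopifnot(inherits(neck, "neck_section"))
  (neck$rect_major + neck$rect_minor) / 2
}

#' Junction aspect ratio from the neck's bounding rectangle
#'
#' Ratio of the major to the minor side of the minimum-area bounding
#' rectangle of the top profile (>= 1; 1 for a circular neck).
#'
#' @param neck a `neck_section` from [find_neck].
#' @return dimensionless aspect ratio.
#' @export
junction_aspect_ratio <- function(neck) {
  stopifnot(inherits(neck, "neck_section"))
  neck$rect_major / neck$rect_minor
}

#' Junction length from the 1.2-fold area rule
#'
#' The length of the constricted region is measured from the neck outward:
#' on each side, the nearest sampled station whose cross-section area
#' reaches `factor` (default 1.2) times the neck area. `L1` is the distance
#' toward the envelope, `L2` the distance toward the ER, and `L = L1 + L2`
#' when both sides are reached. A side whose section series ends before
#' reaching the threshold (a junction truncated at the tomogram border) is
#' reported `NA` and flagged.
#'
#' @param sections a `cross_sections` object.
#' @param neck a `neck_section` from [find_neck].
#' @param factor area ratio defining the ends of the neck region (> 1).
#' @return list with `L`, `L1`, `L2` (nm, possibly `NA`) and `flags`
#'   (character vector, subset of `"truncated_L1"`, `"truncated_L2"`).
#' @export
junction_length <- function(sections, neck, factor = 1.2) {
  stopifnot(inherits(sections, "cross_sections"), inherits(neck, "neck_section"))
  if (factor <= 1) stop("factor must be > 1")
  tab <- sections$table
  target <- factor * neck$area
  flags <- character(0)
  # toward the envelope: stations below the neck, nearest first
  ne_side <- which(tab$station_s < neck$station_s)
  L1 <- NA_real_
  if (length(ne_side)) {
    ne_side <- ne_side[order(neck$station_s - tab$station_s[ne_side])]
    hit <- ne_side[tab$area[ne_side] >= target]
    if (length(hit)) L1 <- neck$station_s - tab$station_s[hit[1]]
  }
  if (is.na(L1)) flags <- c(flags, "truncated_L1")
  # toward the ER: stations above the neck
  er_side <- which(tab$station_s > neck$station_s)
  L2 <- NA_real_
  if (length(er_side)) {
    er_side <- er_side[order(tab$station_s[er_side] - neck$station_s)]
    hit <- er_side[tab$area[er_side] >= target]
    if (length(hit)) L2 <- tab$station_s[hit[1]] - neck$station_s
  }
  if (is.na(L2)) flags <- c(flags, "truncated_L2")
  L <- if (!is.na(L1) && !is.na(L2)) L1 + L2 else NA_real_
  list(L = L, L1 = L1, L2 = L2, flags = flags)
}

#' Correct a measured dimension for specimen shrinkage
#'
#' Chemical processing for electron microscopy shrinks the specimen; a
#' measured dimension underestimates the native one by the shrinkage
#' fraction. The native estimate is `measured / (1 - fraction)`. The default
#' fraction of 0.17 is the calibrated 17% linear shrinkage of the
#' preparation protocol.
#'
#' @param measured measured dimension(s) in nm (vectorised).
#' @param shrinkage_fraction linear shrinkage fraction in `[0, 1)`.
#' @return native-scale dimension(s) in nm.
#' @examples
#' correct_shrinkage(c(7, 20))   # measured width range -> native ~8-24 nm
#' @export
correct_shrinkage <- function(measured, shrinkage_fraction = 0.17) {
  if (!is.numeric(shrinkage_fraction) || length(shrinkage_fraction) != 1 ||
      shrinkage_fraction < 0 || shrinkage_fraction >= 1)
    stop("shrinkage_fraction must be in [0, 1)")
  measured / (1 - shrinkage_fraction)
}

#' Sagittal side profile of a junction
#'
#' Slices the mesh with a plane containing the junction axis and splits the
#' resulting membrane trace at the axis into the two facing profiles, the
#' computed analogue of manually traced side views.
#'
#' @param mesh a [surface_mesh].
#' @param base junction base point (nm).
#' @param axis junction axis (unit vector, envelope to ER).
#' @param angle rotation of the sagittal plane about the axis, radians.
#' @return list with `left` and `right`: matrices with columns `t` (axial
#'   coordinate along the axis, nm) and `w` (signed lateral offset, nm),
#'   each sorted by `t`.
#' @export
side_profile <- function(mesh, base, axis, angle = 0) {
  axis <- unitize(axis)
  b <- orthobasis(axis)
  lateral <- cos(angle) * b$u + sin(angle) * b$v  # in-plane lateral direction
  normal <- cross3(axis, lateral)
  ls <- slice_plane(mesh, base, normal)
  if (length(ls) == 0) stop("sagittal plane misses the mesh")
  pts <- do.call(rbind, lapply(ls, function(l) l$points3d))
  rel <- sweep(pts, 2, base)
  t_ <- as.vector(rel %*% axis)
  w <- as.vector(rel %*% lateral)
  left <- cbind(t = t_[w < 0], w = w[w < 0])
  right <- cbind(t = t_[w >= 0], w = w[w >= 0])
  left <- left[order(left[, 1]), , drop = FALSE]
  right <- right[order(right[, 1]), , drop = FALSE]
  list(left = left, right = right)
}

#' Two-point width measurement
#'
#' Euclidean length of a two-point line traced across a junction neck (or,
#' for non-constricted junctions, across the middle of the base).
#'
#' @param p1,p2 distinct points, length-3 nm coordinates.
#' @return distance in nm.
#' @export
two_point_width <- function(p1, p2) {
  d <- vnorm(as.numeric(p2) - as.numeric(p1))
  if (d == 0) stop("the two points coincide: no width defined")
  d
}

#' Minimum distance from a point to a triangulated surface
#'
#' Exact closest-point distance over all mesh triangles (faces, edges and
#' vertices), in nm. Zero iff the point lies on the mesh.
#'
#' @param point length-3 point in nm.
#' @param mesh a [surface_mesh].
#' @return distance in nm.
#' @export
distance_to_surface <- function(point, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  P <- as.numeric(point)
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  sqrt(min(point_triangle_dist2(P, A, B, C)))
}

# squared distances from point P to each triangle (A, B, C row-wise);
# vectorised closest-point-on-triangle (region decomposition)
point_triangle_dist2 <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, P, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, P, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2, P, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(A)
  u <- numeric(n); v <- numeric(n)  # barycentric along ab, ac
  done <- logical(n)
  # vertex A region
  m <- d1 <= 0 & d2 <= 0
  done <- done | m
  # vertex B region
  m <- !done & d3 >= 0 & d4 <= d3
  u[m] <- 1; done <- done | m
  # vertex C region
  m <- !done & d6 >= 0 & d5 <= d6
  v[m] <- 1; done <- done | m
  # edge AB
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  u[m] <- d1[m] / (d1[m] - d3[m]); done <- done | m
  # edge AC
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  v[m] <- d2[m] / (d2[m] - d6[m]); done <- done | m
  # edge BC
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  w_ <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  u[m] <- 1 - w_[m]; v[m] <- w_[m]; done <- done | m
  # interior
  m <- !done
  denom <- va + vb + vc
  u[m] <- vb[m] / denom[m]
  v[m] <- vc[m] / denom[m]
  Q <- A + u * ab + v * ac
  rowSums(sweep(Q, 2, P)^2)
}

#' Nuclear-envelope width below a junction, with flanking controls
#'
#' Measures the perinuclear-space width as the distance from the junction
#' base point (where the outer membrane would run if the junction were
#' absent) to the nearest point of the inner-membrane surface, plus two
#' control widths taken in opposite directions along the envelope at a
#' control distance (default midpoint of the 200-500 nm band).
#'
#' @param base_point junction base point on the outer-membrane plane (nm).
#' @param inm_surface [surface_mesh] of the inner nuclear membrane.
#' @param lateral unit vector along the envelope plane for control placement.
#' @param controls_at length-2 range (nm) from which the control distance is
#'   taken (its midpoint).
#' @return list with `width_below` (nm) and `control_widths` (two nm values).
#' @export
ne_width_below_junction <- function(base_point, inm_surface, lateral,
                                    controls_at = c(200, 500)) {
  if (missing(inm_surface) || is.null(inm_surface))
    stop("inner-membrane surface is required")
  lateral <- unitize(lateral)
  d0 <- distance_to_surface(base_point, inm_surface)
  dctrl <- mean(controls_at)
  ctrl <- c(
    distance_to_surface(base_point + dctrl * lateral, inm_surface),
    distance_to_surface(base_point - dctrl * lateral, inm_surface))
  list(width_below = d0, control_widths = ctrl)
}

#' Measure one junction end-to-end
#'
#' Runs the full per-junction pipeline: section series from the annotated
#' base along the (adaptive) centreline, neck detection within the search
#' window, width and aspect ratio from the minimum-area bounding rectangle,
#' length from the 1.2-fold area rule, and the sagittal side profile.
#' Optionally maps width and length to native scale with the shrinkage
#' correction.
#'
#' @param mesh a [surface_mesh] of a single junction.
#' @param base junction base point (nm).
#' @param axis unit axis hint (envelope to ER).
#' @param step station spacing in nm (default 0.5).
#' @param window neck search window in nm (default 25).
#' @param factor area factor for the length rule (default 1.2).
#' @param range maximum station sampled (default `window + 30` nm).
#' @param mode centreline mode, `"adaptive"` or `"fixed"`.
#' @param smooth_window odd loop-smoothing window in vertices (default 13,
#'   internally capped at 1/8 of the loop's vertex count); suppresses the
#'   extreme-value bias that vertex noise would otherwise add to the
#'   bounding rectangle.
#' @param shrinkage_fraction if non-`NULL`, also report shrinkage-corrected
#'   width and length.
#' @return an object of class `junction_morphometry`: fields `width_W`,
#'   `aspect_ratio_AR`, `length_L`, `L1`, `L2`, `neck_station`,
#'   `neck_area_Amin`, `side_profile`, `top_profile`, `flags`, `sections`,
#'   and (if requested) `width_native`, `length_native`.
#' @export
measure_junction <- function(mesh, base, axis, step = 0.5, window = 25,
                             factor = 1.2, range = window + 30,
                             mode = c("adaptive", "fixed"),
                             smooth_window = 13, shrinkage_fraction = NULL) {
  mode <- match.arg(mode)
  sec <- section_series(mesh, base, axis, step = step, range = range,
                        mode = mode, smooth_window = smooth_window)
  neck <- find_neck(sec, window = window)
  W <- junction_width(neck)
  AR <- junction_aspect_ratio(neck)
  len <- junction_length(sec, neck, factor = factor)
  flags <- len$flags
  if (neck$non_constricted) flags <- c(flags, "non_constricted")
  prof <- side_profile(mesh, base, axis)
  out <- list(width_W = W, aspect_ratio_AR = AR,
              length_L = len$L, L1 = len$L1, L2 = len$L2,
              neck_station = neck$station_s, neck_area_Amin = neck$area,
              side_profile = prof, top_profile = neck$loop,
              flags = flags, sections = sec, neck = neck)
  if (!is.null(shrinkage_fraction)) {
    out$width_native <- correct_shrinkage(W, shrinkage_fraction)
    out$length_native <- correct_shrinkage(len$L, shrinkage_fraction)
  }
  structure(out, class = "junction_morphometry")
}

#' @export
print.junction_morphometry <- function(x, ...) {
  cat("<junction_morphometry>\n")
  cat(sprintf("  width W        : %.2f nm\n", x$width_W))
  cat(sprintf("  aspect ratio   : %.2f\n", x$aspect_ratio_AR))
  cat(sprintf("  length L       : %s nm (L1 %s + L2 %s)\n",
              fmt_na(x$length_L), fmt_na(x$L1), fmt_na(x$L2)))
  cat(sprintf("  neck           : station %.2f nm, area %.1f nm^2\n",
              x$neck_station, x$neck_area_Amin))
  if (!is.null(x$width_native))
    cat(sprintf("  native scale   : W %.2f nm, L %s nm (shrinkage-corrected)\n",
                x$width_native, fmt_na(x$length_native)))
  if (length(x$flags)) cat("  flags          :", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)

#' @export
summary.junction_morphometry <- function(object, ...) {
  data.frame(width_nm = object$width_W, ar = object$aspect_ratio_AR,
             L_nm = object$length_L, L1_nm = object$L1, L2_nm = object$L2,
             Amin_nm2 = object$neck_area_Amin,
             neck_station_nm = object$neck_station,
             flags = paste(object$flags, collapse = ";"))
}

#' @export
plot.junction_morphometry <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$sections$table$station_s, x$sections$table$area,
                 type = "b", pch = 16, xlab = "station s (nm)",
                 ylab = "area (nm^2)", main = "area profile")
  graphics::abline(v = x$neck_station, lty = 2)
  pl <- x$side_profile
  rngw <- range(c(pl$left[, 2], pl$right[, 2]))
  graphics::plot(pl$right[, 2], pl$right[, 1], type = "p", pch = ".",
                 xlim = rngw, xlab = "lateral (nm)", ylab = "axial (nm)",
                 main = "side profile")
  graphics::points(pl$left[, 2], pl$left[, 1], pch = ".")
  invisible(x)
}

#' Measure every junction of a synthetic scene
#'
#' Convenience driver: applies [measure_junction] to each junction mesh of a
#' scene from [sample_population] and returns one row per junction.
#' Junctions flagged truncated are kept but flagged, and contact-site
#' annotations are excluded from morphometry (their membranes are not
#' continuous).
#'
#' @param scene a `junction_scene` from [sample_population].
#' @param ... passed to [measure_junction].
#' @return data.frame with columns `junction_id`, `lumen_class`,
#'   `width_nm`, `ar`, `L_nm`, `L1_nm`, `L2_nm`, `Amin_nm2`, `flags`.
#' @export
measure_population <- function(scene, ...) {
  stopifnot(inherits(scene, "junction_scene"))
  ann <- scene$annotations
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    if (ann$lumen_class[i] == "contact_site") return(NULL)
    j <- scene$junctions[[i]]
    m <- measure_junction(j$mesh, j$base_point, j$axis, ...)
    data.frame(junction_id = ann$junction_id[i],
               lumen_class = ann$lumen_class[i],
               width_nm = m$width_W, ar = m$aspect_ratio_AR,
               L_nm = m$length_L, L1_nm = m$L1, L2_nm = m$L2,
               Amin_nm2 = m$neck_area_Amin,
               flags = paste(m$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
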