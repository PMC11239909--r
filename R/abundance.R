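#' Nuclear-envelope area from traced contours (mesh method)
#'
#' Stitches the envelope traces into a triangulated surface and sums its
#' triangle areas. This is the mesh-based of the two cross-validating area
#' methods; the other multiplies trace length by depth.
#'
#' @param ne_contours a [contour_stack] of open envelope traces (>= 2
#'   contours).
#' @param interpolate_every optional interpolation spacing in nm passed to
#'   [contours_to_mesh].
#' @return an `ne_area_estimate`: list with `area_um2`, `method = "mesh"`.
#' @export
area_from_mesh <- function(ne_contours, interpolate_every = NULL) {
  stopifnot(inherits(ne_contours, "contour_stack"))
  k <- nrow(unique(ne_contours$contours[, c("object_id", "contour_id")]))
  if (k < 2) stop("need >= 2 contours to estimate an area")
  mesh <- contours_to_mesh(ne_contours, interpolate_every = interpolate_every)
  structure(list(area_um2 = surface_area(mesh) / 1e6, method = "mesh",
                 components = NULL),
            class = "ne_area_estimate")
}

#' Nuclear-envelope area as length x depth
#'
#' Sums `length_um * depth_um` over envelope regions, the overview-image
#' method: the in-plane trace length of each region multiplied by its
#' extent along the tomographic axis.
#'
#' @param components data.frame or matrix with columns `length_um`,
#'   `depth_um` (one row per region), or a list of length-2 vectors.
#' @return an `ne_area_estimate` with `method = "length_x_depth"` and the
#'   components retained.
#' @export
area_from_length_depth <- function(components) {
  if (is.list(components) && !is.data.frame(components))
    components <- do.call(rbind, lapply(components, function(p)
      data.frame(length_um = p[[1]], depth_um = p[[2]])))
  components <- as.data.frame(components)
  if (!all(c("length_um", "depth_um") %in% names(components)))
    names(components)[1:2] <- c("length_um", "depth_um")
  if (any(components$length_um <= 0) || any(components$depth_um <= 0))
    stop("all lengths and depths must be > 0")
  structure(list(area_um2 = sum(components$length_um * components$depth_um),
                 method = "length_x_depth", components = components),
            class = "ne_area_estimate")
}

#' @export
print.ne_area_estimate <- function(x, ...) {
  cat(sprintf("<ne_area_estimate> %.4g um^2 (%s)\n", x$area_um2, x$method))
  invisible(x)
}

#' Relative difference between two area estimates
#'
#' `|a - b| / mean(a, b)`; the two envelope-area methods agree to within a
#' few percent on near-flat envelope regions.
#'
#' @param a,b `ne_area_estimate` objects (or bare numbers, um^2).
#' @return the relative difference (dimensionless).
#' @export
compare_area_methods <- function(a, b) {
  av <- if (inherits(a, "ne_area_estimate")) a$area_um2 else as.numeric(a)
  bv <- if (inherits(b, "ne_area_estimate")) b$area_um2 else as.numeric(b)
  abs(av - bv) / mean(c(av, bv))
}

#' Junction frequency per unit envelope area
#'
#' Divides junction counts (total and per lumen class) by the screened
#' envelope area. Contact-site records are tallied but excluded from the
#' junction total (their membranes are not continuous); ambiguous junctions
#' count toward the total. Rounding happens only at report time: the
#' reported frequency is rounded half-to-even to two decimals, and a
#' truncated (floored) two-decimal value is also emitted so either
#' convention is auditable.
#'
#' @param annotations data.frame with a `lumen_class` column (one row per
#'   deduplicated junction), or an integer count.
#' @param area an `ne_area_estimate` or a number (um^2, > 0).
#' @return an object of class `frequency_estimate`: `counts` (per class),
#'   `n_junctions`, `area_um2`, `frequency_per_um2` (unrounded),
#'   `frequency_reported` (2 decimals, half-even),
#'   `frequency_truncated` (2 decimals, floored), `per_class_frequency`.
#' @export
junction_frequency <- function(annotations, area) {
  area_um2 <- if (inherits(area, "ne_area_estimate")) area$area_um2
              else as.numeric(area)
  if (!is.finite(area_um2) || area_um2 <= 0) stop("area must be > 0 um^2")
  if (is.numeric(annotations) && length(annotations) == 1) {
    counts <- c(all = as.integer(annotations))
    n <- as.integer(annotations)
  } else {
    cls <- as.character(annotations$lumen_class)
    counts <- table(factor(cls, levels = unique(c(
      "with_lumen", "no_lumen", "ambiguous", "contact_site", unique(cls)))))
    counts <- counts[counts > 0 | names(counts) %in%
                       c("with_lumen", "no_lumen", "ambiguous")]
    n <- sum(cls != "contact_site")
  }
  f <- n / area_um2
  per_class <- as.numeric(counts) / area_um2
  names(per_class) <- names(counts)
  structure(list(counts = counts, n_junctions = n, area_um2 = area_um2,
                 frequency_per_um2 = f,
                 frequency_reported = round(f, 2),
                 frequency_truncated = trunc(f * 100) / 100,
                 per_class_frequency = per_class),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("<frequency_estimate> %d junction(s) / %.4g um^2 = %.4f um^-2 (reported %.2f)\n",
              x$n_junctions, x$area_um2, x$frequency_per_um2,
              x$frequency_reported))
  invisible(x)
}

#' Extrapolate junction frequency to a whole nucleus
#'
#' Multiplies a screened frequency by the total envelope area of a nucleus
#' (typically ~400 um^2 in early telophase, ~800 um^2 in interphase) to
#' estimate the junction count per nucleus. The unrounded product is
#' returned together with a one-significant-figure report.
#'
#' @param freq a `frequency_estimate` or a bare frequency (um^-2).
#' @param total_ne_area_um2 total envelope area (> 0).
#' @return list with `estimated_total` (unrounded) and `reported` (one
#'   significant figure).
#' @export
estimate_total <- function(freq, total_ne_area_um2) {
  if (total_ne_area_um2 <= 0) stop("total_ne_area_um2 must be > 0")
  f <- if (inherits(freq, "frequency_estimate")) freq$frequency_per_um2
       else as.numeric(freq)
  est <- f * total_ne_area_um2
  list(estimated_total = est, reported = signif(est, 1))
}

#' Merge duplicate junction records across overlapping tomograms
#'
#' Adjacent tomograms overlap, so a junction near a volume border can be
#' annotated twice. Records closer than `min_separation` are merged by
#' single-linkage clustering and the first record of each cluster is kept.
#' Idempotent.
#'
#' @param annotations data.frame with `x_nm`, `y_nm`, `z_nm` columns.
#' @param min_separation merge radius in nm (default 50).
#' @return the deduplicated data.frame.
#' @export
deduplicate_junctions <- function(annotations, min_separation = 50) {
  n <- nrow(annotations)
  if (n <= 1) return(annotations)
  P <- as.matrix(annotations[, c("x_nm", "y_nm", "z_nm")])
  hc <- stats::hclust(stats::dist(P), method = "single")
  grp <- stats::cutree(hc, h = min_separation - .Machine$double.eps)
  annotations[!duplicated(grp), , drop = FALSE]
}

#' Compare two width samples with the Mann-Whitney test
#'
#' Thin wrapper around the two-sided Wilcoxon rank-sum test, as used to
#' compare constricted junction widths against the wider ER-ER population.
#'
#' @param group_a,group_b numeric width vectors (nm).
#' @return list with `U` (rank-sum statistic) and `p_value`. Warns when
#'   either group has fewer than 3 observations.
#' @export
compare_widths <- function(group_a, group_b) {
  if (min(length(group_a), length(group_b)) < 3)
    warning("fewer than 3 observations in a group: the rank-sum test has little power")
  wt <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
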