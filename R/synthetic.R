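#' Specification of a synthetic junction geometry
#'
#' Parameters of the forward model used to generate junction meshes with
#' known ground truth. The hourglass family is a hyperboloid of revolution,
#' radius profile `r(s) = r0 * sqrt(1 + s^2/c^2)` with `r0 =
#' neck_diameter/2` and `c = neck_scale`, optionally scaled to an elliptical
#' cross-section, blended into a flat envelope annulus at the base and an
#' open ER stub at the far end. The wide-cone family is a monotonically
#' widening funnel whose narrowest opening is the base itself (no interior
#' constriction).
#'
#' @param neck_diameter neck (or cone-base) diameter in nm, > 0. Junctions
#'   without a resolvable lumen sit near the lipid-bilayer thickness
#'   (~6.9 nm); junctions with a lumen around 17.4 nm.
#' @param neck_scale hyperboloid steepness `c` in nm, > 0.
#' @param ellipticity ratio >= 1 of the neck's major to minor axis.
#' @param flare_length axial extent of the hyperboloid on each side of the
#'   neck, nm; also sets the neck's station above the base.
#' @param shape_class `"hourglass"` or `"wide_cone"`.
#' @param lumen_class `"with_lumen"`, `"no_lumen"`, `"ambiguous"` or
#'   `"contact_site"` (annotation label carried downstream).
#' @param jitter_sd isotropic Gaussian vertex noise, nm, >= 0 (emulates
#'   tracing noise).
#' @param mesh_step tessellation pitch in nm; must resolve the neck
#'   (`mesh_step < neck_diameter`).
#' @param cone_half_angle_deg opening half-angle of the wide-cone family.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (spec, seed).
#' @return an object of class `junction_spec`.
#' @export
junction_spec <- function(neck_diameter = 17.4, neck_scale = 10,
                          ellipticity = 1, flare_length = 10,
                          shape_class = c("hourglass", "wide_cone"),
                          lumen_class = c("with_lumen", "no_lumen",
                                          "ambiguous", "contact_site"),
                          jitter_sd = 0, mesh_step = 1,
                          cone_half_angle_deg = 45, seed = 1L) {
  shape_class <- match.arg(shape_class)
  lumen_class <- match.arg(lumen_class)
  if (neck_diameter <= 0) stop("neck_diameter must be > 0")
  if (neck_scale <= 0) stop("neck_scale must be > 0")
  if (ellipticity < 1) stop("ellipticity must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (flare_length <= 0) stop("flare_length must be > 0")
  if (mesh_step <= 0) stop("mesh_step must be > 0")
  structure(list(neck_diameter = neck_diameter, neck_scale = neck_scale,
                 ellipticity = ellipticity, flare_length = flare_length,
                 shape_class = shape_class, lumen_class = lumen_class,
                 jitter_sd = jitter_sd, mesh_step = mesh_step,
                 cone_half_angle_deg = cone_half_angle_deg,
                 seed = as.integer(seed)),
            class = "junction_spec")
}

# surface of revolution from ring radii r(z) at heights z, x scaled by
# `ellipticity`, plus a flat annulus extending outward at the first ring
revolve_rings <- function(z, r, ellipticity, mesh_step, annulus_width) {
  rmax <- max(r) * ellipticity
  ntheta <- max(16L, ceiling(2 * pi * rmax / mesh_step))
  theta <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  ct <- cos(theta); st <- sin(theta)
  # annulus rings (outermost first) in the plane z = z[1]
  na <- max(1L, ceiling(annulus_width / mesh_step))
  ann_scale <- 1 + (na:1) * annulus_width / (na * r[1])
  rings <- vector("list", na + length(z))
  for (k in seq_len(na)) {
    rr <- r[1] * ann_scale[k]
    rings[[k]] <- cbind(ellipticity * rr * ct, rr * st, z[1])
  }
  for (i in seq_along(z)) {
    rings[[na + i]] <- cbind(ellipticity * r[i] * ct, r[i] * st, z[i])
  }
  nr <- length(rings)
  V <- do.call(rbind, rings)
  # quad strips between consecutive rings
  f <- vector("list", nr - 1)
  idx <- seq_len(ntheta)
  nxt <- c(idx[-1], 1L)
  for (k in seq_len(nr - 1)) {
    o1 <- (k - 1L) * ntheta
    o2 <- k * ntheta
    f[[k]] <- rbind(cbind(o1 + idx, o1 + nxt, o2 + idx),
                    cbind(o1 + nxt, o2 + nxt, o2 + idx))
  }
  list(V = V, F = do.call(rbind, f))
}

apply_jitter <- function(V, jitter_sd, seed) {
  if (jitter_sd > 0) {
    with_seed(seed, V + matrix(stats::rnorm(length(V), 0, jitter_sd),
                               ncol = 3))
  } else V
}

#' Generate an hourglass junction mesh with closed-form ground truth
#'
#' Builds the hyperboloid hourglass surface described in [junction_spec]
#' and returns it with its analytic ground truth: the true width is the
#' mean of the neck ellipse's bounding-rectangle sides,
#' `neck_diameter * (1 + ellipticity) / 2`; the true length under the
#' 1.2-fold-area rule is `2 * neck_scale * sqrt(0.2)` (the station where
#' `pi * r(s)^2` first reaches 1.2x the neck area); the true neck station is
#' `flare_length` above the base.
#'
#' @param spec a [junction_spec] with `shape_class = "hourglass"`.
#' @return an object of class `synthetic_junction`: `mesh`
#'   ([surface_mesh]), `truth` (list `true_width`, `true_aspect_ratio`,
#'   `true_length`, `true_neck_station`, `spec`), `base_point`, `axis`.
#' @examples
#' j <- make_hourglass(junction_spec(neck_diameter = 20, neck_scale = 10))
#' j$truth$true_length   # 2 * 10 * sqrt(0.2)
#' @export
make_hourglass <- function(spec) {
  stopifnot(inherits(spec, "junction_spec"))
  if (spec$shape_class != "hourglass") stop("spec$shape_class must be 'hourglass'")
  if (spec$mesh_step >= spec$neck_diameter)
    stop("mesh_step >= neck_diameter: neck unresolvable at this tessellation")
  r0 <- spec$neck_diameter / 2
  cc <- spec$neck_scale
  fl <- spec$flare_length
  z <- seq(-fl, fl, by = spec$mesh_step)
  if (z[length(z)] < fl) z <- c(z, fl)
  r <- r0 * sqrt(1 + z^2 / cc^2)
  rv <- revolve_rings(z, r, spec$ellipticity, spec$mesh_step,
                      annulus_width = fl)
  V <- apply_jitter(rv$V, spec$jitter_sd, spec$seed)
  mesh <- surface_mesh(V, rv$F, validate = FALSE)
  truth <- list(
    true_width = spec$neck_diameter * (1 + spec$ellipticity) / 2,
    true_aspect_ratio = spec$ellipticity,
    true_length = 2 * spec$neck_scale * sqrt(0.2),
    true_neck_station = fl,
    spec = spec)
  structure(list(mesh = mesh, truth = truth,
                 base_point = c(0, 0, -fl), axis = c(0, 0, 1)),
            class = "synthetic_junction")
}

#' Generate a wide-cone junction mesh (no interior constriction)
#'
#' The geometry of a wide, cone-shaped junction base: the radius widens
#' monotonically from the base opening, so the minimum cross-section area is
#' at the base itself and the constriction detector reports
#' `non_constricted`. The true width is the base opening diameter.
#'
#' @param spec a [junction_spec] with `shape_class = "wide_cone"`;
#'   `neck_diameter` is the base opening.
#' @return a `synthetic_junction` (see [make_hourglass]); the ground truth
#'   has `true_length = NA` (no constricted region exists).
#' @export
make_wide_cone <- function(spec) {
  stopifnot(inherits(spec, "junction_spec"))
  if (spec$shape_class != "wide_cone") stop("spec$shape_class must be 'wide_cone'")
  if (spec$mesh_step >= spec$neck_diameter)
    stop("mesh_step >= neck_diameter: base unresolvable at this tessellation")
  r0 <- spec$neck_diameter / 2
  slope <- tan(spec$cone_half_angle_deg * pi / 180)
  z <- seq(0, spec$flare_length, by = spec$mesh_step)
  if (z[length(z)] < spec$flare_length) z <- c(z, spec$flare_length)
  r <- r0 + slope * z
  rv <- revolve_rings(z, r, spec$ellipticity, spec$mesh_step,
                      annulus_width = spec$flare_length)
  V <- apply_jitter(rv$V, spec$jitter_sd, spec$seed)
  mesh <- surface_mesh(V, rv$F, validate = FALSE)
  truth <- list(
    true_width = spec$neck_diameter * (1 + spec$ellipticity) / 2,
    true_aspect_ratio = spec$ellipticity,
    true_length = NA_real_,
    true_neck_station = 0,
    spec = spec)
  structure(list(mesh = mesh, truth = truth,
                 base_point = c(0, 0, 0), axis = c(0, 0, 1)),
            class = "synthetic_junction")
}

#' @export
print.synthetic_junction <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf("<synthetic_junction> %s, neck %.3g nm, %d vertices\n",
              s$shape_class, s$neck_diameter, nrow(x$mesh$vertices)))
  invisible(x)
}

#' Generate a traced nuclear-envelope sheet as a contour stack
#'
#' Emulates manual envelope tracing: open polylines of fixed arc length
#' (one per tomographic slice) spanning `depth_um` along z at the tracing
#' interval. With `curvature = 0` the sheet is flat and its area is
#' analytically `length_um * depth_um`; with positive curvature the trace
#' is a circular arc of the same arc length, so the area is still
#' arc length x depth.
#'
#' @param length_um in-plane trace arc length, micrometres (> 0).
#' @param depth_um extent along the tomographic axis, micrometres (> 0).
#' @param curvature in-plane curvature of the trace in 1/um (>= 0).
#' @param z_spacing_nm tracing interval along z in nm (default 4, within
#'   the 2.25-4.51 nm range used for fine tracing).
#' @param point_spacing_nm sample spacing along each trace in nm.
#' @return a [contour_stack] of open contours; attribute `true_area_um2`
#'   carries the analytic area.
#' @export
make_ne_sheet <- function(length_um, depth_um, curvature = 0,
                          z_spacing_nm = 4, point_spacing_nm = 20) {
  if (length_um <= 0 || depth_um <= 0)
    stop("length_um and depth_um must be > 0")
  if (curvature < 0) stop("curvature must be >= 0")
  len_nm <- length_um * 1e3
  npt <- max(2L, ceiling(len_nm / point_spacing_nm) + 1L)
  s <- seq(0, len_nm, length.out = npt)
  if (curvature == 0) {
    x <- s; y <- rep(0, npt)
  } else {
    R <- 1e3 / curvature  # radius in nm
    phi <- s / R
    x <- R * sin(phi); y <- R * (1 - cos(phi))
  }
  nz <- max(2L, floor(depth_um * 1e3 / z_spacing_nm) + 1L)
  zs <- seq_len(nz) - 1L
  df <- data.frame(
    object_id = "ne_sheet",
    contour_id = rep(zs, each = npt),
    z_index = rep(zs, each = npt),
    x_nm = rep(x, nz), y_nm = rep(y, nz))
  # last slice lands exactly at depth_um
  zsp <- depth_um * 1e3 / (nz - 1L)
  st <- contour_stack(df, z_spacing = zsp, closed = FALSE)
  attr(st, "true_area_um2") <- length_um * depth_um
  st
}

#' Generate a binary ellipsoidal nuclear mask
#'
#' Solid ellipsoid voxel mask for stereology, with the analytic surface
#' area and volume attached for validation.
#'
#' @param semi_axes_um length-3 semi-axes in micrometres (a sphere if all
#'   equal); each must exceed the voxel size.
#' @param voxel_nm voxel edge length(s) in nm; scalar or length 3
#'   (anisotropy allowed).
#' @param margin_voxels empty border around the ellipsoid.
#' @return a `voxel_mask`: list with `mask` (logical 3D array),
#'   `voxel_size` (nm, length 3), and attributes `analytic_volume_um3`,
#'   `analytic_area_um2` (Thomsen approximation for ellipsoids, exact for
#'   spheres).
#' @export
make_nuclear_mask <- function(semi_axes_um, voxel_nm, margin_voxels = 2L) {
  semi <- rep(as.numeric(semi_axes_um), length.out = 3)
  vox <- rep(as.numeric(voxel_nm), length.out = 3)
  if (any(vox <= 0)) stop("voxel size must be > 0")
  if (any(semi * 1e3 <= vox))
    stop("each semi-axis must exceed the voxel size")
  a <- semi * 1e3  # nm
  dims <- ceiling(2 * a / vox) + 2L * margin_voxels
  ctr <- dims / 2
  g <- function(k) ((seq_len(dims[k]) - 0.5 - ctr[k]) * vox[k] / a[k])^2
  x2 <- g(1); y2 <- g(2); z2 <- g(3)
  m <- outer(outer(x2, y2, "+"), z2, "+") <= 1
  p <- 1.6075
  area_um2 <- 4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
                          semi[2]^p * semi[3]^p) / 3)^(1 / p)
  out <- structure(list(mask = m, voxel_size = vox), class = "voxel_mask")
  attr(out, "analytic_volume_um3") <- 4 / 3 * pi * prod(semi)
  attr(out, "analytic_area_um2") <- area_um2
  out
}

#' Population of junctions placed on an envelope sheet
#'
#' Draws `n_junctions` neck diameters from a normal distribution truncated
#' at 2 nm, generates one hourglass junction per draw, places the bases
#' uniformly at random on a square envelope sheet of the given area, and
#' returns the scene together with its annotations and the traced sheet.
#' Deterministic for a fixed seed.
#'
#' @param n_junctions number of junctions (>= 0).
#' @param width_mean,width_sd generating neck-diameter distribution in nm
#'   (defaults: the lumen-class values 17.4 +/- 5.0).
#' @param class_mix named proportions over lumen classes (must sum to 1).
#' @param scene_area_um2 envelope sheet area in um^2.
#' @param seed integer seed.
#' @param jitter_sd,mesh_step per-junction generator settings (see
#'   [junction_spec]).
#' @param make_meshes generate the meshes (set `FALSE` for abundance-only
#'   work where annotations suffice).
#' @return an object of class `junction_scene`: `junctions` (list of
#'   `synthetic_junction` or `NULL`s), `annotations` (data.frame:
#'   `junction_id`, `x_nm`, `y_nm`, `z_nm`, `lumen_class`, `truncated`,
#'   `cell_stage`, `true_width_nm`), `ne_contours` ([contour_stack]),
#'   `scene_area_um2`.
#' @export
sample_population <- function(n_junctions, width_mean = 17.4, width_sd = 5.0,
                              class_mix = c(with_lumen = 1),
                              scene_area_um2 = 178, seed = 1L,
                              jitter_sd = 0.5, mesh_step = 1,
                              make_meshes = TRUE) {
  if (n_junctions < 0) stop("n_junctions must be >= 0")
  if (width_sd < 0) stop("width_sd must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix proportions must sum to 1")
  side_um <- sqrt(scene_area_um2)
  sheet <- make_ne_sheet(side_um, side_um)
  out <- with_seed(seed, {
    d <- numeric(n_junctions)
    if (n_junctions > 0) {
      d <- stats::rnorm(n_junctions, width_mean, width_sd)
      while (any(d < 2)) {
        k <- d < 2
        d[k] <- stats::rnorm(sum(k), width_mean, width_sd)
      }
    }
    classes <- if (n_junctions > 0)
      sample(names(class_mix), n_junctions, replace = TRUE, prob = class_mix)
    else character(0)
    pos <- matrix(stats::runif(2 * n_junctions, 0, side_um * 1e3), ncol = 2)
    seeds <- if (n_junctions > 0) sample.int(.Machine$integer.max,
                                             n_junctions) else integer(0)
    list(d = d, classes = classes, pos = pos, seeds = seeds)
  })
  ann <- data.frame(
    junction_id = if (n_junctions > 0) sprintf("j%03d", seq_len(n_junctions)) else character(0),
    x_nm = if (n_junctions > 0) out$pos[, 1] else numeric(0),
    y_nm = if (n_junctions > 0) out$pos[, 2] else numeric(0),
    z_nm = numeric(n_junctions),
    lumen_class = out$classes,
    truncated = logical(n_junctions),
    cell_stage = rep("interphase", n_junctions),
    true_width_nm = out$d)
  junctions <- vector("list", n_junctions)
  if (make_meshes && n_junctions > 0) {
    for (i in seq_len(n_junctions)) {
      sp <- junction_spec(neck_diameter = out$d[i], jitter_sd = jitter_sd,
                          mesh_step = mesh_step,
                          lumen_class = out$classes[i],
                          seed = out$seeds[i])
      j <- make_hourglass(sp)
      shift <- c(out$pos[i, 1], out$pos[i, 2], 0) - j$base_point
      j$mesh <- transform_mesh(j$mesh, translation = shift)
      j$base_point <- j$base_point + shift
      junctions[[i]] <- j
    }
  }
  structure(list(junctions = junctions, annotations = ann,
                 ne_contours = sheet, scene_area_um2 = scene_area_um2,
                 seed = seed),
            class = "junction_scene")
}

#' @export
print.junction_scene <- function(x, ...) {
  cat(sprintf("<junction_scene> %d junction(s) on %.3g um^2 of envelope (seed %d)\n",
              nrow(x$annotations), x$scene_area_um2, x$seed))
  invisible(x)
}

#' Write / read junction annotations (JSON)
#'
#' @param annotations data.frame as in `junction_scene$annotations`.
#' @param path JSON file path.
#' @return `read_annotations` returns the data.frame; `write_annotations`
#'   returns `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write / read voxel masks (multi-page TIFF)
#'
#' The mask is stored one z-slice per page, 8-bit, foreground = 1. TIFF
#' carries no voxel-size metadata, so `read_mask` takes the voxel size as an
#' argument.
#'
#' @param mask a `voxel_mask`.
#' @param path TIFF file path.
#' @return `read_mask` returns a `voxel_mask`; `write_mask` returns `path`
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  pages <- lapply(seq_len(dim(mask$mask)[3]),
                  function(k) (mask$mask[, , k]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @param voxel_nm voxel size in nm (scalar or length 3).
#' @export
read_mask <- function(path, voxel_nm) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(FALSE, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg > 0.5
  }
  structure(list(mask = arr, voxel_size = rep(as.numeric(voxel_nm),
                                              length.out = 3)),
            class = "voxel_mask")
}
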