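#' Surface voxels of a binary mask
#'
#' A foreground voxel belongs to the surface when at least one of its six
#' face neighbours is background (voxels outside the array count as
#' background). Returns voxel centres in nm, so anisotropic voxels are
#' handled in world units.
#'
#' @param mask a `voxel_mask` (see [make_nuclear_mask], [read_mask]).
#' @return matrix of surface-voxel centres, n x 3, nm; attribute
#'   `voxel_index` holds the (i, j, k) indices.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  m <- mask$mask
  if (!any(m)) stop("mask has no foreground")
  if (all(m)) stop("mask has no background: surface undefined")
  d <- dim(m)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) {
      idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax]
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  has_bg_neighbor <- array(FALSE, dim = d)
  for (ax in 1:3) for (by in c(1, -1)) {
    nb <- shift(m, ax, by)  # neighbour foreground state; borders stay FALSE
    has_bg_neighbor <- has_bg_neighbor | !nb
  }
  surf <- m & has_bg_neighbor
  idx <- which(surf, arr.ind = TRUE)
  centers <- sweep(idx - 0.5, 2, mask$voxel_size, "*")
  colnames(centers) <- c("x", "y", "z")
  attr(centers, "voxel_index") <- idx
  centers
}

#' Evenly spread sample points on a surface
#'
#' Operationalises "one random starting point, the rest spread uniformly":
#' the first point is drawn uniformly from the surface under the seed, and
#' each further point is the surface point farthest (in minimum distance)
#' from all points chosen so far (farthest-point sampling). Deterministic
#' given the seed; returns exactly `n` distinct points.
#'
#' @param surface n x 3 matrix of surface points in nm (from
#'   [extract_surface]).
#' @param n number of points (<= number of surface points).
#' @param seed integer seed for the starting point.
#' @return n x 3 matrix of sampled points; attribute `index` gives their
#'   rows in `surface`.
#' @export
sample_surface_points <- function(surface, n, seed = 1L) {
  surface <- as.matrix(surface)
  ns <- nrow(surface)
  if (n > ns) stop(sprintf("requested %d points but surface has only %d", n, ns))
  if (n < 1) stop("n must be >= 1")
  first <- with_seed(seed, sample.int(ns, 1))
  chosen <- integer(n)
  chosen[1] <- first
  if (n > 1) {
    dmin <- sqrt(colSums((t(surface) - surface[first, ])^2))
    for (k in 2:n) {
      nxt <- which.max(dmin)  # ties: first index, deterministic
      chosen[k] <- nxt
      dnew <- sqrt(colSums((t(surface) - surface[nxt, ])^2))
      dmin <- pmin(dmin, dnew)
    }
  }
  out <- surface[chosen, , drop = FALSE]
  attr(out, "index") <- chosen
  out
}

#' Spherical inspection region of a voxel mask
#'
#' Crops the bounding box of a sphere around a world-coordinate centre and
#' applies the spherical membership (voxel centre within `radius` nm of the
#' ROI centre). A radius smaller than the voxel pitch still yields the
#' single voxel containing the centre. Regions extending past the array
#' border are clipped and flagged.
#'
#' @param mask a `voxel_mask`.
#' @param center length-3 ROI centre in nm.
#' @param radius ROI radius in nm (screening regions are typically
#'   800-1000 nm).
#' @return list of class `roi_sphere`: `subvolume` (logical array:
#'   mask foreground AND inside sphere), `inside` (logical array: sphere
#'   membership alone), `bbox` (2 x 3 voxel index range), `center`,
#'   `radius`, `clipped` (logical), `voxel_count` (voxels inside the
#'   sphere).
#' @export
roi_sphere <- function(mask, center, radius) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (radius <= 0) stop("radius must be > 0")
  d <- dim(mask$mask)
  vox <- mask$voxel_size
  lo <- floor((center - radius) / vox + 0.5) + 1L
  hi <- ceiling((center + radius) / vox + 0.5)
  clipped <- any(lo < 1L) || any(hi > d)
  lo <- pmax(lo, 1L); hi <- pmin(hi, d)
  if (any(lo > hi)) stop("ROI lies entirely outside the mask")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  cx <- (ii - 0.5) * vox[1] - center[1]
  cy <- (jj - 0.5) * vox[2] - center[2]
  cz <- (kk - 0.5) * vox[3] - center[3]
  inside <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= radius^2
  if (!any(inside)) {
    # sub-voxel ROI: keep the voxel that contains the centre
    home <- pmin(pmax(floor(center / vox) + 1L, lo), hi) - lo + 1L
    inside[home[1], home[2], home[3]] <- TRUE
  }
  sub <- mask$mask[ii, jj, kk, drop = FALSE] & inside
  structure(list(subvolume = sub, inside = inside,
                 bbox = rbind(lo = lo, hi = hi), center = center,
                 radius = radius, clipped = clipped,
                 voxel_count = sum(inside)),
            class = "roi_sphere")
}

#' Tabulate junction findings over inspection regions
#'
#' Bookkeeping for manual or automated screening: per-ROI counts of each
#' junction kind and per-kind width summaries. Duplicate findings (same
#' ROI, kind and width) are kept but flagged.
#'
#' @param rois data.frame with at least an `id` column (one row per ROI).
#' @param findings data.frame with columns `roi_id`, `junction_kind`,
#'   `width_nm` (zero rows allowed).
#' @return list of class `screen_report`: `per_roi` (ROI x kind counts,
#'   zero-filled), `per_kind` (n, mean, sd of width per kind), `findings`
#'   (input with a `duplicate` flag column).
#' @export
screen_report <- function(rois, findings) {
  rois <- as.data.frame(rois)
  findings <- as.data.frame(findings)
  if (nrow(findings) == 0) {
    per_roi <- data.frame(roi_id = rois$id, total = 0L)
    per_kind <- data.frame(junction_kind = character(0), n = integer(0),
                           mean_width_nm = numeric(0), sd_width_nm = numeric(0))
    return(structure(list(per_roi = per_roi, per_kind = per_kind,
                          findings = cbind(findings, duplicate = logical(0))),
                     class = "screen_report"))
  }
  findings$duplicate <- duplicated(findings[, c("roi_id", "junction_kind",
                                                "width_nm")])
  kinds <- sort(unique(findings$junction_kind))
  tab <- table(factor(findings$roi_id, levels = rois$id),
               factor(findings$junction_kind, levels = kinds))
  per_roi <- data.frame(roi_id = rois$id, as.data.frame.matrix(tab),
                        check.names = FALSE)
  per_roi$total <- rowSums(tab)
  per_kind <- do.call(rbind, lapply(kinds, function(k) {
    w <- findings$width_nm[findings$junction_kind == k]
    data.frame(junction_kind = k, n = length(w),
               mean_width_nm = mean(w),
               sd_width_nm = if (length(w) > 1) stats::sd(w) else NA_real_)
  }))
  structure(list(per_roi = per_roi, per_kind = per_kind, findings = findings),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d ROI(s), %d finding(s)\n",
              nrow(x$per_roi), nrow(x$findings)))
  if (nrow(x$per_kind)) print(x$per_kind)
  invisible(x)
}
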