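#' Contour stack: z-indexed planar membrane traces
#'
#' The exchange format for manual membrane segmentations: per tomographic
#' slice, ordered polylines sampled along the middle of the lipid bilayer.
#' Closed objects need at least 3 points per contour; open envelope traces
#' need at least 2.
#'
#' @param contours data.frame with columns `object_id`, `contour_id`,
#'   `z_index`, `x_nm`, `y_nm`, rows ordered along each contour.
#' @param z_spacing slice spacing in nm (> 0). Typical tracing intervals are
#'   2.25-4.51 nm for fine junction work and ~9 nm for coarser surveys.
#' @param pixel_size in-plane pixel size in nm (metadata only; coordinates
#'   are already nm).
#' @param closed logical: are contours closed loops (default) or open
#'   traces?
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(contours, z_spacing, pixel_size = NA_real_,
                          closed = TRUE) {
  need <- c("object_id", "contour_id", "z_index", "x_nm", "y_nm")
  if (!all(need %in% names(contours)))
    stop("contours must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(z_spacing) || length(z_spacing) != 1 || z_spacing <= 0)
    stop("z_spacing must be a single positive number (nm)")
  stopifnot_finite(contours$x_nm, "contour x")
  stopifnot_finite(contours$y_nm, "contour y")
  minpts <- if (closed) 3L else 2L
  n_by <- table(interaction(contours$object_id, contours$contour_id, drop = TRUE))
  if (any(n_by < minpts))
    stop(sprintf("every contour needs >= %d points; found one with %d",
                 minpts, min(n_by)))
  contours <- contours[, need]
  structure(list(contours = as.data.frame(contours), z_spacing = z_spacing,
                 pixel_size = pixel_size, closed = closed),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  k <- nrow(unique(x$contours[, c("object_id", "contour_id")]))
  cat(sprintf("<contour_stack> %d contour(s), %d points, z_spacing %.3g nm, %s\n",
              k, nrow(x$contours), x$z_spacing,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# split into per-contour coordinate matrices ordered by z
split_contours <- function(stack, object_id = NULL) {
  df <- stack$contours
  if (!is.null(object_id)) df <- df[df$object_id == object_id, , drop = FALSE]
  key <- interaction(df$object_id, df$contour_id, drop = TRUE)
  parts <- split(df, key)
  ord <- order(vapply(parts, function(p) p$z_index[1], numeric(1)))
  parts[ord]
}

#' Read and write contour stacks (CSV or JSON)
#'
#' CSV schema: header `object_id,contour_id,z_index,x_nm,y_nm`, one point
#' per row, ordered along each contour; a leading `# units: nm` comment and
#' `# z_spacing_nm: <v>` / `# pixel_size_nm: <v>` / `# closed: <0|1>`
#' metadata comments. The JSON schema carries the same fields under
#' `{z_spacing_nm, pixel_size_nm, closed, contours: [{object_id, contour_id,
#' z_index, x_nm: [...], y_nm: [...]}]}`.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `read_contours` returns a [contour_stack]; `write_contours`
#'   returns `path` invisibly.
#' @export
read_contours <- function(path, format = tolower(tools::file_ext(path))) {
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    meta <- lines[startsWith(lines, "#")]
    get_meta <- function(key, default) {
      m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
      if (length(m) == 0) return(default)
      trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
    }
    num_meta <- function(key) {
      v <- get_meta(key, NA)
      if (is.na(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
    }
    zs <- num_meta("z_spacing_nm")
    ps <- num_meta("pixel_size_nm")
    cl <- get_meta("closed", "1") %in% c("1", "true", "TRUE")
    units <- get_meta("units", "nm")
    if (!identical(units, "nm")) stop("mixed or unknown units: ", units)
    body <- lines[!startsWith(lines, "#")]
    df <- utils::read.csv(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
    bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm))
    if (length(bad))
      stop(sprintf("malformed contour row at data line %d of %s", bad[1], path))
    if (is.na(zs)) stop("missing '# z_spacing_nm:' metadata in ", path)
    contour_stack(df, z_spacing = zs, pixel_size = ps, closed = cl)
  } else if (format == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    rows <- do.call(rbind, lapply(seq_len(nrow(j$contours)), function(i) {
      ci <- j$contours[i, ]
      data.frame(object_id = ci$object_id, contour_id = ci$contour_id,
                 z_index = ci$z_index, x_nm = unlist(ci$x_nm),
                 y_nm = unlist(ci$y_nm))
    }))
    contour_stack(rows, z_spacing = j$z_spacing_nm,
                  pixel_size = if (is.null(j$pixel_size_nm)) NA_real_ else j$pixel_size_nm,
                  closed = isTRUE(j$closed))
  } else stop("unknown contour format: ", format)
}

#' @rdname read_contours
#' @param stack a [contour_stack] to write.
#' @export
write_contours <- function(stack, path, format = tolower(tools::file_ext(path))) {
  stopifnot(inherits(stack, "contour_stack"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# units: nm",
                 sprintf("# z_spacing_nm: %.15g", stack$z_spacing),
                 sprintf("# pixel_size_nm: %.15g", stack$pixel_size),
                 sprintf("# closed: %d", as.integer(stack$closed))), con)
    utils::write.csv(stack$contours, con, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    parts <- split(stack$contours,
                   interaction(stack$contours$object_id,
                               stack$contours$contour_id, drop = TRUE))
    contours <- lapply(parts, function(p) list(
      object_id = p$object_id[1], contour_id = p$contour_id[1],
      z_index = p$z_index[1], x_nm = p$x_nm, y_nm = p$y_nm))
    jsonlite::write_json(
      list(units = "nm", z_spacing_nm = stack$z_spacing,
           pixel_size_nm = stack$pixel_size, closed = stack$closed,
           contours = unname(contours)),
      path, auto_unbox = TRUE, digits = NA)
  } else stop("unknown contour format: ", format)
  invisible(path)
}

# resample a polyline (n x 2) to k points uniformly by arc length
resample_polyline <- function(P, k, closed = FALSE) {
  if (closed) P <- rbind(P, P[1, ])
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- if (closed) seq(0, total, length.out = k + 1)[seq_len(k)]
             else seq(0, total, length.out = k)
  x <- stats::approx(s, P[, 1], xout = targets, rule = 2)$y
  y <- stats::approx(s, P[, 2], xout = targets, rule = 2)$y
  cbind(x, y)
}

# signed area of planar polygon (closed, not repeated point)
signed_area2d <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# Greedy zipper between two contours at z1 < z2. A, B are n x 3 matrices
# (already in 3D). Returns face list indexed into rbind(A, B). For closed
# contours, callers must pre-align start points and orientation; the zipper
# wraps around. Advancing on the side with the shorter new diagonal keeps
# the added band area near-minimal and is self-correcting: a pure local
# minimal-triangle-area rule lets the more finely sampled contour run ahead
# and produces a spiralling band.
zipper_band <- function(A, B, closed) {
  na <- nrow(A); nb <- nrow(B)
  offs <- na
  i <- 1L; j <- 1L
  steps_a <- if (closed) na else na - 1L
  steps_b <- if (closed) nb else nb - 1L
  faces <- matrix(0L, nrow = steps_a + steps_b, ncol = 3)
  nf <- 0L
  ia <- 0L; ib <- 0L  # advances taken on each side
  nexta <- function(i) if (i == na) 1L else i + 1L
  nextb <- function(j) if (j == nb) 1L else j + 1L
  while (ia < steps_a || ib < steps_b) {
    can_a <- ia < steps_a
    can_b <- ib < steps_b
    if (can_a) aa <- sum((A[nexta(i), ] - B[j, ])^2)
    if (can_b) ab <- sum((A[i, ] - B[nextb(j), ])^2)
    take_a <- can_a && (!can_b || aa <= ab)
    nf <- nf + 1L
    if (take_a) {
      faces[nf, ] <- c(i, nexta(i), offs + j)
      i <- nexta(i); ia <- ia + 1L
    } else {
      faces[nf, ] <- c(i, offs + nextb(j), offs + j)
      j <- nextb(j); ib <- ib + 1L
    }
  }
  faces[seq_len(nf), , drop = FALSE]
}

# canonical orientation + start alignment for a closed contour pair
align_closed <- function(A, B) {
  if (signed_area2d(A[, 1:2, drop = FALSE]) < 0) A <- A[nrow(A):1, , drop = FALSE]
  if (signed_area2d(B[, 1:2, drop = FALSE]) < 0) B <- B[nrow(B):1, , drop = FALSE]
  d <- colSums((t(B[, 1:2, drop = FALSE]) - A[1, 1:2])^2)
  j0 <- which.min(d)
  if (j0 > 1) B <- B[c(j0:nrow(B), 1:(j0 - 1)), , drop = FALSE]
  list(A = A, B = B)
}

align_open <- function(A, B) {
  # reverse B if it runs the other way
  same <- vnorm(A[1, ] - B[1, ]) + vnorm(A[nrow(A), ] - B[nrow(B), ])
  flip <- vnorm(A[1, ] - B[nrow(B), ]) + vnorm(A[nrow(A), ] - B[1, ])
  if (flip < same) B <- B[nrow(B):1, , drop = FALSE]
  list(A = A, B = B)
}

#' Stitch a contour stack into a triangulated surface
#'
#' Connects each pair of consecutive contours of an object with a greedy
#' zipper that advances on whichever side keeps the new diagonal shorter,
#' keeping the added band area near-minimal and emulating the
#' minimal-total-area banding used by tomography segmentation tools.
#' Optionally inserts linearly interpolated intermediate
#' contours along z so that no band is taller than `interpolate_every` nm.
#'
#' @param stack a [contour_stack] (open or closed contours).
#' @param interpolate_every optional maximum band height in nm; `NULL`
#'   disables interpolation.
#' @param object_id restrict to a single object (default: all objects).
#' @return a [surface_mesh]. Consecutive contours must overlap in
#'   projection; non-overlapping pairs raise an error.
#' @export
contours_to_mesh <- function(stack, interpolate_every = NULL, object_id = NULL) {
  stopifnot(inherits(stack, "contour_stack"))
  objects <- if (is.null(object_id)) unique(stack$contours$object_id) else object_id
  allV <- list(); allF <- list(); voffs <- 0L
  for (ob in objects) {
    parts <- split_contours(stack, ob)
    if (length(parts) < 2)
      stop(sprintf("object '%s' needs >= 2 contours to form a surface", ob))
    polys <- lapply(parts, function(p)
      cbind(p$x_nm, p$y_nm, p$z_index * stack$z_spacing))
    for (k in seq_len(length(polys) - 1)) {
      A <- polys[[k]]; B <- polys[[k + 1]]
      # overlap check in projection: bounding boxes must intersect
      if (max(A[, 1]) < min(B[, 1]) || max(B[, 1]) < min(A[, 1]) ||
          max(A[, 2]) < min(B[, 2]) || max(B[, 2]) < min(A[, 2]))
        stop(sprintf(
          "consecutive contours %d/%d of object '%s' do not overlap in projection",
          k, k + 1, ob))
      lev <- list(A)
      dz <- B[1, 3] - A[1, 3]
      if (!is.null(interpolate_every) && abs(dz) > interpolate_every) {
        nmid <- ceiling(abs(dz) / interpolate_every) - 1L
        npt <- max(nrow(A), nrow(B))
        Ar <- resample_polyline(A[, 1:2, drop = FALSE], npt, stack$closed)
        Br <- resample_polyline(B[, 1:2, drop = FALSE], npt, stack$closed)
        if (stack$closed) {
          al <- align_closed(cbind(Ar, A[1, 3]), cbind(Br, B[1, 3]))
        } else {
          al <- align_open(cbind(Ar, A[1, 3]), cbind(Br, B[1, 3]))
        }
        for (m in seq_len(nmid)) {
          t <- m / (nmid + 1)
          lev[[length(lev) + 1]] <- (1 - t) * al$A + t * al$B
        }
      }
      lev[[length(lev) + 1]] <- B
      for (m in seq_len(length(lev) - 1)) {
        P <- lev[[m]]; Q <- lev[[m + 1]]
        al <- if (stack$closed) align_closed(P, Q) else align_open(P, Q)
        V <- rbind(al$A, al$B)
        F <- zipper_band(al$A, al$B, stack$closed)
        allV[[length(allV) + 1]] <- V
        allF[[length(allF) + 1]] <- F + voffs
        voffs <- voffs + nrow(V)
      }
    }
  }
  V <- do.call(rbind, allV)
  F <- do.call(rbind, allF)
  a <- triangle_areas(V, F)
  surface_mesh(V, F[a > 1e-12, , drop = FALSE], validate = FALSE)
}
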