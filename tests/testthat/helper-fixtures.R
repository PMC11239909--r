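# Analytic mesh fixtures built in code; used as independent geometry oracles.

# icosphere: subdivided icosahedron projected to radius r
icosphere <- function(r = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      V <<- rbind(V, (V[i, ] + V[j, ]) / 2)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    newF <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (k in seq_len(nrow(F))) {
      a <- F[k, 1]; b <- F[k, 2]; cc <- F[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[(4 * k - 3):(4 * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    F <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * r
  surface_mesh(V, F)
}

# open cylinder of radius r, z in [0, h]
cylinder_mesh <- function(r = 10, h = 40, ntheta = 96, nz = 20) {
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  zs <- seq(0, h, length.out = nz)
  V <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th), r * sin(th), z)))
  idx <- seq_len(ntheta); nxt <- c(idx[-1], 1L)
  F <- do.call(rbind, lapply(seq_len(nz - 1), function(k) {
    o1 <- (k - 1) * ntheta; o2 <- k * ntheta
    rbind(cbind(o1 + idx, o1 + nxt, o2 + idx),
          cbind(o1 + nxt, o2 + nxt, o2 + idx))
  }))
  surface_mesh(V, F)
}

# torus, tube radius r around circle of radius R in the xy-plane
torus_mesh <- function(R = 50, r = 10, nu = 72, nv = 36) {
  us <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  vs <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  V <- do.call(rbind, lapply(us, function(u)
    t(vapply(vs, function(v)
      c((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u), r * sin(v)),
      numeric(3)))))
  F <- do.call(rbind, lapply(seq_len(nu), function(i) {
    i2 <- if (i == nu) 1L else i + 1L
    do.call(rbind, lapply(seq_len(nv), function(j) {
      j2 <- if (j == nv) 1L else j + 1L
      a <- (i - 1) * nv + j; b <- (i - 1) * nv + j2
      cc <- (i2 - 1) * nv + j; d <- (i2 - 1) * nv + j2
      rbind(c(a, b, cc), c(b, d, cc))
    }))
  }))
  surface_mesh(V, F)
}

# 90-degree elbow tube: bend radius Rb, tube radius r, arc in the xz-plane
elbow_mesh <- function(Rb = 40, r = 10, nseg = 60, ntheta = 64) {
  phis <- seq(0, pi / 2, length.out = nseg)
  Vs <- lapply(phis, function(p) {
    cen <- c(Rb * sin(p), 0, Rb * (1 - cos(p)))
    tangent <- c(cos(p), 0, sin(p))
    u <- c(0, 1, 0)
    v <- c(tangent[2] * u[3] - tangent[3] * u[2],
           tangent[3] * u[1] - tangent[1] * u[3],
           tangent[1] * u[2] - tangent[2] * u[1])
    th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
    t(vapply(th, function(a) cen + r * cos(a) * u + r * sin(a) * v, numeric(3)))
  })
  V <- do.call(rbind, Vs)
  idx <- seq_len(ntheta); nxt <- c(idx[-1], 1L)
  F <- do.call(rbind, lapply(seq_len(nseg - 1), function(k) {
    o1 <- (k - 1) * ntheta; o2 <- k * ntheta
    rbind(cbind(o1 + idx, o1 + nxt, o2 + idx),
          cbind(o1 + nxt, o2 + nxt, o2 + idx))
  }))
  surface_mesh(V, F)
}

# flat rectangular sheet mesh at height z, spanning [-ext, ext]^2
sheet_mesh <- function(z = 0, ext = 1000, pitch = 50) {
  xs <- seq(-ext, ext, by = pitch)
  n <- length(xs)
  g <- expand.grid(x = xs, y = xs)
  V <- cbind(g$x, g$y, z)
  F <- do.call(rbind, lapply(seq_len(n - 1), function(j) {
    do.call(rbind, lapply(seq_len(n - 1), function(i) {
      v1 <- (j - 1) * n + i
      rbind(c(v1, v1 + 1, v1 + n), c(v1 + 1, v1 + n + 1, v1 + n))
    }))
  }))
  surface_mesh(V, F)
}

# circle contours stacked along z (closed) as a contour_stack
ring_stack <- function(radii, dz = 10, npts = 200) {
  th <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  df <- do.call(rbind, lapply(seq_along(radii), function(i)
    data.frame(object_id = 1, contour_id = i, z_index = i - 1,
               x_nm = radii[i] * cos(th), y_nm = radii[i] * sin(th))))
  contour_stack(df, z_spacing = dz)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  junctmorph:::rotation_matrix(ax, runif(1, 0.3, 2.8))
}
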