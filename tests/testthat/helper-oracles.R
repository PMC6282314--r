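# Independent oracles, deliberately naive: brute-force Delaunay by empty-
# circumsphere enumeration, alpha filtering and component counting from
# first principles, a bisection search on the monotone volume curve, and an
# analytically refined icosphere.  None of these share code with the
# package's computational paths.

oracle_circumsphere <- function(p) {
  A <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
  if (abs(det(A)) < 1e-12) return(NULL)
  x <- solve(A, 0.5 * rowSums(A^2))
  list(centre = p[1, ] + x, r2 = sum(x^2))
}

# all 4-subsets whose open circumsphere contains no other point
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  keep <- list()
  radii <- numeric(0)
  vols <- numeric(0)
  for (i in seq_len(ncol(combs))) {
    id <- combs[, i]
    p <- pts[id, , drop = FALSE]
    cs <- oracle_circumsphere(p)
    if (is.null(cs)) next
    d2 <- rowSums(sweep(pts, 2, cs$centre)^2)
    d2[id] <- Inf
    if (all(d2 > cs$r2 * (1 + 1e-9))) {
      keep[[length(keep) + 1]] <- sort(id)
      radii <- c(radii, sqrt(cs$r2))
      vols <- c(vols, abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ],
                                    p[4, ] - p[1, ]))) / 6)
    }
  }
  list(tets = do.call(rbind, keep), radii = radii, vols = vols)
}

# alpha complex from the brute-force triangulation: volume, boundary-face
# set, component count by breadth-first search over shared faces
oracle_alpha <- function(bt, alpha) {
  kept <- which(bt$radii <= alpha)
  vol <- sum(bt$vols[kept])
  tets <- bt$tets[kept, , drop = FALSE]
  faces <- character(0)
  if (nrow(tets) > 0) {
    all_faces <- do.call(rbind, lapply(seq_len(nrow(tets)), function(i) {
      t(apply(utils::combn(tets[i, ], 3), 2, sort))
    }))
    key <- apply(all_faces, 1, paste, collapse = "-")
    faces <- names(which(table(key) == 1))
  }
  ncomp <- 0L
  if (nrow(tets) > 0) {
    m <- nrow(tets)
    fkeys <- lapply(seq_len(m), function(i)
      apply(utils::combn(tets[i, ], 3), 2, function(v) paste(sort(v), collapse = "-")))
    seen <- rep(FALSE, m)
    for (s in seq_len(m)) {
      if (seen[s]) next
      ncomp <- ncomp + 1L
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (j in seq_len(m)) {
          if (!seen[j] && length(intersect(fkeys[[cur]], fkeys[[j]])) > 0) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  list(volume = vol, boundary_keys = sort(faces), n_components = ncomp,
       kept_tets = tets)
}

# dense-grid bracket + bisection on the monotone alpha-volume curve; the
# volume at each probe is recomputed by a naive circumradius filter
oracle_bisect_k <- function(tri, l_ref, raw, n_grid = 2000) {
  lv <- if (inherits(l_ref, "reference_length")) l_ref$value_mm else l_ref
  vol_at <- function(k) sum(tri$volume[tri$circumradius <= k * lv])
  g <- build_grid(n_grid)$values
  vols <- vapply(g, vol_at, 0)
  stopifnot(any(vols >= raw))
  i <- min(which(vols >= raw))
  stopifnot(i > 1)
  lo <- log10(g[i - 1]); hi <- log10(g[i])
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (vol_at(10^mid) >= raw) hi <- mid else lo <- mid
  }
  10^hi
}

# geodesic icosphere: subdivided icosahedron projected onto the unit sphere
oracle_icosphere <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- V[a, ] + V[b, ]
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    F2 <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; c <- F[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      F2[4 * i - 3, ] <- c(a, ab, ca)
      F2[4 * i - 2, ] <- c(b, bc, ab)
      F2[4 * i - 1, ] <- c(c, ca, bc)
      F2[4 * i, ] <- c(ab, bc, ca)
    }
    F <- F2
  }
  surface_mesh(V * radius, F)
}
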