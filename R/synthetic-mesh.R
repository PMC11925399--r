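# Synthetic spheroidal cell meshes: seeded random directions -> spherical
# Delaunay (3D convex hull) -> Voronoi dual -> centroidal (Lloyd) relaxation.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ordered triangle fan around every site of a spherical Delaunay
# triangulation (hull triangles, CCW outward)
site_triangle_rings <- function(tri, n_sites) {
  nt <- nrow(tri)
  # directed-edge (a,b) -> triangle lookup
  key <- function(a, b) (a - 1) * (n_sites + 1) + b
  ka <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
          key(tri[, 3], tri[, 1]))
  tid <- rep.int(seq_len(nt), 3L)
  oo <- order(ka)
  ka <- ka[oo]
  tid <- tid[oo]
  lookup <- function(a, b) tid[findInterval(key(a, b), ka)]
  # one starting triangle per site + the two other vertices in cycle order
  start <- integer(n_sites)
  start[tri[, 1]] <- seq_len(nt)
  start[tri[, 2]] <- seq_len(nt)
  start[tri[, 3]] <- seq_len(nt)
  deg <- tabulate(as.vector(tri), n_sites)
  rings <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    t0 <- start[s]
    if (t0 == 0L || deg[s] < 3L) return(NULL)
    ring <- integer(deg[s])
    t <- t0
    for (j in seq_len(deg[s])) {
      ring[j] <- t
      v <- tri[t, ]
      k <- which(v == s)
      w <- v[if (k == 3L) 2L else if (k == 1L) 3L else 1L]  # vertex after next
      t <- lookup(s, w)
      if (is.na(t)) return(NULL)
    }
    if (t != t0 || anyDuplicated(ring)) return(NULL)
    rings[[s]] <- ring
  }
  rings
}

#' Generate a relaxed spheroidal cell shell
#'
#' Seeded random directions on the sphere are tessellated by spherical
#' Voronoi (via the 3D convex hull / Delaunay duality) and relaxed by Lloyd
#' iterations toward a centroidal tessellation.  The resulting closed shell
#' passes [validate_shell()]; every Voronoi vertex has exactly three
#' incident cells.
#'
#' @param n_cells number of cells (>= 20).
#' @param seed integer seed; the generator is a pure function of
#'   `(n_cells, seed, relax_iters, radius)`.
#' @param relax_iters Lloyd relaxation sweeps (default 40).
#' @param radius sphere radius; default `sqrt(n_cells / (4 * pi))` so that
#'   the mean cell area is 1 (the preferred area in model units).
#' @return a `cellular_shell`.
#' @export
generate_sphere_shell <- function(n_cells, seed = 1L, relax_iters = 40L,
                                  radius = NULL) {
  if (n_cells < 20L) stop("n_cells must be >= 20")
  if (is.null(radius)) radius <- sqrt(n_cells / (4 * pi))
  for (attempt in 0:4) {
    pts <- with_seed(seed + 1000L * attempt, {
      m <- matrix(stats::rnorm(3 * n_cells), n_cells, 3)
      m / sqrt(rowSums(m^2))
    })
    sh <- tryCatch(
      build_voronoi_shell(pts, radius, relax_iters),
      error = function(e) NULL)
    if (!is.null(sh)) return(sh)
    warning(sprintf(
      "degenerate tessellation for seed %d; regenerating with perturbed points",
      seed))
  }
  stop("failed to generate a valid shell after 5 attempts")
}

build_voronoi_shell <- function(pts, radius, relax_iters) {
  n <- nrow(pts)
  rings <- NULL
  for (it in seq_len(relax_iters + 1L)) {
    tri <- hull_triangles_cpp(pts) + 1L
    rings <- site_triangle_rings(tri, n)
    if (is.null(rings)) stop("degenerate triangulation")
    # Voronoi vertices: unit normals of Delaunay triangles
    vd <- cross3m(pts[tri[, 2], ] - pts[tri[, 1], ],
                  pts[tri[, 3], ] - pts[tri[, 1], ])
    vd <- vd / sqrt(rowSums(vd^2))
    if (it > relax_iters) break
    # Lloyd: move each site to the normalized area-weighted centroid of its
    # Voronoi polygon (fan triangulation from the site)
    for (s in seq_len(n)) {
      poly <- vd[rings[[s]], , drop = FALSE]
      k <- nrow(poly)
      a <- poly
      b <- poly[c(2:k, 1), , drop = FALSE]
      da <- sweep(a, 2, pts[s, ])
      db <- sweep(b, 2, pts[s, ])
      w <- 0.5 * sqrt(rowSums(cross3m(da, db)^2))
      ctr <- colSums(w * (a + b + matrix(pts[s, ], k, 3, byrow = TRUE)) / 3)
      pts[s, ] <- ctr / sqrt(sum(ctr^2))
    }
  }
  cells <- rings
  sh <- cellular_shell(radius * vd, cells, check = FALSE)
  if (enclosed_volume(sh) < 0)
    sh <- cellular_shell(radius * vd, lapply(cells, rev), check = FALSE)
  validate_shell(sh, strict = TRUE)
  sh
}

# rowwise cross product of two n x 3 matrices
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# typical cell diameter (diameter of the equal-area disc)
cell_diameter <- function(shell) {
  2 * sqrt(mean(shell_geometry(shell)$areas) / pi)
}
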