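#' Construct a closed polygonal cell shell
#'
#' A `cellular_shell` represents a closed polygonal 2-manifold: an epithelial
#' monolayer wrapped around a fluid-filled lumen.  Cells are polygons defined
#' by shared vertices; every bond (edge) is shared by exactly two cells, so
#' the surface has no boundary and Euler characteristic V - E + F = 2 for a
#' spheroid.  All cell vertex cycles must be wound consistently so that cell
#' normals point outward (positive enclosed volume).
#'
#' @param positions numeric matrix (n_vertices x 3) of vertex coordinates, in
#'   model length units (the unit of length is the square root of the
#'   preferred cell area).
#' @param cells list of integer vectors; each is one cell's cyclic vertex
#'   list (1-based, consistent outward winding, >= 3 vertices).
#' @param check if `TRUE` (default) the shell is validated strictly on
#'   construction (see [validate_shell()]).
#' @return an object of class `cellular_shell` with derived connectivity:
#'   `bonds` (matrix with columns `v1, v2, c1, c2`), `cell_neighbors`,
#'   `cell_bonds`, and `vertex_cells` (ordered ring of incident cells per
#'   vertex).
#' @seealso [generate_sphere_shell()], [validate_shell()]
#' @export
cellular_shell <- function(positions, cells, check = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  cells <- lapply(cells, as.integer)
  if (any(vapply(cells, length, 1L) < 3L))
    stop("every cell needs at least 3 vertices")
  shell <- structure(list(positions = positions, cells = cells),
                     class = "cellular_shell")
  shell <- shell_build_connectivity(shell)
  if (check) validate_shell(shell, strict = TRUE)
  shell
}

#' @export
print.cellular_shell <- function(x, ...) {
  cat(sprintf("<cellular_shell> %d vertices, %d bonds, %d cells (chi = %d)\n",
              nrow(x$positions), nrow(x$bonds), length(x$cells),
              nrow(x$positions) - nrow(x$bonds) + length(x$cells)))
  invisible(x)
}

# Derive bonds, neighbor lists and ordered vertex rings from the cell cycles.
shell_build_connectivity <- function(shell) {
  cells <- shell$cells
  nc <- length(cells)
  nv <- nrow(shell$positions)
  m <- vapply(cells, length, 1L)
  cell_ptr <- c(0L, cumsum(m))
  cell_vert <- unlist(cells, use.names = FALSE) - 1L

  # directed edges, one per (cell, cycle position)
  from <- unlist(lapply(cells, function(v) v), use.names = FALSE)
  to <- unlist(lapply(cells, function(v) c(v[-1], v[1])), use.names = FALSE)
  ecell <- rep.int(seq_len(nc), m)

  key <- pmin(from, to) * (nv + 1) + pmax(from, to)
  ord <- order(key)
  key_s <- key[ord]
  grp <- cumsum(!duplicated(key_s))
  nb <- max(grp)
  first <- ord[!duplicated(key_s)]
  cnt <- tabulate(grp, nb)
  if (any(cnt != 2L))
    stop("shell is not closed: every bond must border exactly 2 cells")
  second <- ord[duplicated(key_s)]
  # orientation consistency: the two half-edges must be antiparallel
  if (any(from[first] == from[second]))
    stop("inconsistent cell winding: a directed edge appears twice")
  bonds <- cbind(v1 = from[first], v2 = to[first],
                 c1 = ecell[first], c2 = ecell[second])

  # per-cell incident bonds / neighbors
  bond_of_edge <- integer(length(from))
  bond_of_edge[ord] <- grp
  cell_bonds <- split(bond_of_edge, ecell)
  cell_neighbors <- vector("list", nc)
  other <- function(b, c) ifelse(bonds[b, "c1"] == c, bonds[b, "c2"],
                                 bonds[b, "c1"])
  for (c in seq_len(nc)) cell_neighbors[[c]] <- other(cell_bonds[[c]], c)

  # ordered ring of incident cells per vertex: successor of cell c around
  # vertex v is the cell entered by crossing the bond (prev_c(v), v), i.e.
  # the cell whose outgoing edge at v is (v, prev_c(v)).
  prev_at <- unlist(lapply(cells, function(v) c(v[length(v)], v[-length(v)])),
                    use.names = FALSE)
  # map (vertex, out-neighbor) -> cell, via binary search on sorted keys
  okey <- (from - 1) * (nv + 1) + to
  vertex_cells <- vector("list", nv)
  oo <- order(okey)
  okey_s <- okey[oo]
  ocell_s <- ecell[oo]
  lookup <- function(v, w) {
    k <- (v - 1) * (nv + 1) + w
    ocell_s[findInterval(k, okey_s)]
  }
  # incident (cell, prev-vertex) pairs per vertex
  inc_cell <- split(ecell, from)
  inc_prev <- split(prev_at, from)
  for (v in seq_len(nv)) {
    cs <- inc_cell[[as.character(v)]]
    ps <- inc_prev[[as.character(v)]]
    k <- length(cs)
    if (is.null(cs) || k < 3L)
      stop(sprintf("vertex %d has fewer than 3 incident bonds", v))
    ring <- integer(k)
    ring[1] <- cs[1]
    pv <- ps[1]
    for (j in seq_len(k - 1L)) {
      nxt <- lookup(v, pv)
      ring[j + 1L] <- nxt
      pv <- ps[match(nxt, cs)]
    }
    if (anyNA(ring) || length(unique(ring)) != k)
      stop(sprintf("could not order the cell ring around vertex %d", v))
    vertex_cells[[v]] <- ring
  }

  shell$cell_ptr <- cell_ptr
  shell$cell_vert <- cell_vert
  shell$bonds <- bonds
  shell$cell_bonds <- cell_bonds
  shell$cell_neighbors <- cell_neighbors
  shell$vertex_cells <- vertex_cells
  shell
}

# Low-level kernel call; params all zero gives pure geometry.
shell_kernel <- function(shell, params = NULL, q3 = NULL, zeta = 0,
                         forces = FALSE) {
  if (is.null(params))
    params <- list(K = 0, A0 = 0, Lambda = 0, Gamma = 0, beta = 0)
  vm_forces_cpp(shell$positions, shell$cell_vert, shell$cell_ptr,
                shell$bonds[, 1:2, drop = FALSE] - 1L,
                shell$bonds[, 3:4, drop = FALSE] - 1L,
                params$K, params$A0, params$Lambda, params$Gamma,
                params$beta,
                if (is.null(q3)) matrix(0, 0, 6) else q3,
                zeta, forces)
}

#' Per-cell geometry summary for a whole shell
#'
#' Computes, for every cell, the fan-construction geometry: the center (mean
#' of the cell's vertices), area (sum of fan-triangle areas), perimeter (sum
#' of raw bond lengths), outward unit normal (normalized area-weighted mean
#' of fan-triangle normals) and the enclosed volume of the shell.
#'
#' @param shell a `cellular_shell`.
#' @return list with `centers`, `areas`, `perimeters`, `normals` (unit rows),
#'   `volume`, `bond_lengths`, `dihedrals`.
#' @export
shell_geometry <- function(shell) {
  g <- shell_kernel(shell)
  list(centers = g$centers, areas = g$areas, perimeters = g$perimeters,
       normals = g$normals, volume = g$volume, bond_lengths = g$bond_lengths,
       dihedrals = g$dihedrals)
}

#' Geometry of a single cell
#'
#' @param shell a `cellular_shell`.
#' @param cell_id integer cell index.
#' @return a `cell_geometry` list: `center`, `area`, `perimeter`, `normal`
#'   (unit), and a right-handed orthonormal tangent frame `e1`, `e2`
#'   (with `e1 x e2 = normal`).
#' @export
build_cell_geometry <- function(shell, cell_id) {
  vidx <- shell$cells[[cell_id]]
  V <- shell$positions[vidx, , drop = FALSE]
  center <- colMeans(V)
  m <- nrow(V)
  A <- 0
  W <- c(0, 0, 0)
  P <- 0
  for (k in seq_len(m)) {
    Ri <- V[k, ]
    Rj <- V[if (k == m) 1L else k + 1L, ]
    cr <- cross3(Ri - center, Rj - center)
    A <- A + 0.5 * sqrt(sum(cr^2))
    W <- W + cross3(Ri, Rj)
    P <- P + sqrt(sum((Rj - Ri)^2))
  }
  if (A <= 1e-14)
    stop(sprintf("degenerate cell %d: zero total triangle area", cell_id))
  n <- W / sqrt(sum(W^2))
  fr <- tangent_frame(n)
  structure(list(center = center, area = A, perimeter = P, normal = n,
                 e1 = fr$e1, e2 = fr$e2, cell_id = cell_id),
            class = "cell_geometry")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic in-plane frame for a unit normal
tangent_frame <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  list(e1 = e1, e2 = cross3(n, e1))
}

# vectorized frames for all cells given unit normal matrix (nc x 3)
shell_frames <- function(normals) {
  nc <- nrow(normals)
  a <- matrix(rep(c(1, 0, 0), each = nc), nc, 3)
  flip <- abs(normals[, 1]) >= 0.9
  a[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), sum(flip), 3)
  d <- rowSums(a * normals)
  e1 <- a - d * normals
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(normals[, 2] * e1[, 3] - normals[, 3] * e1[, 2],
              normals[, 3] * e1[, 1] - normals[, 1] * e1[, 3],
              normals[, 1] * e1[, 2] - normals[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

#' Enclosed lumen volume
#'
#' Signed volume computed by fan tetrahedra from the origin over all cell
#' fan triangles; positive for outward-wound shells and exactly
#' translation-invariant (the signed contributions of any translation
#' cancel over a closed surface).
#'
#' @param shell a `cellular_shell`.
#' @return scalar volume in model length^3.
#' @export
enclosed_volume <- function(shell) {
  shell_kernel(shell)$volume
}

#' Dihedral angle across a bond
#'
#' The bending angle `theta_b` in `[0, pi]` between the outward unit normals
#' of the two cells sharing the bond; zero for coplanar cells.
#'
#' @param shell a `cellular_shell`.
#' @param bond integer bond index (row of `shell$bonds`), or a length-2
#'   vertex pair identifying the bond.
#' @return angle in radians.
#' @export
dihedral_angle <- function(shell, bond) {
  if (length(bond) == 2L) {
    hit <- which((shell$bonds[, "v1"] == bond[1] &
                  shell$bonds[, "v2"] == bond[2]) |
                 (shell$bonds[, "v1"] == bond[2] &
                  shell$bonds[, "v2"] == bond[1]))
    if (length(hit) != 1L) stop("no such bond")
    bond <- hit
  }
  g <- shell_kernel(shell)
  g$dihedrals[bond]
}

#' Graph distances on the cell-adjacency graph
#'
#' Breadth-first distance: cells are adjacent iff they share a bond; the
#' distance from a set of source cells is the minimal number of
#' neighbor-to-neighbor steps.
#'
#' @param shell a `cellular_shell`.
#' @param source_cells integer vector of source cell ids (distance 0).
#' @return integer vector of distances, one per cell.
#' @export
graph_distances <- function(shell, source_cells) {
  source_cells <- unique(as.integer(source_cells))
  nc <- length(shell$cells)
  if (length(source_cells) == 0L) stop("empty source set")
  if (any(source_cells < 1L | source_cells > nc)) stop("unknown source cell")
  dist <- rep.int(NA_integer_, nc)
  dist[source_cells] <- 0L
  frontier <- source_cells
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(shell$cell_neighbors[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Project a 3D vector into a cell's tangent plane
#'
#' Removes the normal component and returns the 2D components in the cell's
#' orthonormal tangent frame; idempotent for in-plane vectors.
#'
#' @param v numeric length-3 vector.
#' @param geometry a `cell_geometry` from [build_cell_geometry()].
#' @return length-2 numeric (components along `e1`, `e2`).
#' @export
tangent_project <- function(v, geometry) {
  w <- v - sum(v * geometry$normal) * geometry$normal
  c(sum(w * geometry$e1), sum(w * geometry$e2))
}

#' Validate a shell's topological and orientation invariants
#'
#' Checks: closure (every bond borders exactly two cells), Euler
#' characteristic `V - E + F == 2`, consistent outward winding (no repeated
#' directed edge, positive enclosed volume), and minimum vertex degree 3.
#' Most violations are detected during connectivity construction; this
#' reports them as diagnostics or raises in strict mode.
#'
#' @param shell a `cellular_shell` (or a list with `positions` and `cells`
#'   not yet wired up).
#' @param strict if `TRUE`, stop on the first violation.
#' @return (invisibly) a list of diagnostics: `closed`, `euler`,
#'   `oriented`, `volume`, `ok`.
#' @export
validate_shell <- function(shell, strict = FALSE) {
  diag <- list(closed = TRUE, euler = NA_integer_, oriented = TRUE,
               volume = NA_real_, ok = TRUE)
  res <- tryCatch({
    s <- if (is.null(shell$bonds))
      shell_build_connectivity(shell) else shell
    diag$euler <- nrow(s$positions) - nrow(s$bonds) + length(s$cells)
    diag$volume <- enclosed_volume(s)
    if (diag$euler != 2L) {
      diag$ok <- FALSE
      if (strict) stop(sprintf("Euler characteristic %d != 2", diag$euler))
    }
    if (diag$volume <= 0) {
      diag$oriented <- FALSE
      diag$ok <- FALSE
      if (strict) stop("non-positive enclosed volume: windings not outward")
    }
    diag
  }, error = function(e) {
    if (strict) stop(e)
    msg <- conditionMessage(e)
    if (grepl("winding|directed", msg)) diag$oriented <- FALSE
    else diag$closed <- FALSE
    diag$ok <- FALSE
    diag$message <- msg
    diag
  })
  invisible(res)
}
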