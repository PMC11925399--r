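# Shared fixtures: unit cube shell, icosahedron, flat hexagon patches.

cube_shell <- function(edge = 1) {
  pos <- edge * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  cells <- list(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  cellular_shell(pos, cells)
}

# regular icosahedron with unit circumradius, faces outward CCW
icosahedron_shell <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  cellular_shell(v, lapply(seq_len(nrow(f)), function(i) f[i, ]))
}

# single regular polygon in the z = 0 plane as an open patch
regular_polygon_patch <- function(n = 6, edge = 1, lift = NULL) {
  R <- edge / (2 * sin(pi / n))
  pos <- cbind(R * cos(2 * pi * (0:(n - 1)) / n),
               R * sin(2 * pi * (0:(n - 1)) / n), 0)
  if (!is.null(lift)) pos[lift$vertex, 3] <- lift$dz
  cell_patch(pos, list(1:n))
}

# flat patch of hexagonal cells (rows x cols honeycomb), open boundary
hex_patch <- function(rows = 3, cols = 3, edge = 1) {
  key <- new.env(hash = TRUE)
  pos <- list()
  getv <- function(x, y) {
    k <- sprintf("%.6f_%.6f", x, y)
    if (is.null(key[[k]])) {
      pos[[length(pos) + 1L]] <<- c(x, y, 0)
      key[[k]] <- length(pos)
    }
    key[[k]]
  }
  cells <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      cx <- (c - 1) * sqrt(3) * edge + (r %% 2) * sqrt(3) / 2 * edge
      cy <- (r - 1) * 1.5 * edge
      ang <- pi / 6 + 2 * pi * (0:5) / 6
      cells[[length(cells) + 1L]] <-
        vapply(1:6, function(k) getv(cx + edge * cos(ang[k]),
                                     cy + edge * sin(ang[k])), 1L)
    }
  }
  cell_patch(do.call(rbind, pos), cells)
}

# default q3 embedding used by active-force tests (unit Frobenius norm)
q3_of <- function(psi, e1, n) {
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  c2 <- cos(2 * psi) / sqrt(2)
  s2 <- sin(2 * psi) / sqrt(2)
  m <- c2 * (outer(e1, e1) - outer(e2, e2)) +
    s2 * (outer(e1, e2) + outer(e2, e1))
  matrix(c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3]), 1, 6)
}
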