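# Mesh and snapshot I/O: ASCII PLY (read/write), legacy ASCII VTK POLYDATA
# (write), and a lossless JSON snapshot container for simulation states.

#' Write a shell to an ASCII PLY file
#'
#' Polygonal faces; optional per-cell scalar properties are not part of
#' PLY faces, so they go into the snapshot container instead.
#'
#' @param shell a `cellular_shell`.
#' @param file path.
#' @export
write_shell_ply <- function(shell, file) {
  pos <- shell$positions
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment closed polygonal cell shell",
               sprintf("element vertex %d", nrow(pos)),
               "property double x", "property double y",
               "property double z",
               sprintf("element face %d", length(shell$cells)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(apply(pos, 1, function(r) paste(format(r, digits = 17),
                                             collapse = " ")), con)
  writeLines(vapply(shell$cells, function(cy)
    paste(c(length(cy), cy - 1L), collapse = " "), ""), con)
  invisible(file)
}

#' Read a shell from an ASCII PLY file
#'
#' @param file path to a polygonal ASCII PLY.
#' @param check validate the shell on construction.
#' @return a `cellular_shell`.
#' @export
read_shell_ply <- function(file, check = TRUE) {
  ln <- readLines(file)
  if (ln[1] != "ply" || !grepl("ascii", ln[2]))
    stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", ln, value = TRUE)[1]))
  start <- which(ln == "end_header") + 1L
  pos <- do.call(rbind, lapply(ln[start:(start + nv - 1L)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  cells <- lapply(ln[(start + nv):(start + nv + nf - 1L)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    v[seq_len(v[1]) + 1L] + 1L
  })
  cellular_shell(pos, cells, check = check)
}

#' Write a shell to a legacy ASCII VTK POLYDATA file
#'
#' Optionally attaches per-cell scalar fields (e.g. nematic angle,
#' morphogen count) as CELL_DATA.
#'
#' @param shell a `cellular_shell`.
#' @param file path.
#' @param cell_data named list of per-cell numeric vectors.
#' @export
write_shell_vtk <- function(shell, file, cell_data = list()) {
  pos <- shell$positions
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cellular shell", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pos))), con)
  writeLines(apply(pos, 1, function(r) paste(format(r, digits = 17),
                                             collapse = " ")), con)
  sizes <- vapply(shell$cells, length, 1L)
  writeLines(sprintf("POLYGONS %d %d", length(sizes),
                     sum(sizes) + length(sizes)), con)
  writeLines(vapply(shell$cells, function(cy)
    paste(c(length(cy), cy - 1L), collapse = " "), ""), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", length(shell$cells)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 17), con)
    }
  }
  invisible(file)
}

#' Save a simulation state snapshot (lossless JSON container)
#'
#' Stores vertex positions, cell connectivity, per-cell nematic angle and
#' frame axes, morphogen counts and reference areas, parameters, time and
#' the RNG state, so a run can be resumed or inspected exactly.
#'
#' @param state a [shell_state()].
#' @param file path (`.json`).
#' @export
save_snapshot <- function(state, file) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(
    format = "nematoshell-snapshot-1",
    time = state$time, V0 = state$V0, mu = state$mu, zeta = state$zeta,
    n_t1 = state$n_t1,
    positions = state$shell$positions,
    cells = state$shell$cells,
    params = unclass(state$params),
    nematic = if (!is.null(state$nematic)) list(
      psi = state$nematic$psi, e1 = state$nematic$e1,
      normals = state$nematic$normals,
      tau_q = state$nematic$tau_q, alpha = state$nematic$alpha),
    morphogen = if (!is.null(state$morphogen))
      unclass(state$morphogen),
    rng_state = rng)
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}

#' Load a simulation state snapshot
#'
#' @param file path written by [save_snapshot()].
#' @param restore_rng restore the saved RNG state (default FALSE).
#' @return a [shell_state()].
#' @export
load_snapshot <- function(file, restore_rng = FALSE) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "nematoshell-snapshot-1"))
    stop("not a nematoshell snapshot")
  shell <- cellular_shell(obj$positions, obj$cells, check = FALSE)
  p <- do.call(mechanics_params,
               obj$params[c("K", "A0", "Lambda", "Gamma", "beta", "gamma",
                            "dt", "L_th")])
  st <- shell_state(shell, p)
  st$time <- obj$time
  st$V0 <- obj$V0
  st$mu <- obj$mu
  st$zeta <- obj$zeta
  st$n_t1 <- obj$n_t1
  if (!is.null(obj$nematic)) {
    st$nematic <- nematic_field(
      shell, obj$nematic$psi, tau_q = obj$nematic$tau_q,
      alpha = obj$nematic$alpha,
      frames = list(e1 = obj$nematic$e1, normals = obj$nematic$normals))
  }
  if (!is.null(obj$morphogen)) {
    m <- obj$morphogen
    st$morphogen <- morphogen_field(
      shell, N = m$N, D = m$D, r_plus = m$r_plus, r_minus = m$r_minus,
      eps_th = m$eps_th, w = m$w, A_ref = m$A_ref,
      sigmoid_convention = m$sigmoid_convention)
  }
  if (restore_rng && !is.null(obj$rng_state))
    assign(".Random.seed", as.integer(obj$rng_state),
           envir = globalenv())
  st
}
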