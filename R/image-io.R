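# Plain-text grayscale raster I/O (ASCII PGM / CSV).  No TIFF/PNG reader
# is available in the dependency set, so rasters are exchanged as PGM
# (portable graymap, P2) or CSV matrices.

#' Write a grayscale raster as ASCII PGM (P2)
#'
#' Intensities are linearly rescaled to `0..maxval`.
#'
#' @param img numeric matrix.
#' @param file path.
#' @param maxval maximum gray value (default 65535).
#' @export
write_pgm <- function(img, file, maxval = 65535L) {
  rng <- range(img, finite = TRUE)
  scl <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  q <- round(scl * maxval)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# range %.17g %.17g", rng[1], rng[2]),
               sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  write(t(q), con, ncolumns = ncol(img))
  invisible(file)
}

#' Read an ASCII PGM (P2) raster
#'
#' If the file carries the range comment written by [write_pgm()], the
#' original intensity scale is restored.
#'
#' @param file path.
#' @return numeric matrix.
#' @export
read_pgm <- function(file) {
  ln <- readLines(file)
  if (ln[1] != "P2") stop("not an ASCII PGM (P2) file")
  rng <- NULL
  cm <- grep("^# range ", ln, value = TRUE)
  if (length(cm))
    rng <- as.numeric(strsplit(cm[1], " ")[[1]][3:4])
  body <- ln[!grepl("^#", ln)][-1]
  nums <- as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                     "\\s+")))
  nums <- nums[is.finite(nums)]
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  img <- matrix(nums[-(1:3)], nrow = h, ncol = w, byrow = TRUE)
  if (!is.null(rng) && diff(rng) > 0)
    img <- img / maxval * diff(rng) + rng[1]
  img
}
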