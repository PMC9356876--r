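#' Read a fundus image from disk
#'
#' Supports PNG, JPEG and TIFF. Channel count is preserved (RGBA alpha is
#' dropped); 16-bit inputs are rescaled to the 8-bit range with a warning.
#'
#' @param path file path.
#' @param image_id identifier; defaults to the file name.
#' @return a [fundus_image()].
#' @export
read_image <- function(path, image_id = basename(path)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path)),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  # readers return [0,1] doubles; detect 16-bit via TIFF attribute if present
  bits <- attr(px, "bits.per.sample")
  if (!is.null(bits) && bits > 8)
    warning("16-bit image rescaled to 8-bit range: ", path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1]
  fundus_image(round(px * 255), image_id = image_id)
}

#' Write a fundus image to disk
#'
#' @param img a [fundus_image()].
#' @param path output path; format chosen from the extension (png/tiff/jpeg).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  px <- img$pixels
  if (dim(px)[3] == 1L) dim(px) <- dim(px)[1:2]
  px <- pmin(pmax(px / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    jpg = , jpeg = jpeg::writeJPEG(px, path, quality = 1),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vessel pixels are written as 255, background as 0.
#'
#' @param mask a [vessel_mask()] or [skeleton_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(unclass(mask) * 1.0, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels above half intensity are vessel.
#'
#' @param path PNG path.
#' @return a [vessel_mask()].
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  vessel_mask((px > 0.5) * 1L)
}

#' Read junction points from CSV or JSON
#'
#' CSV files need a header `row,col,kind[,score]`; JSON files hold an array of
#' objects with those keys. On-disk coordinates use `origin` (0 by default)
#' and are converted to the package's 1-based convention.
#'
#' @param path file path (`.csv` or `.json`).
#' @param origin index base of the file's coordinates, 0 or 1.
#' @return a [junction_points()] table with provenance `"ground_truth"`.
#' @export
read_points <- function(path, origin = 0) {
  if (!file.exists(path)) stop("points file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0) data.frame(row = numeric(), col = numeric()) else
      as.data.frame(x)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0)
    return(junction_points())
  if (!all(c("row", "col") %in% names(df)))
    stop("points file must have 'row' and 'col' columns: ", path)
  for (cn in c("row", "col")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v) | v < origin)
    if (length(bad))
      stop(sprintf("invalid '%s' value at data line %d of %s", cn, bad[1], path))
    df[[cn]] <- v
  }
  junction_points(row = df$row + (1 - origin), col = df$col + (1 - origin),
                  kind = if ("kind" %in% names(df)) df$kind else "unknown",
                  score = if ("score" %in% names(df)) df$score else 1,
                  provenance = "ground_truth")
}

#' Write junction points to CSV
#'
#' @param points a [junction_points()] table.
#' @param path output CSV path.
#' @param origin index base for the on-disk coordinates, 0 or 1.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, origin = 0) {
  df <- as.data.frame(points)
  df$row <- df$row - (1 - origin)
  df$col <- df$col - (1 - origin)
  write.csv(df[, c("row", "col", "kind", "score")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a correspondence file
#'
#' Plain-text rows of four numbers `x_ref y_ref x_sensed y_sensed`,
#' whitespace- or comma-delimited (the layout used by fundus registration
#' ground-truth sets such as FIRE).
#'
#' @param path file path.
#' @param origin index base of the file's coordinates, 0 or 1.
#' @return a [correspondence_set()].
#' @export
read_correspondences <- function(path, origin = 0) {
  if (!file.exists(path)) stop("correspondence file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty correspondence file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(gsub(",", " ", lines[i]), "[[:space:]]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) != 4)
      stop(sprintf("line %d of %s has %d fields, expected 4", i, path,
                   length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(!is.finite(v)))
      stop(sprintf("non-numeric field at line %d of %s", i, path))
    v
  })
  m <- do.call(rbind, rows) + (1 - origin)
  correspondence_set(ref = m[, 1:2, drop = FALSE],
                     sensed = m[, 3:4, drop = FALSE])
}

#' Write a correspondence file
#'
#' @param cs a [correspondence_set()].
#' @param path output path.
#' @param origin index base for the on-disk coordinates, 0 or 1.
#' @return `path`, invisibly.
#' @export
write_correspondences <- function(cs, path, origin = 0) {
  m <- cbind(cs$ref, cs$sensed) - (1 - origin)
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  invisible(path)
}

#' Write a homography as a 3 x 3 row-major text file
#'
#' @param h a [homography()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homography <- function(h, path) {
  writeLines(apply(unclass(h), 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  invisible(path)
}

#' Read a homography from a 3 x 3 row-major text file
#'
#' @param path input path.
#' @return a [homography()].
#' @export
read_homography <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 9) stop("homography file must hold 9 numbers: ", path)
  homography(matrix(v, 3, 3, byrow = TRUE))
}
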