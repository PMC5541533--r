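# File readers and writers. Images are exchanged as PNG/TIFF/JPEG; masks as
# 0/255 single-channel PNG; tables as CSV; polygons as vertex CSV and a
# GeoJSON-like text file. Pixel coordinates in tables are 0-based (i = row,
# j = column) at pixel centres.

#' Read an image file
#'
#' Reads PNG or TIFF (8- or 16-bit, rescaled to [0, 1]) natively and other
#' formats (e.g. JPEG) through EBImage. Greyscale files yield a matrix;
#' colour files an (h, w, 3) array (any alpha channel is dropped). When
#' \code{fovMm} is given, the physical pixel area is attached as the
#' \code{"pixelArea"} attribute via \code{\link{pixelAreaFromFov}}.
#'
#' @param path image file path.
#' @param fovMm optional c(height, width) field of view in millimetres.
#' @return numeric matrix or (h, w, 3) array in [0, 1].
#' @export
readImageFile <- function(path, fovMm = NULL) {
  if (!file.exists(path)) .stopIO(paste0("cannot read image: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else {
      eb <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(eb)) == 2L) t(eb) else aperm(eb, c(2, 1, 3))
    }
  }, error = function(e)
    .stopIO(paste0("failed to decode ", path, ": ", conditionMessage(e))))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 2L) img <- img[, , 1]               # grey + alpha
    else if (nc >= 4L) img <- img[, , 1:3]        # drop alpha
    else if (nc == 1L) img <- img[, , 1]
    else if (nc != 3L) .stopIO(paste0("unsupported channel count in ", path))
  }
  if (!is.null(fovMm))
    attr(img, "pixelArea") <- pixelAreaFromFov(fovMm[1], fovMm[2],
                                               dim(img)[1], dim(img)[2])
  img
}

#' Write a nucleus label map as a 16-bit TIFF
#'
#' Labels are stored as value/65535 at 16-bit depth, so up to 65535 nuclei
#' round-trip exactly; 0 is background.
#'
#' @param labels integer label matrix.
#' @param path output path (.tiff).
#' @return the path, invisibly.
#' @export
writeLabelTiff <- function(labels, path) {
  if (max(labels) > 65535L)
    .stopIO("more than 65535 labels cannot be stored at 16-bit depth")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF back to an integer label map
#' @param path label TIFF path.
#' @return integer label matrix.
#' @export
readLabelTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write an image to PNG
#' @param img matrix or (h, w, 3) array in [0, 1].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeImageFile <- function(img, path) {
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask binary 0/1 matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskFile <- function(mask, path) {
  .assertMask(mask)
  png::writePNG(mask + 0.0, path)
  invisible(path)
}

#' Read a binary mask (any nonzero pixel is white)
#' @param path mask image path.
#' @return binary 0/1 integer matrix.
#' @export
readMaskFile <- function(path) {
  img <- readImageFile(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  .asIntMask((img > 0) + 0L)
}

#' Write a zone table as CSV
#'
#' One row per zone: zone_id, area_px, area_um2, centroid_i, centroid_j,
#' bbox_i0, bbox_i1, bbox_j0, bbox_j1 (0-based coordinates).
#'
#' @param zones list of \linkS4class{Zone}.
#' @param path output CSV path.
#' @param pixelAreaUm2 pixel area used for physical areas.
#' @return the data frame, invisibly.
#' @export
writeZonesCsv <- function(zones, path, pixelAreaUm2) {
  df <- do.call(rbind, lapply(seq_along(zones), function(k) {
    z <- zones[[k]]
    px <- zonePixels(z)
    data.frame(zone_id = k, area_px = zoneArea(z),
               area_um2 = zoneArea(z) * pixelAreaUm2,
               centroid_i = mean(px[, 1]) - 1, centroid_j = mean(px[, 2]) - 1,
               bbox_i0 = min(px[, 1]) - 1L, bbox_i1 = max(px[, 1]) - 1L,
               bbox_j0 = min(px[, 2]) - 1L, bbox_j1 = max(px[, 2]) - 1L)
  }))
  if (is.null(df))
    df <- data.frame(zone_id = integer(0), area_px = integer(0),
                     area_um2 = numeric(0), centroid_i = numeric(0),
                     centroid_j = numeric(0), bbox_i0 = integer(0),
                     bbox_i1 = integer(0), bbox_j0 = integer(0),
                     bbox_j1 = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a focus contour as a vertex CSV
#'
#' Columns vertex_id, i, j (0-based, pixel-centre coordinates, closed polygon
#' with the first vertex not repeated). An empty focus writes a header-only
#' file.
#'
#' @param focus a \linkS4class{FocusContour}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeContourCsv <- function(focus, path) {
  v <- contourVertices(focus)
  df <- data.frame(vertex_id = seq_len(nrow(v)),
                   i = if (nrow(v)) v[, 1] else numeric(0),
                   j = if (nrow(v)) v[, 2] else numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a focus contour as a GeoJSON-like polygon
#'
#' Coordinates are [j, i] pairs (x = column, y = row), 0-based pixel centres;
#' the first vertex is repeated to close the ring, per the GeoJSON
#' convention.
#'
#' @param focus a \linkS4class{FocusContour}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeContourGeoJson <- function(focus, path) {
  if (isEmptyFocus(focus)) {
    txt <- paste0('{"type": "Feature", "geometry": null, ',
                  '"properties": {"focus": "none", ',
                  '"coordinate_order": "[col, row], 0-based"}}')
  } else {
    v <- contourVertices(focus)
    ring <- rbind(v, v[1, , drop = FALSE])
    coords <- paste0("[", format(ring[, 2], trim = TRUE), ", ",
                     format(ring[, 1], trim = TRUE), "]", collapse = ", ")
    txt <- paste0('{"type": "Feature", "geometry": {"type": "Polygon", ',
                  '"coordinates": [[', coords, ']]}, ',
                  '"properties": {"area_px": ', focusAreaPx(focus),
                  ', "area_fraction": ', focusAreaFraction(focus),
                  ', "coordinate_order": "[col, row], 0-based"}}')
  }
  writeLines(txt, path)
  invisible(path)
}

#' Write nucleus centroids as CSV (nucleus_id, i, j; 0-based)
#' @param nuclei a \linkS4class{NucleusSet}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCentroidsCsv <- function(nuclei, path) {
  cent <- centroids(nuclei)
  df <- data.frame(nucleus_id = seq_len(nrow(cent)),
                   i = if (nrow(cent)) cent[, 1] - 1 else numeric(0),
                   j = if (nrow(cent)) cent[, 2] - 1 else numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a segmentation overlay PNG
#'
#' Blends the inflammation mask in blue and the vein mask in green over the
#' image; where the two overlap, inflammation takes priority.
#'
#' @param img RGB array (h, w, 3) at the masks' scale.
#' @param inflammation,veins binary masks.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOverlayPng <- function(img, inflammation, veins, path) {
  alpha <- 0.45
  out <- img
  vOnly <- veins == 1 & inflammation == 0
  for (c in 1:3) {
    ch <- out[, , c]
    tint <- if (c == 3) 1 else 0   # blue
    ch[inflammation == 1] <- (1 - alpha) * ch[inflammation == 1] +
      alpha * tint
    tint <- if (c == 2) 1 else 0   # green
    ch[vOnly] <- (1 - alpha) * ch[vOnly] + alpha * tint
    out[, , c] <- ch
  }
  writeImageFile(out, path)
}
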