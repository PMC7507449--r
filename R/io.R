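#' Read and write slice outlines as GeoJSON-style polygon files
#'
#' Outlines are stored as a FeatureCollection whose features carry a
#' \code{name} (one of the 13 muscles, "fascia" or "femur") and a
#' \code{slice} property, with Polygon coordinates in 0-based pixel
#' units. \code{readOutlines} validates names and polygon shape and
#' returns one \linkS4class{SliceOutlineSet} per slice.
#'
#' @param path file path.
#' @return \code{readOutlines}: named list of
#'   \linkS4class{SliceOutlineSet}, ordered by slice index.
#' @export
readOutlines <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("input error: not a FeatureCollection")
  valid <- c(thighMuscles(), .outlineExtras)
  bySlice <- list()
  for (fi in seq_along(js$features)) {
    f <- js$features[[fi]]
    nm <- f$properties$name
    sl <- f$properties$slice
    if (is.null(nm) || !nm %in% valid)
      stop("naming error: unknown structure name '", nm,
           "' (feature ", fi, "); valid names are: ",
           paste(valid, collapse = ", "))
    if (is.null(sl)) stop("input error: feature ", fi, " lacks a slice")
    cc <- f$geometry$coordinates[[1]]
    verts <- do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
    if (is.null(verts) || nrow(verts) < 3L || ncol(verts) != 2L)
      stop("input error: malformed polygon for '", nm, "' at feature ",
           fi, " (need >= 3 two-dimensional vertices)")
    ## drop an explicit closing vertex
    if (nrow(verts) > 3L && all(verts[1, ] == verts[nrow(verts), ]))
      verts <- verts[-nrow(verts), , drop = FALSE]
    if (nrow(verts) < 3L)
      stop("input error: malformed polygon for '", nm, "' at feature ", fi)
    key <- as.character(sl)
    bySlice[[key]] <- c(bySlice[[key]],
                        structure(list(verts), names = nm))
  }
  ord <- order(as.integer(names(bySlice)))
  out <- lapply(names(bySlice)[ord], function(k)
    sliceOutlineSet(bySlice[[k]], as.integer(k)))
  names(out) <- names(bySlice)[ord]
  out
}

#' @rdname readOutlines
#' @param outlines list of \linkS4class{SliceOutlineSet}.
#' @export
writeOutlines <- function(outlines, path) {
  if (is(outlines, "SliceOutlineSet")) outlines <- list(outlines)
  features <- list()
  for (os in outlines) {
    for (nm in names(os@polygons)) {
      p <- os@polygons[[nm]]
      ring <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
      ring[[length(ring) + 1L]] <- ring[[1L]]  # close
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(name = nm, slice = os@sliceIndex),
        geometry = list(type = "Polygon", coordinates = list(ring)))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' NIfTI input/output for image stacks and label maps
#'
#' Stacks are written as 3-D NIfTI volumes with the pixel spacing and
#' centre-to-centre slice spacing in the header. Slice thickness and gap
#' are not representable in NIfTI and must be re-supplied when reading.
#'
#' @param stack an \linkS4class{AxialImageStack} or
#'   \linkS4class{TissueLabelMap}.
#' @param path output path (".nii" or ".nii.gz").
#' @export
writeImageStack <- function(stack, path) {
  arr <- simplify2array(stack@slices)
  g <- stack@geometry
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixelSpacingMm(g), pixelSpacingMm(g),
                           g@sliceSpacingMm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeImageStack
#' @param sliceThicknessMm,intersliceGapMm acquisition values to restore
#'   into the geometry (their sum should equal the NIfTI z spacing).
#' @export
readImageStack <- function(path, sliceThicknessMm = 12,
                           intersliceGapMm = 12) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (abs(pd[1] - pd[2]) > 1e-6)
    stop("input error: anisotropic in-plane spacing in ", path)
  d <- dim(arr)
  geom <- acquisitionGeometry(fovMm = pd[1] * d[1:2], matrixPx = d[1:2],
                              sliceThicknessMm = sliceThicknessMm,
                              intersliceGapMm = intersliceGapMm,
                              sliceSpacingMm = pd[3])
  slices <- lapply(seq_len(d[3]), function(s) arr[, , s])
  axialImageStack(slices, geom)
}

#' Write a volume or CSA table as CSV with a units header
#'
#' The first line holds column names, the second the unit of each column
#' (cm^2, cm^3, percent or empty); data start on line three.
#' \code{readVolumeTable} restores the data.frame, dropping the units row.
#'
#' @param tab data.frame.
#' @param path file path.
#' @export
writeVolumeTable <- function(tab, path) {
  units <- vapply(names(tab), function(nm) {
    if (grepl("CSA$", nm)) "cm^2"
    else if (grepl("Volume$", nm)) "cm^3"
    else if (grepl("Content|percent", nm, ignore.case = TRUE)) "%"
    else ""
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname writeVolumeTable
#' @export
readVolumeTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  cols <- strsplit(hdr, ",")[[1]]
  tab <- utils::read.csv(path, skip = 2L, header = FALSE,
                         col.names = cols, stringsAsFactors = FALSE)
  tab
}
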