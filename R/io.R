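# Reading and writing angiogram frames as 8-bit grayscale PNG.

#' Write an angiogram to an 8-bit grayscale PNG
#'
#' The pixel scale and layer are not stored in the PNG; keep them in the
#' cohort table (or pass them back to [read_angiogram()]).
#'
#' @param image A [faz_angiogram] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(image, path) {
  stopifnot(inherits(image, "faz_angiogram"))
  png::writePNG(pmin(pmax(image$pixels, 0), 1), path)
  invisible(path)
}

#' Read an angiogram from a grayscale PNG
#'
#' @param path PNG file path.
#' @param um_per_pixel Pixel scale of the frame (micrometers per pixel).
#' @param layer,eye_id Metadata to attach.
#' @return A [faz_angiogram] object.
#' @export
read_angiogram <- function(path, um_per_pixel = 6.579,
                           layer = "superficial", eye_id = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  faz_angiogram(px, um_per_pixel, layer,
                eye_id %||% tools::file_path_sans_ext(basename(path)))
}
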