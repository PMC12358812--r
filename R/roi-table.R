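#' Default bilateral cortical ROI table
#'
#' Ten bilateral dorsal-cortex regions with nominal atlas-derived
#' stereotaxic centers (anterior-posterior and medial-lateral offsets from
#' bregma, mm), converted to pixel coordinates for a given image geometry.
#' Anterior is at the top of the image and bregma is given in pixel
#' coordinates; +ML maps to the right hemisphere (+x).
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param bregma_xy Bregma position `c(x, y)` in pixels (default image
#'   centre).
#' @return Data frame with columns `name`, `hemisphere` ("L"/"R"),
#'   `x`, `y` (pixels, 1-based), `ap_mm`, `ml_mm`, `homolog_name`.
#' @export
default_roi_table <- function(image_shape = c(64, 64), pixel_size_um = 134,
                              bregma_xy = (image_shape[c(2, 1)] + 1) / 2) {
  regions <- data.frame(
    name  = c("MOp", "MOs", "SSp_bfd", "SSp_ll", "SSp_ul",
              "VISam", "VISp", "VISpm", "RSPagl", "VISa"),
    ap_mm = c(1.0, 2.3, -1.0, -1.0, -0.5, -2.7, -3.4, -3.2, -2.8, -2.4),
    ml_mm = c(1.5, 1.0, 3.3, 1.5, 2.0, 1.7, 2.5, 1.6, 0.6, 2.3)
  )
  px_mm <- 1000 / pixel_size_um
  build <- function(side, sgn) {
    data.frame(
      name = paste0(regions$name, "_", side),
      hemisphere = side,
      x = round(bregma_xy[1] + sgn * regions$ml_mm * px_mm),
      y = round(bregma_xy[2] - regions$ap_mm * px_mm),
      ap_mm = regions$ap_mm,
      ml_mm = sgn * regions$ml_mm,
      homolog_name = paste0(regions$name, "_", if (side == "L") "R" else "L")
    )
  }
  tab <- rbind(build("L", -1), build("R", 1))
  rownames(tab) <- NULL
  validate_roi_table(tab, image_shape)
  tab
}

validate_roi_table <- function(tab, image_shape = NULL) {
  need <- c("name", "hemisphere", "x", "y", "homolog_name")
  if (!all(need %in% names(tab)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name)) stop("ROI names must be unique")
  hm <- match(tab$homolog_name, tab$name)
  if (anyNA(hm)) stop("every ROI needs a homolog entry in the table")
  if (any(tab$hemisphere[hm] == tab$hemisphere))
    stop("homolog pairs must lie in opposite hemispheres")
  if (!is.null(image_shape)) {
    if (any(tab$x < 2 | tab$x > image_shape[2] - 1 |
            tab$y < 2 | tab$y > image_shape[1] - 1))
      stop("ROI 3x3 neighborhoods must lie inside the image")
  }
  invisible(tab)
}
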