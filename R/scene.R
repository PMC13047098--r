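#' Construct a 4-band spectral scene
#'
#' A scene bundles the four band grids (Blue, Green, Red, NIR) with the
#' acquisition's timing index (1-7), growth-stage label, and a simple
#' affine georeference (grid origin and pixel size). Bands may hold
#' scaled integers (reflectance times 10,000, `rescaled = FALSE`) or unit
#' reflectance (`rescaled = TRUE`).
#'
#' @param B,G,R,NIR Numeric matrices of equal dimension.
#' @param timing Integer timing index (1-7).
#' @param stage Growth-stage label, e.g. `"V10-V11"`.
#' @param rescaled Logical; `TRUE` if bands are reflectance in `[0, 1]`.
#' @param pixel_size_m Pixel edge length in meters.
#' @param origin Numeric `c(x, y)` of the grid's upper-left corner (m).
#' @param trial_id Optional trial label carried as metadata.
#' @return An object of class `spectral_scene`.
#' @export
spectral_scene <- function(B, G, R, NIR, timing = NA_integer_, stage = NA_character_,
                           rescaled = FALSE, pixel_size_m = 3,
                           origin = c(0, 0), trial_id = NA_character_) {
  dims <- lapply(list(B, G, R, NIR), dim)
  if (length(unique(vapply(dims, paste, collapse = "x", FUN.VALUE = ""))) != 1) {
    stop("all four bands must share the same dimensions")
  }
  structure(
    list(
      bands = list(B = B, G = G, R = R, NIR = NIR),
      timing = as.integer(timing), stage = stage, rescaled = isTRUE(rescaled),
      pixel_size_m = pixel_size_m, origin = origin, trial_id = trial_id
    ),
    class = "spectral_scene"
  )
}

#' @export
print.spectral_scene <- function(x, ...) {
  d <- dim(x$bands$B)
  cat(sprintf(
    "<spectral_scene> %d x %d px, bands B/G/R/NIR (%s), timing %s (%s), trial %s\n",
    d[1], d[2], if (x$rescaled) "reflectance 0-1" else "scaled integer 0-10000",
    x$timing, x$stage, x$trial_id
  ))
  invisible(x)
}

#' Rescale a scene's bands from scaled integers to reflectance
#'
#' @param scene A [spectral_scene] holding scaled integers.
#' @return The scene with bands divided by 10,000 and `rescaled = TRUE`.
#' @export
rescale_scene <- function(scene) {
  stopifnot(inherits(scene, "spectral_scene"))
  if (isTRUE(scene$rescaled)) return(scene)
  scene$bands <- lapply(scene$bands, rescale_reflectance)
  scene$rescaled <- TRUE
  scene
}

#' Write a scene to a multiband 16-bit TIFF with a JSON sidecar
#'
#' Bands are written in order B, G, R, NIR as one 16-bit TIFF page each,
#' preserving the scaled-integer convention exactly. Georeference and
#' acquisition metadata (origin, pixel size, band order, scale factor,
#' timing, stage) go to `<path>.json`.
#'
#' @param scene A [spectral_scene]; scaled-integer scenes are written
#'   as-is, rescaled scenes are converted back to scaled integers.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "spectral_scene"))
  bands <- scene$bands
  if (isTRUE(scene$rescaled)) bands <- lapply(bands, function(b) round(b * 10000))
  bands <- lapply(bands, function(b) {
    if (any(b < 0 | b > 10000, na.rm = TRUE)) stop("band values outside 0..10000")
    # 16-bit TIFF samples are value * 65535; integers <= 10000 survive exactly
    b / 65535
  })
  tiff::writeTIFF(unname(bands), path, bits.per.sample = 16L)
  meta <- list(
    band_order = c("B", "G", "R", "NIR"),
    scale_factor = 10000,
    pixel_size_m = scene$pixel_size_m,
    origin = as.numeric(scene$origin),
    # row-major affine: x = origin[1] + (col-1)*px, y = origin[2] - (row-1)*px
    transform = c(scene$pixel_size_m, 0, as.numeric(scene$origin[1]),
                  0, -scene$pixel_size_m, as.numeric(scene$origin[2])),
    timing = scene$timing, stage = scene$stage, trial_id = scene$trial_id
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [write_scene()]
#'
#' @param path TIFF path (with `<path>.json` sidecar alongside).
#' @return A [spectral_scene] holding scaled integers.
#' @export
read_scene <- function(path) {
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  if (length(pages) != 4) stop("expected a 4-page (4-band) TIFF")
  bands <- lapply(pages, function(p) round(p * 65535))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  ord <- unlist(meta$band_order %||% c("B", "G", "R", "NIR"))
  names(bands) <- ord
  spectral_scene(
    B = bands$B, G = bands$G, R = bands$R, NIR = bands$NIR,
    timing = meta$timing %||% NA_integer_,
    stage = meta$stage %||% NA_character_,
    rescaled = FALSE,
    pixel_size_m = meta$pixel_size_m %||% 3,
    origin = unlist(meta$origin %||% c(0, 0)),
    trial_id = meta$trial_id %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
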