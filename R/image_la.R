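#' Convert an 8-bit sRGB canopy image to CIELAB
#'
#' Standard sRGB -> XYZ -> CIELAB conversion under the D65 reference white
#' (via [grDevices::convertColor()]). Neutral grays map to a* = b* = 0 and
#' L* spans 0 (black) to 100 (white).
#'
#' @param img numeric array `H x W x 3` of sRGB values in \[0, 255\] (8-bit
#'   levels) or in \[0, 1\].
#' @return list of numeric `H x W` matrices `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("`img` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(!is.finite(img)) || any(img < 0)) {
    stop("`img` channel values must be finite and non-negative", call. = FALSE)
  }
  mx <- max(img)
  if (mx > 255) stop("`img` channel values must be at most 255", call. = FALSE)
  scale <- if (mx > 1) 255 else 1
  h <- dim(img)[1]; w <- dim(img)[2]
  flat <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3])) / scale
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab",
                                 scale.in = 1)
  list(L = matrix(lab[, 1], h, w),
       a = matrix(lab[, 2], h, w),
       b = matrix(lab[, 3], h, w))
}

#' Clip the opponent channels to their warm halves
#'
#' L* is left unchanged; a* (green-red) and b* (blue-yellow) have their
#' negative (cool) halves removed: `a' = max(a, 0)`, `b' = max(b, 0)`.
#'
#' @param lab list with matrices `L`, `a`, `b` as from [srgb_to_lab()].
#' @return list of the same shape with clipped `a`, `b`.
#' @export
clip_warm_channels <- function(lab) {
  stopifnot(is.list(lab), all(c("L", "a", "b") %in% names(lab)))
  list(L = lab$L, a = pmax(lab$a, 0), b = pmax(lab$b, 0))
}

#' Binary warm/cool mask of a CIELAB image
#'
#' Labels each pixel warm (1, "white") or cool (0, "black"). The default
#' predicate is `a > 0`: pixels red of the neutral axis are warm. Green
#' vegetation has a* < 0, while senescent straw and exposed soil have
#' a* > 0, so on canopy imagery warm pixels indicate lodged or senesced
#' material. The predicate is configurable as any function of the three
#' channel matrices.
#'
#' @param lab list with matrices `L`, `a`, `b` (clipped or unclipped; the
#'   default predicate gives identical results either way up to the
#'   measure-zero boundary a == 0, which counts as cool).
#' @param predicate function `(L, a, b) -> logical matrix`, TRUE = warm.
#' @return list with `mask` (integer `H x W`, 1 = warm), `warm_count`,
#'   `cool_count`.
#' @export
warm_cool_mask <- function(lab, predicate = function(L, a, b) a > 0) {
  stopifnot(is.list(lab), all(c("L", "a", "b") %in% names(lab)))
  warm <- predicate(lab$L, lab$a, lab$b)
  if (!is.logical(warm) || !identical(dim(warm), dim(lab$a))) {
    stop("predicate must return a logical matrix of the image shape",
         call. = FALSE)
  }
  mask <- matrix(as.integer(warm), nrow(warm), ncol(warm))
  list(mask = mask,
       warm_count = sum(mask == 1L),
       cool_count = sum(mask == 0L))
}

#' Combined warm-intensity predicate
#'
#' Alternative mask rule `w_a * max(a, 0) + w_b * max(b, 0) > tau`, for
#' scenes where yellowing (b*) should contribute to the warm call.
#'
#' @param w_a,w_b channel weights.
#' @param tau decision threshold in Lab units.
#' @return a predicate function usable with [warm_cool_mask()].
#' @export
warm_intensity_predicate <- function(w_a = 1, w_b = 0.5, tau = 5) {
  force(w_a); force(w_b); force(tau)
  function(L, a, b) w_a * pmax(a, 0) + w_b * pmax(b, 0) > tau
}

#' Lodged-area percentage from a warm/cool mask
#'
#' The warm ("white") pixel fraction times 100. Lodged canopy exposes warm
#' straw and soil tones, so the warm fraction is read as the lodged-area
#' indicator; the raw black:white ratio is also returned for reference.
#'
#' @param mask list from [warm_cool_mask()].
#' @param verbose if TRUE, return a list with `la_pct`, `warm_count`,
#'   `cool_count`, `black_white_ratio`; otherwise the percentage alone.
#' @return lodged-area percent in \[0, 100\], or the verbose list.
#' @export
lodged_area_percent <- function(mask, verbose = FALSE) {
  total <- mask$warm_count + mask$cool_count
  if (total <= 0) stop("empty image", call. = FALSE)
  la <- 100 * mask$warm_count / total
  if (!verbose) return(la)
  list(la_pct = la, warm_count = mask$warm_count,
       cool_count = mask$cool_count,
       black_white_ratio = if (mask$warm_count > 0) {
         mask$cool_count / mask$warm_count
       } else {
         Inf
       })
}

#' Estimate lodged area from a canopy image
#'
#' The full pipeline: sRGB -> CIELAB -> warm-half channel clipping ->
#' warm/cool binary mask -> warm pixel percentage. An optional crop box is
#' applied first; an optional affine calibration (fit against visual
#' quadrant assessments) is applied last.
#'
#' @param img `H x W x 3` sRGB array, or a path to a PNG/JPEG file.
#' @param predicate warm predicate, as in [warm_cool_mask()].
#' @param crop optional `c(row1, row2, col1, col2)` crop box (1-based,
#'   inclusive).
#' @param calibration optional `c(intercept, slope)` applied as
#'   `intercept + slope * la`, clamped to \[0, 100\].
#' @return lodged-area estimate in percent.
#' @export
estimate_la_from_image <- function(img,
                                   predicate = function(L, a, b) a > 0,
                                   crop = NULL, calibration = NULL) {
  if (is.character(img)) img <- read_canopy_image(img)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4L)
    img <- img[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
  }
  lab <- clip_warm_channels(srgb_to_lab(img))
  la <- lodged_area_percent(warm_cool_mask(lab, predicate))
  if (!is.null(calibration)) {
    la <- min(max(calibration[1] + calibration[2] * la, 0), 100)
  }
  la
}

#' Read a canopy image from disk
#'
#' PNG via the `png` package; other formats (JPEG) via `EBImage` when
#' available.
#'
#' @param path image file path.
#' @return `H x W x 3` numeric array with values in \[0, 1\].
#' @export
read_canopy_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading non-PNG images requires the EBImage package",
           call. = FALSE)
    }
    e <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(e), c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as a PNG
#'
#' @param mask integer/logical `H x W` matrix (1 = warm/lodged).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- mask
  if (is.list(m)) m <- m$mask
  png::writePNG(matrix(as.numeric(m > 0), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Batch lodged-area estimates for a set of images
#'
#' @param paths character vector of image paths, or a directory (all
#'   PNG/JPEG files within).
#' @param predicate warm predicate.
#' @return data.frame with `image_id`, `warm_count`, `cool_count`, `la_pct`.
#' @export
la_from_images <- function(paths, predicate = function(L, a, b) a > 0) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  rows <- lapply(paths, function(p) {
    img <- read_canopy_image(p)
    msk <- warm_cool_mask(clip_warm_channels(srgb_to_lab(img)), predicate)
    data.frame(image_id = basename(p), warm_count = msk$warm_count,
               cool_count = msk$cool_count,
               la_pct = lodged_area_percent(msk))
  })
  do.call(rbind, rows)
}
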