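#' Convert an 8-bit RGB fruit image to CIELAB
#'
#' Per-pixel sRGB (D65/2 degrees) to CIELAB conversion with the standard sRGB
#' gamma linearization, via `grDevices::convertColor`. `L*` is in \[0, 100\];
#' white (255,255,255) maps to `L* = 100` with `a*`, `b*` at the achromatic
#' axis.
#'
#' @param image A `height x width x 3` array of 8-bit channel values
#'   (\[0, 255\]).
#' @return A `height x width x 3` numeric array of `L*`, `a*`, `b*` planes.
#' @export
rgb_to_lab <- function(image) {
  check_image(image)
  d <- dim(image)
  px <- matrix(as.numeric(image), ncol = 3) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab",
                                 to.ref.white = "D65")
  array(lab, dim = d)
}

#' Color statistics of a fruit image
#'
#' Mean and population SD (pixels are the full population of the region) of
#' each RGB channel and each CIELAB channel over the masked pixels (the whole
#' image when no mask is given), in the frozen order `mean_R, sd_R, mean_G,
#' sd_G, mean_B, sd_B, mean_L, sd_L, mean_a, sd_a, mean_b, sd_b`.
#'
#' @param image A `height x width x 3` 8-bit RGB array.
#' @param mask Optional logical matrix selecting fruit pixels.
#' @return A 1-row tibble with the 12 named columns.
#' @export
color_statistics <- function(image, mask = NULL) {
  check_image(image)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(image)[1:2]))
    if (!any(mask)) {
      abort("mask selects no pixels", class = "plumfuse_mask_error")
    }
  }
  lab <- rgb_to_lab(image)
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                L = lab[, , 1], a = lab[, , 2], b = lab[, , 3])
  vals <- purrr::imap(chans, function(ch, nm) {
    v <- if (is.null(mask)) as.numeric(ch) else ch[mask]
    c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  })
  tibble(
    mean_R = vals$R[["mean"]], sd_R = vals$R[["sd"]],
    mean_G = vals$G[["mean"]], sd_G = vals$G[["sd"]],
    mean_B = vals$B[["mean"]], sd_B = vals$B[["sd"]],
    mean_L = vals$L[["mean"]], sd_L = vals$L[["sd"]],
    mean_a = vals$a[["mean"]], sd_a = vals$a[["sd"]],
    mean_b = vals$b[["mean"]], sd_b = vals$b[["sd"]]
  )
}

#' Gray-level co-occurrence matrix texture features
#'
#' Quantizes the image luminance (ITU-R BT.601 weights, fixed \[0, 255\]
#' range) to `levels` gray bins, builds the symmetric normalized
#' co-occurrence matrix `P` for each of the four orientations (0, 45, 90,
#' 135 degrees) at the given pixel offset, computes contrast
#' `sum P(i,j) (i-j)^2`, dissimilarity `sum P(i,j) |i-j|`, energy
#' `sum P(i,j)^2` (the angular second moment, not its square root) and
#' homogeneity `sum P(i,j) / (1 + (i-j)^2)`, and averages each property over
#' the four angles.
#'
#' @param image A `height x width x 3` 8-bit RGB array (or a 2-d grayscale
#'   matrix in \[0, 255\]).
#' @param levels Number of gray levels (default 32, which keeps `P` well
#'   populated for small fruit regions).
#' @param distance Pixel offset (default 1).
#' @return A 1-row tibble: `glcm_contrast`, `glcm_dissimilarity`,
#'   `glcm_energy`, `glcm_homogeneity`.
#' @export
glcm_features <- function(image, levels = 32, distance = 1) {
  gray <- if (length(dim(image)) == 3) {
    check_image(image)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    as.matrix(image)
  }
  if (levels < 2 || distance < 1) {
    abort("need `levels` >= 2 and `distance` >= 1",
          class = "plumfuse_parameter_error")
  }
  if (nrow(gray) <= distance && ncol(gray) <= distance) {
    abort("image smaller than `distance` + 1 in both dimensions",
          class = "plumfuse_parameter_error")
  }
  q <- pmin(floor(gray / 256 * levels), levels - 1)   # bins 0..levels-1

  # offsets (drow, dcol): 0, 45, 90, 135 degrees at `distance` pixels
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  props <- vapply(offsets, function(o) {
    glcm_props(q, levels, o[1] * distance, o[2] * distance)
  }, numeric(4))
  avg <- unname(rowMeans(props))
  tibble(glcm_contrast = avg[1], glcm_dissimilarity = avg[2],
         glcm_energy = avg[3], glcm_homogeneity = avg[4])
}

# symmetric normalized GLCM for one offset, then the four Haralick properties
glcm_props <- function(q, levels, drow, dcol) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - drow):min(nr, nr - drow)
  c1 <- max(1, 1 - dcol):min(nc, nc - dcol)
  if (length(r1) == 0 || length(c1) == 0) return(c(NA, NA, NA, NA))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + drow, c1 + dcol, drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels * levels)
  cm <- matrix(counts, levels, levels, byrow = TRUE)  # rows = level of a
  cm <- cm + t(cm)
  pm <- cm / sum(cm)
  dmat <- abs(row(pm) - col(pm))
  c(contrast = sum(pm * dmat^2),
    dissimilarity = sum(pm * dmat),
    energy = sum(pm^2),
    homogeneity = sum(pm / (1 + dmat^2)))
}

#' Extract the 16-dimensional visual feature vector
#'
#' Concatenates the 12 color statistics ([color_statistics()]) and the 4
#' GLCM texture features ([glcm_features()]) in the frozen order downstream
#' models depend on: `mean_R, sd_R, mean_G, sd_G, mean_B, sd_B, mean_L,
#' sd_L, mean_a, sd_a, mean_b, sd_b, glcm_contrast, glcm_dissimilarity,
#' glcm_energy, glcm_homogeneity`.
#'
#' @param image A `height x width x 3` 8-bit RGB array.
#' @param mask Optional logical fruit mask, applied to the color statistics
#'   only (GLCM uses the mask's bounding box); default `NULL` uses the full
#'   image.
#' @param levels,distance GLCM settings (see [glcm_features()]).
#' @return A 1-row tibble with 16 columns.
#' @examples
#' img <- simulate_images(sample_ssc(1, seed = 1), image_size = 32, seed = 1)[[1]]
#' extract_visual_features(img)
#' @export
extract_visual_features <- function(image, mask = NULL, levels = 32,
                                    distance = 1) {
  glcm_img <- image
  if (!is.null(mask)) {
    rr <- range(which(apply(mask, 1, any)))
    cc <- range(which(apply(mask, 2, any)))
    glcm_img <- image[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  }
  dplyr::bind_cols(color_statistics(image, mask),
                   glcm_features(glcm_img, levels, distance))
}

#' Extract visual features for a directory (or list) of fruit images
#'
#' @param images A named list of image arrays (names = sample ids) or a
#'   directory path containing `<sample_id>.png` files.
#' @inheritParams extract_visual_features
#' @return A tibble: `sample_id` plus the 16 feature columns, one row per
#'   image, ordered by sample id for directories.
#' @export
extract_features_table <- function(images, mask = NULL, levels = 32,
                                   distance = 1) {
  if (is.character(images)) {
    paths <- sort(list.files(images, pattern = "\\.png$", full.names = TRUE))
    ids <- tools::file_path_sans_ext(basename(paths))
    images <- stats::setNames(lapply(paths, read_fruit_image), ids)
  }
  purrr::imap(images, function(img, id) {
    dplyr::bind_cols(tibble(sample_id = id),
                     extract_visual_features(img, mask, levels, distance))
  }) |>
    purrr::list_rbind()
}

check_image <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3 || d[1] < 2 || d[2] < 2 ||
      min(image) < 0 || max(image) > 255) {
    abort("image must be a height x width x 3 array of values in [0, 255]",
          class = "plumfuse_format_error")
  }
  invisible(image)
}
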