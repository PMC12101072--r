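#' Crop region
#'
#' An axis-aligned square region, 0-based, half-open: rows
#' `row0 .. row0 + side_px - 1` and likewise for columns (in 0-based
#' indexing). `physical_size_mm` is filled in when a field-of-view
#' calibration is supplied.
#'
#' @param row0,col0 top-left corner, 0-based.
#' @param side_px side length in pixels, `>= 1`.
#' @param physical_size_mm side length in mm, or `NA`.
#' @return object of class `crop_region`.
#' @export
crop_region <- function(row0, col0, side_px, physical_size_mm = NA_real_) {
  stopifnot(row0 >= 0, col0 >= 0, side_px >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 side_px = as.integer(side_px),
                 physical_size_mm = physical_size_mm),
            class = "crop_region")
}

#' @export
print.crop_region <- function(x, ...) {
  cat(sprintf("<crop_region> %d px square at (row0 = %d, col0 = %d)%s\n",
              x$side_px, x$row0, x$col0,
              if (is.na(x$physical_size_mm)) "" else
                sprintf(", %.3f mm", x$physical_size_mm)))
  invisible(x)
}

#' Physical side length of a crop
#'
#' `side_px * fov_mm / width_px`: the crop side in mm given the horizontal
#' field of view of the full frame.
#'
#' @param region [crop_region].
#' @param fov_mm horizontal field of view of the full frame in mm.
#' @param width_px full-frame width in pixels.
#' @return the region with `physical_size_mm` set.
#' @export
calibrate_crop <- function(region, fov_mm, width_px) {
  stopifnot(fov_mm > 0, width_px > 0)
  region$physical_size_mm <- region$side_px * fov_mm / width_px
  region
}

#' Extract the pixels of a crop region
#' @param image matrix.
#' @param region [crop_region].
#' @return `side_px` x `side_px` matrix.
#' @export
apply_crop <- function(image, region) {
  r <- region$row0 + seq_len(region$side_px)
  cl <- region$col0 + seq_len(region$side_px)
  if (max(r) > nrow(image) || max(cl) > ncol(image))
    stop("crop region exceeds image bounds")
  image[r, cl, drop = FALSE]
}

#' Largest axis-aligned square inscribed in a mask
#'
#' The analysis region for a specimen: the biggest all-foreground square
#' inside its segmentation mask, found with the classic dynamic-programming
#' maximal-square recurrence. If several squares tie for side length, the
#' one whose centre is nearest the foreground centroid wins; remaining ties
#' go to the smallest `row0`, then smallest `col0`. A multi-component mask
#' is reduced to its largest 4-connected component (with a message).
#'
#' @param mask logical (or 0/1) matrix with at least one foreground pixel.
#' @return [crop_region].
#' @export
largest_inscribed_square <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("mask has no foreground pixels")
  lab <- label_components(mask)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    message("mask has ", max(lab),
            " components; using the largest (", sizes[keep], " px)")
    mask <- lab == keep
  }
  nr <- nrow(mask); nc <- ncol(mask)
  s <- matrix(0L, nr, nc)
  s[1L, ] <- as.integer(mask[1L, ])
  s[, 1L] <- as.integer(mask[, 1L])
  for (i in 2:nr) {
    si1 <- s[i - 1L, ]
    row <- s[i, ]
    for (j in 2:nc) {
      if (mask[i, j])
        row[j] <- min(si1[j], row[j - 1L], si1[j - 1L]) + 1L
    }
    s[i, ] <- row
  }
  side <- max(s)
  # bottom-right corners of all maximal squares
  idx <- which(s == side)
  br_r <- (idx - 1L) %% nr + 1L
  br_c <- (idx - 1L) %/% nr + 1L
  r0 <- br_r - side  # 0-based top row
  c0 <- br_c - side
  fg <- which(mask)
  cen_r <- mean((fg - 1L) %% nr)      # 0-based centroid
  cen_c <- mean((fg - 1L) %/% nr)
  d2 <- (r0 + (side - 1) / 2 - cen_r)^2 + (c0 + (side - 1) / 2 - cen_c)^2
  ord <- order(d2, r0, c0)
  best <- ord[1]
  crop_region(r0[best], c0[best], side)
}

#' Centre square crop of a rectangular image
#'
#' Scene images are cropped to the largest centred square: side
#' `min(height, width)`, offset `floor((long - side) / 2)` along the long
#' axis.
#'
#' @param image matrix, or `c(height, width)` dimensions.
#' @return [crop_region].
#' @export
center_square_crop <- function(image) {
  d <- if (is.matrix(image)) dim(image) else as.integer(image)
  h <- d[1]; w <- d[2]
  side <- min(h, w)
  crop_region((h - side) %/% 2L, (w - side) %/% 2L, side)
}
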