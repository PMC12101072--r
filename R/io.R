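#' Read an ASCII PGM (P2) raster
#'
#' Rasters are exchanged as plain-text PGM: a portable greyscale format that
#' supports 16-bit data (maxval up to 65535), which covers the 16-bit sensor
#' rasters and 8-bit masks this package works with.
#'
#' @param path file path to a P2 PGM file.
#' @return numeric matrix (rows = image rows); attribute `maxval` carries the
#'   file's stated maximum sample value.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2")
    stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != w * h)
    stop("PGM pixel count mismatch in ", path)
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  attr(m, "maxval") <- maxval
  m
}

#' Write an ASCII PGM (P2) raster
#'
#' @param image numeric matrix; values are rounded to integers in
#'   `[0, maxval]`.
#' @param path output path.
#' @param maxval maximum sample value (65535 for 16-bit sensor data, 255 for
#'   masks).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  stopifnot(is.matrix(image), maxval >= 1)
  v <- round(image)
  v[v < 0] <- 0
  v[v > maxval] <- maxval
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  # one image row per line keeps files diffable
  writeLines(apply(matrix(as.integer(v), nrow(image)), 1L, paste,
                   collapse = " "), con)
  invisible(path)
}

#' Read spectral sensitivity curves from CSV
#'
#' The CSV must have a `wavelength_nm` column followed by one column per
#' curve (camera filter or receptor).
#'
#' @param path CSV path.
#' @return named list of [sensitivity_curve] objects.
#' @export
read_sensitivity_curves <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("curve CSV needs a 'wavelength_nm' column")
  wl <- df$wavelength_nm
  cols <- setdiff(names(df), "wavelength_nm")
  stats::setNames(
    lapply(cols, function(cn) sensitivity_curve(wl, df[[cn]])), cols)
}

#' Write a set of sensitivity curves to CSV
#' @param curves named list of [sensitivity_curve] objects on a shared grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_curves <- function(curves, path) {
  wl <- curves[[1]]$wavelength_nm
  for (cu in curves)
    if (!isTRUE(all.equal(cu$wavelength_nm, wl)))
      stop("curves must share a wavelength grid to be written together")
  df <- data.frame(wavelength_nm = wl,
                   lapply(curves, function(cu) cu$sensitivity),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table (per-unit spectral slopes) from CSV
#'
#' Expected columns: `unit_id`, `group` (spider/scene), `species`, `sex`,
#' `region`, `slope`. Spider rows must carry species and sex; scene rows a
#' region.
#'
#' @param path CSV path.
#' @return data.frame validated by [validate_cohort()].
#' @export
read_cohort <- function(path) {
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
validate_cohort <- function(cohort) {
  need <- c("unit_id", "group", "slope")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  if (!all(cohort$group %in% c("spider", "scene")))
    stop("cohort 'group' must be 'spider' or 'scene'")
  if (anyNA(cohort$slope) || any(!is.finite(cohort$slope)))
    stop("cohort slopes must be finite")
  sp <- cohort$group == "spider"
  if (any(sp)) {
    if (!all(c("species", "sex") %in% names(cohort)) ||
        anyNA(cohort$species[sp]) || anyNA(cohort$sex[sp]))
      stop("spider rows need species and sex")
    if (!all(cohort$sex[sp] %in% c("male", "female")))
      stop("sex must be 'male' or 'female'")
  }
  if (any(!sp)) {
    if (!"region" %in% names(cohort) || anyNA(cohort$region[!sp]))
      stop("scene rows need a region label")
  }
  cohort
}
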