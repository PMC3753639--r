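#' Value grid over the section window
#'
#' A `value_grid` holds per-cell quantities aligned to a section matrix's
#' bounding window, plus a validity mask (noise / missing wells are
#' invalid).
#'
#' @param values Numeric matrix (window rows x window cols).
#' @param valid Logical matrix of the same shape.
#' @param assay_id Assay identifier tag.
#' @param normalization Normalization tag (e.g. `"genomic_18s"` or
#'   `"raw"`).
#' @return An object of class `value_grid`.
#' @export
value_grid <- function(values, valid, assay_id = "", normalization = "raw") {
  stopifnot(is.matrix(values), is.matrix(valid),
            all(dim(values) == dim(valid)))
  values[!valid] <- NA_real_
  if (any(values[valid] < 0, na.rm = TRUE)) {
    stop("valid grid values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, valid = valid, assay_id = assay_id,
                 normalization = normalization),
            class = "value_grid")
}

#' @export
print.value_grid <- function(x, ...) {
  cat(sprintf("<value_grid> %s (%s): %d x %d window, %d valid cells\n",
              x$assay_id, x$normalization, nrow(x$values), ncol(x$values),
              sum(x$valid)))
  invisible(x)
}

#' @rdname tidy-designs
#' @method tidy value_grid
#' @export
tidy.value_grid <- function(x, ...) {
  tibble::tibble(
    window_row = as.integer(row(x$values)),
    window_col = as.integer(col(x$values)),
    value = as.numeric(x$values),
    valid = as.logical(x$valid)
  ) |>
    dplyr::arrange(.data$window_row, .data$window_col)
}

#' Deconvolute analysis-plate records onto the section grid
#'
#' Places each sample well's value at its section cell via the inverse
#' layout mapping. Records for reference or blank wells are ignored (they
#' feed standard-curve fitting, never the image); sample cells without a
#' usable record become invalid.
#'
#' @param records A tibble keyed by `well` with a `value` column (for raw
#'   records use `quantity`; pass the normalized table with
#'   `value = "ratio"`).
#' @param matrix The [section_matrix()].
#' @param layout The layout from [map_to_analysis_plate()].
#' @param value Name of the value column (default `"value"`, falling back
#'   to `"quantity"` then `"ratio"` if absent).
#' @param valid Optional name of a logical validity column (e.g.
#'   `"valid"`); records `FALSE` there become invalid cells. Noise flags
#'   (`noise_flag`) are honored automatically when present.
#' @param assay_id,normalization Tags stored on the grid.
#' @return A [value_grid()].
#' @export
grid_from_records <- function(records, matrix, layout, value = NULL,
                              valid = NULL, assay_id = "",
                              normalization = "raw") {
  stopifnot(inherits(matrix, "section_matrix"))
  value <- value %||% intersect(c("value", "quantity", "ratio"),
                                names(records))[1]
  if (is.na(value)) stop("no value column found in records", call. = FALSE)
  sec <- layout_to_section(layout, matrix)
  joined <- sec |>
    dplyr::left_join(records, by = c(well_label = "well"))
  vals <- joined[[value]]
  ok <- !is.na(vals)
  if ("noise_flag" %in% names(joined)) {
    ok <- ok & !dplyr::coalesce(joined$noise_flag, TRUE)
  }
  if (!is.null(valid) && valid %in% names(joined)) {
    ok <- ok & dplyr::coalesce(joined[[valid]], FALSE)
  }
  win <- matrix$window
  values <- matrix(NA_real_, win$n_rows, win$n_cols)
  mask <- matrix(FALSE, win$n_rows, win$n_cols)
  idx <- cbind(joined$window_row, joined$window_col)
  values[idx[ok, , drop = FALSE]] <- vals[ok]
  mask[idx[ok, , drop = FALSE]] <- TRUE
  value_grid(values, mask, assay_id = assay_id, normalization = normalization)
}

#' Render a value grid as an RGBA raster
#'
#' Valid cells are colored by intensity (per-image max-normalized, mirroring
#' the percent-of-max figure convention), invalid cells are transparent or
#' zero-colored, and each cell becomes an `upsample x upsample` pixel block
#' (nearest neighbor; the plate's true resolution, no smoothing). Output is
#' deterministic for fixed inputs.
#'
#' @param grid A [value_grid()].
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param scaling `"linear"` or `"log"` intensity scaling.
#' @param upsample Integer pixel block size per cell (default 8).
#' @param invalid `"transparent"` (default) or `"zero"` (renders invalid
#'   cells like zero signal).
#' @return Numeric RGBA array, rows x cols x 4, values in \[0, 1\].
#' @export
render_grid <- function(grid, colormap = "viridis",
                        scaling = c("linear", "log"), upsample = 8L,
                        invalid = c("transparent", "zero")) {
  stopifnot(inherits(grid, "value_grid"), upsample >= 1L)
  scaling <- match.arg(scaling)
  invalid <- match.arg(invalid)
  if (!any(grid$valid)) stop("grid has no valid cells to render", call. = FALSE)
  v <- grid$values
  if (scaling == "log") {
    floor_val <- min(v[grid$valid & v > 0], na.rm = TRUE)
    v <- log10(pmax(v, floor_val))
  }
  vmax <- max(v[grid$valid]); vmin <- min(v[grid$valid])
  intensity <- if (vmax > vmin) (v - vmin) / (vmax - vmin) else
    ifelse(grid$valid, 1, NA_real_)
  n_col <- 256L
  pal <- grDevices::hcl.colors(n_col, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  bin <- pmin(n_col, pmax(1L, 1L + as.integer(round(intensity * (n_col - 1L)))))
  nr <- nrow(v); nc <- ncol(v)
  img <- array(0, dim = c(nr, nc, 4))
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, bin], nr, nc)
    plane[!grid$valid] <- if (invalid == "zero") rgb[ch, 1] else 0
    img[, , ch] <- plane
  }
  alpha <- matrix(1, nr, nc)
  if (invalid == "transparent") alpha[!grid$valid] <- 0
  img[, , 4] <- alpha
  if (upsample > 1L) {
    ri <- rep(seq_len(nr), each = upsample)
    ci <- rep(seq_len(nc), each = upsample)
    img <- img[ri, ci, , drop = FALSE]
  }
  img
}

#' Write a rendered raster to PNG
#'
#' @param raster RGBA array from [render_grid()] or [overlay_photo()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(raster, path) {
  png::writePNG(raster, path)
  invisible(path)
}

#' Section photograph with plate registration
#'
#' Wraps a raster photograph of the sealed section together with the
#' similarity transform (per-axis scale + translation) mapping section
#' window coordinates (cell units) to photo pixels.
#'
#' @param image Numeric array (rows x cols x channels, values in \[0, 1\])
#'   or matrix (grayscale).
#' @param scale Numeric length-2, pixels per grid cell (row, col).
#' @param translation Numeric length-2, pixel offset (row, col) of grid
#'   cell (1, 1)'s top-left corner.
#' @return An object of class `section_photo`.
#' @export
section_photo <- function(image, scale = c(1, 1), translation = c(0, 0)) {
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3))
  stopifnot(length(dim(image)) == 3, all(scale > 0))
  structure(list(image = image, scale = as.numeric(scale),
                 translation = as.numeric(translation)),
            class = "section_photo")
}

#' Overlay a rendered grid on the section photograph
#'
#' Resamples the rendering into the photo frame (nearest neighbor, using
#' the photo's registration transform) and alpha-blends:
#' `alpha = 0` returns the photo, `alpha = 1` the rendering.
#'
#' @param grid A [value_grid()].
#' @param photo A [section_photo()].
#' @param alpha Blend weight of the rendering in \[0, 1\].
#' @param ... Passed to [render_grid()] (`upsample` is ignored; resampling
#'   is driven by the photo transform).
#' @return Numeric RGB array with the photo's dimensions.
#' @export
overlay_photo <- function(grid, photo, alpha = 0.5, ...) {
  stopifnot(inherits(grid, "value_grid"), inherits(photo, "section_photo"),
            alpha >= 0, alpha <= 1)
  rendered <- render_grid(grid, upsample = 1L, ...)
  ph <- photo$image
  np_r <- dim(ph)[1]; np_c <- dim(ph)[2]
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  # grid extent in photo pixels
  r_hi <- photo$translation[1] + nr * photo$scale[1]
  c_hi <- photo$translation[2] + nc * photo$scale[2]
  if (photo$translation[1] < 0 || photo$translation[2] < 0 ||
      r_hi > np_r + 1e-9 || c_hi > np_c + 1e-9) {
    stop("registration transform maps the grid outside the photo bounds",
         call. = FALSE)
  }
  out <- ph[, , 1:3, drop = FALSE]
  px_r <- seq_len(np_r); px_c <- seq_len(np_c)
  gr <- floor((px_r - 1 - photo$translation[1]) / photo$scale[1]) + 1
  gc <- floor((px_c - 1 - photo$translation[2]) / photo$scale[2]) + 1
  in_r <- gr >= 1 & gr <= nr
  in_c <- gc >= 1 & gc <= nc
  for (ch in 1:3) {
    ren_plane <- rendered[, , ch]
    a_plane <- rendered[, , 4]
    sub <- out[in_r, in_c, ch, drop = TRUE]
    ren <- ren_plane[gr[in_r], gc[in_c], drop = FALSE]
    a <- alpha * a_plane[gr[in_r], gc[in_c], drop = FALSE]
    out[in_r, in_c, ch] <- (1 - a) * sub + a * ren
  }
  out
}

#' Export a value grid
#'
#' TSV export writes `window_row`, `window_col`, `value`, `valid` (invalid
#' values as `NA`) and round-trips bit-exactly via [read_grid_tsv()].
#' Analyze 7.5 export writes the classic `.hdr`/`.img` pair (little-endian,
#' 32-bit float, invalid cells as NaN) for imaging viewers.
#'
#' @param grid A [value_grid()].
#' @param path Output path; for Analyze, the base name without extension.
#' @param format `"tsv"` (default) or `"analyze"`.
#' @return The path(s) written, invisibly.
#' @export
export_grid <- function(grid, path, format = c("tsv", "analyze")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy(grid), path)
    return(invisible(path))
  }
  write_analyze75(grid, path)
}

#' @rdname export_grid
#' @export
read_grid_tsv <- function(path, assay_id = "", normalization = "raw") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  nr <- max(tab$window_row); nc <- max(tab$window_col)
  values <- matrix(NA_real_, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  idx <- cbind(tab$window_row, tab$window_col)
  values[idx] <- tab$value
  mask[idx] <- tab$valid
  value_grid(values, mask, assay_id = assay_id, normalization = normalization)
}

#' @rdname export_grid
#' @param assay_id,normalization Tags for the re-read grid.
#' @export
write_analyze75 <- function(grid, path) {
  stopifnot(inherits(grid, "value_grid"))
  if (!requireNamespace("oro.nifti", quietly = TRUE)) {
    stop("Analyze 7.5 export requires the oro.nifti package", call. = FALSE)
  }
  base <- sub("\\.(hdr|img)$", "", path)
  v <- grid$values
  v[!grid$valid] <- NaN
  # Analyze stores x fastest; transpose so x = column index
  arr <- array(t(v), dim = c(ncol(v), nrow(v), 1L))
  aim <- oro.nifti::anlz(arr, datatype = 16L)  # 32-bit float
  oro.nifti::writeANALYZE(aim, base, gzipped = FALSE)
  invisible(paste0(base, c(".hdr", ".img")))
}

#' Heatmap of a value grid
#'
#' @param object A [value_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot value_grid
#' @export
autoplot.value_grid <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$window_col,
                                    y = -.data$window_row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$assay_id,
                  subtitle = paste("normalization:", object$normalization),
                  x = NULL, y = NULL, fill = "signal") +
    ggplot2::theme_minimal()
}
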