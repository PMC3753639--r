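#' Microtiter plate formats
#'
#' Constructs a plate-format descriptor for the three SLAS footprints used in
#' whole-body scanning PCR: the 1536-well extraction plate, the 384-well
#' analysis plate and the 96-well format. Well pitch defaults to ANSI/SLAS
#' geometry (96: 9 mm, 384: 4.5 mm, 1536: 2.25 mm).
#'
#' @param wells Total well count; one of 96, 384, 1536.
#' @param pitch Center-to-center well spacing in mm. Defaults per format.
#' @param a1_offset Numeric length-2, (x, y) position in mm of well A1's
#'   center relative to the plate origin.
#' @return An object of class `plate_format` with fields `name`, `n_rows`,
#'   `n_cols`, `pitch`, `a1_offset`.
#' @export
#' @examples
#' plate_format(384)
plate_format <- function(wells = 384, pitch = NULL, a1_offset = c(0, 0)) {
  dims <- switch(as.character(wells),
    "96"   = list(rows = 8L,  cols = 12L, pitch = 9),
    "384"  = list(rows = 16L, cols = 24L, pitch = 4.5),
    "1536" = list(rows = 32L, cols = 48L, pitch = 2.25),
    stop("unsupported plate format: ", wells, call. = FALSE)
  )
  pitch <- pitch %||% dims$pitch
  stopifnot(pitch > 0, length(a1_offset) == 2)
  structure(
    list(name = paste0("plate", wells), n_rows = dims$rows, n_cols = dims$cols,
         pitch = pitch, a1_offset = as.numeric(a1_offset)),
    class = "plate_format"
  )
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf("<plate_format> %s: %d rows x %d cols, pitch %.2f mm\n",
              x$name, x$n_rows, x$n_cols, x$pitch))
  invisible(x)
}

# spreadsheet-style row letters: A..Z, AA, AB, ... (1536 plates run A..AF)
row_index_to_letters <- function(i) {
  vapply(as.integer(i), function(k) {
    stopifnot(k >= 1L)
    out <- character(0)
    while (k > 0L) {
      rem <- (k - 1L) %% 26L
      out <- c(LETTERS[rem + 1L], out)
      k <- (k - 1L) %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

row_letters_to_index <- function(s) {
  vapply(toupper(s), function(x) {
    ch <- strsplit(x, "")[[1]]
    stopifnot(all(ch %in% LETTERS))
    sum((match(ch, LETTERS)) * 26L^rev(seq_along(ch) - 1L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse an alphanumeric well label
#'
#' Converts an A1-style label into 1-based row/column indices, validating
#' against the plate format. Row letters run A..Z then AA..AF for the 1536
#' format.
#'
#' @param label Character vector of labels, e.g. `"A1"`, `"AF48"`.
#' @param format A [plate_format()].
#' @return A tibble with columns `label` (canonical upper-case), `row`, `col`.
#' @export
#' @examples
#' parse_well_label("AF48", plate_format(1536))
parse_well_label <- function(label, format) {
  stopifnot(inherits(format, "plate_format"))
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  rows <- row_letters_to_index(vapply(m, `[`, character(1), 2L))
  cols <- as.integer(vapply(m, `[`, character(1), 3L))
  oob <- rows < 1 | rows > format$n_rows | cols < 1 | cols > format$n_cols
  if (any(oob)) {
    stop("well label(s) out of range for ", format$name, ": ",
         paste(label[oob], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(label = format_well_label(rows, cols),
                 row = as.integer(rows), col = cols)
}

#' Format row/column indices as a well label
#'
#' @param row,col 1-based integer vectors.
#' @return Character vector of A1-style labels.
#' @export
format_well_label <- function(row, col) {
  paste0(row_index_to_letters(row), as.integer(col))
}

#' Physical center of a well in plate coordinates
#'
#' @param row,col 1-based indices.
#' @param format A [plate_format()].
#' @return A tibble with columns `x`, `y` in mm (`x` grows with column,
#'   `y` with row).
#' @export
well_center <- function(row, col, format) {
  stopifnot(inherits(format, "plate_format"),
            all(row >= 1 & row <= format$n_rows),
            all(col >= 1 & col <= format$n_cols))
  tibble::tibble(
    x = format$a1_offset[1] + (as.numeric(col) - 1) * format$pitch,
    y = format$a1_offset[2] + (as.numeric(row) - 1) * format$pitch
  )
}

#' Section matrix: the extraction-well mask on the 1536-well plate
#'
#' A section matrix records which wells of the 1536-well extraction plate lie
#' under the whole-body section, together with a deterministic row-major
#' enumeration of those wells (`sample_index`, 1-based). The bounding window
#' (`window_row`/`window_col`, 1-based within the window) is retained for
#' spatial reconstruction.
#'
#' @param cells A data frame with columns `row`, `col` (1-based plate
#'   indices) marking extraction wells.
#' @param format A [plate_format()], normally `plate_format(1536)`.
#' @return An object of class `section_matrix`: a list with `format`,
#'   `cells` (tibble: `row`, `col`, `well_label`, `window_row`, `window_col`,
#'   `sample_index`) and `window` (list: `row0`, `col0`, `n_rows`, `n_cols`).
#' @export
section_matrix <- function(cells, format = plate_format(1536)) {
  stopifnot(inherits(format, "plate_format"),
            all(c("row", "col") %in% names(cells)))
  cells <- dplyr::as_tibble(cells[, c("row", "col")])
  cells$row <- as.integer(cells$row)
  cells$col <- as.integer(cells$col)
  cells <- dplyr::distinct(cells)
  if (nrow(cells) == 0L) stop("section matrix has no cells", call. = FALSE)
  if (any(cells$row < 1 | cells$row > format$n_rows |
          cells$col < 1 | cells$col > format$n_cols)) {
    stop("section cells outside ", format$name, " bounds", call. = FALSE)
  }
  row0 <- min(cells$row); col0 <- min(cells$col)
  cells <- cells |>
    dplyr::arrange(.data$row, .data$col) |>
    dplyr::mutate(
      well_label = format_well_label(.data$row, .data$col),
      window_row = .data$row - row0 + 1L,
      window_col = .data$col - col0 + 1L,
      sample_index = dplyr::row_number()
    )
  structure(
    list(format = format, cells = cells,
         window = list(row0 = row0, col0 = col0,
                       n_rows = max(cells$window_row),
                       n_cols = max(cells$window_col))),
    class = "section_matrix"
  )
}

#' @export
print.section_matrix <- function(x, ...) {
  cat(sprintf("<section_matrix> %d extraction wells on %s (window %d x %d)\n",
              nrow(x$cells), x$format$name, x$window$n_rows, x$window$n_cols))
  invisible(x)
}

# Deterministic stylized sagittal mouse silhouette on a 22-row x 33-col
# window. Shapes (head/body ellipses, ear, tail, legs) are dilated or eroded
# at the boundary, in a fixed order, until the mask holds exactly `n_cells`.
default_silhouette_mask <- function(n_cells = 363L, n_rows = 22L, n_cols = 33L) {
  inside <- function(r, c, cr, cc, rr, rc) ((r - cr) / rr)^2 + ((c - cc) / rc)^2 <= 1
  m <- matrix(FALSE, n_rows, n_cols)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    m[r, c] <- inside(r, c, 8.5, 5, 5, 4.5) ||      # head
      inside(r, c, 11.5, 18, 7.5, 11.5) ||          # trunk
      (r >= 3 && r <= 4 && c >= 6 && c <= 7) ||     # ear
      (r >= 12 && r <= 13 && c >= 29 && c <= 33) || # tail
      (r >= 18 && r <= 21 && c >= 12 && c <= 13) || # front leg
      (r >= 18 && r <= 22 && c >= 24 && c <= 26)    # hind leg
  }
  neighbor_count <- function(mask, r, c) {
    sum(c(r > 1 && mask[r - 1L, c], r < nrow(mask) && mask[r + 1L, c],
          c > 1 && mask[r, c - 1L], c < ncol(mask) && mask[r, c + 1L]))
  }
  while (sum(m) < n_cells) {
    # grow: unmasked cells touching the mask, most-supported first, row-major
    cand <- which(!m, arr.ind = TRUE)
    nb <- apply(cand, 1L, function(rc) neighbor_count(m, rc[1], rc[2]))
    cand <- cand[nb > 0, , drop = FALSE]; nb <- nb[nb > 0]
    ord <- order(-nb, cand[, 1], cand[, 2])
    pick <- cand[ord[1], ]
    m[pick[1], pick[2]] <- TRUE
  }
  while (sum(m) > n_cells) {
    # shave: masked cells with the fewest masked neighbors, row-major
    cand <- which(m, arr.ind = TRUE)
    nb <- apply(cand, 1L, function(rc) neighbor_count(m, rc[1], rc[2]))
    ord <- order(nb, cand[, 1], cand[, 2])
    pick <- cand[ord[1], ]
    m[pick[1], pick[2]] <- FALSE
  }
  m
}

# Tissue labels over the silhouette window; organ shapes are fixed rectangles
# or ellipses assigned in priority order, remaining body cells are muscle.
default_tissue_labels <- function(mask) {
  inside <- function(r, c, cr, cc, rr, rc) ((r - cr) / rr)^2 + ((c - cc) / rc)^2 <= 1
  lab <- matrix(NA_character_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    lab[r, c] <-
      if (inside(r, c, 8, 5, 2.4, 2.7)) "brain"
      else if (r == 7 && c >= 10 && c <= 26) "spinal_cord"
      else if (r >= 9 && r <= 11 && c >= 10 && c <= 13) "lung"
      else if (r >= 12 && r <= 13 && c >= 10 && c <= 12) "heart"
      else if (r >= 12 && r <= 13 && c == 13) "blood"
      else if (r >= 10 && r <= 14 && c >= 14 && c <= 18) "liver"
      else if (r >= 9 && r <= 10 && c >= 19 && c <= 20) "spleen"
      else if (r >= 11 && r <= 13 && c >= 20 && c <= 22) "kidney"
      else if (r >= 14 && r <= 17 && c >= 17 && c <= 25) "GI"
      else "muscle"
  }
  lab
}

#' Default 363-well section matrix
#'
#' The packaged stylized mouse-silhouette template: exactly 363 extraction
#' wells on a 22 x 33 window of the 1536-well plate, anchored at plate row 6,
#' column 8. The mask and its row-major enumeration are deterministic, so
#' exports built on it are reproducible bit-for-bit.
#'
#' @return A [section_matrix()] with 363 cells.
#' @export
#' @examples
#' sm <- build_default_section_matrix()
#' nrow(sm$cells)
build_default_section_matrix <- function() {
  mask <- default_silhouette_mask()
  idx <- which(mask, arr.ind = TRUE)
  section_matrix(
    data.frame(row = idx[, 1] + 5L, col = idx[, 2] + 7L),
    format = plate_format(1536)
  )
}

#' Map a section matrix onto a 384-well analysis plate
#'
#' Lysates from the extraction wells are transferred to a 384-well qPCR plate.
#' Samples fill the analysis plate in column-major order (A1, B1, ..., P1,
#' A2, ...) following the section's row-major sample enumeration; the default
#' policy then allocates 20 reference wells (for standards or reference
#' samples) and leaves one well blank, which accounts for all 384 wells when
#' 363 samples are loaded.
#'
#' @param matrix A [section_matrix()].
#' @param n_reference Number of reference wells (default 20).
#' @param n_blank Number of blank wells (default 1).
#' @param format A [plate_format()] for the analysis plate.
#' @return A tibble (the analysis layout) with columns `well_label`, `row`,
#'   `col`, `role` (`"sample"`, `"reference"`, `"blank"`), `sample_index`
#'   (NA for non-sample wells).
#' @export
map_to_analysis_plate <- function(matrix, n_reference = 20L, n_blank = 1L,
                                  format = plate_format(384)) {
  stopifnot(inherits(matrix, "section_matrix"))
  n_samples <- nrow(matrix$cells)
  capacity <- format$n_rows * format$n_cols
  if (n_samples > capacity - n_reference - n_blank) {
    stop(sprintf("%d samples exceed capacity of %s with %d reference and %d blank wells",
                 n_samples, format$name, n_reference, n_blank), call. = FALSE)
  }
  # column-major fill order over the analysis plate
  fill <- tidyr::expand_grid(col = seq_len(format$n_cols),
                             row = seq_len(format$n_rows))
  roles <- c(rep("sample", n_samples),
             rep("reference", n_reference),
             rep("blank", n_blank))
  roles <- c(roles, rep("blank", capacity - length(roles)))
  fill |>
    dplyr::mutate(
      well_label = format_well_label(.data$row, .data$col),
      role = roles[seq_len(capacity)],
      sample_index = dplyr::if_else(.data$role == "sample",
                                    dplyr::row_number(), NA_integer_)
    ) |>
    dplyr::select("well_label", "row", "col", "role", "sample_index")
}

#' Join analysis-plate records back to section cells
#'
#' Inverse of the sample mapping: attaches the section-window coordinates of
#' each sample well to a layout (or to records keyed by `well_label`).
#'
#' @param layout A layout tibble from [map_to_analysis_plate()].
#' @param matrix The [section_matrix()] the layout was built from.
#' @return The layout restricted to sample wells, with `window_row`,
#'   `window_col` and `section_label` columns appended.
#' @export
layout_to_section <- function(layout, matrix) {
  stopifnot(inherits(matrix, "section_matrix"))
  layout |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::inner_join(
      matrix$cells |>
        dplyr::select("sample_index", "window_row", "window_col",
                      section_label = "well_label"),
      by = "sample_index"
    )
}

#' Read / write a section matrix as TSV
#'
#' The on-disk form has columns `row_label`, `col_index`, `role`; roles other
#' than `"sample"` are ignored on read.
#'
#' @param matrix A [section_matrix()].
#' @param path File path.
#' @return `write_section_matrix()` returns `path` invisibly;
#'   `read_section_matrix()` returns a [section_matrix()].
#' @export
write_section_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "section_matrix"))
  matrix$cells |>
    dplyr::transmute(row_label = row_index_to_letters(.data$row),
                     col_index = .data$col, role = "sample") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_section_matrix
#' @param format Plate format for the read matrix.
#' @export
read_section_matrix <- function(path, format = plate_format(1536)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("row_label", "col_index", "role") %in% names(tab)))
  tab <- tab[tab$role == "sample", ]
  section_matrix(
    data.frame(row = row_letters_to_index(tab$row_label),
               col = as.integer(tab$col_index)),
    format = format
  )
}

#' Read / write an analysis layout as TSV
#'
#' Columns: `well_label`, `role`, `sample_index`.
#'
#' @param layout A layout tibble from [map_to_analysis_plate()].
#' @param path File path.
#' @param format Plate format used to recover row/col on read.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(layout[, c("well_label", "role", "sample_index")], path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path, format = plate_format(384)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("well_label", "role", "sample_index") %in% names(tab)))
  addr <- parse_well_label(tab$well_label, format)
  tibble::tibble(well_label = addr$label, row = addr$row, col = addr$col,
                 role = tab$role, sample_index = as.integer(tab$sample_index))
}
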