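test_that("record deconvolution inverts the plate mapping", {
  sm <- build_default_section_matrix()
  lay <- map_to_analysis_plate(sm)
  sample_wells <- lay$well_label[lay$role == "sample"]
  recs <- tibble::tibble(well = sample_wells,
                         value = as.numeric(lay$sample_index[lay$role == "sample"]))
  grid <- grid_from_records(recs, sm, lay, assay_id = "perm")
  expect_equal(sum(grid$valid), 363L)
  # every cell carries its own sample rank
  got <- grid$values[cbind(sm$cells$window_row, sm$cells$window_col)]
  expect_equal(got, as.numeric(sm$cells$sample_index))
  # shuffled record order changes nothing
  set.seed(5)
  grid2 <- grid_from_records(recs[sample(nrow(recs)), ], sm, lay)
  expect_identical(grid2$values, grid$values)
  # one missing record leaves exactly one invalid cell at the mapped spot
  drop_well <- sample_wells[100]
  grid3 <- grid_from_records(recs[recs$well != drop_well, ], sm, lay)
  expect_equal(sum(grid3$valid), 362L)
  missing_cell <- layout_to_section(lay, sm)
  missing_cell <- missing_cell[missing_cell$well_label == drop_well, ]
  expect_false(grid3$valid[missing_cell$window_row, missing_cell$window_col])
})

test_that("reference-well records never reach the grid", {
  sm <- build_default_section_matrix()
  lay <- map_to_analysis_plate(sm)
  ref_wells <- lay$well_label[lay$role == "reference"]
  recs <- tibble::tibble(well = c(lay$well_label[lay$role == "sample"][1], ref_wells),
                         value = 1)
  grid <- grid_from_records(recs, sm, lay)
  expect_equal(sum(grid$valid), 1L)
})

test_that("rendering is deterministic, block-structured and scale-equivariant", {
  grid <- small_grid()
  r1 <- render_grid(grid, upsample = 1L)
  r2 <- render_grid(grid, upsample = 1L)
  expect_identical(r1, r2)
  # upsample 4: each cell becomes a 4x4 constant block
  r4 <- render_grid(grid, upsample = 4L)
  expect_equal(dim(r4), c(8L, 12L, 4L))
  block <- r4[1:4, 1:4, 1]
  expect_true(all(block == block[1, 1]))
  # invalid cells are transparent; validity is untouched by colormap choice
  expect_equal(r1[2, 3, 4], 0)
  r_mag <- render_grid(grid, colormap = "Inferno", upsample = 1L)
  expect_identical(r_mag[, , 4], r1[, , 4])
  # zero policy paints invalid cells opaque bottom-of-scale
  r0 <- render_grid(grid, invalid = "zero", upsample = 1L)
  expect_equal(r0[2, 3, 4], 1)
  # multiplying all values by k > 0 yields the identical image
  scaled <- value_grid(grid$values * 17, grid$valid)
  expect_identical(render_grid(scaled, upsample = 1L), r1)
  # constant grids render a single uniform color
  const <- value_grid(matrix(3, 2, 2), matrix(TRUE, 2, 2))
  rc <- render_grid(const, upsample = 1L)
  expect_equal(length(unique(as.vector(rc[, , 1]))), 1L)
  empty <- value_grid(matrix(NA_real_, 2, 2), matrix(FALSE, 2, 2))
  expect_error(render_grid(empty), "no valid cells")
})

test_that("grid TSV exports round-trip bit-exactly with NA sentinels", {
  grid <- small_grid()
  path <- withr::local_tempfile(fileext = ".tsv")
  export_grid(grid, path)
  back <- read_grid_tsv(path, assay_id = "toy")
  expect_identical(back$values, grid$values)
  expect_identical(back$valid, grid$valid)
})

test_that("Analyze 7.5 export writes a well-formed header and NaN-coded image", {
  grid <- small_grid()
  base <- file.path(withr::local_tempdir(), "grid")
  paths <- write_analyze75(grid, base)
  hdr <- readBin(paths[1], "raw", n = 400)
  expect_length(hdr, 348L)
  expect_equal(readBin(hdr[1:4], "integer", size = 4, endian = "little"), 348L)
  dims <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = "little")
  expect_equal(dims[2:3], c(ncol(grid$values), nrow(grid$values)))
  img <- readBin(paths[2], "numeric", n = 6, size = 4, endian = "little")
  expect_length(img, 6L)
  # row-major emission: x runs fastest
  expect_equal(img[1:3], grid$values[1, ])
  expect_true(is.nan(img[6]))
})

test_that("PNG rendering writes deterministic bytes", {
  grid <- small_grid()
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_render_png(render_grid(grid), p1)
  write_render_png(render_grid(grid), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("photo overlay respects the blend limits and registration bounds", {
  grid <- small_grid()
  photo_img <- array(stats::runif(2 * 3 * 3 * 16), dim = c(8, 12, 3))
  photo <- section_photo(photo_img, scale = c(4, 4))
  out0 <- overlay_photo(grid, photo, alpha = 0)
  expect_equal(out0, photo_img)
  out1 <- overlay_photo(grid, photo, alpha = 1)
  rendered <- render_grid(grid, upsample = 4L)
  # opaque (valid) cells show pure rendering at alpha 1
  expect_equal(out1[1, 1, 1], rendered[1, 1, 1])
  # invalid cells always show the photo
  expect_equal(out1[5:8, 9:12, ], photo_img[5:8, 9:12, ])
  small_photo <- section_photo(array(0, dim = c(4, 4, 3)), scale = c(4, 4))
  expect_error(overlay_photo(grid, small_photo, alpha = 0.5), "outside")
})

test_that("a self-consistent silhouette photo aligns with the rendered section", {
  sec <- make_default_section()
  sm <- sec$matrix
  # photograph synthesized from the same silhouette at 1 px per cell
  photo_img <- matrix(0, sm$window$n_rows, sm$window$n_cols)
  photo_img[cbind(sec$cells$window_row, sec$cells$window_col)] <- 0.5
  photo <- section_photo(photo_img)
  lay <- map_to_analysis_plate(sm)
  sample_wells <- lay$well_label[lay$role == "sample"]
  recs <- tibble::tibble(well = sample_wells, value = 1)
  grid <- grid_from_records(recs, sm, lay)
  out <- overlay_photo(grid, photo, alpha = 1)
  lit <- out[, , 1] != photo_img | out[, , 2] != photo_img | out[, , 3] != photo_img
  mask <- matrix(FALSE, sm$window$n_rows, sm$window$n_cols)
  mask[cbind(sec$cells$window_row, sec$cells$window_col)] <- TRUE
  # rendered footprint coincides exactly with the section mask
  expect_identical(lit, mask)
})

test_that("value grids tidy and plot", {
  grid <- small_grid()
  tab <- tidy(grid)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$valid), 5L)
  p <- autoplot(grid)
  expect_s3_class(p, "ggplot")
})
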