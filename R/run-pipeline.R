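#' Run configuration
#'
#' Bundles every tunable of a reproducible run. Defaults equal the
#' protocol constants used throughout the package: TaqMan/genomic Ct noise
#' cutoff 35 at 40 cycles, small-RNA/CL-qPCR censoring at 50 cycles with
#' linear-range filtering, TRS default length 8, forward/RT overlap cap 3,
#' minimum gene-specific length 12, truncation tolerance 2. Round-trips
#' losslessly through YAML.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed funnelling all randomness.
#' @param ct_cutoff TaqMan/genomic noise threshold.
#' @param trs_length,max_overlap,min_specific Primer-design defaults.
#' @param truncation_tolerance Simulator detection tolerance (nt).
#' @param reference_assay Assay id used for normalization.
#' @param normalization `"quantity"` or `"delta_ct"`.
#' @param noise_sd Simulator Ct noise.
#' @param knockdown,treatment Dosing-scenario settings.
#' @param upsample,colormap Render settings.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = ".", seed = 1L, ct_cutoff = 35,
                       trs_length = 8L, max_overlap = 3L, min_specific = 12L,
                       truncation_tolerance = 2L,
                       reference_assay = "genomic_18s",
                       normalization = "quantity", noise_sd = 0.2,
                       knockdown = 0.9, treatment = "vehicle",
                       upsample = 8L, colormap = "viridis") {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), ct_cutoff = ct_cutoff,
         trs_length = as.integer(trs_length),
         max_overlap = as.integer(max_overlap),
         min_specific = as.integer(min_specific),
         truncation_tolerance = as.integer(truncation_tolerance),
         reference_assay = reference_assay, normalization = normalization,
         noise_sd = noise_sd, knockdown = knockdown, treatment = treatment,
         upsample = as.integer(upsample), colormap = colormap),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

provenance_record <- function(config, extra = list()) {
  c(list(package = "wbspcr",
         version = as.character(utils::packageVersion("wbspcr")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = unclass(config)),
    extra)
}

#' Simulate a whole-body scan run to disk
#'
#' Writes the plate-reader-dialect records CSV for the default section and
#' atlas under `config`, plus ground-truth section/atlas/layout files and a
#' provenance record, so a scan run can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @return Named list of written paths, invisibly; the records tibble as
#'   attribute `"records"`.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  section <- make_default_section(seed = config$seed)
  atlas <- default_expression_atlas()
  if (config$treatment == "amo") {
    atlas <- apply_scenario(atlas, dose_scenario("amo",
                                                 knockdown = config$knockdown))
  }
  model <- assay_model(noise_sd = config$noise_sd,
                       truncation_tolerance = config$truncation_tolerance)
  layout <- map_to_analysis_plate(section$matrix)
  records <- simulate_ct(section, atlas, model, layout, seed = config$seed)
  paths <- list(
    records = file.path(config$out_dir, "records.csv"),
    matrix = file.path(config$out_dir, "section_matrix.tsv"),
    layout = file.path(config$out_dir, "layout.tsv"),
    atlas = file.path(config$out_dir, "atlas_truth.tsv"),
    section = file.path(config$out_dir, "section_truth.tsv"),
    provenance = file.path(config$out_dir, "provenance.json")
  )
  write_plate_ct(records, paths$records)
  write_section_matrix(section$matrix, paths$matrix)
  write_layout(layout, paths$layout)
  readr::write_tsv(atlas, paths$atlas)
  readr::write_tsv(section$cells, paths$section)
  jsonlite::write_json(provenance_record(config, list(step = "simulate")),
                       paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  attr(paths, "records") <- records
  invisible(paths)
}

#' Reconstruct grids and images from records
#'
#' The scan step of the pipeline: reads (or accepts) amplification records,
#' fits standard curves for linear-range-filtered chemistries from a
#' simulated calibration series, applies the noise filters, quantifies,
#' normalizes every non-reference assay against the reference assay, and
#' writes one grid TSV and one PNG per assay plus a noise log and
#' provenance record.
#'
#' @param records An [amplification_records()] tibble or a path readable by
#'   [read_plate_ct()].
#' @param matrix A [section_matrix()] or path to its TSV.
#' @param layout A layout tibble or path to its TSV.
#' @param config A [run_config()].
#' @param normalize Normalize against `config$reference_assay`? (default
#'   TRUE).
#' @return Named list of `value_grid` objects (one per assay), invisibly;
#'   written paths as attribute `"paths"`, the noise log as attribute
#'   `"noise_log"`.
#' @export
run_scan <- function(records, matrix, layout, config = run_config(),
                     normalize = TRUE) {
  if (is.character(records)) records <- read_plate_ct(records)
  if (is.character(matrix)) matrix <- read_section_matrix(matrix)
  if (is.character(layout)) layout <- read_layout(layout)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (normalize && !(config$reference_assay %in% records$assay_id)) {
    stop("normalization requested but reference assay '",
         config$reference_assay, "' has no records", call. = FALSE)
  }
  model <- assay_model(noise_sd = config$noise_sd)
  needs_curve <- unique(records$assay_id[records$chemistry %in%
                                           c("smallrna", "clqpcr")])
  curves <- lapply(stats::setNames(needs_curve, needs_curve), function(id) {
    chem <- records$chemistry[records$assay_id == id][1]
    fit_standard_curve(simulate_dilution_series(model, chemistry = chem,
                                                seed = config$seed))
  })
  records <- apply_noise_filters(records, curves, ct_cutoff = config$ct_cutoff)
  records <- quantify_records(records, curves)
  noise_log <- records |>
    dplyr::filter(.data$noise_flag) |>
    dplyr::select("well", "assay_id", "ct", "noise_reason")
  assays <- setdiff(unique(records$assay_id),
                    if (normalize) config$reference_assay else character(0))
  ref <- records[records$assay_id == config$reference_assay, ]
  grids <- lapply(stats::setNames(assays, assays), function(id) {
    tgt <- records[records$assay_id == id, ]
    if (normalize) {
      norm <- normalize_to_reference(tgt, ref, method = config$normalization)
      grid_from_records(norm, matrix, layout, value = "ratio",
                        valid = "valid", assay_id = id,
                        normalization = config$reference_assay)
    } else {
      grid_from_records(tgt, matrix, layout, value = "quantity",
                        assay_id = id, normalization = "raw")
    }
  })
  paths <- character(0)
  for (id in names(grids)) {
    tsv <- file.path(config$out_dir, paste0("grid_", id, ".tsv"))
    png_path <- file.path(config$out_dir, paste0("grid_", id, ".png"))
    export_grid(grids[[id]], tsv)
    write_render_png(render_grid(grids[[id]], colormap = config$colormap,
                                 upsample = config$upsample), png_path)
    paths <- c(paths, tsv, png_path)
  }
  log_path <- file.path(config$out_dir, "noise_log.tsv")
  readr::write_tsv(noise_log, log_path)
  prov_path <- file.path(config$out_dir, "provenance_scan.json")
  jsonlite::write_json(provenance_record(config, list(step = "scan")),
                       prov_path, auto_unbox = TRUE, pretty = TRUE)
  attr(grids, "paths") <- c(paths, log_path, prov_path)
  attr(grids, "noise_log") <- noise_log
  invisible(grids)
}

#' Design assays for templates in a sequence file
#'
#' Runs the small-RNA designer (and optionally the CL-qPCR ligator
#' designer) over every template in a FASTA / plain-text file, writes a TSV
#' design table and a human-readable validation report.
#'
#' @param path Sequence file (see [read_templates()]).
#' @param out_dir Output directory.
#' @param ligators Also design CL-qPCR ligator pairs? (default FALSE).
#' @param ... Passed to [design_assay()] / [design_ligators()].
#' @return A list with `designs`, `validations`, `all_pass`; written paths
#'   as attribute `"paths"`.
#' @export
run_design <- function(path, out_dir = ".", ligators = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  templates <- read_templates(path)
  designs <- lapply(templates, function(t) {
    d <- list(assay = design_assay(t))
    if (ligators) d$ligators <- design_ligators(t, ...)
    d
  })
  validations <- lapply(designs, function(d) {
    v <- list(assay = validate_assay(d$assay))
    if (!is.null(d$ligators)) v$ligators <- validate_assay(d$ligators)
    v
  })
  all_pass <- all(vapply(validations, function(v)
    all(vapply(v, validation_passed, logical(1))), logical(1)))
  design_tab <- dplyr::bind_rows(lapply(names(designs), function(nm) {
    tab <- tidy(designs[[nm]]$assay)
    if (!is.null(designs[[nm]]$ligators)) {
      tab <- dplyr::bind_rows(tab, tidy(designs[[nm]]$ligators))
    }
    dplyr::mutate(tab, name = nm, .before = 1)
  }))
  tsv <- file.path(out_dir, "designs.tsv")
  readr::write_tsv(design_tab, tsv)
  report <- file.path(out_dir, "design_report.txt")
  lines <- unlist(lapply(names(validations), function(nm) {
    v <- validations[[nm]]
    c(paste0("== ", nm, " =="),
      unlist(lapply(names(v), function(part) {
        tab <- v[[part]]
        paste0("  [", ifelse(tab$pass, "PASS", "FAIL"), "] ", part, "/",
               tab$rule, ": ", tab$detail)
      })))
  }))
  writeLines(lines, report)
  out <- list(designs = designs, validations = validations,
              all_pass = all_pass)
  attr(out, "paths") <- c(tsv, report)
  out
}
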