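#' Cycle maximum for a qPCR chemistry
#'
#' One-step TaqMan (mRNA/rRNA) and genomic 18S reactions run 40 cycles;
#' the two-step small-RNA RT-qPCR and CL-qPCR reactions run 50 cycles.
#'
#' @param chemistry Character vector: `"taqman"`, `"genomic"`, `"smallrna"`,
#'   `"clqpcr"`.
#' @return Integer vector of cycle maxima.
#' @export
cycle_max_for <- function(chemistry) {
  lookup <- c(taqman = 40L, genomic = 40L, smallrna = 50L, clqpcr = 50L)
  bad <- !chemistry %in% names(lookup)
  if (any(bad)) stop("unknown chemistry: ",
                     paste(unique(chemistry[bad]), collapse = ", "), call. = FALSE)
  unname(lookup[chemistry])
}

#' Build an amplification record table
#'
#' Canonicalizes per-well qPCR results into the tibble the rest of the
#' pipeline consumes. Censored wells (no amplification within the cycle
#' maximum, "Undetermined" in plate-reader exports) carry `censored = TRUE`
#' and `ct = NA`.
#'
#' @param well Well labels on the analysis plate.
#' @param assay_id Assay identifier per record.
#' @param ct Threshold-cycle values; `NA` for censored wells.
#' @param chemistry Chemistry per record (recycled).
#' @param censored Logical; defaults to `is.na(ct)`.
#' @return A tibble with columns `well`, `assay_id`, `chemistry`, `ct`,
#'   `censored`, `cycle_max`.
#' @export
amplification_records <- function(well, assay_id, ct,
                                  chemistry = "smallrna",
                                  censored = is.na(ct)) {
  out <- tibble::tibble(
    well = as.character(well), assay_id = as.character(assay_id),
    chemistry = chemistry, ct = as.numeric(ct), censored = censored
  )
  out$cycle_max <- cycle_max_for(out$chemistry)
  bad <- !out$censored & (is.na(out$ct) | out$ct > out$cycle_max)
  if (any(bad)) {
    stop("non-censored Ct above the cycle maximum in ", sum(bad), " record(s)",
         call. = FALSE)
  }
  out
}

#' Geometric dilution series
#'
#' Serial dilution from `top` down to the first value at or below `bottom`
#' (inclusive). The canonical small-RNA standard series runs from 10 ng/ul
#' down to 1 zg/ul (1 zg/ul = 1e-12 ng/ul), i.e. 14 ten-fold points; the
#' antagomir series runs 8 ng/ul down to 0.8 zg/ul.
#'
#' @param top,bottom Highest and lowest concentration (same unit, ng/ul by
#'   convention).
#' @param fold Dilution factor between adjacent points (default 10).
#' @return Numeric vector of concentrations, strictly decreasing.
#' @export
#' @examples
#' length(make_dilution_series())  # 14
make_dilution_series <- function(top = 10, bottom = 1e-12, fold = 10) {
  stopifnot(top > 0, bottom > 0, top >= bottom, fold > 1)
  n <- ceiling(log(top / bottom) / log(fold) - 1e-9) + 1
  top / fold^(seq_len(n) - 1)
}

#' Fit a log-linear qPCR standard curve
#'
#' Fits mean Ct against log10(concentration) by least squares over the
#' detected linear range: the longest contiguous run of at least
#' `min_points` dilution points whose fit has R^2 >= `min_r2` and every
#' point residual within `max_resid` Ct. Ties prefer the run starting at the
#' highest concentration. Amplification efficiency is `10^(-1/slope) - 1`;
#' the limit of detection (LOD) is the lowest concentration detected
#' (non-censored) in at least `lod_fraction` of replicates, contiguously
#' from the top of the series.
#'
#' @param series A tibble with columns `concentration`, `ct`, `censored`
#'   (one row per replicate measurement), e.g. from
#'   [simulate_dilution_series()].
#' @param max_resid Maximum absolute residual per point in Ct (default 0.5).
#' @param min_r2 Minimum R^2 of the accepted fit (default 0.98).
#' @param min_points Minimum points in the linear range (default 4).
#' @param lod_fraction Fraction of replicates that must be detected at the
#'   LOD (default 1, i.e. all).
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `linear_range` (length-2
#'   numeric, low/high), `lod`, `n_points`, `points` (the per-concentration
#'   summary tibble).
#' @export
fit_standard_curve <- function(series, max_resid = 0.5, min_r2 = 0.98,
                               min_points = 4L, lod_fraction = 1) {
  stopifnot(all(c("concentration", "ct", "censored") %in% names(series)))
  pts <- series |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_detected = sum(!.data$censored),
      mean_ct = if (any(!.data$censored)) mean(.data$ct[!.data$censored]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$concentration))
  usable <- which(pts$n_detected > 0L)
  if (length(usable) < min_points) {
    stop("fewer than ", min_points, " non-censored concentration points",
         call. = FALSE)
  }
  fit_run <- function(idx) {
    d <- pts[idx, ]
    fit <- stats::lm(mean_ct ~ log10(concentration), data = d)
    # noiseless calibrations fit exactly; the lm summary warning is expected
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(fit = fit, r2 = r2,
         max_abs_resid = max(abs(stats::residuals(fit))))
  }
  best <- NULL
  for (len in seq.int(length(usable), min_points)) {
    for (start in seq_len(length(usable) - len + 1L)) {
      idx <- usable[seq.int(start, start + len - 1L)]
      if (any(diff(idx) != 1L)) next  # contiguous in the dilution order
      cand <- fit_run(idx)
      if (cand$r2 >= min_r2 && cand$max_abs_resid <= max_resid) {
        best <- c(cand, list(idx = idx))
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    stop("no contiguous run of >= ", min_points,
         " points satisfies the linearity thresholds", call. = FALSE)
  }
  coefs <- stats::coef(best$fit)
  slope <- unname(coefs[2]); intercept <- unname(coefs[1])
  if (slope >= 0) stop("fitted slope is non-negative; not a dilution response",
                       call. = FALSE)
  # LOD: detection fraction criterion, contiguous from the top concentration
  frac <- pts$n_detected / pts$n
  ok <- frac >= lod_fraction
  lod <- NA_real_
  if (any(ok)) {
    run_end <- which(!ok)[1]
    last_ok <- if (is.na(run_end)) nrow(pts) else run_end - 1L
    if (last_ok >= 1L && ok[1]) lod <- pts$concentration[last_ok]
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = best$r2,
         efficiency = 10^(-1 / slope) - 1,
         linear_range = c(min(pts$concentration[best$idx]),
                          max(pts$concentration[best$idx])),
         lod = lod, n_points = length(best$idx), points = pts),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> Ct = %.3f %+.4f x log10(conc); ",
                     "eff %.1f%%, R2 %.4f\n"),
              x$intercept, x$slope, 100 * x$efficiency, x$r_squared))
  cat(sprintf("  linear range [%g, %g], LOD %g (%d points)\n",
              x$linear_range[1], x$linear_range[2], x$lod, x$n_points))
  invisible(x)
}

#' @rdname tidy-designs
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' Glance at a fitted standard curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return One-row tibble with fit summaries.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 linear_low = x$linear_range[1], linear_high = x$linear_range[2],
                 lod = x$lod, n_points = x$n_points)
}

#' Back-compute concentration from Ct
#'
#' Inverse of the standard-curve calibration:
#' `concentration = 10^((ct - intercept) / slope)`.
#'
#' @param ct Numeric vector of threshold cycles (`NA` for censored wells).
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of concentrations in curve units; `NA` where `ct`
#'   is `NA`.
#' @export
quantify_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Apply the per-chemistry noise filters
#'
#' TaqMan and genomic-18S records are noise when censored or when Ct exceeds
#' 35 (strictly; Ct = 35.0 is retained). Small-RNA RT-qPCR and CL-qPCR
#' records are noise when censored or when the back-computed concentration
#' falls outside the linear range of the assay's standard curve. The
#' operation is idempotent: it recomputes flags from the raw columns.
#'
#' @param records An [amplification_records()] tibble.
#' @param curves Named list of [fit_standard_curve()] objects keyed by
#'   `assay_id`; required for every small-RNA/CL-qPCR assay present.
#' @param ct_cutoff TaqMan/genomic noise threshold (default 35).
#' @return `records` with logical `noise_flag` and character `noise_reason`
#'   columns (reason `NA` when retained).
#' @export
apply_noise_filters <- function(records, curves = list(), ct_cutoff = 35) {
  stopifnot(all(c("assay_id", "chemistry", "ct", "censored") %in% names(records)))
  needs_curve <- unique(records$assay_id[records$chemistry %in% c("smallrna", "clqpcr")])
  missing <- setdiff(needs_curve, names(curves))
  if (length(missing) > 0L) {
    stop("no standard curve supplied for linear-range-filtered assay(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  flag <- logical(n); reason <- rep(NA_character_, n)
  flag[records$censored] <- TRUE
  reason[records$censored] <- "censored"
  ct_rule <- records$chemistry %in% c("taqman", "genomic") & !records$censored
  hi <- ct_rule & records$ct > ct_cutoff
  flag[hi] <- TRUE; reason[hi] <- sprintf("ct_above_%g", ct_cutoff)
  lin_rule <- which(records$chemistry %in% c("smallrna", "clqpcr") & !records$censored)
  for (i in lin_rule) {
    curve <- curves[[records$assay_id[i]]]
    conc <- quantify_ct(records$ct[i], curve)
    if (conc < curve$linear_range[1] || conc > curve$linear_range[2]) {
      flag[i] <- TRUE
      reason[i] <- "outside_linear_range"
    }
  }
  records$noise_flag <- flag
  records$noise_reason <- reason
  records
}

#' Quantify filtered records against their standard curves
#'
#' Adds a `quantity` column (curve units); noise-flagged or censored records
#' get `NA`. TaqMan/genomic records without a curve fall back to the
#' exponential Ct transform `2^(-ct)`, a relative quantity sufficient for
#' ratio-based normalization.
#'
#' @inheritParams apply_noise_filters
#' @return `records` with a `quantity` column appended.
#' @export
quantify_records <- function(records, curves = list()) {
  if (!("noise_flag" %in% names(records))) {
    records <- apply_noise_filters(records, curves)
  }
  records$quantity <- purrr::map2_dbl(
    seq_len(nrow(records)), records$assay_id,
    function(i, id) {
      if (records$noise_flag[i] || records$censored[i]) return(NA_real_)
      if (!is.null(curves[[id]])) quantify_ct(records$ct[i], curves[[id]])
      else 2^(-records$ct[i])
    }
  )
  records
}

#' Normalize target signals against a per-well reference
#'
#' Genomic 18S qPCR measures cell content / extraction efficiency per well;
#' dividing each target signal by the reference cancels those biases. The
#' default method is a ratio of back-computed quantities; with
#' `method = "delta_ct"` the curve-free fallback `2^-(ct_target - ct_ref)`
#' is used. Wells whose reference is noise or missing are marked invalid.
#'
#' @param target,reference [amplification_records()] tibbles measured on the
#'   same wells (after [quantify_records()] for the quantity method).
#' @param method `"quantity"` (default) or `"delta_ct"`.
#' @return A tibble with `well`, `raw_quantity`, `reference_quantity`,
#'   `ratio`, `valid`.
#' @export
normalize_to_reference <- function(target, reference,
                                   method = c("quantity", "delta_ct")) {
  method <- match.arg(method)
  common <- intersect(target$well, reference$well)
  if (length(common) == 0L) stop("target and reference share no wells", call. = FALSE)
  t <- target[match(common, target$well), ]
  r <- reference[match(common, reference$well), ]
  t_noise <- if ("noise_flag" %in% names(t)) t$noise_flag else t$censored
  r_noise <- if ("noise_flag" %in% names(r)) r$noise_flag else r$censored
  if (method == "quantity") {
    stopifnot("quantity" %in% names(t), "quantity" %in% names(r))
    raw <- t$quantity; ref <- r$quantity
  } else {
    raw <- 2^(-t$ct); ref <- 2^(-r$ct)
  }
  valid <- !t_noise & !r_noise & !is.na(raw) & !is.na(ref) & ref > 0
  tibble::tibble(
    well = common,
    raw_quantity = raw, reference_quantity = ref,
    ratio = ifelse(valid, raw / ref, NA_real_),
    valid = valid
  )
}

#' Scale a profile to percent of its maximum
#'
#' Mirrors the figure convention in which the maximum averaged signal per
#' target is set to 100%.
#'
#' @param x Numeric vector (NAs are carried through as invalid).
#' @return `x * 100 / max(x, na.rm = TRUE)`.
#' @export
#' @examples
#' percent_of_max(c(2, 4, 8))
percent_of_max <- function(x) {
  if (all(is.na(x))) stop("no valid values to scale", call. = FALSE)
  x * 100 / max(x, na.rm = TRUE)
}

#' Cross-reactivity matrix in percent of matched signal
#'
#' For a panel of primer sets assayed against every template, each entry is
#' the quantity seen by primer set `p` on template `t`, as a percentage of
#' the quantity `p` sees on its perfectly matched template. Noise, censored
#' or absent entries score 0%.
#'
#' @param panel A tibble with columns `primer_set`, `template`, `quantity`
#'   (replicates are averaged), and optionally `noise_flag`.
#' @param matched Named character vector mapping each primer set to its
#'   matched template; defaults to identity (primer set names equal template
#'   names).
#' @return A tibble with `primer_set`, `template`, `percent`.
#' @export
cross_reactivity_matrix <- function(panel, matched = NULL) {
  stopifnot(all(c("primer_set", "template", "quantity") %in% names(panel)))
  if ("noise_flag" %in% names(panel)) {
    panel$quantity[panel$noise_flag] <- NA_real_
  }
  avg <- panel |>
    dplyr::group_by(.data$primer_set, .data$template) |>
    dplyr::summarise(quantity = mean(.data$quantity, na.rm = FALSE),
                     .groups = "drop")
  sets <- unique(avg$primer_set)
  if (is.null(matched)) matched <- stats::setNames(sets, sets)
  ref <- avg |>
    dplyr::filter(.data$template == matched[.data$primer_set]) |>
    dplyr::select("primer_set", matched_quantity = "quantity")
  if (any(is.na(ref$matched_quantity) | ref$matched_quantity <= 0) ||
      !all(sets %in% ref$primer_set)) {
    stop("matched-pair quantity missing or zero for some primer set", call. = FALSE)
  }
  avg |>
    dplyr::left_join(ref, by = "primer_set") |>
    dplyr::mutate(
      percent = dplyr::if_else(
        is.na(.data$quantity) | .data$quantity <= 0, 0,
        100 * .data$quantity / .data$matched_quantity)
    ) |>
    dplyr::select("primer_set", "template", "percent")
}

#' Read a plate-reader Ct export
#'
#' Tolerant reader for SDS-style exports: any preamble is skipped up to the
#' header line (the first line whose first field is `Well`), the delimiter
#' (tab or comma) is sniffed, and `Undetermined` Ct values become censored
#' records. Expected columns (case-insensitive): `Well`, `Detector` (or
#' `Assay`), `Ct`, optional `Chemistry`.
#'
#' @param path File path.
#' @param chemistry Default chemistry for records without a chemistry
#'   column.
#' @return An [amplification_records()] tibble.
#' @export
read_plate_ct <- function(path, chemistry = "smallrna") {
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^\\s*\"?well\"?\\s*[,\t]", lines, ignore.case = TRUE)
  if (!any(is_header)) stop("no header line starting with 'Well' in ", path,
                            call. = FALSE)
  start <- which(is_header)[1]
  delim <- if (grepl("\t", lines[start])) "\t" else ","
  tab <- utils::read.table(text = lines[start:length(lines)], sep = delim,
                           header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  names(tab) <- tolower(names(tab))
  assay_col <- intersect(c("detector", "assay", "assay_id"), names(tab))[1]
  stopifnot(!is.na(assay_col), "well" %in% names(tab), "ct" %in% names(tab))
  ct_raw <- trimws(as.character(tab$ct))
  censored <- toupper(ct_raw) %in% c("UNDETERMINED", "UNDET", "NA", "")
  ct <- suppressWarnings(as.numeric(ct_raw))
  ct[censored] <- NA_real_
  chem <- if ("chemistry" %in% names(tab)) tab$chemistry else chemistry
  amplification_records(well = tab$well, assay_id = tab[[assay_col]],
                        ct = ct, chemistry = chem, censored = censored)
}

#' Write amplification records in the plate-reader dialect
#'
#' Emits the same SDS-style CSV [read_plate_ct()] consumes (two preamble
#' lines, then `Well,Detector,Ct,Chemistry` with `Undetermined` for censored
#' wells), closing the simulate -> scan loop.
#'
#' @param records An [amplification_records()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_ct <- function(records, path) {
  ct_out <- ifelse(records$censored, "Undetermined",
                   formatC(records$ct, digits = 6, format = "f"))
  lines <- c(
    "SDS-style export",
    paste0("# generated ", "by wbspcr simulator"),
    "Well,Detector,Ct,Chemistry",
    paste(records$well, records$assay_id, ct_out, records$chemistry, sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
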