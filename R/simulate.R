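#' Tissue identifiers recognized by the simulator
#' @return Character vector of tissue ids.
#' @export
tissue_ids <- function() {
  c("brain", "spinal_cord", "heart", "lung", "liver", "kidney", "spleen",
    "muscle", "GI", "blood", "tumor", "background")
}

#' Synthetic tissued whole-body section
#'
#' Builds the stylized mouse section used throughout testing: the packaged
#' 363-cell silhouette ([build_default_section_matrix()]) with contiguous
#' organ regions (brain, spinal cord, lung, heart, blood, liver, spleen,
#' kidney, GI; remaining body cells are skeletal muscle), plus a per-cell
#' multiplicative extraction-efficiency field. The efficiency field defaults
#' to a mild brain elevation (factor 1.5), emulating the cell-density /
#' extraction bias that genomic 18S normalization is meant to cancel;
#' optional per-cell lognormal jitter is controlled by `efficiency_sd`.
#'
#' @param seed Integer seed for the efficiency jitter.
#' @param brain_factor Extraction-efficiency multiplier in the brain
#'   (default 1.5).
#' @param efficiency_sd Standard deviation of per-cell lognormal efficiency
#'   noise on the log scale (default 0, i.e. none).
#' @return An object of class `tissued_section`: list with `matrix` (the
#'   [section_matrix()]) and `cells` (tibble: section cell coordinates,
#'   `tissue`, `efficiency`).
#' @export
#' @examples
#' sec <- make_default_section()
#' table(sec$cells$tissue)
make_default_section <- function(seed = 1L, brain_factor = 1.5,
                                 efficiency_sd = 0) {
  sm <- build_default_section_matrix()
  mask <- matrix(FALSE, sm$window$n_rows, sm$window$n_cols)
  mask[cbind(sm$cells$window_row, sm$cells$window_col)] <- TRUE
  labels <- default_tissue_labels(mask)
  cells <- sm$cells
  cells$tissue <- labels[cbind(cells$window_row, cells$window_col)]
  eff <- rep(1, nrow(cells))
  eff[cells$tissue == "brain"] <- brain_factor
  if (efficiency_sd > 0) {
    set.seed(seed)
    eff <- eff * exp(stats::rnorm(length(eff), 0, efficiency_sd))
  }
  cells$efficiency <- eff
  structure(list(matrix = sm, cells = cells), class = "tissued_section")
}

#' @export
print.tissued_section <- function(x, ...) {
  cat(sprintf("<tissued_section> %d cells, %d tissues\n",
              nrow(x$cells), length(unique(x$cells$tissue))))
  invisible(x)
}

#' Default expression atlas
#'
#' Qualitative per-tissue abundances (in curve units, ng/ul scale) for a
#' panel echoing the characterized targets: a liver-restricted miRNA
#' (miR-122), a heart-restricted miRNA (miR-208a), a brain-restricted miRNA
#' (miR-124), two ubiquitous miRNAs (miR-191, miR-16), and genomic 18S as
#' the normalization reference. Presence/absence is qualitative
#' (tissue-restricted targets are absent elsewhere); magnitudes are chosen
#' to sit comfortably inside a 14-point standard series.
#'
#' @return A tibble with columns `assay_id`, `chemistry`, `tissue`,
#'   `abundance`.
#' @export
default_expression_atlas <- function() {
  tissues <- setdiff(tissue_ids(), c("tumor", "background"))
  base <- tidyr::expand_grid(
    assay_id = c("mir122", "mir208a", "mir124", "mir191", "mir16"),
    tissue = tissues
  ) |>
    dplyr::mutate(chemistry = "smallrna", abundance = 0)
  base$abundance[base$assay_id == "mir122" & base$tissue == "liver"] <- 1e-4
  base$abundance[base$assay_id == "mir208a" & base$tissue == "heart"] <- 1e-4
  base$abundance[base$assay_id == "mir124" & base$tissue == "brain"] <- 1e-4
  base$abundance[base$assay_id == "mir191"] <- 5e-5
  base$abundance[base$assay_id == "mir16"] <- 5e-5
  ref <- tibble::tibble(assay_id = "genomic_18s", tissue = tissues,
                        chemistry = "genomic", abundance = 1e-3)
  dplyr::bind_rows(base, ref) |>
    dplyr::select("assay_id", "chemistry", "tissue", "abundance")
}

#' Assay response model for the simulator
#'
#' Log-linear Ct response: `Ct = intercept + slope * log10(effective
#' abundance)`, Gaussian noise of `noise_sd` cycles, censoring at the
#' chemistry's cycle maximum, additive cross-reactive contributions before
#' the log, and hard detection collapse for end-truncated templates beyond
#' `truncation_tolerance` nucleotides. The default slope is the ideal
#' `-1/log10(2)` (100% efficiency, ~ -3.32 Ct per decade); the LOD implied
#' by intercept 20 and a 50-cycle maximum spans the sub-femtogram regime
#' reported for these assays.
#'
#' @param slope Ct change per decade of concentration (negative).
#' @param intercept Ct at 1 curve unit.
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param cross_reactivity Optional tibble `primer_set`, `template`,
#'   `fraction` giving off-target signal fractions.
#' @param truncation_tolerance Maximum nucleotides removable from either
#'   template end with retained detection (default 2).
#' @return An object of class `assay_model`.
#' @export
assay_model <- function(slope = -1 / log10(2), intercept = 20,
                        noise_sd = 0.2, cross_reactivity = NULL,
                        truncation_tolerance = 2L) {
  stopifnot(slope < 0, noise_sd >= 0, truncation_tolerance >= 0)
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 cross_reactivity = cross_reactivity,
                 truncation_tolerance = as.integer(truncation_tolerance)),
            class = "assay_model")
}

#' @export
print.assay_model <- function(x, ...) {
  cat(sprintf("<assay_model> Ct = %.2f %+.4f log10(conc), sd %.2f\n",
              x$intercept, x$slope, x$noise_sd))
  invisible(x)
}

model_ct <- function(model, abundance) {
  ifelse(abundance > 0, model$intercept + model$slope * log10(abundance),
         Inf)
}

censor_records <- function(well, assay_id, chemistry, ct_true, model, seed) {
  cmax <- cycle_max_for(chemistry)
  set.seed(seed)
  noise <- stats::rnorm(length(ct_true), 0, model$noise_sd)
  ct <- ct_true + ifelse(is.finite(ct_true), noise, 0)
  censored <- !is.finite(ct) | ct > cmax
  amplification_records(
    well = well, assay_id = assay_id,
    ct = ifelse(censored, NA_real_, ct),
    chemistry = chemistry, censored = censored
  )
}

#' Simulate per-well Ct records for a section
#'
#' Runs the forward model over every sample cell of the section for every
#' assay in the atlas: effective abundance = tissue abundance x cell
#' extraction efficiency (+ cross-reactive contributions), converted to Ct,
#' jittered and censored. Records are keyed by analysis-plate wells through
#' `layout`. Zero effective abundance is always censored. Identical seeds
#' give bit-identical records.
#'
#' @param section A [make_default_section()] result.
#' @param atlas An expression atlas tibble (see
#'   [default_expression_atlas()]).
#' @param model An [assay_model()].
#' @param layout Analysis layout (default derived from the section's
#'   matrix).
#' @param seed Integer seed.
#' @return An [amplification_records()] tibble covering all sample wells
#'   and assays.
#' @export
simulate_ct <- function(section, atlas, model,
                        layout = map_to_analysis_plate(section$matrix),
                        seed = 1L) {
  stopifnot(inherits(section, "tissued_section"), inherits(model, "assay_model"))
  missing <- setdiff(unique(section$cells$tissue), unique(atlas$tissue))
  if (length(missing) > 0L) {
    stop("atlas does not cover tissue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sec <- layout_to_section(layout, section$matrix) |>
    dplyr::inner_join(
      dplyr::select(section$cells, "sample_index", "tissue", "efficiency"),
      by = "sample_index"
    )
  assays <- dplyr::distinct(atlas, .data$assay_id, .data$chemistry)
  per_assay <- purrr::pmap(assays, function(assay_id, chemistry) {
    ab <- atlas[atlas$assay_id == assay_id, c("tissue", "abundance")]
    eff_ab <- ab$abundance[match(sec$tissue, ab$tissue)] * sec$efficiency
    if (!is.null(model$cross_reactivity)) {
      xr <- model$cross_reactivity[model$cross_reactivity$primer_set == assay_id, ]
      for (k in seq_len(nrow(xr))) {
        off <- atlas[atlas$assay_id == xr$template[k], c("tissue", "abundance")]
        if (nrow(off) == 0L) next
        eff_ab <- eff_ab +
          xr$fraction[k] * off$abundance[match(sec$tissue, off$tissue)] * sec$efficiency
      }
    }
    tibble::tibble(well = sec$well_label, assay_id = assay_id,
                   chemistry = chemistry, ct_true = model_ct(model, eff_ab))
  })
  all <- dplyr::bind_rows(per_assay)
  censor_records(all$well, all$assay_id, all$chemistry, all$ct_true, model,
                 seed = seed)
}

#' Simulate replicate Cts for a dilution series
#'
#' @param model An [assay_model()].
#' @param concentrations Concentration vector, e.g.
#'   [make_dilution_series()].
#' @param replicates Replicates per concentration (default 3).
#' @param chemistry Chemistry (sets the censoring cycle maximum).
#' @param seed Integer seed.
#' @return A tibble with `concentration`, `replicate`, `ct`, `censored`.
#' @export
simulate_dilution_series <- function(model,
                                     concentrations = make_dilution_series(),
                                     replicates = 3L, chemistry = "smallrna",
                                     seed = 1L) {
  stopifnot(inherits(model, "assay_model"))
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(replicates))
  cmax <- cycle_max_for(chemistry)
  set.seed(seed)
  ct <- model_ct(model, grid$concentration) +
    stats::rnorm(nrow(grid), 0, model$noise_sd)
  censored <- !is.finite(ct) | ct > cmax
  grid$ct <- ifelse(censored, NA_real_, ct)
  grid$censored <- censored
  grid
}

#' Simulate an end-truncation detection panel
#'
#' Emulates the sensitivity collapse seen for truncated oligonucleotide
#' metabolites: a template truncated by at most `truncation_tolerance`
#' nucleotides at either end retains its effective abundance; beyond that,
#' detection collapses (effective abundance 0, hence censored).
#'
#' @param template Template sequence (sets the admissible depth range).
#' @param depths Integer truncation depths to probe.
#' @param model An [assay_model()] (holds the tolerance).
#' @param end `"3p"`, `"5p"` or `"both"`.
#' @param abundance Input abundance, default well above LOD.
#' @param seed Integer seed.
#' @return A tibble with `depth`, `end`, `ct`, `censored`, `detected`.
#' @export
simulate_truncation_panel <- function(template, depths = 0:5, model,
                                      end = c("3p", "5p", "both"),
                                      abundance = 1e-4, seed = 1L) {
  end <- match.arg(end)
  t <- as_dna(template)
  stopifnot(all(depths >= 0), all(depths <= nchar(t)))
  eff <- ifelse(depths <= model$truncation_tolerance, abundance, 0)
  recs <- censor_records(
    well = format_well_label(1L, seq_along(depths)),
    assay_id = paste0("trunc_", end, "_", depths),
    chemistry = "smallrna",
    ct_true = model_ct(model, eff), model = model, seed = seed
  )
  tibble::tibble(depth = as.integer(depths), end = end,
                 ct = recs$ct, censored = recs$censored,
                 detected = !recs$censored)
}

#' Antagomir dosing scenario
#'
#' Describes an anti-miRNA oligonucleotide (AMO) dose: the targeted miRNA
#' is knocked down by `knockdown` in every tissue except the spared ones
#' (the AMO does not cross the blood-brain barrier, so brain is spared by
#' default), a control miRNA is untouched, and the AMO analyte itself
#' distributes to all tissues except the spared set.
#'
#' @param treatment `"amo"` or `"vehicle"`.
#' @param target Targeted miRNA assay id (default `"mir16"`).
#' @param knockdown Knockdown fraction in \[0, 1\] (default 0.9).
#' @param spared Tissues spared from both knockdown and AMO uptake
#'   (default `"brain"`).
#' @param control Control assay id expected to remain unchanged.
#' @param amo_assay Assay id for the AMO analyte (CL-qPCR chemistry).
#' @param amo_abundance AMO tissue abundance in curve units.
#' @return An object of class `dose_scenario`.
#' @export
dose_scenario <- function(treatment = c("amo", "vehicle"), target = "mir16",
                          knockdown = 0.9, spared = "brain",
                          control = "mir191", amo_assay = "amo_mir16",
                          amo_abundance = 2e-5) {
  treatment <- match.arg(treatment)
  stopifnot(knockdown >= 0, knockdown <= 1)
  structure(list(treatment = treatment, target = target,
                 knockdown = knockdown, spared = spared, control = control,
                 amo_assay = amo_assay, amo_abundance = amo_abundance),
            class = "dose_scenario")
}

#' Apply a dosing scenario to an expression atlas
#'
#' Vehicle scenarios return the atlas unchanged. AMO scenarios multiply the
#' targeted miRNA's abundance by `1 - knockdown` outside the spared
#' tissues, leave the control target untouched, add the AMO analyte's
#' tissue distribution (zero in spared tissues), and attach a plasma
#' clearance time course (single-exponential decay crossing the assay LOD
#' within the horizon) as attribute `"plasma"`.
#'
#' @param atlas An expression atlas tibble.
#' @param scenario A [dose_scenario()].
#' @param horizon_h Plasma sampling horizon in hours (default 24); the
#'   decay constant is set so the signal crosses `plasma_lod` within 1 h.
#' @param plasma_c0 Initial plasma concentration (curve units).
#' @param plasma_lod Detection limit used for the clearance crossing.
#' @return The modified atlas with attribute `"plasma"` (tibble `time_h`,
#'   `concentration`, `detectable`).
#' @export
apply_scenario <- function(atlas, scenario, horizon_h = 24,
                           plasma_c0 = 1e-3, plasma_lod = 1e-9) {
  stopifnot(inherits(scenario, "dose_scenario"))
  if (scenario$treatment == "vehicle") return(atlas)
  if (!scenario$target %in% atlas$assay_id) {
    stop("targeted assay ", scenario$target, " not in atlas", call. = FALSE)
  }
  hit <- atlas$assay_id == scenario$target & !(atlas$tissue %in% scenario$spared)
  atlas$abundance[hit] <- atlas$abundance[hit] * (1 - scenario$knockdown)
  tissues <- unique(atlas$tissue)
  amo <- tibble::tibble(
    assay_id = scenario$amo_assay, chemistry = "clqpcr", tissue = tissues,
    abundance = ifelse(tissues %in% scenario$spared, 0, scenario$amo_abundance)
  )
  out <- dplyr::bind_rows(atlas, amo)
  k <- log(plasma_c0 / plasma_lod) / 0.75  # crosses LOD at 45 min < 1 h
  times <- sort(unique(c(0, 0.25, 0.5, 1, 2, 4, 8, horizon_h)))
  times <- times[times <= horizon_h]
  plasma <- tibble::tibble(
    time_h = times,
    concentration = plasma_c0 * exp(-k * times),
    detectable = plasma_c0 * exp(-k * times) >= plasma_lod
  )
  attr(out, "plasma") <- plasma
  out
}
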