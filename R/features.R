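CATALOGUE_VERSION <- "1.0"

REGION_NAMES <- c("PQ1", "PQ2", "PQ3", "PQ4", "SH1", "SH2", "SH3", "SH4")

bin_tags <- function(n_bins, span = c(-190, -30)) {
  width <- (span[2] - span[1]) / n_bins
  lo <- span[1] + width * (seq_len(n_bins) - 1)
  sprintf("%d_%d", abs(lo), abs(lo + width))
}

# Single source of truth for catalogue structure: the full 148-name roster
# in extraction order, with group / category / units metadata.
catalogue_skeleton <- function() {
  t8 <- bin_tags(8); t4 <- bin_tags(4)
  row <- function(name, category, group, units, definition)
    data.frame(name = name, category = category, group = group,
               units = units, definition = definition,
               stringsAsFactors = FALSE)
  morph <- rbind(
    row("EAT_vol", "morphological", "global_morphology", "cm3",
        "total EAT volume (voxel count x voxel volume)"),
    row("Sac_vol", "morphological", "global_morphology", "cm3",
        "pericardial sac volume"),
    row("EAT_fraction", "morphological", "global_morphology", "1",
        "EAT_vol / Sac_vol"),
    row("Axis_Major", "morphological", "global_morphology", "mm",
        "major principal-axis extent of the sac (principal_axes)"),
    row("Axis_Intermediate", "morphological", "global_morphology", "mm",
        "intermediate principal-axis extent of the sac"),
    row("Axis_Minor", "morphological", "global_morphology", "mm",
        "minor principal-axis extent of the sac"),
    row("Aspect_Major_Minor", "morphological", "global_morphology", "1",
        "Axis_Major / Axis_Minor"),
    row("Aspect_Major_Intermediate", "morphological", "global_morphology",
        "1", "Axis_Major / Axis_Intermediate"))
  thick <- rbind(
    row("Thickness_Mean", "morphological", "thickness", "mm",
        "mean of the 64,800-ray thickness field (measure_thickness_field)"),
    row("Thickness_Max", "morphological", "thickness", "mm",
        "maximum ray thickness"),
    row("Thickness_Median", "morphological", "thickness", "mm",
        "median ray thickness"),
    row("Thickness_Std", "morphological", "thickness", "mm",
        "standard deviation of ray thicknesses"),
    row("Thickness_Skewness", "morphological", "thickness", "1",
        "skewness of the thickness distribution"),
    row("Thickness_Kurtosis", "morphological", "thickness", "1",
        "excess kurtosis of the thickness distribution"),
    do.call(rbind, lapply(c("0_8", "8_16", "16_24", "24_32"), function(b)
      row(paste0("TB_", b), "morphological", "thickness", "rays",
          paste0("ray count with thickness in the ", b, " mm bin")))),
    do.call(rbind, lapply(c("0_8", "8_16", "16_24", "24_32"), function(b)
      row(paste0("TF_", b), "morphological", "thickness", "1",
          paste0("fraction of rays with thickness in the ", b, " mm bin")))))
  inten <- rbind(
    row("EAT_HUmin", "intensity", "global_intensity", "HU",
        "minimum HU over EAT voxels (hu_summary)"),
    row("EAT_HUmax", "intensity", "global_intensity", "HU", "maximum HU"),
    row("EAT_mean_HU", "intensity", "global_intensity", "HU", "mean HU"),
    row("EAT_HUstd", "intensity", "global_intensity", "HU",
        "HU standard deviation"),
    row("EAT_HU_NegSkewness", "intensity", "global_intensity", "1",
        "negative skewness of EAT HU (positive = piled toward high HU)"),
    row("EAT_HUkurtosis", "intensity", "global_intensity", "1",
        "excess kurtosis of EAT HU"),
    do.call(rbind, lapply(t8, function(b)
      row(paste0("Vol_", b), "intensity", "global_intensity", "cm3",
          paste0("EAT volume with HU in the -", sub("_", "..-", b),
                 " bin (hu_bins, 8 bins)")))),
    do.call(rbind, lapply(t8, function(b)
      row(paste0("Pro_", b), "intensity", "global_intensity", "1",
          paste0("probability of EAT HU in the -", sub("_", "..-", b),
                 " bin")))),
    do.call(rbind, lapply(t4, function(b)
      row(paste0("Vol4_", b), "intensity", "global_intensity", "cm3",
          paste0("EAT volume with HU in the 40-HU-wide -",
                 sub("_", "..-", b), " bin (hu_bins, 4 bins)")))),
    do.call(rbind, lapply(t4, function(b)
      row(paste0("Pro4_", b), "intensity", "global_intensity", "1",
          paste0("probability of EAT HU in the 40-HU-wide -",
                 sub("_", "..-", b), " bin")))))
  sub <- do.call(rbind, lapply(REGION_NAMES, function(r) {
    where <- if (grepl("^PQ", r))
      paste0("axial slab ", r, " (PQ1 lowermost .. PQ4 uppermost)")
    else
      paste0("equidistant shell ", r, " (SH1 outermost .. SH4 innermost)")
    rbind(
      row(paste0("Vol_", r), "spatial", "subregion", "cm3",
          paste0("EAT volume inside ", where)),
      row(paste0("VolFrac_", r), "spatial", "subregion", "1",
          paste0("fraction of total EAT volume inside ", where)),
      row(paste0("HUmean_", r), "spatial", "subregion", "HU",
          paste0("mean EAT HU inside ", where)),
      row(paste0("HUmin_", r), "spatial", "subregion", "HU",
          paste0("minimum EAT HU inside ", where)),
      row(paste0("HUmax_", r), "spatial", "subregion", "HU",
          paste0("maximum EAT HU inside ", where)),
      row(paste0("HUstd_", r), "spatial", "subregion", "HU",
          paste0("EAT HU standard deviation inside ", where)),
      row(paste0("HU_NegSkew_", r), "spatial", "subregion", "1",
          paste0("negative skewness of EAT HU inside ", where)),
      row(paste0("HUkurt_", r), "spatial", "subregion", "1",
          paste0("excess kurtosis of EAT HU inside ", where)),
      do.call(rbind, lapply(t4, function(b)
        row(paste0("Vol4_", b, "_", r), "spatial", "subregion", "cm3",
            paste0("EAT volume with HU in the -", sub("_", "..-", b),
                   " bin inside ", where)))))
  }))
  rbind(morph, thick, inten, sub)
}

#' The fat-omics feature dictionary
#'
#' Machine-readable roster of the 148-feature catalogue: name, category
#' (morphological / intensity / spatial), structural group
#' (global_morphology 8, thickness 14, global_intensity 30, subregion 96),
#' units and a one-line definition naming the computing operation.
#'
#' @return data.frame with 148 rows and columns `name`, `category`, `group`,
#'   `units`, `definition`, plus a `version` attribute.
#' @export
feature_dictionary <- function() {
  d <- catalogue_skeleton()
  attr(d, "version") <- CATALOGUE_VERSION
  d
}

empty_hu_block <- function() {
  c(mean = 0, min = 0, max = 0, std = 0, negskew = 0, kurt = 0)
}

#' Extract the 148-feature fat-omics vector for one subject
#'
#' Computes the full catalogue from a CT volume, pericardial sac mask, and
#' fat (EAT) mask: 8 global morphology features, 14 thickness-field
#' features, 30 global HU features, and 12 features for each of the 8
#' subregions (axial slabs PQ1..PQ4 cut from the sac's foreground slices;
#' equidistant shells SH1..SH4 cut from the sac's exterior-distance field,
#' both intersected with the EAT mask). Volumes are in cm^3, thicknesses in
#' mm. Degenerate regions (empty EAT or empty subregion) yield 0 for the
#' affected features; their names are recorded in the `flags` attribute.
#'
#' @param ct an `image_volume`.
#' @param sac pericardium `mask_volume`, congruent with `ct`, non-empty.
#' @param eat optional EAT `mask_volume`; derived from `ct` and `sac` via
#'   [derive_eat_mask()] when `NULL`.
#' @param subject_id stored in the result's metadata.
#' @param config list of options: `hu_window` (fat window for mask
#'   derivation), `step_deg`, `ray_step` (thickness sweep),
#'   `include_zero_rays` (thickness statistics convention).
#' @return Named numeric vector of class `feature_vector`, length 148, with
#'   attributes `subject_id`, `version` and `flags`.
#' @export
extract_features <- function(ct, sac, eat = NULL, subject_id = NULL,
                             config = list()) {
  check_congruent(ct, sac)
  if (!any(sac$data != 0L)) stop("sac mask is empty")
  hu_window <- config$hu_window %||% c(-190, -30)
  step_deg <- config$step_deg %||% 1.0
  include_zeros <- config$include_zero_rays %||% TRUE
  if (is.null(eat)) eat <- derive_eat_mask(ct, sac, hu_window)
  check_congruent(ct, eat)

  flags <- character(0)
  vv <- voxel_volume_mm3(ct) / 1000
  n_eat <- sum(eat$data != 0L)
  eat_vol <- n_eat * vv
  sac_vol <- sum(sac$data != 0L) * vv
  if (n_eat == 0) warning("EAT mask is empty; moment features are zero-imputed")

  ax <- principal_axes(sac)
  out <- c(EAT_vol = eat_vol, Sac_vol = sac_vol,
           EAT_fraction = eat_vol / sac_vol,
           Axis_Major = ax$lengths[["major"]],
           Axis_Intermediate = ax$lengths[["intermediate"]],
           Axis_Minor = ax$lengths[["minor"]],
           Aspect_Major_Minor = ax$aspect_major_minor,
           Aspect_Major_Intermediate = ax$aspect_major_intermediate)

  fld <- measure_thickness_field(eat, sac, step_deg = step_deg,
                                 ray_step = config$ray_step)
  ts <- summarize_thickness(fld, include_zeros = include_zeros)
  out <- c(out,
           Thickness_Mean = ts$mean, Thickness_Max = ts$max,
           Thickness_Median = ts$median, Thickness_Std = ts$std,
           Thickness_Skewness = ts$skewness,
           Thickness_Kurtosis = ts$kurtosis,
           ts$bin_counts, ts$bin_fractions)

  if (n_eat > 0) {
    hs <- hu_summary(ct, eat, "EAT")
    g6 <- c(EAT_HUmin = hs$min, EAT_HUmax = hs$max, EAT_mean_HU = hs$mean,
            EAT_HUstd = hs$std, EAT_HU_NegSkewness = hs$neg_skewness,
            EAT_HUkurtosis = hs$kurtosis)
    b8 <- hu_bins(ct, eat, n_bins = 8)
    b4 <- hu_bins(ct, eat, n_bins = 4, prefix = c("Vol4", "Pro4"))
    gi <- c(g6,
            stats::setNames(b8$bins$volume_cm3, b8$bins$name_vol),
            stats::setNames(b8$bins$prob, b8$bins$name_pro),
            stats::setNames(b4$bins$volume_cm3, b4$bins$name_vol),
            stats::setNames(b4$bins$prob, b4$bins$name_pro))
  } else {
    t8 <- bin_tags(8); t4 <- bin_tags(4)
    gi <- stats::setNames(rep(0, 30),
            c("EAT_HUmin", "EAT_HUmax", "EAT_mean_HU", "EAT_HUstd",
              "EAT_HU_NegSkewness", "EAT_HUkurtosis",
              paste0("Vol_", t8), paste0("Pro_", t8),
              paste0("Vol4_", t4), paste0("Pro4_", t4)))
    flags <- c(flags, names(gi))
  }
  out <- c(out, gi)

  slabs <- partition_axial_slabs(sac, n = 4)
  shells <- partition_shells(sac, n = 4)
  t4 <- bin_tags(4)
  for (r in REGION_NAMES) {
    labmap <- if (grepl("^PQ", r)) slabs else shells
    lab <- as.integer(sub("^(PQ|SH)", "", r))
    sub_mask <- region_submask(labmap, lab, parent = eat)
    n_sub <- sum(sub_mask$data != 0L)
    vol_r <- n_sub * vv
    block <- c(vol_r, if (eat_vol > 0) vol_r / eat_vol else 0)
    if (n_sub > 0) {
      hs <- hu_summary(ct, sub_mask, r)
      bb <- hu_bins(ct, sub_mask, n_bins = 4, prefix = c("Vol4", "Pro4"))
      block <- c(block, hs$mean, hs$min, hs$max, hs$std, hs$neg_skewness,
                 hs$kurtosis, bb$bins$volume_cm3)
    } else {
      block <- c(block, rep(0, 6), rep(0, 4))
      flags <- c(flags, paste0(c("HUmean_", "HUmin_", "HUmax_", "HUstd_",
                                 "HU_NegSkew_", "HUkurt_"), r))
    }
    names(block) <- c(paste0(c("Vol_", "VolFrac_", "HUmean_", "HUmin_",
                               "HUmax_", "HUstd_", "HU_NegSkew_",
                               "HUkurt_"), r),
                      paste0("Vol4_", t4, "_", r))
    out <- c(out, block)
  }

  dict_names <- catalogue_skeleton()$name
  stopifnot(identical(names(out), dict_names), length(out) == 148L,
            all(is.finite(out)))
  structure(out, subject_id = subject_id, version = CATALOGUE_VERSION,
            flags = flags, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features, catalogue v%s, subject %s\n",
              length(x), attr(x, "version"),
              attr(x, "subject_id") %||% "<unset>"))
  utils::str(stats::setNames(as.numeric(x[1:6]), names(x)[1:6]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
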