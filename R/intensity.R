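#' HU distribution summary over a region
#'
#' Moments of the Hounsfield values of the region's voxels. The skewness is
#' reported with a flipped sign (`neg_skewness`): a positive value marks a
#' distribution piled toward high (less negative) HU, the pattern associated
#' with fat inflammation. Kurtosis is excess kurtosis (normal -> 0); both are
#' 0 for a constant region.
#'
#' @param ct an `image_volume`.
#' @param region a congruent, non-empty `mask_volume`.
#' @param region_name used in error messages.
#' @return A `hu_summary` list: `min`, `max`, `mean`, `std`,
#'   `neg_skewness`, `kurtosis`, `n_voxels`, `volume_cm3`.
#' @export
hu_summary <- function(ct, region, region_name = "region") {
  check_congruent(ct, region)
  sel <- region$data != 0L
  n <- sum(sel)
  if (n == 0) stop("region `", region_name, "` is empty")
  x <- ct$data[sel]
  structure(list(min = min(x), max = max(x), mean = mean(x),
                 std = sample_std(x),
                 neg_skewness = -sample_skewness(x),
                 kurtosis = sample_kurtosis(x),
                 n_voxels = n,
                 volume_cm3 = n * voxel_volume_mm3(ct) / 1000),
            class = "hu_summary")
}

#' Fixed HU-bin volumes and probabilities over a region
#'
#' Tiles `span` into `n_bins` equal-width bins, right-open except the last
#' (so \[-50, -30\] is closed at -30), and reports per-bin volume (cm^3) and
#' probability (bin volume / in-span region volume). Names follow the
#' `Vol_<|lo|>_<|hi|>` / `Pro_<|lo|>_<|hi|>` convention, e.g. `Vol_50_30`
#' for HU in \[-50, -30\]. Voxels outside the span are excluded from the
#' bins and reported in `n_out_of_span`.
#'
#' @param ct an `image_volume`.
#' @param region a congruent, non-empty `mask_volume`.
#' @param n_bins 4 or 8 for the default span (any count that divides the
#'   span into equal-width bins is accepted).
#' @param span HU interval covered by the bins.
#' @param prefix length-2 names prefix for volumes and probabilities.
#' @return A `hu_bin_set`: data.frame `bins` (lo, hi, name_vol, name_pro,
#'   n_voxels, volume_cm3, prob), `span`, `n_out_of_span`,
#'   `in_span_volume_cm3`.
#' @export
hu_bins <- function(ct, region, n_bins = 8, span = c(-190, -30),
                    prefix = c("Vol", "Pro")) {
  check_congruent(ct, region)
  sel <- region$data != 0L
  if (!any(sel)) stop("region is empty")
  width <- (span[2] - span[1]) / n_bins
  if (abs(width - round(width)) > 1e-9)
    stop("span ", span[1], "..", span[2], " does not divide into ",
         n_bins, " equal integer-width bins")
  x <- ct$data[sel]
  in_span <- x >= span[1] & x <= span[2]
  b <- floor((x[in_span] - span[1]) / width) + 1
  b[b > n_bins] <- n_bins  # x == span[2]: last bin is closed
  counts <- tabulate(b, nbins = n_bins)
  lo <- span[1] + width * (seq_len(n_bins) - 1)
  hi <- lo + width
  vv <- voxel_volume_mm3(ct) / 1000
  vols <- counts * vv
  in_vol <- sum(counts) * vv
  bins <- data.frame(
    lo = lo, hi = hi,
    name_vol = sprintf("%s_%d_%d", prefix[1], abs(lo), abs(hi)),
    name_pro = sprintf("%s_%d_%d", prefix[2], abs(lo), abs(hi)),
    n_voxels = counts, volume_cm3 = vols,
    prob = if (in_vol > 0) vols / in_vol else rep(0, n_bins),
    stringsAsFactors = FALSE)
  structure(list(bins = bins, span = span,
                 n_out_of_span = sum(!in_span),
                 in_span_volume_cm3 = in_vol),
            class = "hu_bin_set")
}
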