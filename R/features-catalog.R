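#' The fixed per-cell feature catalog
#'
#' Ordered feature (column) names of the extraction output: 14 shape
#' features from the segmentation mask, then 18 intensity and 42 texture
#' features (15 GLCM + 7 GLDM + 9 GLSZM + 11 GLRLM) for the brightfield
#' channel, the same 60 for the fluorescent channel when present, and the
#' vesicle count — 135 names with a fluorescent channel, 74 without.
#' Channel-specific names carry a `_bf` / `_fl` suffix; group prefixes are
#' `shape`, `intensity`, `glcm`, `gldm`, `glszm`, `glrlm` and `ca2+`.
#'
#' @param fluorescent include the fluorescent-channel block and the vesicle
#'   count.
#' @return Character vector of feature names, in table column order.
#' @examples
#' length(feature_catalog(TRUE))   # 135
#' length(feature_catalog(FALSE))  # 74
#' @export
feature_catalog <- function(fluorescent = TRUE) {
  base <- c(shape_feature_names(),
            paste0(c(intensity_feature_names(), texture_feature_names()), "_bf"))
  if (!fluorescent) return(base)
  c(base,
    paste0(c(intensity_feature_names(), texture_feature_names()), "_fl"),
    "ca2+_number_of_vesicles")
}

shape_feature_names <- function() {
  paste0("shape_", c(
    "pixel_surface", "perimeter", "major_axis_length", "minor_axis_length",
    "maximum_diameter", "perimeter_surface_ratio", "sphericity", "elongation",
    "convex_area", "bounding_box_area", "extent", "eccentricity",
    "equivalent_diameter", "solidity"))
}

intensity_feature_names <- function() {
  paste0("intensity_", c(
    "mean", "variance", "median", "minimum", "maximum", "range",
    "10th_percentile", "90th_percentile", "interquartile_range",
    "mean_absolute_deviation", "robust_mean_absolute_deviation",
    "root_mean_squared", "entropy", "energy", "total_energy", "uniformity",
    "skewness", "kurtosis"))
}

glcm_feature_names <- function() {
  paste0("glcm_", c(
    "contrast", "correlation", "autocorrelation", "difference_average",
    "difference_entropy", "difference_variance", "inverse_difference",
    "inverse_difference_moment", "imc1", "imc2", "inverse_variance",
    "joint_average", "joint_energy", "joint_entropy", "mcc"))
}

gldm_feature_names <- function() {
  paste0("gldm_", c(
    "dependence_entropy", "dependence_non_uniformity", "dependence_variance",
    "gray_level_non_uniformity", "gray_level_variance",
    "low_gray_level_emphasis", "high_gray_level_emphasis"))
}

glszm_feature_names <- function() {
  paste0("glszm_", c(
    "high_gray_level_zone_emphasis", "large_area_emphasis",
    "large_area_high_gray_level_emphasis",
    "large_area_low_gray_level_emphasis", "low_gray_level_zone_emphasis",
    "size_zone_non_uniformity", "small_area_emphasis",
    "small_area_high_gray_level_emphasis",
    "small_area_low_gray_level_emphasis"))
}

glrlm_feature_names <- function() {
  paste0("glrlm_", c(
    "long_run_emphasis", "long_run_high_gray_level_emphasis",
    "long_run_low_gray_level_emphasis", "low_gray_level_run_emphasis",
    "run_entropy", "run_length_non_uniformity", "run_percentage",
    "run_variance", "short_run_emphasis",
    "short_run_high_gray_level_emphasis",
    "short_run_low_gray_level_emphasis"))
}

texture_feature_names <- function() {
  c(glcm_feature_names(), gldm_feature_names(), glszm_feature_names(),
    glrlm_feature_names())
}
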