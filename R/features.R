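#' Names of the full 39-feature panel
#'
#' 15 classic (time, frequency, Poincare) + 5 entropy + 19 FRP texture
#' features (texture names carry the `frp_` prefix).
#' @export
all_feature_names <- c(classic_feature_names, entropy_feature_names,
                       paste0("frp_", texture_feature_names))

#' Extract the 39-feature panel from one recording
#'
#' Runs the outlier screen, classic features, the five entropies on the raw
#' RR series, and the FRP -> GLCM texture chain, returning one named row of
#' the feature table.
#'
#' @param rr an [rr_series()].
#' @param frp_c,frp_m fuzzy C-means cluster count and fuzzifier for the FRP.
#' @param frp_seed seed for the FCM initialization.
#' @param levels grey levels for GLCM quantization.
#' @param glcm_d,glcm_angle GLCM offset distance and orientation.
#' @param fs tachogram resampling rate (Hz).
#' @param lo,hi outlier-filter bounds (ms); `NULL` skips filtering.
#' @param entropy an [entropy_config()] list.
#' @return Named numeric vector of length 39 (order of [all_feature_names]).
#' @export
extract_features <- function(rr, frp_c = 3, frp_m = 2, frp_seed = NULL,
                             levels = 8L, glcm_d = 1L, glcm_angle = 0,
                             fs = 4, lo = 333, hi = 2000,
                             entropy = entropy_config()) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is.null(lo)) rr <- remove_outliers(rr, lo, hi)$rr
  img <- frp(rr$intervals, c = frp_c, m = frp_m, seed = frp_seed)
  tex <- texture_features(glcm(quantize(img, levels), levels = levels,
                               d = glcm_d, angle = glcm_angle))
  out <- c(classic_features(rr, fs = fs),
           entropy_features(rr$intervals, entropy),
           stats::setNames(tex, paste0("frp_", names(tex))))
  stopifnot(identical(names(out), all_feature_names))
  out
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to every recording, deriving a reproducible
#' per-recording FCM seed from `seed`.
#'
#' @param cohort an [simulate_cohort()] / [read_cohort()] cohort.
#' @param seed master seed for the per-recording FCM initializations.
#' @param ... passed to [extract_features()].
#' @return A data.frame with `subject_id`, `condition` and the 39 feature
#'   columns; class `c("feature_table", "data.frame")`.
#' @export
cohort_features <- function(cohort, seed = 1, ...) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  rows <- lapply(seq_along(cohort$recordings), function(i) {
    extract_features(cohort$recordings[[i]],
                     frp_seed = derive_seed(seed, i), ...)
  })
  feats <- as.data.frame(do.call(rbind, rows))
  out <- cbind(cohort$manifest[, c("subject_id", "condition")], feats)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d recordings x %d features\n",
              nrow(x), ncol(x) - 2L))
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

# Split a feature table into the numeric matrix and the label factor.
table_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  meta <- intersect(c("subject_id", "condition"), names(table))
  list(x = as.matrix(table[, setdiff(names(table), meta), drop = FALSE]),
       condition = table[["condition"]],
       subject_id = table[["subject_id"]])
}
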