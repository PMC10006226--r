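FEATURE_NAMES <- c("ASM", "IDM", "CON", "COR", "SA", "SVAR",
                   "EnLH", "EnHL", "EnHH")

#' The nine-number texture feature vector of one ROI
#'
#' Quantizes the patch for the co-occurrence analysis, computes the six GLCM
#' features (averaged over angles per the GLCM config), and appends the
#' three level-1 Haar detail-band energies computed on the raw (or, if
#' configured, quantized) intensities.
#'
#' @param patch A raw (unquantized) [gray_patch()].
#' @param quantization A [quantization_config()].
#' @param glcm A [glcm_config()].
#' @param wavelet A [wavelet_config()].
#' @return Named numeric vector
#'   `c(ASM, IDM, CON, COR, SA, SVAR, EnLH, EnHL, EnHH)`.
#' @export
texture_features <- function(patch,
                             quantization = quantization_config(),
                             glcm = glcm_config(),
                             wavelet = wavelet_config()) {
  qp <- quantize_gray(patch, quantization$levels, quantization$strategy)
  g <- glcm_feature_vector(qp, glcm)
  wp <- if (wavelet$on == "raw") patch else qp
  en <- subband_energies(haar_decompose(wp), wavelet$denominator)
  c(g, en)
}

#' Extract the per-ROI feature table for a whole dataset
#'
#' Iterates over the manifest, loads each ROI and computes its nine texture
#' features. Any per-ROI failure is re-raised with the offending `roi_id` in
#' the message.
#'
#' @param manifest A manifest data.frame from [read_manifest()] (or a path
#'   to the manifest CSV).
#' @inheritParams texture_features
#' @return A data.frame with columns `roi_id, group, animal_id` and the nine
#'   feature columns, one row per ROI.
#' @export
extract_features <- function(manifest,
                             quantization = quantization_config(),
                             glcm = glcm_config(),
                             wavelet = wavelet_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  feats <- matrix(NA_real_, nrow(manifest), length(FEATURE_NAMES),
                  dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    feats[i, ] <- tryCatch(
      texture_features(load_roi(rec), quantization, glcm, wavelet),
      error = function(e) {
        stop("feature extraction failed for ROI '", rec$roi_id, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  cbind(manifest[, c("roi_id", "group", "animal_id")],
        as.data.frame(feats))
}

#' Write / read the ROI feature table CSV
#'
#' Column layout:
#' `roi_id,group,animal_id,ASM,IDM,CON,COR,SA,SVAR,EnLH,EnHL,EnHH`.
#'
#' @param features Feature data.frame from [extract_features()].
#' @param path Output CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_feature_table <- function(features, path) {
  cols <- c("roi_id", "group", "animal_id", FEATURE_NAMES)
  stopifnot(all(cols %in% names(features)))
  utils::write.csv(features[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(roi_id = "character",
                                 animal_id = "character"))
}
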