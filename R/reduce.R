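# Deterministic slice-selection rules producing the reduced-slice protocols
# from a full study.  "Within the LV" means the slice has a non-empty
# endocardial contour at end-diastole (frame 1).  Kept slices carry their
# original planes and contours unchanged.

lv_sax_indices <- function(study) {
  is_sax <- vapply(study$slices, function(s) s$plane$slice_label == "SAX", TRUE)
  has_endo <- vapply(study$slices, function(s) nrow(s$endo[[1L]]) >= 3L, TRUE)
  which(is_sax & has_endo)
}

keep_slices <- function(study, keep_idx, protocol) {
  is_lax <- vapply(study$slices, function(s)
    s$plane$slice_label != "SAX", TRUE)
  study$slices <- study$slices[sort(unique(c(keep_idx, which(is_lax))))]
  study$meta$protocol <- protocol
  study
}

#' Six-slice protocol reduction
#'
#' Keeps four SAX slices plus the two LAX slices: the most basal and most
#' apical slices within the LV are dropped, every second remaining slice is
#' kept starting from the second-most-basal, surplus slices are dropped from
#' the apical end, and a shortfall is filled from the remaining interior
#' slices, most apical first.
#'
#' @param study a full [cine_study()].
#' @return a [cine_study()] with 4 SAX + 2 LAX slices.
#' @export
reduce_six <- function(study) {
  lv <- lv_sax_indices(study)
  n <- length(lv)
  if (n < 6L)
    stop("reduce_six: need at least 6 SAX slices within the LV, got ", n)
  interior <- 2:(n - 1L)
  alt <- interior[seq(1L, length(interior), by = 2L)]
  if (length(alt) > 4L) alt <- alt[seq_len(4L)]
  if (length(alt) < 4L) {
    fill <- rev(setdiff(interior, alt))
    alt <- sort(c(alt, fill[seq_len(4L - length(alt))]))
  }
  keep_slices(study, lv[alt], "six")
}

#' Four-slice protocol reduction
#'
#' Keeps two SAX slices plus the two LAX slices: one in the middle of the
#' basal half and one in the middle of the apical half of the LV, at 1-based
#' positions round(N/4) and round(3N/4) with ties rounded toward the base.
#'
#' @param study a full [cine_study()].
#' @return a [cine_study()] with 2 SAX + 2 LAX slices.
#' @export
reduce_four <- function(study) {
  lv <- lv_sax_indices(study)
  n <- length(lv)
  if (n < 4L)
    stop("reduce_four: need at least 4 SAX slices within the LV, got ", n)
  toward_base <- function(x) as.integer(ceiling(x - 0.5))
  keep <- pmax(1L, c(toward_base(n / 4), toward_base(3 * n / 4)))
  keep_slices(study, lv[keep], "four")
}
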