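#' Derived global-function parameters
#'
#' Computes stroke volume SV = EDV - ESV, ejection fraction EF = SV / EDV and
#' LV mass = 1.05 mg/ul times the myocardial volume, the shared output of the
#' standard and model-based analysis paths.  EF is stored as a fraction and
#' rendered as % in reports.
#'
#' @param edv_ul,esv_ul end-diastolic and end-systolic cavity volumes (ul).
#' @param myo_volume_ul myocardial volume (ul) entering the mass.
#' @param method_label label of the producing method.
#' @param infarct_pct optional infarct size (%).
#' @return an object of class `function_report` with fields `edv_ul`,
#'   `esv_ul`, `sv_ul`, `ef_fraction`, `lvm_mg`, `infarct_pct`,
#'   `method_label` and `density_g_per_ml`.
#' @export
derive_function_report <- function(edv_ul, esv_ul, myo_volume_ul,
                                   method_label = "unknown",
                                   infarct_pct = NA_real_) {
  if (esv_ul < 0 || edv_ul < esv_ul)
    stop("derive_function_report: need edv_ul >= esv_ul >= 0, got EDV = ",
         edv_ul, ", ESV = ", esv_ul)
  sv <- edv_ul - esv_ul
  structure(
    list(edv_ul = edv_ul, esv_ul = esv_ul, sv_ul = sv,
         ef_fraction = if (edv_ul > 0) sv / edv_ul else 0,
         lvm_mg = 1.05 * myo_volume_ul, infarct_pct = infarct_pct,
         method_label = method_label, density_g_per_ml = 1.05),
    class = "function_report")
}

#' @export
print.function_report <- function(x, ...) {
  cat(sprintf(
    "LV function [%s]: EDV %.1f ul  ESV %.1f ul  SV %.1f ul  EF %.1f%%  mass %.1f mg\n",
    x$method_label, x$edv_ul, x$esv_ul, x$sv_ul, 100 * x$ef_fraction, x$lvm_mg))
  if (is.finite(x$infarct_pct))
    cat(sprintf("  infarct size %.1f%% of myocardium\n", x$infarct_pct))
  invisible(x)
}

report_fields <- function(r) {
  c(edv_ul = r$edv_ul, esv_ul = r$esv_ul, sv_ul = r$sv_ul,
    ef_pct = 100 * r$ef_fraction, lvm_mg = r$lvm_mg)
}
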