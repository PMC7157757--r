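# Size-exclusion chromatography calibration: partition coefficients,
# exponential molecular-weight calibration, and oligomer-state calls.

#' Column geometry for size-exclusion chromatography
#'
#' Defaults correspond to a HiPrep 16/60 Sephacryl S-100 HR column: void
#' volume 36 mL, geometric column volume 120 mL.
#'
#' @param vo void volume, mL.
#' @param vc geometric column volume, mL (> `vo`).
#' @return A `sec_geometry` list.
#' @export
sec_geometry <- function(vo = 36, vc = 120) {
  if (!(vo > 0 && vc > vo)) stop("need 0 < Vo < Vc")
  structure(list(vo = vo, vc = vc), class = "sec_geometry")
}

#' Partition coefficient Kav
#'
#' `Kav = (Ve - Vo) / (Vc - Vo)`: 0 at the void volume, 1 at the geometric
#' column volume, affine in the elution volume.
#'
#' @param ve elution volume(s), mL, within `[Vo, Vc]`.
#' @param geometry a [sec_geometry()].
#' @return Kav value(s) in `[0, 1]`.
#' @examples
#' kav(78)  # 0.5 with the default 36/120 mL column
#' @export
kav <- function(ve, geometry = sec_geometry()) {
  stopifnot(inherits(geometry, "sec_geometry"))
  if (any(ve < geometry$vo | ve > geometry$vc)) {
    stop("elution volume outside [Vo, Vc] = [", geometry$vo, ", ",
         geometry$vc, "] mL")
  }
  (ve - geometry$vo) / (geometry$vc - geometry$vo)
}

#' Construct a calibration curve from known coefficients
#'
#' The model is `MW(Da) = a * exp(-b * Kav)`.
#'
#' @param a intercept in Da (> 0).
#' @param b decay rate per unit Kav (>= 0).
#' @param r_squared optional fit quality in `[0, 1]`.
#' @return A `calibration_curve`.
#' @examples
#' predict_mw(calibration_curve(166086, 3.377), 0)  # 166086 Da
#' @export
calibration_curve <- function(a, b, r_squared = NA_real_) {
  stopifnot(a > 0, b >= 0, is.na(r_squared) || (r_squared >= 0 && r_squared <= 1))
  structure(list(a = a, b = b, r_squared = r_squared),
            class = "calibration_curve")
}

#' Fit an exponential molecular-weight calibration curve
#'
#' Ordinary least squares of `ln(MW in Da)` on Kav: the fitted model is
#' `MW = a * exp(-b * Kav)` with `a = exp(intercept)`, `b = -slope`;
#' `r_squared` is that of the linear fit in log space.
#'
#' @param standards data.frame with columns `mw_kda` and `ve_ml` (e.g. from
#'   [read_sec_standards()] or [synthetic_sec_standards()]).
#' @param geometry a [sec_geometry()].
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(standards, geometry = sec_geometry()) {
  need <- c("mw_kda", "ve_ml")
  if (!all(need %in% names(standards))) {
    stop("standards need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(standards) < 3L) {
    stop("at least 3 standards are required (got ", nrow(standards), ")")
  }
  k <- kav(standards$ve_ml, geometry)
  if (max(k) - min(k) < 1e-9) stop("degenerate Kav spread; fit is singular")
  fit <- stats::lm(log(standards$mw_kda * 1000) ~ k)
  # suppressWarnings: summary.lm warns on an exact (noiseless) fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  calibration_curve(a = exp(unname(stats::coef(fit)[1])),
                    b = -unname(stats::coef(fit)[2]),
                    r_squared = r2)
}

#' Predict molecular weight from a calibration curve
#'
#' @param curve a [calibration_curve()].
#' @param kav partition coefficient(s).
#' @return Molecular weight(s) in Da.
#' @export
predict_mw <- function(curve, kav) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$a * exp(-curve$b * kav)
}

#' Read SEC calibration standards from CSV
#'
#' @param path CSV with columns `name,mw_kda,ve_ml`.
#' @return data.frame of standards.
#' @export
read_sec_standards <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mw_kda", "ve_ml")
  if (!all(need %in% names(tab))) {
    stop("standards CSV needs columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Infer oligomeric state from an observed molecular weight
#'
#' Compares an observed (e.g. SEC-derived) molecular weight with a known
#' monomer weight: the nearest integer multiple is named (monomer, dimer,
#' trimer, n-mer) when the observed weight falls within `tolerance` of that
#' multiple, otherwise the call is `ambiguous`.
#'
#' @param observed_mw observed molecular weight (any unit, same as monomer).
#' @param monomer_mw monomer molecular weight (> 0).
#' @param tolerance relative tolerance (default 0.15).
#' @return An `oligomer_call`: list with `multiple` (>= 1), `call`,
#'   `observed_mw`, `monomer_mw`, `tolerance`.
#' @examples
#' infer_oligomer(60, 30)$call  # "dimer"
#' infer_oligomer(50, 30)$call  # "ambiguous"
#' @export
infer_oligomer <- function(observed_mw, monomer_mw, tolerance = 0.15) {
  stopifnot(observed_mw > 0, monomer_mw > 0, tolerance >= 0)
  multiple <- max(1L, as.integer(round(observed_mw / monomer_mw)))
  expected <- multiple * monomer_mw
  ok <- abs(observed_mw - expected) <= tolerance * expected
  call <- if (!ok) "ambiguous" else switch(as.character(multiple),
    "1" = "monomer", "2" = "dimer", "3" = "trimer",
    paste0(multiple, "-mer"))
  structure(list(multiple = multiple, call = call, observed_mw = observed_mw,
                 monomer_mw = monomer_mw, tolerance = tolerance),
            class = "oligomer_call")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: MW = %.6g * exp(-%.4g * Kav) Da", x$a, x$b))
  if (!is.na(x$r_squared)) cat(sprintf(" (r^2 = %.4f, log-space)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
print.oligomer_call <- function(x, ...) {
  cat(sprintf("oligomer_call: observed %.3g vs monomer %.3g -> %s (x%d, tol %.0f%%)\n",
              x$observed_mw, x$monomer_mw, x$call, x$multiple, 100 * x$tolerance))
  invisible(x)
}
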