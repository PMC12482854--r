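# R^2 of a simple OLS fit = squared Pearson correlation (computed directly,
# avoiding summary.lm's warning on exact fits)
ols_r2 <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Two-point calibration anchors
#'
#' Group-mean SUVr of the young cognitively-normal amyloid-negative anchor
#' cohort and of the AD-dementia anchor cohort. These two means pin the 0 and
#' 100 points of the Centiloid scale.
#'
#' @param m_ycn young-CN group mean SUVr.
#' @param m_ad AD group mean SUVr (must exceed `m_ycn`).
#' @return object of class `two_point_anchors`.
#' @export
two_point_anchors <- function(m_ycn, m_ad) {
  if (!is.finite(m_ycn) || !is.finite(m_ad)) stopf("anchors must be finite")
  if (m_ad <= m_ycn)
    stopf("inverted anchors: AD mean (%g) must exceed yCN mean (%g)", m_ad, m_ycn)
  structure(list(m_ycn = m_ycn, m_ad = m_ad), class = "two_point_anchors")
}

#' Tracer-specific linear conversion
#'
#' Affine map from SUVr to a harmonized scale: `value = slope * suvr +
#' intercept`.
#'
#' @param tracer tracer id (e.g. `"PiB"`, `"FBP"`, `"FTP"`).
#' @param modality one of `"amyloid_CL"`, `"tau_CTRz"`, `"tau_SUVr_CTR"`.
#' @param slope positive slope.
#' @param intercept intercept.
#' @param r2 optional goodness-of-fit of the underlying regression.
#' @return object of class `linear_conversion`.
#' @export
linear_conversion <- function(tracer, modality, slope, intercept, r2 = NULL) {
  if (!is.finite(slope) || slope <= 0) stopf("slope must be positive, got %g", slope)
  if (!is.finite(intercept)) stopf("intercept must be finite")
  structure(list(tracer = as.character(tracer), modality = as.character(modality),
                 slope = slope, intercept = intercept, r2 = r2),
            class = "linear_conversion")
}

#' Evaluate a linear conversion
#' @param conversion a [linear_conversion()].
#' @param suvr SUVr value(s).
#' @return converted value(s).
#' @export
apply_conversion <- function(conversion, suvr) {
  conversion$slope * suvr + conversion$intercept
}

#' Expand two-point anchors into the Centiloid linear map
#'
#' The Centiloid definition `CL = 100 * (SUVr - m_ycn) / (m_ad - m_ycn)`
#' written as slope/intercept: `slope = 100 / (m_ad - m_ycn)`,
#' `intercept = -100 * m_ycn / (m_ad - m_ycn)`. Unrounded algebra is used, so
#' evaluating at the anchors gives exactly 0 and 100.
#'
#' @param anchors a [two_point_anchors()].
#' @param tracer tracer id for the returned conversion.
#' @return a [linear_conversion()] (modality `"amyloid_CL"`).
#' @export
expand_two_point <- function(anchors, tracer = "PiB") {
  stopifnot(inherits(anchors, "two_point_anchors"))
  span <- anchors$m_ad - anchors$m_ycn
  if (span <= 0) stopf("zero or negative anchor span")
  linear_conversion(tracer, "amyloid_CL",
                    slope = 100 / span,
                    intercept = -100 * anchors$m_ycn / span)
}

#' Level-1 Centiloid calibration from anchor cohorts
#'
#' Computes the group-mean anchors from the two cohorts' global SUVr values and
#' expands them into the SUVr-to-CL map (the two-point procedure of the
#' Centiloid protocol).
#'
#' @param ycn_suvrs SUVr values of the young-CN anchor group (>= 2).
#' @param ad_suvrs SUVr values of the AD anchor group (>= 2).
#' @param tracer tracer id.
#' @return list with `anchors` ([two_point_anchors()]) and `conversion`
#'   ([linear_conversion()]).
#' @export
fit_level1_centiloid <- function(ycn_suvrs, ad_suvrs, tracer = "PiB") {
  if (length(ycn_suvrs) < 2 || length(ad_suvrs) < 2)
    stopf("need at least 2 subjects per anchor group")
  anchors <- two_point_anchors(mean(ycn_suvrs), mean(ad_suvrs))
  list(anchors = anchors, conversion = expand_two_point(anchors, tracer))
}

#' Level-2 cross-tracer Centiloid calibration
#'
#' Regresses paired PiB SUVr on the other tracer's SUVr by ordinary least
#' squares and composes the fit with the PiB-to-CL conversion by exact algebra
#' (no refit): `CL = pib.slope * (b1 * x + b0) + pib.intercept`.
#'
#' @param tracer_suvrs SUVr of the tracer to calibrate (>= 3 subjects).
#' @param pib_suvrs paired PiB SUVr of the same subjects.
#' @param pib_conversion the PiB [linear_conversion()].
#' @param tracer tracer id for the result.
#' @return a [linear_conversion()] with attributes `regression` (slope,
#'   intercept, r2 of the tracer-to-PiB OLS fit).
#' @export
fit_level2 <- function(tracer_suvrs, pib_suvrs, pib_conversion,
                       tracer = "tracer") {
  n <- length(tracer_suvrs)
  if (n != length(pib_suvrs)) stopf("paired lists differ in length")
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  if (stats::var(tracer_suvrs) == 0) stopf("zero-variance predictor")
  fit <- stats::lm(pib_suvrs ~ tracer_suvrs)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  r2 <- ols_r2(tracer_suvrs, pib_suvrs)
  out <- linear_conversion(
    tracer, "amyloid_CL",
    slope = pib_conversion$slope * b1,
    intercept = pib_conversion$slope * b0 + pib_conversion$intercept,
    r2 = r2)
  attr(out, "regression") <- c(slope = b1, intercept = b0, r2 = r2)
  out
}

#' CenTauR pipeline-harmonization (Level-1) fit
#'
#' OLS regression of this pipeline's meta-temporal FTP SUVr on the published
#' SUVr_CTR values, `S = b * SUVr_CTR + a`, returned in the inverse form used
#' for conversion: `SUVr_CTR = (S - a) / b`.
#'
#' @param pipeline_suvrs this pipeline's SUVr values (>= 3 subjects).
#' @param published_ctr_suvrs paired published SUVr_CTR values.
#' @param tracer tracer id.
#' @return a [linear_conversion()] (modality `"tau_SUVr_CTR"`, slope `1/b`,
#'   intercept `-a/b`) with attribute `ab = c(a, b)` and `r2` of the fit.
#' @export
fit_centaur_level1 <- function(pipeline_suvrs, published_ctr_suvrs,
                               tracer = "FTP") {
  n <- length(pipeline_suvrs)
  if (n != length(published_ctr_suvrs)) stopf("paired lists differ in length")
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  if (stats::var(published_ctr_suvrs) == 0) stopf("zero-variance predictor")
  fit <- stats::lm(pipeline_suvrs ~ published_ctr_suvrs)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (b <= 0) stopf("non-positive fitted scale b = %g", b)
  out <- linear_conversion(tracer, "tau_SUVr_CTR",
                           slope = 1 / b, intercept = -a / b,
                           r2 = ols_r2(published_ctr_suvrs, pipeline_suvrs))
  attr(out, "ab") <- c(a = a, b = b)
  out
}

#' Bundled tracer conversion table
#'
#' Loads the versioned JSON table of published linear conversions: five
#' amyloid tracers to Centiloid, six tau tracers to CenTauRz (meta-temporal
#' mask), and the FTP pipeline-harmonization constants. Coefficients are kept
#' exactly as printed (4 decimals).
#'
#' @param path optional replacement JSON file.
#' @return nested list (see `inst/extdata/conversions.json`).
#' @export
conversion_table <- function(path = NULL) {
  read_json(path %||% pkg_extdata("conversions.json"))
}

#' Convert a SUVr to Centiloid or CenTauRz using the bundled coefficients
#'
#' @param value SUVr value(s).
#' @param tracer tracer id; amyloid tracers (PiB, FBP, FBB, FTM, NAV) map to
#'   CL, tau tracers (FTP, RO, MK, GTP, PBB3, PI) to CTRz.
#' @param table a [conversion_table()].
#' @return converted value(s), with attribute `scale` (`"CL"` or `"CTRz"`).
#' @export
convert_suvr <- function(value, tracer, table = conversion_table()) {
  if (tracer %in% names(table$amyloid_CL)) {
    co <- table$amyloid_CL[[tracer]]
    scale <- "CL"
  } else if (tracer %in% names(table$tau_CTRz)) {
    co <- table$tau_CTRz[[tracer]]
    scale <- "CTRz"
  } else {
    stopf("unknown tracer '%s'; known: %s", tracer,
          paste(c(names(table$amyloid_CL), names(table$tau_CTRz)),
                collapse = ", "))
  }
  structure(co$slope * value + co$intercept, scale = scale)
}

#' Check a calibration against the Centiloid-project validity criteria
#'
#' OLS regression of computed on published values. The calibration passes when
#' the slope lies in [0.98, 1.02], the absolute intercept is at most 2 (in CL
#' units; the published criteria state the intercept bound for Centiloid only,
#' so it is computed but not enforced for CTRz) and R^2 exceeds 0.98.
#'
#' @param computed values produced by this pipeline (>= 3).
#' @param published paired reference values.
#' @param modality `"CL"` or `"CTRz"`.
#' @return object of class `calibration_report`: `slope`, `intercept`,
#'   `r_squared`, `n`, `modality`, logical `pass_slope`, `pass_intercept`
#'   (`NA` for CTRz), `pass_r2`, `pass`.
#' @export
validate_calibration <- function(computed, published,
                                 modality = c("CL", "CTRz")) {
  modality <- match.arg(modality)
  n <- length(computed)
  if (n != length(published)) stopf("paired lists differ in length")
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  fit <- stats::lm(computed ~ published)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- ols_r2(published, computed)
  pass_slope <- slope >= 0.98 && slope <= 1.02
  pass_intercept <- if (modality == "CL") abs(intercept) <= 2 else NA
  pass_r2 <- r2 > 0.98
  pass <- pass_slope && pass_r2 && (is.na(pass_intercept) || pass_intercept)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = n, modality = modality,
                 pass_slope = pass_slope, pass_intercept = pass_intercept,
                 pass_r2 = pass_r2, pass = pass),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s, n = %d\n", x$modality, x$n))
  cat(sprintf("  slope     %.4f  [0.98, 1.02]  %s\n", x$slope,
              if (x$pass_slope) "pass" else "FAIL"))
  cat(sprintf("  intercept %+.4f  |.| <= 2      %s\n", x$intercept,
              if (is.na(x$pass_intercept)) "(not enforced)"
              else if (x$pass_intercept) "pass" else "FAIL"))
  cat(sprintf("  R^2       %.4f  > 0.98        %s\n", x$r_squared,
              if (x$pass_r2) "pass" else "FAIL"))
  cat(sprintf("  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Pick the candidate mask whose values best track the published scale
#'
#' Fits an OLS regression per candidate mask (pipeline SUVr on published
#' SUVr_CTR) and returns the mask with the highest R^2 — the procedure that
#' identifies which predefined CenTauR mask a subject-specific mask resembles
#' most. Ties within 1e-12 are broken toward the lexicographically smallest
#' name and flagged.
#'
#' @param candidates named list; each element is a list/data frame with
#'   components `published` and `pipeline` (paired, >= 3 values).
#' @return list with `best` (name), `r2_table` (data frame `mask`, `r2`,
#'   ordered by R^2), `tie` (logical).
#' @export
select_best_mask <- function(candidates) {
  if (length(candidates) == 0) stopf("no candidate masks supplied")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stopf("candidates must be a named list")
  r2 <- vapply(names(candidates), function(nm) {
    p <- candidates[[nm]]
    if (length(p$published) < 3 || length(p$published) != length(p$pipeline))
      stopf("candidate '%s' needs >= 3 paired values", nm)
    ols_r2(p$published, p$pipeline)
  }, numeric(1))
  ord <- order(-r2, names(candidates))
  tab <- data.frame(mask = names(candidates)[ord], r2 = r2[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  tie <- nrow(tab) > 1 && abs(tab$r2[1] - tab$r2[2]) < 1e-12
  list(best = tab$mask[1], r2_table = tab, tie = tie)
}
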