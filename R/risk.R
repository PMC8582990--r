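#' Exposure parameters for ingestion risk assessment
#'
#' Point-value exposure factors for drinking-water ingestion of inorganic
#' arsenic, following the USEPA deterministic framework. Defaults are
#' standard adult residential values: daily water intake IR = 1.4
#' L/day, body weight BW = 64.5 kg, exposure duration ED = 30 yr at
#' EF = 365 day/yr, averaging time AT = 79.0 x 365 = 28,835 days (a
#' 79-year life expectancy), oral reference dose RfD = 0.3 ug/(kg day)
#' and cancer slope factor CSF = 1.5 (mg/(kg day))^-1 from IRIS. The
#' 10^-3 factor converts ug to mg in the carcinogenic model.
#'
#' @param IR Daily water intake (L/day).
#' @param ED Exposure duration (yr).
#' @param EF Exposure frequency (day/yr), at most 366.
#' @param BW Body weight (kg).
#' @param AT Averaging time (day).
#' @param RfD Oral reference dose (ug/kg/day).
#' @param CSF Cancer slope factor ((mg/kg/day)^-1).
#' @param unit_conversion ug-to-mg factor (10^-3).
#' @return An object of class `exposure_params`.
#' @export
exposure_params <- function(IR = 1.4, ED = 30, EF = 365, BW = 64.5,
                            AT = 79.0 * 365, RfD = 0.3, CSF = 1.5,
                            unit_conversion = 1e-3) {
  p <- list(IR = IR, ED = ED, EF = EF, BW = BW, AT = AT, RfD = RfD,
            CSF = CSF, unit_conversion = unit_conversion)
  if (any(!vapply(p, function(v) is.numeric(v) && is.finite(v) && v > 0,
                  logical(1))))
    stop("all exposure parameters must be strictly positive numbers")
  if (EF > 366) stop("EF cannot exceed 366 day/yr")
  structure(p, class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure parameters (drinking-water ingestion)\n")
  cat(sprintf("  IR %g L/day, BW %g kg, ED %g yr, EF %g day/yr, AT %g day\n",
              x$IR, x$BW, x$ED, x$EF, x$AT))
  cat(sprintf("  RfD %g ug/(kg day), CSF %g (mg/(kg day))^-1\n",
              x$RfD, x$CSF))
  invisible(x)
}

#' Daily intake of arsenic from drinking water
#'
#' `DI = C * IR / BW` in ug/kg/day.
#'
#' @param C Arsenic concentration(s), ug/L, non-negative.
#' @param p An [exposure_params()].
#' @return Daily intake, same length as `C`.
#' @export
daily_intake <- function(C, p = exposure_params()) {
  stopifnot(inherits(p, "exposure_params"))
  if (any(C < 0)) stop("concentration must be >= 0")
  C * p$IR / p$BW
}

#' Non-carcinogenic hazard quotient
#'
#' `HQ = DI / RfD`; values above 1 flag possible adverse non-cancer
#' effects.
#'
#' @inheritParams daily_intake
#' @return Dimensionless HQ.
#' @export
hazard_quotient <- function(C, p = exposure_params()) {
  daily_intake(C, p) / p$RfD
}

#' Carcinogenic target risk
#'
#' Incremental lifetime cancer risk
#' `TR = (C * IR / BW) * (EF * ED / AT) * CSF * 10^-3`, with the 10^-3
#' factor converting the intake from ug to mg to match the slope
#' factor's units.
#'
#' @inheritParams daily_intake
#' @return Dimensionless TR.
#' @export
target_risk <- function(C, p = exposure_params()) {
  daily_intake(C, p) * (p$EF * p$ED / p$AT) * p$CSF * p$unit_conversion
}

#' Classify carcinogenic target risk into three levels
#'
#' Level 1 (negligible): TR below 10^-6. Level 2 (acceptable): TR between
#' 10^-6 and 10^-4, boundaries inclusive. Level 3 (unacceptable): TR
#' above 10^-4.
#'
#' @param TR Non-negative target risk values.
#' @param lower,upper The two boundaries (defaults `1e-6`, `1e-4`).
#' @return Integer levels in 1:3.
#' @export
classify_tr <- function(TR, lower = 1e-6, upper = 1e-4) {
  if (any(TR < 0)) stop("TR must be >= 0")
  ifelse(TR < lower, 1L, ifelse(TR <= upper, 2L, 3L))
}

#' Classify hazard quotient into two levels
#'
#' Level 1 (adverse effect possible): HQ strictly greater than 1.
#' Level 2 (acceptable): HQ at or below 1.
#'
#' @param HQ Non-negative hazard quotients.
#' @param threshold Default 1.
#' @return Integer levels in 1:2.
#' @export
classify_hq <- function(HQ, threshold = 1) {
  if (any(HQ < 0)) stop("HQ must be >= 0")
  ifelse(HQ > threshold, 1L, 2L)
}

#' Irrigation/aquaculture suitability
#'
#' Water exceeding the 50 ug/L acceptable limit for irrigation and
#' aquaculture is classed unsuitable; the limit itself is acceptable.
#'
#' @param C Non-negative concentrations (ug/L).
#' @param limit Acceptable limit (default 50).
#' @return Factor with levels `suitable`, `unsuitable`.
#' @export
classify_suitability <- function(C, limit = 50) {
  if (any(C < 0)) stop("concentration must be >= 0")
  factor(ifelse(C > limit, "unsuitable", "suitable"),
         levels = c("suitable", "unsuitable"))
}

#' Four-level concentration classification
#'
#' Half-open, lower-inclusive classes `[0,5)`, `[5,10)`, `[10,50)` and
#' `[50, Inf)` ug/L — the 10 ug/L WHO drinking-water guideline and the
#' 50 ug/L irrigation limit are two of the three cut points.
#'
#' @param C Non-negative concentrations (ug/L).
#' @return Factor with levels `"<5"`, `"5-10"`, `"10-50"`, `">50"`.
#' @export
concentration_class <- function(C) {
  if (any(C < 0)) stop("concentration must be >= 0")
  cut(C, breaks = c(0, 5, 10, 50, Inf), right = FALSE,
      include.lowest = TRUE, labels = c("<5", "5-10", "10-50", ">50"))
}

#' Full risk table for a vector of concentrations
#'
#' @param C Non-negative concentrations (ug/L).
#' @param p An [exposure_params()].
#' @return Data frame with columns `conc_ugL, DI, HQ, TR, hq_level,
#'   tr_level, conc_class, suitability`.
#' @export
risk_table <- function(C, p = exposure_params()) {
  DI <- daily_intake(C, p)
  HQ <- DI / p$RfD
  TR <- target_risk(C, p)
  data.frame(conc_ugL = C, DI = DI, HQ = HQ, TR = TR,
             hq_level = classify_hq(HQ), tr_level = classify_tr(TR),
             conc_class = concentration_class(C),
             suitability = classify_suitability(C),
             stringsAsFactors = FALSE)
}

#' Append risk layers to a concentration grid
#'
#' Computes DI, HQ, TR and the classification layers from the grid's
#' back-transformed (ug/L) concentration layer.
#'
#' @param cgrid A `concentration_grid` (from [ok_map()] or [bpnn_map()]).
#' @param p An [exposure_params()].
#' @return The grid with layers `DI`, `HQ`, `TR`, `hq_level`,
#'   `tr_level`, `conc_class` (integer codes 1-4), `suitability`
#'   (1 = suitable, 2 = unsuitable) added.
#' @export
add_risk_layers <- function(cgrid, p = exposure_params()) {
  stopifnot(inherits(cgrid, "concentration_grid"))
  conc <- cgrid$layers$conc_ugL
  shp <- function(v) matrix(v, nrow = nrow(conc), ncol = ncol(conc))
  cgrid$layers$DI <- shp(daily_intake(as.numeric(conc), p))
  cgrid$layers$HQ <- shp(hazard_quotient(as.numeric(conc), p))
  cgrid$layers$TR <- shp(target_risk(as.numeric(conc), p))
  cgrid$layers$hq_level <- shp(classify_hq(as.numeric(cgrid$layers$HQ)))
  cgrid$layers$tr_level <- shp(classify_tr(as.numeric(cgrid$layers$TR)))
  cgrid$layers$conc_class <- shp(as.integer(concentration_class(
    as.numeric(conc))))
  cgrid$layers$suitability <- shp(as.integer(classify_suitability(
    as.numeric(conc))))
  cgrid
}
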