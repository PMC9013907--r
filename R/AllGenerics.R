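## Accessor generics and show methods.

#' @rdname Transition
#' @param object,method an object of the documented class
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname Transition
#' @export
setMethod("transitions", "SRMMethod", function(object) object@transitions)

#' @describeIn Transition label of a transition, e.g. `"405>359"`
#' @param x a `Transition`
#' @export
transitionLabel <- function(x) {
  sprintf("%g>%g", x@precursorMz, x@productMz)
}

#' @describeIn Transition the quantifier transition of a method
#' @export
quantifier <- function(method) {
  .byRole(method, "quantifier")[[1]]
}

#' @describeIn Transition the internal-standard transition of a method
#' @export
internalStandard <- function(method) {
  .byRole(method, "internal_standard")[[1]]
}

#' @describeIn Transition the qualifier transitions of a method (a list)
#' @export
qualifiers <- function(method) {
  .byRole(method, "qualifier")
}

.byRole <- function(method, role) {
  tr <- transitions(method)
  tr[vapply(tr, function(t) t@role == role, logical(1))]
}

#' @describeIn CalibrationFit-class calibration slope (ratio per pg/mg)
#' @param object a `CalibrationFit`
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname CalibrationFit-class
#' @export
setMethod("slope", "CalibrationFit", function(object) object@slope)

#' @describeIn CalibrationFit-class calibration intercept (ratio)
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname CalibrationFit-class
#' @export
setMethod("intercept", "CalibrationFit", function(object) object@intercept)

#' @describeIn CalibrationFit-class residual standard deviation s_y/x
#' @export
setGeneric("residualSd", function(object) standardGeneric("residualSd"))

#' @rdname CalibrationFit-class
#' @export
setMethod("residualSd", "CalibrationFit", function(object) object@residualSd)

#' @describeIn CalibrationFit-class coefficient of determination
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname CalibrationFit-class
#' @export
setMethod("rSquared", "CalibrationFit", function(object) object@rSquared)

#' @describeIn CalibrationFit-class working range c(low, high) in pg/mg
#' @export
setGeneric("calibrationRange",
           function(object) standardGeneric("calibrationRange"))

#' @rdname CalibrationFit-class
#' @export
setMethod("calibrationRange", "CalibrationFit", function(object) object@range)

setMethod("show", "Transition", function(object) {
  cat(sprintf("Transition %s (%s, CE %g V)\n", transitionLabel(object),
              object@role, object@collisionEnergy))
})

setMethod("show", "SRMMethod", function(object) {
  cat(sprintf("SRMMethod with %d transitions\n", length(object@transitions)))
  for (t in object@transitions)
    cat(sprintf("  %-8s %s (CE %g V)\n", transitionLabel(t), t@role,
                t@collisionEnergy))
})

setMethod("show", "SRMTrace", function(object) {
  cat(sprintf("SRMTrace %s: %d samples, %.1f-%.1f s\n",
              transitionLabel(object@transition), length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "PeakResult", function(object) {
  cat(sprintf(
    "PeakResult: rt %.2f s, height %.1f, area %.1f, noise %.2f, S/N %.1f\n",
    object@retentionTime, object@height, object@area, object@noiseRms,
    object@snr))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: ratio = %.5g + %.5g * conc (n = %d, R2 = %.4f)\n",
    object@intercept, object@slope, object@n, object@rSquared))
  cat(sprintf("  s_y/x = %.5g, range %g-%g pg/mg\n", object@residualSd,
              object@range[1], object@range[2]))
})

setMethod("show", "LinearityVerdict", function(object) {
  verdict <- function(p) if (isTRUE(p)) "pass" else "FAIL"
  cat(sprintf("LinearityVerdict (alpha = %g):\n", object@alpha))
  cat(sprintf("  Fisher homoscedasticity: F = %.3g (%s)\n", object@fisherF,
              verdict(object@fisherPass)))
  cat(sprintf("  Lack-of-fit: F = %.3g on (%d, %d) df (%s)\n", object@lofF,
              object@lofDf[1], object@lofDf[2], verdict(object@lofPass)))
  cat(sprintf("  Mandel: F = %.3g on (%d, %d) df (%s)\n", object@mandelF,
              object@mandelDf[1], object@mandelDf[2],
              verdict(object@mandelPass)))
})

setMethod("show", "LodResult", function(object) {
  if (!object@determined) {
    cat(sprintf("LodResult (%s): undetermined\n", object@method))
  } else if (object@method == "hubaux_vos") {
    cat(sprintf(
      "LodResult (Hubaux-Vos): LOD %.4g pg/mg, decision limit %.4g pg/mg (alpha %g, beta %g)\n",
      object@lod, object@decisionLimit, object@alpha, object@beta))
  } else {
    cat(sprintf("LodResult (S/N): LOD %.4g pg/mg\n", object@lod))
  }
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: overall %s\n",
              if (object@overallPass) "PASS" else "FAIL"))
  if (length(object@reasons))
    cat(paste0("  reason: ", object@reasons, "\n"), sep = "")
  cat(sprintf("  LOQ: %s pg/mg\n",
              if (object@loqDefined) format(object@loq) else "undefined"))
  if (nrow(object@qc)) {
    cat("  QC levels:\n")
    for (i in seq_len(nrow(object@qc)))
      cat(sprintf("    %g pg/mg [%s]: RSD %g%%, bias %g%% (n = %d)\n",
                  object@qc$nominal[i], object@qc$scope[i],
                  roundHalfUp(object@qc$rsd_percent[i]),
                  roundHalfUp(object@qc$bias_percent[i], 1),
                  object@qc$n[i]))
  }
})
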