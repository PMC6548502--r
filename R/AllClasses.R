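#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SpikeInFit: normalization factors estimated from spike-ins
#'
#' Holds the result of fitting the spike-in count model: per-sample depth
#' factors F_j, per-sample cross-contamination fractions chi_j (fixed to 1
#' for RNA-seq samples), per-spike extraction probabilities and the shared
#' negative binomial dispersion theta.
#'
#' @slot samples data.frame with columns sample_id, protocol, size_factor,
#'   chi.
#' @slot p data.frame with columns spike_id, class (one of
#'   \code{labeled}, \code{unlabeled_ttseq}, \code{unlabeled_rnaseq}) and p.
#' @slot theta shared NB dispersion.
#' @slot logLik log-likelihood at the optimum.
#' @slot convergence list with optimizer diagnostics.
#' @export
setClass("SpikeInFit",
  representation(samples = "data.frame", p = "data.frame",
                 theta = "numeric", logLik = "numeric",
                 convergence = "list"))

setValidity("SpikeInFit", function(object) {
  s <- object@samples
  msg <- character(0)
  if (!all(c("sample_id", "protocol", "size_factor", "chi") %in% names(s)))
    msg <- c(msg, "samples table incomplete")
  else {
    if (any(s$size_factor <= 0)) msg <- c(msg, "size factors must be positive")
    if (any(s$chi <= 0 | s$chi > 1)) msg <- c(msg, "chi must lie in (0,1]")
    if (any(s$chi[s$protocol == "rnaseq"] != 1))
      msg <- c(msg, "chi must equal 1 for RNA-seq samples")
  }
  if (length(object@theta) != 1 || object@theta <= 0)
    msg <- c(msg, "theta must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpikeInFit per-sample factor table
#' @param object,x a SpikeInFit
#' @export
sampleFactors <- function(object) object@samples

#' @describeIn SpikeInFit named vector of depth factors F_j
#' @export
depthFactors <- function(object) {
  with(object@samples, stats::setNames(size_factor, sample_id))
}

#' @describeIn SpikeInFit named vector of cross-contamination fractions
#' @export
crossContamination <- function(object) {
  with(object@samples, stats::setNames(chi, sample_id))
}

#' @describeIn SpikeInFit shared NB dispersion theta
#' @export
dispersion <- function(object) object@theta

#' @describeIn SpikeInFit spike-in extraction probabilities
#' @export
extractionProbabilities <- function(object) object@p

setMethod("show", "SpikeInFit", function(object) {
  s <- object@samples
  cat("SpikeInFit:", nrow(s), "samples,",
      sum(s$protocol == "ttseq"), "TT-seq /",
      sum(s$protocol == "rnaseq"), "RNA-seq\n")
  cat(sprintf("  dispersion theta = %.4g, logLik = %.4g\n",
              object@theta, object@logLik))
  tt <- s$chi[s$protocol == "ttseq"]
  if (length(tt))
    cat(sprintf("  TT-seq cross-contamination chi: median %.3g (range %.3g-%.3g)\n",
                stats::median(tt), min(tt), max(tt)))
})

#' RateEstimates: per-bond kinetic parameter estimates
#'
#' Container for maximum-likelihood kinetic estimates. The estimate table
#' always carries \code{bond_id}, model-specific rate columns, the
#' log-likelihood at the optimum, the number of successful random
#' initializations, the total raw count of the bond and a \code{status}
#' flag (\code{ok}, \code{low_count} or \code{failed}).
#'
#' For the first-order model the columns are \code{alpha} (synthesis rate,
#' normalized counts/min), \code{beta} (decay rate, 1/min) and
#' \code{half_life} = ln(2)/beta in minutes. The delay model reports
#' \code{alpha}, \code{tau} (intronic transcription delay, min) and
#' \code{lambda} (first-step cleavage rate, 1/min); the coupled model
#' reports \code{alpha}, \code{beta_spl} and \code{beta_deg}.
#'
#' @slot estimates data.frame of per-bond estimates.
#' @slot model one of \code{first_order}, \code{delay}, \code{coupled}.
#' @slot design the labeling design used.
#' @export
setClass("RateEstimates",
  representation(estimates = "data.frame", model = "character",
                 design = "data.frame"))

setValidity("RateEstimates", function(object) {
  msg <- character(0)
  if (!object@model %in% c("first_order", "delay", "coupled"))
    msg <- c(msg, "unknown model")
  e <- object@estimates
  if (!"bond_id" %in% names(e)) msg <- c(msg, "estimates need bond_id")
  if (object@model == "first_order" && nrow(e) &&
      any(ok <- e$status == "ok")) {
    if (any(abs(e$half_life[ok] - log(2) / e$beta[ok]) >
            1e-8 * e$half_life[ok]))
      msg <- c(msg, "half_life must equal ln(2)/beta")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RateEstimates the per-bond estimate table
#' @param object a RateEstimates
#' @export
rateTable <- function(object) object@estimates

#' @describeIn RateEstimates named vector of synthesis rates (status ok only)
#' @export
synthesisRates <- function(object) {
  e <- object@estimates[object@estimates$status == "ok", ]
  stats::setNames(e$alpha, e$bond_id)
}

#' @describeIn RateEstimates named vector of half-lives in minutes
#'   (first-order model; status ok only)
#' @export
halfLives <- function(object) {
  if (object@model != "first_order")
    stop("half-lives are reported by the first-order model; see rateTable()")
  e <- object@estimates[object@estimates$status == "ok", ]
  stats::setNames(e$half_life, e$bond_id)
}

#' @describeIn RateEstimates fitted kinetic model kind
#' @export
modelKind <- function(object) object@model

setMethod("show", "RateEstimates", function(object) {
  e <- object@estimates
  cat("RateEstimates (", object@model, " model): ", nrow(e), " bonds; ",
      sum(e$status == "ok"), " ok, ",
      sum(e$status == "low_count"), " below count threshold, ",
      sum(e$status == "failed"), " failed\n", sep = "")
  if (object@model == "first_order" && any(e$status == "ok")) {
    hl <- e$half_life[e$status == "ok"]
    cat(sprintf("  half-life (min): median %.3g, IQR %.3g-%.3g\n",
                stats::median(hl), stats::quantile(hl, 0.25),
                stats::quantile(hl, 0.75)))
  }
})
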