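#' Labeling design of a 4sU time-series experiment
#'
#' A labeling design records, per sequencing sample, the protocol (TT-seq,
#' i.e. purified 4sU-labeled RNA, or total RNA-seq), the 4sU labeling
#' duration in minutes and the replicate. The default mirrors the study
#' design this package models: TT-seq and RNA-seq after 2, 5, 10, 15, 20,
#' 30 and 60 min of labeling, two biological replicates each (28 samples).
#'
#' @param protocol character vector, each element \code{"ttseq"} or
#'   \code{"rnaseq"}.
#' @param time labeling duration in minutes; must be positive for TT-seq
#'   samples. For RNA-seq samples the value is recorded but plays no role
#'   in the kinetic model (total RNA is at steady state).
#' @param replicate replicate identifiers.
#' @param sample_id optional explicit sample ids; default
#'   \code{<protocol>_<time>min_r<replicate>}.
#' @return a \code{data.frame} with columns \code{sample_id},
#'   \code{protocol}, \code{time}, \code{replicate}.
#' @examples
#' d <- defaultDesign()
#' table(d$protocol)
#' @export
labelingDesign <- function(protocol, time, replicate, sample_id = NULL) {
  protocol <- match.arg(protocol, c("ttseq", "rnaseq"), several.ok = TRUE)
  n <- max(length(protocol), length(time), length(replicate))
  protocol <- rep_len(protocol, n)
  time <- rep_len(as.numeric(time), n)
  replicate <- rep_len(replicate, n)
  if (any(protocol == "ttseq" & !(time > 0)))
    stop("TT-seq samples require a positive labeling duration")
  if (is.null(sample_id))
    sample_id <- sprintf("%s_%gmin_r%s", protocol, time, replicate)
  if (anyDuplicated(sample_id))
    stop("sample ids must be unique")
  data.frame(sample_id = sample_id, protocol = protocol, time = time,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' @rdname labelingDesign
#' @param durations labeling durations (minutes) used for both protocols.
#' @param replicates number of replicates per protocol x duration.
#' @export
defaultDesign <- function(durations = c(2, 5, 10, 15, 20, 30, 60),
                          replicates = 2) {
  grid <- expand.grid(time = durations, replicate = seq_len(replicates),
                      protocol = c("ttseq", "rnaseq"),
                      stringsAsFactors = FALSE)
  labelingDesign(grid$protocol, grid$time, grid$replicate)
}

checkDesign <- function(design) {
  need <- c("sample_id", "protocol", "time", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("design must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (!all(design$protocol %in% c("ttseq", "rnaseq")))
    stop("protocol must be 'ttseq' or 'rnaseq'")
  invisible(design)
}

## Resolve per-sample normalization factors against a design. `factors` may
## be a SpikeInFit or a list(size_factors=, chi=, theta=) with named or
## unnamed (design-ordered) vectors. Returns list(F, chi, theta) aligned to
## design rows; chi forced to 1 for RNA-seq samples.
resolveFactors <- function(factors, design) {
  checkDesign(design)
  if (is(factors, "SpikeInFit")) {
    tab <- sampleFactors(factors)
    theta <- dispersion(factors)
    F <- tab$size_factor[match(design$sample_id, tab$sample_id)]
    chi <- tab$chi[match(design$sample_id, tab$sample_id)]
  } else if (is.list(factors)) {
    theta <- factors$theta
    alignVec <- function(v) {
      if (is.null(names(v))) rep_len(v, nrow(design))
      else unname(v[design$sample_id])
    }
    F <- alignVec(factors$size_factors)
    chi <- alignVec(factors$chi)
  } else stop("factors must be a SpikeInFit or a list")
  if (anyNA(F) || anyNA(chi))
    stop("factors missing for some samples in the design")
  chi[design$protocol == "rnaseq"] <- 1
  if (any(F <= 0)) stop("size factors must be positive")
  if (any(chi <= 0 | chi > 1)) stop("chi must lie in (0, 1]")
  if (is.null(theta) || theta <= 0) stop("a positive dispersion is required")
  list(F = as.numeric(F), chi = as.numeric(chi), theta = as.numeric(theta))
}
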