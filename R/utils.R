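#' Negative binomial log density (mean/dispersion form)
#'
#' Log density of the negative binomial distribution parameterized by mean
#' \code{mu} and dispersion (size) \code{theta}, so that the variance equals
#' \code{mu + mu^2/theta}. Written in terms of \code{lgamma} so that
#' non-integer "counts" (e.g. noiseless expected counts used in round-trip
#' tests) are handled as a continuous relaxation; for integer counts it is
#' identical to \code{dnbinom(k, size = theta, mu = mu, log = TRUE)}.
#'
#' @param k observed counts (numeric vector, >= 0).
#' @param mu expected counts (positive).
#' @param theta dispersion; larger values approach the Poisson limit.
#' @return numeric vector of log densities.
#' @export
nbLogDensity <- function(k, mu, theta) {
  stopifnot(all(k >= 0), all(theta > 0))
  mu <- pmax(mu, 1e-12)
  lgamma(k + theta) - lgamma(theta) - lgamma(k + 1) +
    theta * (log(theta) - log(theta + mu)) +
    k * (log(mu) - log(theta + mu))
}

#' @rdname nbLogDensity
#' @export
nbLogLik <- function(k, mu, theta) sum(nbLogDensity(k, mu, theta))

#' Evaluate code under a private RNG seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded simulations do not disturb
#' the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
withLocalSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## deterministic small-integer hash of strings, used to assign CV folds by id
stringHash <- function(x, mod = .Machine$integer.max) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

logit <- function(p) log(p) - log1p(-p)
expit <- function(x) 1 / (1 + exp(-x))

geomMean <- function(x) exp(mean(log(x)))

gcFraction <- function(x) {
  chars <- strsplit(toupper(as.character(x)), "")[[1]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0) return(NA_real_)
  mean(acgt %in% c("G", "C"))
}
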