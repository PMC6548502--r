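## Maximum-likelihood fitting of per-bond kinetic models.
##
## Counts k_ij for one bond across the samples of a labeling design are
## modeled as negative binomial with mean given by the kinetic model
## expectation (modelExpectation) and the shared dispersion theta from the
## spike-in fit. Optimization runs on log-transformed parameters with BFGS,
## initialized from several independent random draws; the reported solution
## is the element-wise median across successful runs, which guards against
## occasional convergence to poor local optima.

## random initialization ranges (natural scale)
.initRanges <- list(alpha = c(1e-2, 1e3), half_life = c(0.1, 1e4),
                    tau = c(0.1, 10))

.runifLog <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

## parameter bookkeeping per model: names on log scale, init draw
.modelPars <- function(model) {
  switch(model,
    first_order = c("alpha", "beta"),
    delay = c("alpha", "tau", "lambda"),
    coupled = c("alpha", "beta_spl", "beta_deg"))
}

.drawInits <- function(model, n) {
  a <- .runifLog(n, .initRanges$alpha)
  hl <- .runifLog(n, .initRanges$half_life)
  switch(model,
    first_order = cbind(alpha = a, beta = log(2) / hl),
    delay = cbind(alpha = a, tau = .runifLog(n, .initRanges$tau),
                  lambda = log(2) / hl),
    coupled = cbind(alpha = a, beta_spl = log(2) / .runifLog(n, .initRanges$half_life),
                    beta_deg = log(2) / hl))
}

## negative log-likelihood for one bond, parameters on log scale
.bondNll <- function(logpar, model, k, design, F, chi, theta) {
  if (any(!is.finite(logpar)) || any(abs(logpar) > 50)) return(1e18)
  par <- as.list(exp(logpar))
  names(par) <- .modelPars(model)
  mu <- modelExpectation(model, par, design, F, chi)
  if (any(!is.finite(mu)) || any(mu < 0)) return(1e18)
  nll <- -sum(nbLogDensity(k, mu, theta))
  if (!is.finite(nll)) 1e18 else nll
}

## analytic gradient, first-order model only (the hot path in simulations)
.firstOrderGrad <- function(logpar, model, k, design, F, chi, theta) {
  if (any(!is.finite(logpar)) || any(abs(logpar) > 50)) return(c(0, 0))
  a <- exp(logpar[1]); b <- exp(logpar[2])
  tt <- design$protocol == "ttseq"
  ss <- F * a / b
  mu <- ss
  e <- exp(-design$time[tt] * b)
  mu[tt] <- ss[tt] * (1 + e * (chi[tt] - 1))
  mu <- pmax(mu, 1e-12)
  dldmu <- k / mu - (k + theta) / (mu + theta)
  dmu_la <- mu
  dmu_lb <- -mu
  dmu_lb[tt] <- dmu_lb[tt] - F[tt] * a * design$time[tt] * e * (chi[tt] - 1)
  -c(sum(dldmu * dmu_la), sum(dldmu * dmu_lb))
}

## fit a single bond: multi-start BFGS, median of successful runs
.fitOneBond <- function(k, model, design, F, chi, theta, inits,
                        extra_rounds = 3) {
  gr <- if (model == "first_order") .firstOrderGrad else NULL
  pars <- .modelPars(model)
  sols <- matrix(NA_real_, nrow = 0, ncol = length(pars))
  vals <- numeric(0)
  round <- 0
  repeat {
    for (i in seq_len(nrow(inits))) {
      fit <- tryCatch(
        stats::optim(log(inits[i, ]), .bondNll, gr = gr, model = model,
                     k = k, design = design, F = F, chi = chi, theta = theta,
                     method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$convergence == 0 && fit$value < 1e17 &&
          all(is.finite(fit$par))) {
        sol <- exp(fit$par)
        ## the coupled product curve is invariant under swapping the two
        ## rates (with alpha rescaled to keep the steady state): pick the
        ## physical branch where splicing is the fast step
        if (model == "coupled" && sol[2] < sol[3])
          sol <- c(sol[1] * sol[2] / sol[3], sol[3], sol[2])
        sols <- rbind(sols, sol)
        vals <- c(vals, fit$value)
      }
    }
    if (nrow(sols) > 0 || round >= extra_rounds) break
    round <- round + 1
    inits <- .drawInits(model, nrow(inits))
  }
  if (nrow(sols) == 0)
    return(list(par = stats::setNames(rep(NA_real_, length(pars)), pars),
                logLik = NA_real_, n_inits_used = 0L, status = "failed"))
  ## median only over runs that reached the best optimum: runs stuck in a
  ## clearly worse local mode (e.g. the degenerate plateau with alpha and
  ## beta jointly diverging) would poison the element-wise median
  top <- vals <= min(vals) + 0.5
  sols <- sols[top, , drop = FALSE]
  med <- apply(sols, 2, stats::median)
  names(med) <- pars
  ll <- -.bondNll(log(med), model, k, design, F, chi, theta)
  list(par = med, logLik = ll, n_inits_used = nrow(sols), status = "ok")
}

.fitBondModel <- function(counts, design, factors, model,
                          min_total_count = 100, n_starts = 10, seed = 1) {
  checkDesign(design)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list("bond_1", NULL))
  if (ncol(counts) != nrow(design))
    stop("counts must have one column per design sample")
  if (!is.null(colnames(counts))) {
    if (!all(design$sample_id %in% colnames(counts)))
      stop("counts are missing samples present in the design")
    counts <- counts[, design$sample_id, drop = FALSE]
  }
  fac <- resolveFactors(factors, design)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("bond_", seq_len(nrow(counts)))
  total <- rowSums(counts)
  pars <- .modelPars(model)

  ## pre-draw every initialization so results are reproducible and
  ## independent of fitting order
  inits <- withLocalSeed(seed, {
    lapply(seq_len(nrow(counts)), function(i) .drawInits(model, n_starts))
  })

  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (total[i] < min_total_count) {
      rows[[i]] <- c(as.list(stats::setNames(rep(NA_real_, length(pars)), pars)),
                     list(logLik = NA_real_, n_inits_used = 0L,
                          status = "low_count"))
      next
    }
    fit <- withLocalSeed(seed + i, {
      .fitOneBond(counts[i, ], model, design, fac$F, fac$chi, fac$theta,
                  inits[[i]])
    })
    rows[[i]] <- c(as.list(fit$par),
                   list(logLik = fit$logLik, n_inits_used = fit$n_inits_used,
                        status = fit$status))
  }
  est <- do.call(rbind, lapply(rows, as.data.frame))
  est <- cbind(bond_id = ids, est, total_count = unname(total))
  if (model == "first_order")
    est$half_life <- log(2) / est$beta
  rownames(est) <- NULL
  new("RateEstimates", estimates = est, model = model, design = design)
}

#' Fit the first-order kinetic model per bond
#'
#' Maximizes the negative binomial log-likelihood of the counts of each
#' bond across all samples, with expectations from
#' \code{\link{expectedBondCount}}. Each bond is fitted with
#' \code{n_starts} independent random initializations (synthesis rate
#' log-uniform over 0.01-1000 normalized counts/min, half-life log-uniform
#' over 0.1-10000 min) and the reported rates are the element-wise medians
#' over the successful runs. Bonds whose total raw count across samples is
#' below \code{min_total_count} (default 100, the coverage filter under
#' which simulations show relative errors typically surpassing 100%) are
#' skipped with status \code{low_count}.
#'
#' @param counts numeric matrix, bonds x samples (column names matching
#'   \code{design$sample_id} if present), or a vector for a single bond.
#' @param design labeling design, see \code{\link{labelingDesign}}.
#' @param factors a \code{\link{SpikeInFit}} or a list with elements
#'   \code{size_factors}, \code{chi} and \code{theta}.
#' @param min_total_count minimum total raw count per bond.
#' @param n_starts number of random initializations per bond.
#' @param seed integer seed making the multi-start fit deterministic.
#' @return a \code{\link{RateEstimates}} object.
#' @export
fitFirstOrder <- function(counts, design, factors, min_total_count = 100,
                          n_starts = 10, seed = 1) {
  .fitBondModel(counts, design, factors, "first_order",
                min_total_count, n_starts, seed)
}

#' Fit the delay model for donor bonds
#'
#' Donor bond cleavage cannot begin before the intron is transcribed up to
#' the branchpoint; the delay model represents this with a fixed delay
#' \code{tau} (min) followed by first-order kinetics of the first
#' transesterification with rate \code{lambda}. The labeled concentration
#' is 0 for t < tau and (alpha/lambda)(1 - exp(-(t - tau) lambda))
#' afterwards. Note the two parameters are only weakly identifiable from
#' TT-seq time series: a first-order fit to delay-generated data recovers
#' approximately tau + ln(2)/lambda as the apparent half-life.
#'
#' @inheritParams fitFirstOrder
#' @return a \code{\link{RateEstimates}} with columns alpha, tau, lambda.
#' @export
fitDelayModel <- function(counts, design, factors, min_total_count = 100,
                          n_starts = 10, seed = 1) {
  .fitBondModel(counts, design, factors, "delay",
                min_total_count, n_starts, seed)
}

#' Fit the coupled precursor-product model for junction bonds
#'
#' Junction bonds are formed by splicing of a precursor (first-order with
#' splicing rate \code{beta_spl}) and degraded with rate \code{beta_deg};
#' \code{alpha} is the precursor synthesis rate feeding the junction. A
#' first-order fit to data generated under this model recovers
#' approximately ln(2)/beta_spl + ln(2)/beta_deg as the apparent junction
#' half-life.
#'
#' @inheritParams fitFirstOrder
#' @return a \code{\link{RateEstimates}} with columns alpha, beta_spl,
#'   beta_deg.
#' @export
fitCoupledModel <- function(counts, design, factors, min_total_count = 100,
                            n_starts = 10, seed = 1) {
  .fitBondModel(counts, design, factors, "coupled",
                min_total_count, n_starts, seed)
}
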