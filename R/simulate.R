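## Synthetic-data generation for estimator validation.
##
## The simulator reproduces the full experimental design (TT-seq and
## RNA-seq at 2, 5, 10, 15, 20, 30, 60 min x 2 replicates, 28 samples),
## negative binomial count noise with a shared dispersion, per-sample depth
## factors and cross-contamination, and spike-in tables generated under the
## same expectation model the normalization fit assumes. Ground-truth rates
## are drawn log-uniformly over configurable ranges so that bias, coverage
## dependence and dynamic-range limits of the estimators can be measured
## against known truth.

#' Simulation configuration
#'
#' Bundles the stated world of a simulation: number of bonds, generating
#' kinetic model, parameter ranges (sampled log-uniformly), labeling
#' design, per-sample factors and NB dispersion, and the mandatory seed.
#'
#' Default parameter ranges: synthesis rate alpha log-uniform over
#' 0.1-100 normalized counts/min, half-life log-uniform over 1-1000 min,
#' intronic transcription delay tau log-uniform over 0.1-10 min, splicing
#' half-time log-uniform over 1-30 min and product half-life log-uniform
#' over 30-1000 min for the coupled model. Default factors: F_j = 1,
#' chi_j = 0.05 for TT-seq samples, theta = 20.
#'
#' @param n_bonds number of bonds to simulate.
#' @param model generating model: \code{first_order}, \code{delay} or
#'   \code{coupled}.
#' @param design labeling design (default \code{\link{defaultDesign}()}).
#' @param alpha_range,half_life_range,tau_range log-uniform ranges (lo, hi).
#' @param splicing_half_time_range,product_half_life_range log-uniform
#'   ranges (lo, hi) for the coupled model.
#' @param size_factors,chi per-sample true factors (scalar or per-sample
#'   vector); chi is forced to 1 for RNA-seq samples.
#' @param theta true NB dispersion.
#' @param seed integer seed (mandatory).
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_bonds, model = c("first_order", "delay",
                                                "coupled"),
                             design = defaultDesign(),
                             alpha_range = c(0.1, 100),
                             half_life_range = c(1, 1000),
                             tau_range = c(0.1, 10),
                             splicing_half_time_range = c(1, 30),
                             product_half_life_range = c(30, 1000),
                             size_factors = 1, chi = 0.05, theta = 20,
                             seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  checkDesign(design)
  for (r in list(alpha_range, half_life_range, tau_range,
                 splicing_half_time_range, product_half_life_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("parameter ranges must be positive with lo <= hi")
  }
  chi <- rep_len(chi, nrow(design))
  chi[design$protocol == "rnaseq"] <- 1
  cfg <- list(n_bonds = as.integer(n_bonds), model = model, design = design,
              alpha_range = alpha_range, half_life_range = half_life_range,
              tau_range = tau_range,
              splicing_half_time_range = splicing_half_time_range,
              product_half_life_range = product_half_life_range,
              size_factors = rep_len(size_factors, nrow(design)),
              chi = chi, theta = theta, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Draw ground-truth kinetic parameters
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame with \code{bond_id}, \code{model} and the true
#'   parameters of the configured model, plus \code{ref_half_life}: the
#'   half-life a first-order description should recover (ln2/beta for
#'   first-order truth, tau + ln2/lambda for delay truth,
#'   ln2/beta_spl + ln2/beta_deg for coupled truth).
#' @export
sampleGroundTruth <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_bonds
  withLocalSeed(config$seed, {
    alpha <- .runifLog(n, config$alpha_range)
    truth <- switch(config$model,
      first_order = {
        hl <- .runifLog(n, config$half_life_range)
        data.frame(alpha = alpha, beta = log(2) / hl, ref_half_life = hl)
      },
      delay = {
        ht <- .runifLog(n, config$half_life_range)
        tau <- .runifLog(n, config$tau_range)
        data.frame(alpha = alpha, tau = tau, lambda = log(2) / ht,
                   ref_half_life = tau + ht)
      },
      coupled = {
        hs <- .runifLog(n, config$splicing_half_time_range)
        hd <- .runifLog(n, config$product_half_life_range)
        data.frame(alpha = alpha, beta_spl = log(2) / hs,
                   beta_deg = log(2) / hd, ref_half_life = hs + hd)
      })
    cbind(bond_id = sprintf("bond_%05d", seq_len(n)),
          model = config$model, truth)
  })
}

## expected counts for every bond x sample of a truth table
.truthExpectations <- function(truth, config) {
  pars <- .modelPars(config$model)
  t(vapply(seq_len(nrow(truth)), function(i) {
    par <- as.list(truth[i, pars])
    modelExpectation(config$model, par, config$design,
                     config$size_factors, config$chi)
  }, numeric(nrow(config$design))))
}

#' Rescale synthesis rates to hit target total coverages
#'
#' Total coverage of a bond is its expected raw count summed over all
#' samples (the quantity the min-count filter acts on). Expectations are
#' linear in alpha, so each bond's alpha is rescaled to meet its target.
#'
#' @param truth a ground-truth table from \code{\link{sampleGroundTruth}}.
#' @param config the matching configuration.
#' @param coverage target total expected count, scalar or per bond.
#' @return the truth table with rescaled \code{alpha}.
#' @export
calibrateCoverage <- function(truth, config, coverage) {
  mu <- .truthExpectations(truth, config)
  truth$alpha <- truth$alpha * rep_len(coverage, nrow(truth)) / rowSums(mu)
  truth
}

#' Simulate bond counts under a ground truth
#'
#' Draws negative binomial counts with mean given by the configured
#' model's expectation in each sample (RNA-seq samples at steady state)
#' and the shared dispersion theta.
#'
#' @param truth ground-truth table.
#' @param config matching \code{\link{simulationConfig}}.
#' @param seed optional seed; defaults to \code{config$seed + 1} so that
#'   truth sampling and count noise use distinct streams.
#' @return integer matrix, bonds x samples, with the design's sample ids
#'   as column names.
#' @export
simulateBondCounts <- function(truth, config, seed = config$seed + 1) {
  mu <- .truthExpectations(truth, config)
  bad <- !is.finite(mu) | mu > 1e15
  if (any(bad)) {
    warning(sum(rowSums(bad) > 0), " bond(s) with overflowing expectations skipped")
    mu[bad] <- 0
  }
  counts <- withLocalSeed(seed, {
    matrix(stats::rnbinom(length(mu), size = config$theta, mu = mu),
           nrow = nrow(mu))
  })
  dimnames(counts) <- list(truth$bond_id, config$design$sample_id)
  counts
}

#' Simulate a spike-in count table
#'
#' Generates labeled and unlabeled spike-in counts under the normalization
#' expectation model with the configured true factors, for use as input to
#' \code{\link{fitSpikeInModel}}. The true extraction probabilities are
#' drawn to satisfy the model's identifiability constraints (geometric
#' mean of labeled p equal to \code{p_labeled_geomean}; geometric means of
#' unlabeled TT-seq and RNA-seq p equal), so fitted and true parameters
#' are directly comparable.
#'
#' @param config a \code{\link{simulationConfig}} (provides design,
#'   factors, theta and seed).
#' @param n_labeled,n_unlabeled numbers of spike-ins of each kind.
#' @param base_count typical expected count of a spike-in in an average
#'   sample (controls spike-in depth).
#' @param p_labeled_geomean constraint constant, as in
#'   \code{\link{fitSpikeInModel}}.
#' @return list with \code{counts} (matrix spikes x samples),
#'   \code{labeled} (logical), and \code{truth} (list of true F, chi,
#'   theta and p values).
#' @export
simulateSpikeIns <- function(config, n_labeled = 4, n_unlabeled = 4,
                             base_count = 1000, p_labeled_geomean = 0.5) {
  design <- config$design
  is_tt <- design$protocol == "ttseq"
  withLocalSeed(config$seed + 2, {
    lp <- stats::runif(n_labeled, -1, 1)
    p_lab <- exp(lp - mean(lp) + log(p_labeled_geomean))
    lr <- stats::runif(n_unlabeled, log(0.05), log(0.5))
    p_rna <- exp(lr)
    lt <- stats::runif(n_unlabeled, log(0.05), log(0.5))
    p_tt <- exp(lt - mean(lt) + mean(lr))
    F <- config$size_factors * base_count / p_labeled_geomean
    mu <- matrix(0, n_labeled + n_unlabeled, nrow(design))
    for (j in seq_len(nrow(design))) {
      mu[seq_len(n_labeled), j] <- F[j] * p_lab
      p <- if (is_tt[j]) p_tt else p_rna
      mu[n_labeled + seq_len(n_unlabeled), j] <- F[j] * p * config$chi[j]
    }
    counts <- matrix(stats::rnbinom(length(mu), size = config$theta, mu = mu),
                     nrow = nrow(mu))
    dimnames(counts) <- list(c(sprintf("labeled_%d", seq_len(n_labeled)),
                               sprintf("unlabeled_%d", seq_len(n_unlabeled))),
                             design$sample_id)
    list(counts = counts,
         labeled = rep(c(TRUE, FALSE), c(n_labeled, n_unlabeled)),
         truth = list(F = F, chi = config$chi, theta = config$theta,
                      p_lab = p_lab, p_tt = p_tt, p_rna = p_rna))
  })
}

#' Simulate, fit, and summarize estimator recovery
#'
#' Runs the full validation loop: draw ground truth under the configured
#' generating model, simulate counts, fit the requested model, and report
#' per-bond relative errors and relative levels of the half-life estimate
#' against the reference half-life (for mismatched-model studies the
#' reference is tau + ln2/lambda for delay truth and
#' ln2/beta_spl + ln2/beta_deg for coupled truth).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param fit_model model to fit: \code{first_order}, \code{delay} or
#'   \code{coupled}.
#' @param factors factors used for fitting; default the config's true
#'   factors (pass a \code{\link{SpikeInFit}} to emulate the full
#'   pipeline).
#' @param min_total_count,n_starts passed to the fitting routine.
#' @param coverage optional per-bond target coverage passed to
#'   \code{\link{calibrateCoverage}}.
#' @return list with \code{per_bond} (truth, estimates, relative level
#'   est/ref and relative error |est-ref|/ref) and \code{summary}
#'   (medians overall; fit failures are counted, not raised).
#' @export
recoveryStudy <- function(config, fit_model = "first_order",
                          factors = NULL, min_total_count = 0,
                          n_starts = 10, coverage = NULL) {
  truth <- sampleGroundTruth(config)
  if (!is.null(coverage)) truth <- calibrateCoverage(truth, config, coverage)
  counts <- simulateBondCounts(truth, config)
  if (is.null(factors))
    factors <- list(size_factors = config$size_factors, chi = config$chi,
                    theta = config$theta)
  est <- .fitBondModel(counts, config$design, factors, fit_model,
                       min_total_count = min_total_count,
                       n_starts = n_starts, seed = config$seed + 3)
  tab <- rateTable(est)
  est_hl <- switch(fit_model,
    first_order = tab$half_life,
    delay = tab$tau + log(2) / tab$lambda,
    coupled = log(2) / tab$beta_spl + log(2) / tab$beta_deg)
  per_bond <- cbind(truth,
                    est = tab[, setdiff(names(tab), "bond_id")],
                    est_half_life = est_hl)
  per_bond$rel_level <- est_hl / truth$ref_half_life
  per_bond$rel_error <- abs(est_hl - truth$ref_half_life) /
    truth$ref_half_life
  ## the multiplicative error currency: exp(|log(est/ref)|) - 1, which
  ## penalizes x-fold under- and overestimation symmetrically
  per_bond$rel_error_mult <- pmax(est_hl / truth$ref_half_life,
                                  truth$ref_half_life / est_hl) - 1
  ok <- per_bond$est.status == "ok"
  list(per_bond = per_bond,
       summary = data.frame(
         n = nrow(per_bond), n_ok = sum(ok),
         n_failed = sum(per_bond$est.status == "failed"),
         median_rel_level = stats::median(per_bond$rel_level[ok]),
         median_rel_error = stats::median(per_bond$rel_error[ok]),
         median_rel_error_mult = stats::median(per_bond$rel_error_mult[ok])))
}
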