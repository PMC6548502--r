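## Spike-in based normalization.
##
## Labeled and unlabeled synthetic RNA spike-ins are added at constant
## amounts to every sample before purification. Labeled spike-ins behave
## like newly synthesized RNA and calibrate sequencing depth and the
## labeled-fraction size of each library (F_j); unlabeled spike-ins should
## be absent from a perfect TT-seq library, so their counts measure the
## cross-contamination fraction chi_j of unlabeled RNA co-purified. For
## RNA-seq libraries nothing is purified away and chi_j = 1 by definition.
##
## The expectation of spike-in i in sample j is
##   E_ij = F_j * p_ij * w_ij,  w_ij = 1 (labeled) or chi_j (unlabeled),
## where p_ij is the extraction probability: one value per labeled spike-in
## shared across all samples, and one TT-seq and one RNA-seq value per
## unlabeled spike-in. Counts are negative binomial with a dispersion theta
## shared across the whole data set.
##
## Two scale degeneracies are fixed by constraints: (i) F_j and p trade off
## (F*c, p/c), resolved by pinning the geometric mean of the labeled-spike
## p at a configured constant; (ii) for unlabeled spikes the products
## F_j * p_i^tt * chi_j only identify p^tt and chi up to a constant,
## resolved by constraining the geometric mean of p^tt to equal that of
## p^rna across unlabeled spikes.

#' Expected spike-in count
#'
#' @param size_factor depth factor F of the sample, positive.
#' @param p extraction probability in (0, 1].
#' @param chi cross-contamination fraction in (0, 1]; 1 for RNA-seq. The
#'   boundary chi = 0 (perfect purification) is also accepted.
#' @param labeled logical; TRUE for a labeled spike-in.
#' @return expected count F * p for labeled spikes, F * p * chi for
#'   unlabeled ones.
#' @examples
#' expectedSpikeCount(2, 0.5, 0.1, labeled = FALSE)  # 0.1
#' @export
expectedSpikeCount <- function(size_factor, p, chi, labeled) {
  stopifnot(all(size_factor > 0), all(p > 0 & p <= 1))
  if (any(chi < 0 | chi > 1)) stop("chi must lie in [0, 1]")
  size_factor * p * ifelse(labeled, 1, chi)
}

#' Background subtraction of cross-contaminating unlabeled signal
#'
#' Depth-normalizes a labeled-fraction count and removes the expected
#' contribution of co-purified unlabeled RNA estimated from a matched
#' RNA-seq sample: K/F - chi * K_rnaseq / F_rnaseq. The result may be
#' negative and is reported as-is.
#'
#' @param count raw count in the TT-seq (or 4sU-seq) sample.
#' @param size_factor,chi factors of that sample.
#' @param count_rnaseq,size_factor_rnaseq matched RNA-seq count and factor.
#' @return corrected normalized count.
#' @export
backgroundSubtract <- function(count, size_factor, chi,
                               count_rnaseq, size_factor_rnaseq) {
  if (missing(count_rnaseq) || is.null(count_rnaseq))
    stop("a matched RNA-seq reference count is required")
  count / size_factor - chi * count_rnaseq / size_factor_rnaseq
}

## ---- model internals -------------------------------------------------

## index bookkeeping for the packed parameter vector
.spikeParIndex <- function(n_samples, tt_idx, n_lab, n_unl) {
  i <- 0
  idx <- list()
  idx$logF <- i + seq_len(n_samples); i <- i + n_samples
  idx$lchi <- if (length(tt_idx)) i + seq_along(tt_idx) else integer(0)
  i <- i + length(tt_idx)
  idx$plab <- if (n_lab > 1) i + seq_len(n_lab - 1) else integer(0)
  i <- i + max(n_lab - 1, 0)
  idx$prna <- i + seq_len(n_unl); i <- i + n_unl
  idx$ptt <- if (n_unl > 1) i + seq_len(n_unl - 1) else integer(0)
  i <- i + max(n_unl - 1, 0)
  idx$n <- i
  idx
}

## unpack to natural-scale parameters honoring the two constraints
.spikeUnpack <- function(par, idx, tt_idx, n_samples, n_lab, n_unl,
                         log_p0) {
  F <- exp(par[idx$logF])
  chi <- rep(1, n_samples)
  chi[tt_idx] <- expit(par[idx$lchi])
  lp_lab <- if (n_lab > 1) {
    free <- par[idx$plab]
    c(free, n_lab * log_p0 - sum(free))
  } else log_p0
  lp_rna <- par[idx$prna]
  lp_tt <- if (n_unl > 1) {
    free <- par[idx$ptt]
    c(free, sum(lp_rna) - sum(free))
  } else lp_rna
  list(F = F, chi = chi, p_lab = exp(lp_lab), p_rna = exp(lp_rna),
       p_tt = exp(lp_tt))
}

.spikeMu <- function(np, labeled, is_tt) {
  n_samples <- length(np$F)
  mu <- matrix(0, length(labeled), n_samples)
  lab_rows <- which(labeled)
  unl_rows <- which(!labeled)
  for (j in seq_len(n_samples)) {
    if (length(lab_rows))
      mu[lab_rows, j] <- np$F[j] * np$p_lab
    if (length(unl_rows)) {
      p <- if (is_tt[j]) np$p_tt else np$p_rna
      mu[unl_rows, j] <- np$F[j] * p * np$chi[j]
    }
  }
  mu
}

#' Fit the spike-in normalization model
#'
#' Negative binomial maximum likelihood fit of per-sample depth factors
#' F_j, per-TT-seq-sample cross-contamination chi_j, per-spike extraction
#' probabilities and the shared dispersion theta. See the package vignette
#' for the parameter-sharing scheme and the two identifiability
#' constraints.
#'
#' @param counts integer matrix, spike-ins x samples; column names must
#'   match \code{design$sample_id} when present.
#' @param labeled logical vector per spike-in (TRUE = labeled).
#' @param design labeling design (\code{\link{labelingDesign}}); only the
#'   protocol column is used here.
#' @param p_labeled_geomean constant at which the geometric mean of the
#'   labeled-spike extraction probabilities is pinned (default 0.5).
#' @param max_rounds maximum alternations between the (F, chi, p) fit and
#'   the profile fit of theta.
#' @param reltol relative objective-change convergence threshold.
#' @return a \code{\link{SpikeInFit}}.
#' @export
fitSpikeInModel <- function(counts, labeled, design,
                            p_labeled_geomean = 0.5,
                            max_rounds = 6, reltol = 1e-10) {
  checkDesign(design)
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts))) {
    if (!all(design$sample_id %in% colnames(counts)))
      stop("counts are missing samples present in the design")
    counts <- counts[, design$sample_id, drop = FALSE]
  }
  if (ncol(counts) != nrow(design))
    stop("counts must have one column per design sample")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 spike-ins and 2 samples")
  labeled <- as.logical(labeled)
  if (!any(labeled) || !any(!labeled))
    stop("need at least one labeled and one unlabeled spike-in")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero spike-in counts for sample(s): ",
         paste(design$sample_id[zero], collapse = ", "))

  is_tt <- design$protocol == "ttseq"
  tt_idx <- which(is_tt)
  n_samples <- nrow(design)
  n_lab <- sum(labeled); n_unl <- sum(!labeled)
  log_p0 <- log(p_labeled_geomean)
  idx <- .spikeParIndex(n_samples, tt_idx, n_lab, n_unl)

  ## reorder count rows: labeled first (matches .spikeMu row blocks)
  ord <- order(!labeled)
  counts_o <- counts[ord, , drop = FALSE]
  labeled_o <- labeled[ord]

  nll <- function(par, theta) {
    if (any(!is.finite(par)) || any(abs(par) > 60)) return(1e18)
    np <- .spikeUnpack(par, idx, tt_idx, n_samples, n_lab, n_unl, log_p0)
    mu <- .spikeMu(np, labeled_o, is_tt)
    v <- -sum(nbLogDensity(as.vector(counts_o), as.vector(mu), theta))
    if (!is.finite(v)) 1e18 else v
  }

  ## analytic gradient of nll on the packed (constrained) parameters
  gnll <- function(par, theta) {
    if (any(!is.finite(par)) || any(abs(par) > 60))
      return(numeric(idx$n))
    np <- .spikeUnpack(par, idx, tt_idx, n_samples, n_lab, n_unl, log_p0)
    mu <- .spikeMu(np, labeled_o, is_tt)
    mu <- pmax(mu, 1e-12)
    ## D_ij = -dlogLik/dmu * mu (elasticity of nll w.r.t. log mu)
    D <- -(counts_o / mu - (counts_o + theta) / (mu + theta)) * mu
    g <- numeric(idx$n)
    g[idx$logF] <- colSums(D)
    lab_rows <- seq_len(n_lab)
    unl_rows <- n_lab + seq_len(n_unl)
    if (length(idx$lchi)) {
      ## mu of unlabeled rows scales with chi; d chi/d logit = chi(1-chi)
      g[idx$lchi] <- colSums(D[unl_rows, tt_idx, drop = FALSE]) *
        (1 - np$chi[tt_idx])
    }
    if (n_lab > 1) {
      S <- rowSums(D[lab_rows, , drop = FALSE])
      g[idx$plab] <- S[-n_lab] - S[n_lab]
    }
    R <- rowSums(D[unl_rows, !is_tt, drop = FALSE])
    Tt <- rowSums(D[unl_rows, is_tt, drop = FALSE])
    if (n_unl > 1) {
      g[idx$prna] <- R + Tt[n_unl]
      g[idx$ptt] <- Tt[-n_unl] - Tt[n_unl]
    } else {
      ## single unlabeled spike: p_tt tied to p_rna
      g[idx$prna] <- R + Tt
    }
    g
  }

  ## moment-based initialization from labeled spikes
  lab_counts <- counts_o[labeled_o, , drop = FALSE]
  lK <- log(lab_counts + 0.5)
  ## log K_ij ~ log F_j + log p_i with mean(log p_lab) = log_p0
  logF0 <- colMeans(lK) - log_p0
  par0 <- numeric(idx$n)
  par0[idx$logF] <- logF0
  if (length(idx$lchi)) par0[idx$lchi] <- logit(0.1)
  if (n_lab > 1) {
    lp <- rowMeans(lK) - mean(logF0)
    lp <- lp - mean(lp) + log_p0
    par0[idx$plab] <- lp[-n_lab]
  }
  unl_counts <- counts_o[!labeled_o, , drop = FALSE]
  lp_rna0 <- log(rowMeans(unl_counts[, !is_tt, drop = FALSE]) + 0.5) -
    mean(logF0[!is_tt])
  lp_rna0 <- pmin(lp_rna0, -1e-3)
  par0[idx$prna] <- lp_rna0
  if (n_unl > 1) par0[idx$ptt] <- lp_rna0[-n_unl]

  theta <- 10
  obj_prev <- Inf
  ## a few starts guard against the degenerate chi -> 1 local optimum
  starts <- list(par0,
                 { p <- par0; if (length(idx$lchi)) p[idx$lchi] <- logit(0.02); p },
                 { p <- par0; if (length(idx$lchi)) p[idx$lchi] <- logit(0.5); p })
  fit <- NULL
  for (s0 in starts) {
    cand <- stats::optim(s0, nll, gr = gnll, theta = theta, method = "BFGS",
                         control = list(maxit = 3000, reltol = 1e-14))
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  for (round in seq_len(max_rounds)) {
    ## (F, chi, p) given theta; chain BFGS restarts until no improvement
    for (rep in 1:4) {
      fit2 <- stats::optim(fit$par, nll, gr = gnll, theta = theta,
                           method = "BFGS",
                           control = list(maxit = 3000, reltol = 1e-14))
      if (fit2$value < fit$value) fit <- fit2 else break
    }
    ## profile likelihood for theta on the same objective
    prof <- stats::optimize(function(lt) nll(fit$par, exp(lt)),
                            interval = log(c(1e-3, 1e6)), tol = 1e-10)
    theta <- exp(prof$minimum)
    obj <- prof$objective
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < reltol * (abs(obj) + 1e-30)) break
    obj_prev <- obj
  }
  if (fit$convergence != 0)
    warning("spike-in model fit did not formally converge (code ",
            fit$convergence, "); last objective ", signif(obj, 8))

  np <- .spikeUnpack(fit$par, idx, tt_idx, n_samples, n_lab, n_unl, log_p0)
  samples <- data.frame(sample_id = design$sample_id,
                        protocol = design$protocol,
                        size_factor = unname(np$F),
                        chi = unname(np$chi),
                        stringsAsFactors = FALSE)
  spike_ids <- rownames(counts)
  if (is.null(spike_ids)) spike_ids <- paste0("spike_", seq_len(nrow(counts)))
  lab_ids <- spike_ids[labeled]
  unl_ids <- spike_ids[!labeled]
  p <- rbind(
    data.frame(spike_id = lab_ids, class = "labeled", p = np$p_lab),
    data.frame(spike_id = unl_ids, class = "unlabeled_ttseq", p = np$p_tt),
    data.frame(spike_id = unl_ids, class = "unlabeled_rnaseq", p = np$p_rna))
  rownames(p) <- NULL
  new("SpikeInFit", samples = samples, p = p, theta = theta,
      logLik = -obj, convergence = list(code = fit$convergence,
                                        objective = obj, rounds = round))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
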