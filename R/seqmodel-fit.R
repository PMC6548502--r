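## Sequence-effect regression: single-nucleotide and octamer models.
##
## Both models regress log-transformed bond half-life (or log splicing
## yield) on sequence features, using L1 (lasso) selection via glmnet with
## deterministic, id-hashed cross-validation folds, followed by an
## unpenalized refit of the survivors so coefficients are interpretable as
## multiplicative effects relative to the consensus sequence.

## literature consensus bases at canonical window positions, used only to
## break modal-nucleotide ties. Windows are 2*flank nt (donor/acceptor)
## or 2*flank+1 nt (branchpoint); positions here are for flank = 20.
.canonicalBases <- function(window, flank = 20) {
  switch(window,
    donor = c(stats::setNames(c("G", "T"), c(flank + 1, flank + 2))),
    acceptor = c(stats::setNames(c("A", "G"), c(flank - 1, flank))),
    branchpoint = stats::setNames("A", flank + 1),
    NULL)
}

## modal nucleotide per position; ties toward the canonical base when one
## is defined for the position, else alphabetical
.consensusOf <- function(seqs, window = "") {
  mat <- do.call(rbind, strsplit(seqs, ""))
  canon <- .canonicalBases(window)
  vapply(seq_len(ncol(mat)), function(i) {
    tab <- table(factor(mat[, i], levels = c("A", "C", "G", "T")))
    top <- names(tab)[tab == max(tab)]
    cb <- canon[as.character(i)]
    if (!is.null(cb) && !is.na(cb) && cb %in% top) cb else top[1]
  }, character(1))
}

## 3 indicator columns per position (non-consensus bases)
.oneHotVsConsensus <- function(seqs, consensus, prefix) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  cols <- list()
  for (i in seq_along(consensus)) {
    for (b in setdiff(c("A", "C", "G", "T"), consensus[i])) {
      cols[[sprintf("%s_p%02d_%s", prefix, i, b)]] <-
        as.numeric(mat[, i] == b)
    }
  }
  do.call(cbind, cols)
}

## deterministic CV folds from intron ids
.foldsFromIds <- function(ids, nfolds, seed) {
  (stringHash(paste0(ids, "#", seed)) %% nfolds) + 1L
}

#' Fit the single-nucleotide sequence-effect model
#'
#' Two-stage fit of log half-life (or any log-scale response) on the
#' nucleotides of the donor, acceptor and branchpoint windows: (1) lasso
#' selection at the largest penalty within one standard error of the
#' minimal cross-validated MSE (10-fold CV, folds assigned by a hash of
#' the intron id so they are reproducible); positions where all three
#' substitution coefficients are exactly 0 are dropped; (2) ordinary
#' least squares refit on the surviving positions plus the three GC
#' covariates (whole intron, donor window, acceptor window), which are
#' mean-centered so that a consensus sequence predicts exactly the
#' intercept. Rows whose windows contain N are excluded.
#'
#' @param contexts data.frame from \code{\link{extractContext}} (needs the
#'   window and GC columns for the requested windows).
#' @param response numeric response on the log scale, aligned to contexts.
#' @param windows which windows to use (default all three).
#' @param seed seed for the fold assignment.
#' @param lambda optional fixed penalty overriding CV (\code{Inf} gives
#'   the intercept-only model).
#' @return an object of class \code{SequenceEffectModel}: consensus per
#'   window, coefficient table (all positions; dropped positions and
#'   consensus bases have effect 0), centered-GC effects, intercept,
#'   variance explained and multiplicative median error
#'   median(exp(|log(y/yhat)|)).
#' @export
fitSingleNtModel <- function(contexts, response,
                             windows = c("donor", "acceptor", "branchpoint"),
                             seed = 1, lambda = NULL) {
  stopifnot(length(response) == nrow(contexts))
  if (stats::var(response, na.rm = TRUE) == 0)
    stop("constant response")
  wincols <- paste0(windows, "_window")
  stopifnot(all(wincols %in% names(contexts)))
  seqs <- lapply(wincols, function(w) toupper(contexts[[w]]))
  keep <- Reduce(`&`, lapply(seqs, function(s) !grepl("[^ACGT]", s))) &
    is.finite(response)
  if (sum(keep) < 10) stop("too few usable introns after N filtering")
  contexts <- contexts[keep, , drop = FALSE]
  seqs <- lapply(seqs, function(s) s[keep])
  y <- response[keep]

  consensus <- Map(.consensusOf, seqs, windows)
  names(consensus) <- windows
  X <- do.call(cbind, Map(.oneHotVsConsensus, seqs, consensus, windows))
  gc_cols <- intersect(c("gc_intron", "gc_donor", "gc_acceptor"),
                       names(contexts))
  G <- as.matrix(contexts[, gc_cols, drop = FALSE])
  gc_center <- colMeans(G)
  Gc <- sweep(G, 2, gc_center)

  ## stage 1: lasso selection over nucleotide indicators + GC
  intercept_only <- FALSE
  if (!is.null(lambda) && is.infinite(lambda)) {
    kept_cols <- character(0)
    intercept_only <- TRUE
  } else {
    foldid <- .foldsFromIds(contexts$intron_id, 10, seed)
    cvfit <- glmnet::cv.glmnet(cbind(X, Gc), y, alpha = 1, foldid = foldid,
                               lambda = if (is.null(lambda)) NULL
                                        else c(lambda * c(2, 1, 0.5)))
    s <- if (is.null(lambda)) cvfit$lambda.1se else lambda
    beta <- as.matrix(stats::coef(cvfit, s = s))[-1, 1]
    nt_beta <- beta[colnames(X)]
    ## drop positions whose every substitution coefficient is exactly 0
    pos_of <- sub("_[ACGT]$", "", colnames(X))
    keep_pos <- unique(pos_of[nt_beta != 0])
    kept_cols <- colnames(X)[pos_of %in% keep_pos]
    if (length(kept_cols) == 0) intercept_only <- TRUE
  }

  ridge_flag <- FALSE
  if (intercept_only) {
    fit_coefs <- stats::setNames(numeric(0), character(0))
    gc_effects <- stats::setNames(rep(0, length(gc_cols)), gc_cols)
    intercept <- mean(y)
    yhat <- rep(intercept, length(y))
  } else {
    Xr <- cbind(X[, kept_cols, drop = FALSE], Gc)
    df <- data.frame(y = y, Xr, check.names = FALSE)
    ols <- stats::lm(y ~ ., data = df)
    cf <- stats::coef(ols)
    if (anyNA(cf)) {
      ## rank deficiency after selection: minimal ridge refit
      ridge_flag <- TRUE
      lam <- 1e-6
      XtX <- crossprod(cbind(1, Xr))
      cf <- solve(XtX + lam * diag(nrow(XtX)),
                  crossprod(cbind(1, Xr), y))[, 1]
      names(cf) <- c("(Intercept)", colnames(Xr))
    }
    intercept <- cf[["(Intercept)"]]
    cfv <- cf[-1]
    names(cfv) <- colnames(Xr)
    fit_coefs <- cfv[kept_cols]
    gc_effects <- cfv[gc_cols]
    yhat <- intercept + as.vector(Xr %*% cfv)
  }

  ## full coefficient table: every position x base, 0 where dropped or
  ## consensus
  coef_tab <- do.call(rbind, lapply(seq_along(windows), function(wi) {
    w <- windows[wi]
    cons <- consensus[[w]]
    do.call(rbind, lapply(seq_along(cons), function(i) {
      data.frame(window = w, position = i,
                 base = c("A", "C", "G", "T"),
                 consensus = cons[i],
                 effect = vapply(c("A", "C", "G", "T"), function(b) {
                   nm <- sprintf("%s_p%02d_%s", w, i, b)
                   if (nm %in% names(fit_coefs)) unname(fit_coefs[nm]) else 0
                 }, numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(coef_tab) <- NULL

  res <- list(windows = windows, consensus = consensus,
              coefficients = coef_tab,
              gc_effects = gc_effects, gc_center = gc_center,
              intercept = unname(intercept),
              retained_positions = if (intercept_only) character(0)
                                   else unique(sub("_[ACGT]$", "", kept_cols)),
              r_squared = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
              median_mult_error = stats::median(exp(abs(y - yhat))),
              ridge = ridge_flag, n = length(y),
              feature_matrix = if (intercept_only) NULL
                               else X[, kept_cols, drop = FALSE],
              used = which(keep))
  class(res) <- "SequenceEffectModel"
  res
}

#' @export
print.SequenceEffectModel <- function(x, ...) {
  cat("SequenceEffectModel:", length(x$retained_positions),
      "retained positions over", paste(x$windows, collapse = "/"),
      "windows\n")
  cat(sprintf("  n = %d, variance explained = %.1f%%, multiplicative median error = %.3g\n",
              x$n, 100 * x$r_squared, x$median_mult_error))
  invisible(x)
}

#' Predict from a single-nucleotide sequence-effect model
#'
#' GC covariates are centered at their training means, so contexts
#' lacking GC columns (or a pure consensus sequence) predict the
#' intercept plus nucleotide effects only.
#'
#' @param object a SequenceEffectModel.
#' @param newdata data.frame with the window (and optionally GC) columns.
#' @param ... unused.
#' @return predicted response (log scale).
#' @export
predict.SequenceEffectModel <- function(object, newdata, ...) {
  pred <- rep(object$intercept, nrow(newdata))
  for (w in object$windows) {
    seqs <- toupper(newdata[[paste0(w, "_window")]])
    mat <- do.call(rbind, strsplit(seqs, ""))
    cons <- object$consensus[[w]]
    ct <- object$coefficients[object$coefficients$window == w, ]
    for (i in seq_along(cons)) {
      eff <- ct$effect[ct$position == i]
      names(eff) <- ct$base[ct$position == i]
      v <- eff[mat[, i]]
      v[is.na(v)] <- 0  # N bases are neutral at prediction time
      pred <- pred + v
    }
  }
  for (g in names(object$gc_effects)) {
    if (g %in% names(newdata))
      pred <- pred + object$gc_effects[[g]] *
        (newdata[[g]] - object$gc_center[[g]])
  }
  unname(pred)
}

#' Sequence model for splicing yield
#'
#' Reuses the single-nucleotide machinery with log-transformed splicing
#' yield as the response (floored at \code{epsilon} since estimated
#' yields can be 0) over the branchpoint and acceptor windows, where
#' yield determinants act.
#'
#' @param contexts as in \code{\link{fitSingleNtModel}}.
#' @param eta splicing yields aligned to contexts.
#' @param epsilon floor applied before the log transform.
#' @param seed fold seed.
#' @return a \code{SequenceEffectModel}.
#' @export
yieldSequenceModel <- function(contexts, eta, epsilon = 0.01, seed = 1) {
  fitSingleNtModel(contexts, log(pmax(eta, epsilon)),
                   windows = c("acceptor", "branchpoint"), seed = seed)
}
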