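## Octamer counting, two-stage octamer selection and the joint
## multivariate model with its variance-explained ledger.

#' Count octamer occurrences allowing mismatches
#'
#' Number of alignment offsets at which the Hamming distance between the
#' octamer and the sequence window is at most \code{max_mismatch};
#' overlapping offsets all count. Backed by
#' \code{Biostrings::vcountPattern}.
#'
#' @param sequences character vector (or DNAStringSet) of region
#'   sequences; empty strings give 0.
#' @param octamers character vector of 8-mers.
#' @param max_mismatch 0, 1 or 2 mismatches (default 2).
#' @return integer matrix, sequences x octamers.
#' @export
countOctamers <- function(sequences, octamers, max_mismatch = 2) {
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")
  if (any(nchar(octamers) != 8)) stop("octamers must have length 8")
  seqs <- Biostrings::DNAStringSet(
    ifelse(nchar(sequences) == 0, "A", toupper(as.character(sequences))))
  empty <- nchar(as.character(sequences)) == 0
  out <- vapply(octamers, function(oct) {
    v <- Biostrings::vcountPattern(oct, seqs, max.mismatch = max_mismatch,
                                   with.indels = FALSE, fixed = TRUE)
    v[empty] <- 0L
    v
  }, integer(length(seqs)))
  matrix(out, nrow = length(seqs),
         dimnames = list(NULL, octamers))
}

## all 8-mers occurring exactly (0 mismatches) in a set of sequences;
## the default octamer universe at desk scale
.observedOctamers <- function(sequences) {
  seqs <- sequences[nchar(sequences) >= 8 & !grepl("[^ACGT]",
                                                   toupper(sequences))]
  if (length(seqs) == 0) return(character(0))
  octs <- unlist(lapply(toupper(seqs), function(s) {
    n <- nchar(s)
    substring(s, 1:(n - 7), 8:n)
  }))
  sort(unique(octs))
}

.regionNames <- c("donor_downstream", "branchpoint_upstream", "polyY",
                  "acceptor_upstream")

#' Fit the octamer model with joint refinement and variance ledger
#'
#' Stage 1: within each of the four intronic regions, lasso regression
#' (5-fold CV, penalty at lambda.1se) of the response on
#' log2(octamer count + 1) covariates plus the intron and region GC
#' fractions selects candidate octamers. Stage 2: all selected octamers,
#' the single-nucleotide model features, the GC fraction of each region
#' and of the intron, log intron length, and the first-intron flag enter
#' a joint lasso (10-fold CV) that refines the selection. The variance
#' ledger reports the joint model's variance explained, each feature
#' group's individual (alone, OLS) variance explained, and the drop when
#' the group is removed from the joint model.
#'
#' @param regions data.frame from \code{\link{intronRegions}}.
#' @param response log-scale response aligned to regions rows.
#' @param contexts optional data.frame from \code{\link{extractContext}}
#'   (provides gc_intron, intron_length, first_intron).
#' @param single_nt_features optional numeric matrix of single-nucleotide
#'   model features (e.g. \code{$feature_matrix} of a
#'   \code{\link{fitSingleNtModel}} fit on the same introns).
#' @param octamers candidate octamer universe; default: all 8-mers
#'   observed exactly in the supplied regions. Pass all 65,536 octamers
#'   to reproduce a full-scale search.
#' @param max_mismatch mismatches allowed when counting (default 2).
#' @param seed fold-assignment seed.
#' @return an object of class \code{OctamerModel} with per-region and
#'   joint selections, joint coefficients, and the variance ledger.
#' @export
fitOctamerModel <- function(regions, response, contexts = NULL,
                            single_nt_features = NULL, octamers = NULL,
                            max_mismatch = 2, seed = 1) {
  stopifnot(nrow(regions) == length(response))
  ok <- is.finite(response)
  regions <- regions[ok, , drop = FALSE]
  y <- response[ok]
  if (!is.null(contexts)) contexts <- contexts[ok, , drop = FALSE]
  if (!is.null(single_nt_features))
    single_nt_features <- single_nt_features[ok, , drop = FALSE]
  ids <- regions$intron_id

  present <- .regionNames[vapply(.regionNames, function(r)
    any(nchar(regions[[r]]) > 0), logical(1))]
  if (length(present) < length(.regionNames))
    warning("region(s) empty for all introns omitted: ",
            paste(setdiff(.regionNames, present), collapse = ", "))

  if (is.null(octamers))
    octamers <- .observedOctamers(unlist(regions[present]))
  if (length(octamers) < 2) stop("need at least 2 candidate octamers")

  gc_intron <- if (!is.null(contexts)) contexts$gc_intron else NULL

  ## stage 1: per-region selection
  region_sel <- list()
  region_covs <- list()
  for (r in present) {
    cnt <- countOctamers(regions[[r]], octamers, max_mismatch)
    covs <- log2(cnt + 1)
    colnames(covs) <- paste0(r, ".", octamers)
    region_covs[[r]] <- covs
    gc_r <- regions[[paste0("gc_", r)]]
    gc_r[is.na(gc_r)] <- mean(gc_r, na.rm = TRUE)
    extra <- cbind(gc_region = gc_r)
    if (!is.null(gc_intron)) extra <- cbind(extra, gc_intron = gc_intron)
    X <- cbind(covs, extra)
    if (stats::sd(y) == 0 || ncol(X) < 2) { region_sel[[r]] <- character(0); next }
    foldid <- .foldsFromIds(ids, 5, seed + match(r, .regionNames))
    cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid)
    beta <- as.matrix(stats::coef(cvfit, s = cvfit$lambda.1se))[-1, 1]
    sel <- names(beta)[beta != 0 & names(beta) %in% colnames(covs)]
    region_sel[[r]] <- sub(paste0("^", r, "\\."), "", sel)
  }

  ## stage 2: joint refinement
  groups <- list()
  for (r in present) {
    if (length(region_sel[[r]]))
      groups[[paste0("octamers_", r)]] <-
        region_covs[[r]][, paste0(r, ".", region_sel[[r]]), drop = FALSE]
  }
  if (!is.null(single_nt_features) && ncol(single_nt_features) > 0)
    groups[["single_nt"]] <- as.matrix(single_nt_features)
  gc_block <- do.call(cbind, c(
    lapply(present, function(r) {
      v <- regions[[paste0("gc_", r)]]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      stats::setNames(data.frame(v), paste0("gc_", r))
    }),
    if (!is.null(gc_intron)) list(data.frame(gc_intron = gc_intron))))
  groups[["gc"]] <- as.matrix(gc_block)
  if (!is.null(contexts)) {
    groups[["intron_length"]] <-
      matrix(log(contexts$intron_length), ncol = 1,
             dimnames = list(NULL, "log_intron_length"))
    fi <- as.numeric(contexts$first_intron)
    if (stats::sd(fi) > 0)
      groups[["first_intron"]] <- matrix(fi, ncol = 1,
                                         dimnames = list(NULL, "first_intron"))
  }

  Xj <- do.call(cbind, groups)
  foldid <- .foldsFromIds(ids, 10, seed)
  joint <- glmnet::cv.glmnet(Xj, y, alpha = 1, foldid = foldid)
  beta_j <- as.matrix(stats::coef(joint, s = joint$lambda.1se))[, 1]
  yhat <- as.vector(stats::predict(joint, Xj, s = joint$lambda.1se))
  r2 <- function(pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  joint_r2 <- r2(yhat)

  ## ledger: individual (group alone, OLS) and drop-one (joint lasso
  ## without the group) variance explained
  olsR2 <- function(X) {
    df <- data.frame(y = y, X, check.names = FALSE)
    r2(stats::fitted(stats::lm(y ~ ., data = df)))
  }
  ledger <- do.call(rbind, lapply(names(groups), function(g) {
    rest <- do.call(cbind, groups[setdiff(names(groups), g)])
    drop_r2 <- if (is.null(rest) || ncol(rest) < 2) 0 else {
      cvd <- glmnet::cv.glmnet(rest, y, alpha = 1, foldid = foldid)
      r2(as.vector(stats::predict(cvd, rest, s = cvd$lambda.1se)))
    }
    data.frame(feature = g,
               individual_r2 = olsR2(groups[[g]]),
               drop_r2 = joint_r2 - drop_r2,
               stringsAsFactors = FALSE)
  }))
  ledger <- rbind(data.frame(feature = "joint", individual_r2 = joint_r2,
                             drop_r2 = NA_real_), ledger)

  sel_joint <- names(beta_j)[beta_j != 0]
  res <- list(region_selected = region_sel,
              joint_selected = setdiff(sel_joint, "(Intercept)"),
              coefficients = beta_j[beta_j != 0],
              variance_ledger = ledger,
              r_squared = joint_r2,
              octamer_universe_size = length(octamers),
              n = length(y))
  class(res) <- "OctamerModel"
  res
}

#' @export
print.OctamerModel <- function(x, ...) {
  cat("OctamerModel: joint variance explained =",
      sprintf("%.1f%%", 100 * x$r_squared), "\n")
  for (r in names(x$region_selected))
    cat(sprintf("  %s: %d octamer(s) selected\n", r,
                length(x$region_selected[[r]])))
  invisible(x)
}
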