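## Octamer matching against RNA-binding-protein position weight matrices.

#' Relative PWM match score of an octamer
#'
#' Ratio between the probability of the best-matching alignment of the
#' octamer to the PWM and the highest probability any sequence can
#' achieve, so the score lies in (0, 1] with 1 for a consensus match.
#' When the PWM is longer than 8 columns the octamer is padded with an
#' equal number of Ns on both sides (one extra N on the right for odd
#' differences); an N contributes the column maximum, i.e. a neutral
#' factor.
#'
#' @param octamer an 8-character ACGT string.
#' @param pwm numeric matrix with rows A, C, G, T and one column per
#'   position; column probabilities must not be all zero.
#' @return score in (0, 1].
#' @export
rpmScore <- function(octamer, pwm) {
  octamer <- toupper(octamer)
  if (nchar(octamer) != 8) stop("octamer must have length 8")
  pwm <- as.matrix(pwm)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  colmax <- apply(pwm, 2, max)
  if (any(colmax <= 0))
    stop("PWM has a zero column; apply a pseudo-probability upstream")
  L <- ncol(pwm)
  bases <- strsplit(octamer, "")[[1]]
  if (L > 8) {
    pad <- L - 8
    bases <- c(rep("N", floor(pad / 2)), bases, rep("N", ceiling(pad / 2)))
  }
  n_off <- length(bases) - L + 1
  best <- -Inf
  for (k in seq_len(n_off)) {
    b <- bases[k:(k + L - 1)]
    p <- vapply(seq_len(L), function(j)
      if (b[j] == "N") colmax[j] else pwm[b[j], j], numeric(1))
    best <- max(best, prod(p))
  }
  best / prod(colmax)
}

#' Match octamers to a PWM collection
#'
#' Scores every octamer against every PWM with at least
#' \code{min_length} columns, keeps for each PWM the matches ranking in
#' the top 5\% by score, then removes matches scoring below 0.9.
#'
#' @param octamers character vector of 8-mers.
#' @param pwms named list of PWM matrices (rows A, C, G, T).
#' @param min_length minimum PWM length considered (default 5).
#' @param top_fraction fraction of best matches kept per PWM.
#' @param min_score score threshold applied after ranking.
#' @return data.frame with octamer, pwm_id, rpm_score for the retained
#'   hits.
#' @export
matchAttract <- function(octamers, pwms, min_length = 5,
                         top_fraction = 0.05, min_score = 0.9) {
  pwms <- pwms[vapply(pwms, ncol, integer(1)) >= min_length]
  if (length(pwms) == 0)
    return(data.frame(octamer = character(0), pwm_id = character(0),
                      rpm_score = numeric(0)))
  hits <- lapply(names(pwms), function(id) {
    sc <- vapply(octamers, rpmScore, numeric(1), pwm = pwms[[id]])
    n_keep <- ceiling(top_fraction * length(sc))
    ord <- order(-sc, octamers)
    keep <- ord[seq_len(n_keep)]
    keep <- keep[sc[keep] >= min_score]
    if (length(keep) == 0) return(NULL)
    data.frame(octamer = octamers[keep], pwm_id = id,
               rpm_score = unname(sc[keep]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(octamer = character(0), pwm_id = character(0),
                      rpm_score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Read PWMs in ATtRACT-style plain text
#'
#' Parses a text file of blocks starting with a \code{>id} header line
#' followed by one line per position with four whitespace-separated
#' probabilities (A C G T order).
#'
#' @param path file path.
#' @return named list of 4 x L matrices with rows A, C, G, T.
#' @export
readAttractPwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM headers found")
  ends <- c(heads[-1] - 1, length(lines))
  pwms <- lapply(seq_along(heads), function(i) {
    rows <- lines[(heads[i] + 1):ends[i]]
    m <- t(vapply(strsplit(rows, "\\s+"), function(v)
      as.numeric(v[1:4]), numeric(4)))
    mat <- t(m)
    rownames(mat) <- c("A", "C", "G", "T")
    mat
  })
  names(pwms) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[heads]))
  pwms
}
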