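#' Splicing yield of a splice site
#'
#' The splicing yield eta of an acceptor (or donor) site is the ratio of
#' the summed synthesis rates of all exon-exon junction bonds using that
#' site to the synthesis rate of the site's own bond:
#' \deqn{\eta_{acceptor} = \sum_{donor} \alpha_{junction(donor, acceptor)}
#'   / \alpha_{acceptor}.}
#' A yield of 1 means every synthesized precursor is converted to spliced
#' product. Estimates are deliberately not capped at 1: estimation error
#' in the synthesis rates can push eta above 1 and truncating would bias
#' downstream comparisons.
#'
#' @param junction_alphas synthesis rates of the junction bonds using the
#'   site (from the coupled model); may be empty.
#' @param site_alpha synthesis rate of the site bond (from the first-order
#'   model), positive.
#' @return eta (unitless, >= 0).
#' @examples
#' splicingYield(c(0.3, 0.2), 1)  # 0.5
#' @export
splicingYield <- function(junction_alphas, site_alpha) {
  stopifnot(length(site_alpha) == 1, site_alpha > 0)
  if (length(junction_alphas) == 0) return(0)
  sum(junction_alphas) / site_alpha
}

#' Per-site splicing yield table
#'
#' Joins junction synthesis-rate estimates (coupled model) to splice-site
#' synthesis-rate estimates (first-order model) through an intron table
#' and aggregates junctions per site. The acceptor side is the default
#' reported yield (its estimation does not involve a transcription delay
#' and is more robust); the donor side is computed identically over each
#' donor's junction set.
#'
#' @param junction_rates \code{\link{RateEstimates}} (or plain data.frame
#'   with bond_id, alpha, status) for the junction bonds, ids matching
#'   \code{intron_table$intron_id}.
#' @param site_rates \code{\link{RateEstimates}} (or data.frame) for the
#'   site bonds, ids matching the chosen site id column.
#' @param intron_table data.frame with columns \code{intron_id},
#'   \code{donor_id}, \code{acceptor_id}.
#' @param side \code{"acceptor"} (default) or \code{"donor"}.
#' @return data.frame with site_id, site_type, eta, n_junctions (used),
#'   n_junctions_total, complete (TRUE when every junction of the site had
#'   a usable rate; failed fits are excluded from the sum).
#' @export
yieldTable <- function(junction_rates, site_rates, intron_table,
                       side = c("acceptor", "donor")) {
  side <- match.arg(side)
  jr <- if (is(junction_rates, "RateEstimates")) rateTable(junction_rates)
        else junction_rates
  sr <- if (is(site_rates, "RateEstimates")) rateTable(site_rates)
        else site_rates
  key <- paste0(side, "_id")
  stopifnot(all(c("intron_id", key) %in% names(intron_table)))
  unknown <- !(intron_table$intron_id %in% jr$bond_id)
  if (any(unknown)) {
    warning(sum(unknown), " intron(s) without junction rate estimate skipped")
    intron_table <- intron_table[!unknown, , drop = FALSE]
  }
  j <- jr[match(intron_table$intron_id, jr$bond_id), ]
  usable <- j$status == "ok" & is.finite(j$alpha)
  sites <- unique(intron_table[[key]])
  out <- lapply(sites, function(s) {
    rows <- intron_table[[key]] == s
    srow <- sr[match(s, sr$bond_id), ]
    if (is.na(srow$alpha) || srow$status != "ok") return(NULL)
    use <- rows & usable
    data.frame(site_id = s, site_type = side,
               eta = splicingYield(j$alpha[use], srow$alpha),
               n_junctions = sum(use), n_junctions_total = sum(rows),
               complete = sum(use) == sum(rows),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(site_id = character(0), site_type = character(0),
                      eta = numeric(0), n_junctions = integer(0),
                      n_junctions_total = integer(0), complete = logical(0))
  rownames(out) <- NULL
  out
}
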