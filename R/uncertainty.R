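#' Relative uncertainty of a group of rate estimates
#'
#' Under the conservative assumption that all members of a group share one
#' true value (all donor and acceptor bonds of a major isoform share the
#' gene's synthesis rate; all its junction bonds share the mature-RNA
#' half-life), the spread of the estimates measures their uncertainty.
#' Because rate noise is multiplicative, the standard error is computed on
#' the log scale and reported as its exponential: a unitless
#' multiplicative factor >= 1, with 1 meaning perfect agreement.
#'
#' @param rates positive rates of one group (>= 2 values), natural scale.
#' @return exp(sd(log rates) / sqrt(n)), or NA for groups of size < 2.
#' @examples
#' relativeUncertainty(c(1, 4))  # ~2.0
#' relativeUncertainty(c(5, 5, 5))  # exactly 1
#' @export
relativeUncertainty <- function(rates) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 2) return(NA_real_)
  stopifnot(all(rates > 0))
  exp(stats::sd(log(rates)) / sqrt(length(rates)))
}

#' Relative uncertainties per group
#'
#' @param rates positive rates, natural scale.
#' @param group grouping factor (e.g. major-isoform id).
#' @param quantity label stored in the output (\code{"synthesis"} or
#'   \code{"half_life"}).
#' @return data.frame with group_id, quantity, n, relative_uncertainty
#'   (NA with a warning for singleton groups).
#' @export
relativeUncertaintyTable <- function(rates, group,
                                     quantity = c("synthesis", "half_life")) {
  quantity <- match.arg(quantity)
  sp <- split(rates, group)
  ru <- vapply(sp, relativeUncertainty, numeric(1))
  if (any(is.na(ru)))
    warning(sum(is.na(ru)), " group(s) of size < 2 reported as NA")
  data.frame(group_id = names(sp), quantity = quantity,
             n = lengths(sp), relative_uncertainty = unname(ru),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the major isoform per gene
#'
#' The major isoform of a gene is the isoform with the maximum mean TPM
#' across all RNA-seq samples. Ties are broken lexicographically by
#' isoform id; genes without isoform rows are omitted with a warning.
#'
#' @param tpm numeric matrix, isoforms x RNA-seq samples (rownames are
#'   isoform ids).
#' @param gene_map data.frame with columns \code{isoform_id} and
#'   \code{gene_id} mapping every isoform to one gene.
#' @return named character vector: gene_id -> major isoform id.
#' @export
selectMajorIsoform <- function(tpm, gene_map) {
  stopifnot(is.matrix(tpm) || is.data.frame(tpm),
            all(c("isoform_id", "gene_id") %in% names(gene_map)))
  tpm <- as.matrix(tpm)
  means <- rowMeans(tpm)
  genes <- unique(gene_map$gene_id)
  res <- vapply(genes, function(g) {
    iso <- sort(gene_map$isoform_id[gene_map$gene_id == g])
    iso <- iso[iso %in% rownames(tpm)]
    if (length(iso) == 0) return(NA_character_)
    m <- means[iso]
    iso[which.max(m)]  # which.max takes the first maximum: lexicographic tie-break
  }, character(1))
  if (anyNA(res)) {
    warning(sum(is.na(res)), " gene(s) without isoform rows omitted")
    res <- res[!is.na(res)]
  }
  res
}
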