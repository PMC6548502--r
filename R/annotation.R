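## Gene-model import and six-way intron classification.

#' Import a gene annotation for intron classification
#'
#' Reads a GTF (GENCODE dialect), derives per-transcript introns from
#' consecutive exons, and collects the annotated donor sites, acceptor
#' sites and gene extents needed by \code{\link{classifyIntrons}}.
#' Records without a strand are skipped with a warning.
#'
#' @param gtf path to a GTF file.
#' @return list with GRanges elements \code{introns}, \code{genes} and
#'   the donor/acceptor site keys used internally.
#' @export
importAnnotation <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  nostrand <- as.character(strand(gr)) == "*"
  if (any(nostrand)) {
    warning(sum(nostrand), " annotation record(s) without strand skipped")
    gr <- gr[!nostrand]
  }
  exons <- gr[gr$type == "exon"]
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0 && length(exons) > 0) {
    genes <- unlist(range(S4Vectors::split(granges(exons),
                                           exons$gene_id)))
  }
  exbytx <- S4Vectors::split(granges(exons), exons$transcript_id)
  introns <- unlist(IRanges::psetdiff(unlist(range(exbytx)), exbytx),
                    use.names = FALSE)
  introns <- unique(introns)
  names(introns) <- .intronId(introns)
  list(introns = introns, genes = genes,
       donor_keys = .siteKeys(introns, "donor"),
       acceptor_keys = .siteKeys(introns, "acceptor"))
}

## A site key identifies a donor or acceptor position: the genomic
## coordinate of the first (donor) or last (acceptor) intronic base, with
## chromosome and strand; the roles swap on the minus strand.
.siteKeys <- function(introns, which = c("donor", "acceptor")) {
  which <- match.arg(which)
  plus <- as.character(strand(introns)) == "+"
  pos <- if (which == "donor") ifelse(plus, start(introns), end(introns))
         else ifelse(plus, end(introns), start(introns))
  unique(sprintf("%s:%d:%s", as.character(seqnames(introns)), pos,
                 as.character(strand(introns))))
}

#' Classify introns against an annotation
#'
#' Assigns each intron one of six categories: \code{annotated} (interval
#' matches an annotated intron exactly), \code{novel_combination} (both
#' sites annotated, but never paired), \code{novel_donor} /
#' \code{novel_acceptor} (one site unannotated),
#' \code{novel_both_intragenic} / \code{novel_both_intergenic} (both
#' sites unannotated; split by overlap with any annotated gene body on
#' either strand).
#'
#' @param introns GRanges of introns to classify.
#' @param annotation result of \code{\link{importAnnotation}}.
#' @return the introns with a \code{category} metadata factor.
#' @export
classifyIntrons <- function(introns, annotation) {
  ann_ids <- names(annotation$introns)
  ids <- .intronId(introns)
  donor_ann <- .siteKeysOf(introns, "donor") %in% annotation$donor_keys
  acceptor_ann <- .siteKeysOf(introns, "acceptor") %in% annotation$acceptor_keys
  in_gene <- IRanges::overlapsAny(introns, annotation$genes,
                                  ignore.strand = TRUE)
  category <- ifelse(ids %in% ann_ids, "annotated",
    ifelse(donor_ann & acceptor_ann, "novel_combination",
      ifelse(!donor_ann & acceptor_ann, "novel_donor",
        ifelse(donor_ann & !acceptor_ann, "novel_acceptor",
          ifelse(in_gene, "novel_both_intragenic",
                 "novel_both_intergenic")))))
  mcols(introns)$category <- factor(category,
    levels = c("annotated", "novel_combination", "novel_donor",
               "novel_acceptor", "novel_both_intragenic",
               "novel_both_intergenic"))
  introns
}

## per-intron (non-unique) site keys
.siteKeysOf <- function(introns, which) {
  plus <- as.character(strand(introns)) == "+"
  pos <- if (which == "donor") ifelse(plus, start(introns), end(introns))
         else ifelse(plus, end(introns), start(introns))
  sprintf("%s:%d:%s", as.character(seqnames(introns)), pos,
          as.character(strand(introns)))
}
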