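## Splice-site sequence context extraction.
##
## All windows are reported in RNA sense (reverse-complemented for minus
## strand introns). The donor and acceptor windows are 40 nt: 20 nt on the
## exonic and 20 nt on the intronic side of the bond. The branchpoint
## window is 41 nt: the branchpoint adenosine plus 20 nt on either side.

## strand-aware sequence extraction from a DNAStringSet genome (or any
## object getSeq() accepts, e.g. an indexed FaFile)
.getSeqs <- function(genome, gr, what = NULL) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    chr_names <- sub(" .*", "", names(genome))
    idx <- match(as.character(seqnames(gr)), chr_names)
    if (anyNA(idx)) stop("contig(s) missing from genome: ",
                         paste(unique(as.character(seqnames(gr))[is.na(idx)]),
                               collapse = ", "))
    lens <- Biostrings::width(genome)[idx]
    off <- which(start(gr) < 1 | end(gr) > lens)
    if (length(off))
      stop("window runs off contig for: ",
           paste(utils::head(what[off], 3), collapse = ", "))
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
      as.character(Biostrings::subseq(genome[[idx[i]]], start(gr)[i],
                                      end(gr)[i])), character(1)))
    neg <- as.character(strand(gr)) == "-"
    if (any(neg))
      seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    seqs
  } else {
    Biostrings::getSeq(genome, gr)
  }
}

#' Extract splice-site sequence context for introns
#'
#' @param genome a named DNAStringSet, a path to a FASTA file, or any
#'   object \code{Biostrings::getSeq} accepts.
#' @param introns GRanges of introns (names used as ids).
#' @param branchpoints named numeric vector of genomic branchpoint
#'   positions (1-based), one per intron id; branchpoint coordinates are
#'   an input (predicted or measured externally) and must lie within the
#'   intron.
#' @param first_intron optional named logical: is the intron the first of
#'   its major isoform.
#' @param flank window half-width around each site (default 20 nt).
#' @return data.frame with RNA-sense windows \code{donor_window},
#'   \code{acceptor_window}, \code{branchpoint_window}, GC fractions of
#'   the whole intron and the donor/acceptor windows, intron length,
#'   branchpoint offset from the intron 5' end, and first-intron flag.
#' @export
extractContext <- function(genome, introns, branchpoints,
                           first_intron = NULL, flank = 20) {
  if (is.null(names(introns))) names(introns) <- .intronId(introns)
  ids <- names(introns)
  bp <- branchpoints[ids]
  if (anyNA(bp)) stop("branchpoint missing for: ",
                      paste(utils::head(ids[is.na(bp)], 3), collapse = ", "))
  if (any(bp < start(introns) | bp > end(introns)))
    stop("branchpoint outside intron for: ",
         paste(utils::head(ids[bp < start(introns) | bp > end(introns)], 3),
               collapse = ", "))
  plus <- as.character(strand(introns)) == "+"
  s <- start(introns); e <- end(introns)
  win <- function(center_left) {
    ## window spanning [center_left - flank + 1, center_left + flank]
    GRanges(seqnames(introns),
            IRanges(center_left - flank + 1L, center_left + flank),
            strand = strand(introns))
  }
  ## genomic left base of each bond: the window [left - flank + 1,
  ## left + flank] is symmetric around the bond on both strands
  donor_gr <- win(ifelse(plus, s - 1L, e))
  acceptor_gr <- win(ifelse(plus, e, s - 1L))
  bp_gr <- GRanges(seqnames(introns), IRanges(bp - flank, bp + flank),
                   strand = strand(introns))
  donor_seq <- .getSeqs(genome, donor_gr, ids)
  acceptor_seq <- .getSeqs(genome, acceptor_gr, ids)
  bp_seq <- .getSeqs(genome, bp_gr, ids)
  intron_seq <- .getSeqs(genome, granges(introns), ids)
  data.frame(
    intron_id = ids,
    donor_window = as.character(donor_seq),
    acceptor_window = as.character(acceptor_seq),
    branchpoint_window = as.character(bp_seq),
    gc_intron = vapply(as.character(intron_seq), gcFraction, numeric(1),
                       USE.NAMES = FALSE),
    gc_donor = vapply(as.character(donor_seq), gcFraction, numeric(1),
                      USE.NAMES = FALSE),
    gc_acceptor = vapply(as.character(acceptor_seq), gcFraction, numeric(1),
                         USE.NAMES = FALSE),
    intron_length = end(introns) - start(introns) + 1L,
    bp_offset = as.integer(ifelse(plus, bp - s + 1L, e - bp + 1L)),
    first_intron = if (is.null(first_intron)) FALSE
                   else unname(first_intron[ids]),
    stringsAsFactors = FALSE)
}

#' Intronic regions searched for regulatory octamers
#'
#' Four intronic regions, in transcript orientation, cropped so they never
#' extend into exons: 15-100 nt downstream of the donor site, 100 nt
#' upstream of the branchpoint, the stretch between the branchpoint and
#' 5 nt upstream of the acceptor site (polypyrimidine-tract region), and
#' 5-100 nt upstream of the acceptor site. The 15 nt after the donor and
#' 5 nt before the acceptor are excluded because the single-nucleotide
#' model already covers them.
#'
#' @inheritParams extractContext
#' @return data.frame with intron_id, one sequence column per region
#'   (\code{donor_downstream}, \code{branchpoint_upstream}, \code{polyY},
#'   \code{acceptor_upstream}; empty string when fully cropped) and the
#'   GC fraction of each region.
#' @export
intronRegions <- function(genome, introns, branchpoints) {
  ctx <- extractContext(genome, introns, branchpoints)
  intron_seq <- as.character(.getSeqs(genome, granges(introns),
                                      names(introns)))
  L <- nchar(intron_seq)
  p <- ctx$bp_offset
  cut <- function(seq, from, to) {
    ifelse(from <= to & from >= 1, substr(seq, pmax(from, 1), to), "")
  }
  out <- data.frame(
    intron_id = ctx$intron_id,
    donor_downstream = cut(intron_seq, 16, pmin(100, L)),
    branchpoint_upstream = cut(intron_seq, p - 100, p - 1),
    polyY = cut(intron_seq, p + 1, L - 5),
    acceptor_upstream = cut(intron_seq, L - 99, L - 5),
    stringsAsFactors = FALSE)
  for (r in c("donor_downstream", "branchpoint_upstream", "polyY",
              "acceptor_upstream"))
    out[[paste0("gc_", r)]] <- vapply(out[[r]], function(x)
      if (nchar(x) == 0) NA_real_ else gcFraction(x), numeric(1),
      USE.NAMES = FALSE)
  out
}
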