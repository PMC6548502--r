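## Intron discovery and bond-level read counting from alignments.
##
## Splicing state is read off alignments at three phosphodiester bonds per
## intron: the donor bond (last exonic base | first intronic base, 5' of
## the intron in transcript orientation), the acceptor bond (last intronic
## base | first exonic base) and the exon-exon junction bond created by
## completed splicing. A split read whose skipped interval equals the
## intron supports the junction; a read with one aligned block covering
## both bases flanking a bond supports that bond being intact.
##
## Coordinates are 1-based closed (GRanges convention); BED export
## converts to 0-based half-open.

#' @importFrom GenomicRanges GRanges seqnames start end strand
#'   findOverlaps reduce resize mcols mcols<- granges
#' @importFrom IRanges IRanges ranges
#' @importFrom S4Vectors queryHits subjectHits Rle
NULL

## Accept a BAM path, or a plain-text SAM path converted on the fly. The
## SAM parser silently drops records it cannot parse, so compare record
## counts to catch malformed input.
.asBamFile <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    out <- tryCatch(Rsamtools::asBam(file, dest, overwrite = TRUE,
                                     indexDestination = TRUE),
                    error = function(e)
                      stop("malformed alignment stream: ",
                           conditionMessage(e), call. = FALSE))
    n_lines <- sum(!grepl("^@", readLines(file)))
    n_rec <- Rsamtools::countBam(out)$records
    if (n_rec < n_lines)
      stop("malformed alignment stream: ", n_lines - n_rec,
           " record(s) could not be parsed", call. = FALSE)
    out
  } else file
}

## Load primary alignments passing the mapping-quality filter, keeping
## query names and flags (needed for mate-aware strand and deduplication).
.loadAlignments <- function(file, mapq = 255) {
  bam <- .asBamFile(file)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    what = "flag", mapqFilter = mapq)
  aln <- tryCatch(GenomicAlignments::readGAlignments(bam, param = param,
                                                     use.names = TRUE),
                  error = function(e)
                    stop("malformed alignment stream: ",
                         conditionMessage(e), call. = FALSE))
  aln
}

## Strand of the originating RNA fragment under a stranded library
## protocol: "rf" (first read reverse-complement of the transcript, the
## default for dUTP-class kits) or "fr". Unpaired reads are treated as
## first mates.
.fragmentStrand <- function(aln, strandedness = c("rf", "fr")) {
  strandedness <- match.arg(strandedness)
  flag <- mcols(aln)$flag
  paired <- bitwAnd(flag, 1L) > 0L
  first <- !paired | bitwAnd(flag, 64L) > 0L
  s <- as.character(strand(aln))
  flip <- if (strandedness == "rf") first else !first
  s[flip] <- ifelse(s[flip] == "+", "-", "+")
  s
}

.intronId <- function(gr) {
  sprintf("%s:%d-%d:%s", as.character(seqnames(gr)), start(gr), end(gr),
          as.character(strand(gr)))
}

#' Discover introns from split reads
#'
#' Extracts the skipped intervals (N operations in the CIGAR) of all
#' primary alignments passing the mapping-quality filter and reports every
#' distinct interval supported by at least \code{min_split_reads}
#' fragments (mates sharing a query name support an interval once).
#' Strand is assigned from the library protocol.
#'
#' @param file path to a coordinate-sorted BAM, or a SAM text file
#'   (converted internally).
#' @param min_split_reads minimum supporting split fragments (default 10).
#' @param mapq required mapping quality (default 255, the unique-mapping
#'   score emitted by the aligner used upstream).
#' @param strandedness \code{"rf"} (default) or \code{"fr"}.
#' @return GRanges of introns, names are stable ids
#'   \code{chrom:start-end:strand}, with metadata column
#'   \code{n_split_reads}. Empty if no interval passes (not an error).
#' @export
discoverIntrons <- function(file, min_split_reads = 10, mapq = 255,
                            strandedness = c("rf", "fr")) {
  stopifnot(min_split_reads >= 1)
  strandedness <- match.arg(strandedness)
  aln <- .loadAlignments(file, mapq)
  if (length(aln) == 0)
    return(GRanges(n_split_reads = integer(0)))
  jx <- GenomicAlignments::junctions(aln)
  nj <- lengths(jx)
  if (sum(nj) == 0) {
    gr <- GRanges()
    mcols(gr)$n_split_reads <- integer(0)
    return(gr)
  }
  frag_strand <- .fragmentStrand(aln, strandedness)
  flat <- unlist(jx, use.names = FALSE)
  read_of <- rep(seq_along(aln), nj)
  key <- sprintf("%s:%d-%d:%s", as.character(seqnames(flat)),
                 start(flat), end(flat), frag_strand[read_of])
  ## one vote per fragment (query name) per junction
  frag_key <- paste(names(aln)[read_of], key)
  keep <- !duplicated(frag_key)
  support <- table(key[keep])
  pass <- names(support)[support >= min_split_reads]
  if (length(pass) == 0) {
    gr <- GRanges()
    mcols(gr)$n_split_reads <- integer(0)
    return(gr)
  }
  parts <- do.call(rbind, strsplit(pass, ":"))
  rng <- do.call(rbind, strsplit(parts[, 2], "-"))
  gr <- GRanges(parts[, 1],
                IRanges(as.integer(rng[, 1]), as.integer(rng[, 2])),
                strand = parts[, 3])
  mcols(gr)$n_split_reads <- as.integer(support[pass])
  names(gr) <- .intronId(gr)
  sort(gr)
}

## 2-bp spans of the donor and acceptor bonds of an intron set. Donor is
## the transcript-5' boundary of the intron, acceptor the 3' one; on the
## minus strand the genomic roles swap.
.bondSpans <- function(introns) {
  plus <- as.character(strand(introns)) == "+"
  donor_start <- ifelse(plus, start(introns) - 1L, end(introns))
  acceptor_start <- ifelse(plus, end(introns), start(introns) - 1L)
  list(donor = GRanges(seqnames(introns),
                       IRanges(donor_start, donor_start + 1L),
                       strand = strand(introns)),
       acceptor = GRanges(seqnames(introns),
                          IRanges(acceptor_start, acceptor_start + 1L),
                          strand = strand(introns)))
}

#' Count donor-, acceptor- and junction-supporting reads per intron
#'
#' For each intron, counts fragments whose aligned blocks contiguously
#' cover both bases flanking the donor bond (donor class), both bases
#' flanking the acceptor bond (acceptor class), or whose skipped interval
#' equals the intron exactly (junction class). A read whose single block
#' spans the entire intron starts, in transcript orientation, in the
#' upstream exon and is counted as donor only, so the three classes are
#' disjoint per read. Mates are evaluated independently and a fragment
#' contributes at most once per (intron, class). Reads whose skips
#' partially overlap an intron contribute to none of its classes.
#'
#' @inheritParams discoverIntrons
#' @param introns GRanges of introns (e.g. from
#'   \code{\link{discoverIntrons}}); names are used as intron ids.
#' @return data.frame with intron_id, donor, acceptor, junction counts.
#' @export
countBondReads <- function(file, introns, mapq = 255,
                           strandedness = c("rf", "fr")) {
  strandedness <- match.arg(strandedness)
  if (is.null(names(introns))) names(introns) <- .intronId(introns)
  aln <- .loadAlignments(file, mapq)
  res <- data.frame(intron_id = names(introns),
                    donor = 0L, acceptor = 0L, junction = 0L,
                    stringsAsFactors = FALSE)
  if (length(aln) == 0 || length(introns) == 0) return(res)
  frag_strand <- .fragmentStrand(aln, strandedness)
  qname <- names(aln)

  ## junction class: exact skip match, matching fragment strand
  jx <- GenomicAlignments::junctions(aln)
  nj <- lengths(jx)
  if (sum(nj) > 0) {
    flat <- unlist(jx, use.names = FALSE)
    read_of <- rep(seq_along(aln), nj)
    jkey <- sprintf("%s:%d-%d:%s", as.character(seqnames(flat)),
                    start(flat), end(flat), frag_strand[read_of])
    hit <- match(jkey, names(introns))
    ok <- !is.na(hit)
    if (any(ok)) {
      fk <- paste(hit[ok], qname[read_of][ok])
      first <- !duplicated(fk)
      tab <- table(hit[ok][first])
      res$junction[as.integer(names(tab))] <- as.integer(tab)
    }
  }

  ## donor / acceptor classes: a bond span contained in one aligned block
  blocks <- GenomicAlignments::grglist(aln)
  nb <- lengths(blocks)
  flat_b <- unlist(blocks, use.names = FALSE)
  block_read <- rep(seq_along(aln), nb)
  spans <- .bondSpans(introns)
  ## per-read (intron, read) hits: a bond span contained in a block
  spanHits <- function(span) {
    ov <- findOverlaps(span, flat_b, type = "within", ignore.strand = TRUE)
    ii <- queryHits(ov)
    rr <- block_read[subjectHits(ov)]
    keep <- frag_strand[rr] == as.character(strand(introns))[ii]
    unique(data.frame(i = ii[keep], r = rr[keep]))
  }
  don <- spanHits(spans$donor)
  acc <- spanHits(spans$acceptor)
  ## disjointness is per read: a read whose block spans the whole intron
  ## starts, in transcript orientation, in the upstream exon -> donor only
  acc <- acc[!paste(acc$i, acc$r) %in% paste(don$i, don$r), , drop = FALSE]
  countFragments <- function(hits) {
    ## one count per (intron, fragment): mates pooled via the query name
    fk <- paste(hits$i, qname[hits$r])
    hits <- hits[!duplicated(fk), , drop = FALSE]
    out <- integer(length(introns))
    tab <- table(hits$i)
    out[as.integer(names(tab))] <- as.integer(tab)
    out
  }
  res$donor <- countFragments(don)
  res$acceptor <- countFragments(acc)
  res
}

#' Assemble bond counts across samples into a SummarizedExperiment
#'
#' @param tables named list of per-sample tables from
#'   \code{\link{countBondReads}}; names must match
#'   \code{design$sample_id}.
#' @param design labeling design.
#' @param introns optional GRanges used as rowRanges.
#' @return SummarizedExperiment with assays \code{donor}, \code{acceptor},
#'   \code{junction} (introns x samples) and the design as colData.
#' @export
bondCountsExperiment <- function(tables, design, introns = NULL) {
  checkDesign(design)
  stopifnot(all(design$sample_id %in% names(tables)))
  tables <- tables[design$sample_id]
  ids <- tables[[1]]$intron_id
  getA <- function(cl) {
    m <- vapply(tables, function(t) {
      stopifnot(identical(t$intron_id, ids))
      as.integer(t[[cl]])
    }, integer(length(ids)))
    m <- matrix(m, nrow = length(ids),
                dimnames = list(ids, design$sample_id))
    m
  }
  assays <- list(donor = getA("donor"), acceptor = getA("acceptor"),
                 junction = getA("junction"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = S4Vectors::DataFrame(design,
                                                    row.names = design$sample_id))
  if (!is.null(introns)) {
    stopifnot(all(ids %in% names(introns)))
    SummarizedExperiment::rowRanges(se) <- introns[ids]
  }
  se
}

#' Long-format bond counts
#'
#' @param se a SummarizedExperiment from \code{\link{bondCountsExperiment}}.
#' @return data.frame intron_id, sample_id, donor, acceptor, junction.
#' @export
bondCountsLong <- function(se) {
  ids <- rownames(se)
  samples <- colnames(se)
  grid <- expand.grid(intron_id = ids, sample_id = samples,
                      stringsAsFactors = FALSE)
  for (cl in c("donor", "acceptor", "junction"))
    grid[[cl]] <- as.vector(SummarizedExperiment::assay(se, cl))
  grid
}

#' Export introns as BED6 (+ category TSV)
#'
#' @param introns GRanges with optional \code{category} metadata.
#' @param file output BED path (0-based half-open; score column holds the
#'   split-read support when available).
#' @export
writeIntronBed <- function(introns, file) {
  score <- if (!is.null(mcols(introns)$n_split_reads))
    mcols(introns)$n_split_reads else 0L
  bed <- data.frame(chrom = as.character(seqnames(introns)),
                    start = start(introns) - 1L, end = end(introns),
                    name = if (is.null(names(introns))) .intronId(introns)
                           else names(introns),
                    score = score, strand = as.character(strand(introns)))
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
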