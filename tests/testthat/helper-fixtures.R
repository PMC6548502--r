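## Fixture builders: plain-text SAM alignments, toy GTF annotation and a
## deterministic toy genome, all generated in code at test time.

samHeader <- function(contigs = c(chr1 = 10000L)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
}

## minimal SAM record; flag 0 = plus-strand unpaired primary. Paired
## flags get placeholder mate fields so the SAM parser accepts them.
samRead <- function(qname, pos, cigar, flag = 0L, rname = "chr1",
                    mapq = 255L) {
  paired <- bitwAnd(flag, 1L) > 0L
  paste(qname, flag, rname, pos, mapq, cigar,
        if (paired) "=" else "*", if (paired) 1L else 0L, 0, "*", "*",
        sep = "\t")
}

writeSam <- function(reads, contigs = c(chr1 = 10000L),
                     file = tempfile(fileext = ".sam")) {
  writeLines(c(samHeader(contigs), reads), file)
  file
}

## n identical reads with distinct query names
samReads <- function(n, pos, cigar, flag = 0L, prefix = "r", ...) {
  vapply(seq_len(n), function(i)
    samRead(sprintf("%s%03d", prefix, i), pos, cigar, flag = flag, ...),
    character(1))
}

## --- brute-force oracle for bond counting -------------------------------

## parse a CIGAR into aligned reference blocks and skipped intervals
cigarBlocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  blocks <- list(); skips <- list()
  cur <- pos; bstart <- pos
  inblock <- FALSE
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (!inblock) { bstart <- cur; inblock <- TRUE }
      cur <- cur + len[i]
    } else if (op[i] == "N") {
      if (inblock) blocks[[length(blocks) + 1]] <- c(bstart, cur - 1)
      inblock <- FALSE
      skips[[length(skips) + 1]] <- c(cur, cur + len[i] - 1)
      cur <- cur + len[i]
    }
    ## I, S, H, P consume no reference
  }
  if (inblock) blocks[[length(blocks) + 1]] <- c(bstart, cur - 1)
  list(blocks = blocks, skips = skips)
}

## scan every read of a SAM file against every bond definition of every
## intron; mirrors the bond definitions with none of the package's
## machinery (shares only the arithmetic of CIGAR walking)
bruteForceBondCounts <- function(sam_file, introns_df,
                                 strandedness = "rf", mapq = 255) {
  lines <- readLines(sam_file)
  lines <- lines[!grepl("^@", lines)]
  out <- data.frame(intron_id = introns_df$intron_id,
                    donor = 0L, acceptor = 0L, junction = 0L)
  seen <- list(donor = character(0), acceptor = character(0),
               junction = character(0))
  for (l in lines) {
    f <- strsplit(l, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 4L) > 0) next
    if (as.integer(f[5]) < mapq) next
    aln_strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
    paired <- bitwAnd(flag, 1L) > 0
    first <- !paired || bitwAnd(flag, 64L) > 0
    flip <- if (strandedness == "rf") first else !first
    fs <- if (flip) setdiff(c("+", "-"), aln_strand) else aln_strand
    cb <- cigarBlocks(as.integer(f[4]), f[6])
    for (k in seq_len(nrow(introns_df))) {
      it <- introns_df[k, ]
      if (it$chrom != f[3] || it$strand != fs) next
      ## bond base pairs (1-based, both bases flanking the bond)
      if (it$strand == "+") {
        donor_bp <- c(it$start - 1, it$start)
        acceptor_bp <- c(it$end, it$end + 1)
      } else {
        donor_bp <- c(it$end, it$end + 1)
        acceptor_bp <- c(it$start - 1, it$start)
      }
      covers <- function(bp) any(vapply(cb$blocks, function(b)
        b[1] <= bp[1] && b[2] >= bp[2], logical(1)))
      jx <- any(vapply(cb$skips, function(s)
        s[1] == it$start && s[2] == it$end, logical(1)))
      d <- covers(donor_bp); a <- covers(acceptor_bp)
      if (d && a) a <- FALSE  # full-intron block starts in the upstream exon
      mark <- function(class, hit) {
        key <- paste(k, f[1])
        if (hit && !key %in% seen[[class]]) {
          seen[[class]] <<- c(seen[[class]], key)
          out[[class]][k] <<- out[[class]][k] + 1L
        }
      }
      mark("donor", d); mark("acceptor", a); mark("junction", jx)
    }
  }
  out
}

intronsDf <- function(gr) {
  data.frame(intron_id = names(gr),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

## --- toy annotation -----------------------------------------------------

## GTF with two genes; geneA (+, chr1) has two transcripts sharing exons
writeToyGtf <- function(file = tempfile(fileext = ".gtf")) {
  g <- function(type, start, end, strand, gene, tx = NA) {
    attrs <- sprintf('gene_id "%s";', gene)
    if (!is.na(tx)) attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
    sprintf("chr1\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            type, start, end, strand, attrs)
  }
  lines <- c(
    g("gene", 1001, 3000, "+", "geneA"),
    g("transcript", 1001, 3000, "+", "geneA", "txA1"),
    g("exon", 1001, 1100, "+", "geneA", "txA1"),
    g("exon", 1301, 1400, "+", "geneA", "txA1"),
    g("exon", 2001, 2100, "+", "geneA", "txA1"),
    g("transcript", 1001, 2100, "+", "geneA", "txA2"),
    g("exon", 1001, 1100, "+", "geneA", "txA2"),
    g("exon", 2001, 2100, "+", "geneA", "txA2"),
    g("transcript", 1301, 1700, "+", "geneA", "txA3"),
    g("exon", 1301, 1400, "+", "geneA", "txA3"),
    g("exon", 1601, 1700, "+", "geneA", "txA3"),
    g("gene", 5001, 6000, "-", "geneB"),
    g("transcript", 5001, 6000, "-", "geneB", "txB1"),
    g("exon", 5001, 5100, "-", "geneB", "txB1"),
    g("exon", 5901, 6000, "-", "geneB", "txB1"))
  writeLines(lines, file)
  file
}

## deterministic toy genome as a named DNAStringSet
toyGenome <- function(len = 10000, seed = 99) {
  bases <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), len, replace = TRUE))
  Biostrings::DNAStringSet(c(chr1 = paste(bases, collapse = "")))
}

grIntron <- function(chrom, start, end, strand) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  names(gr) <- sprintf("%s:%d-%d:%s", chrom, start, end, strand)
  gr
}
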