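## Read counting fixtures use unpaired reads with strandedness "fr"
## (alignment strand = fragment strand) unless a test exercises the
## mate-aware "rf" logic explicitly.

test_that("intron discovery honors the split-read support threshold", {
  ## 12 identical split reads skipping 101-200 -> one intron
  sam <- writeSam(samReads(12, 81, "20M100N20M"))
  introns <- discoverIntrons(sam, min_split_reads = 10,
                             strandedness = "fr")
  expect_length(introns, 1)
  expect_equal(GenomicRanges::start(introns), 101)
  expect_equal(GenomicRanges::end(introns), 200)
  expect_equal(as.character(GenomicRanges::strand(introns)), "+")
  expect_equal(introns$n_split_reads, 12L)

  ## 9 identical reads stay below the default threshold
  sam9 <- writeSam(samReads(9, 81, "20M100N20M"))
  expect_length(discoverIntrons(sam9, 10, strandedness = "fr"), 0)

  ## raising the threshold can only shrink the result
  for (thr in c(1, 5, 11, 12, 13)) {
    found <- length(discoverIntrons(sam, thr, strandedness = "fr"))
    expect_equal(found, as.integer(thr <= 12))
  }
})

test_that("secondary alignments and low MAPQ reads are not counted", {
  reads <- c(samReads(15, 81, "20M100N20M", prefix = "a"),
             samReads(11, 481, "20M200N20M", prefix = "b"),
             ## 3 secondary-flagged copies of the second junction
             samReads(3, 481, "20M200N20M", flag = 256L, prefix = "s"),
             ## low MAPQ split reads are filtered
             samReads(5, 81, "20M100N20M", mapq = 50L, prefix = "q"))
  sam <- writeSam(reads)
  introns <- discoverIntrons(sam, 10, strandedness = "fr")
  expect_length(introns, 2)
  expect_equal(sort(introns$n_split_reads), c(11L, 15L))
})

test_that("bond classes follow the spanning and exact-skip definitions", {
  intron <- grIntron("chr1", 101, 200, "+")
  ## single block 96..110 covers the donor bond (100|101) only
  sam <- writeSam(samRead("r1", 96, "15M"))
  cnt <- countBondReads(sam, intron, strandedness = "fr")
  expect_equal(unlist(cnt[, c("donor", "acceptor", "junction")]),
               c(donor = 1L, acceptor = 0L, junction = 0L))
  ## exact skip 101-200 is a junction read only
  sam2 <- writeSam(samRead("r1", 81, "20M100N20M"))
  cnt2 <- countBondReads(sam2, intron, strandedness = "fr")
  expect_equal(unlist(cnt2[, c("donor", "acceptor", "junction")]),
               c(donor = 0L, acceptor = 0L, junction = 1L))
  ## partial-overlap skip contributes to no class
  sam3 <- writeSam(samRead("r1", 101, "20M100N20M"))  # skip 121-220
  cnt3 <- countBondReads(sam3, intron, strandedness = "fr")
  expect_equal(sum(cnt3[, c("donor", "acceptor", "junction")]), 0L)
})

test_that("a crafted 20-read fixture gives counts (8, 5, 4)", {
  intron <- grIntron("chr1", 101, 200, "+")
  reads <- c(samReads(8, 91, "20M", prefix = "don"),       # spans 100|101
             samReads(5, 191, "20M", prefix = "acc"),      # spans 200|201
             samReads(4, 81, "20M100N20M", prefix = "jx"), # exact skip
             samRead("irr1", 301, "20M"),                  # elsewhere
             samRead("irr2", 120, "30M"),                  # inside intron
             samRead("irr3", 81, "10M110N20M"))            # wrong skip
  sam <- writeSam(reads)
  cnt <- countBondReads(sam, intron, strandedness = "fr")
  expect_equal(unlist(cnt[, c("donor", "acceptor", "junction")]),
               c(donor = 8L, acceptor = 5L, junction = 4L))
})

test_that("counting is idempotent and strand-aware", {
  intron_plus <- grIntron("chr1", 101, 200, "+")
  intron_minus <- grIntron("chr1", 101, 200, "-")
  reads <- c(samReads(3, 91, "20M", prefix = "p"),
             samReads(2, 91, "20M", flag = 16L, prefix = "m"))
  sam <- writeSam(reads)
  both <- c(intron_plus, intron_minus)
  cnt1 <- countBondReads(sam, both, strandedness = "fr")
  cnt2 <- countBondReads(sam, both, strandedness = "fr")
  expect_identical(cnt1, cnt2)
  ## plus-strand fragments feed the plus intron's donor; minus fragments
  ## cover the minus intron's acceptor bond (100|101 on minus strand)
  expect_equal(cnt1$donor, c(3L, 0L))
  expect_equal(cnt1$acceptor, c(0L, 2L))
  ## under "rf", unpaired reads flip: alignment + becomes fragment -
  cnt_rf <- countBondReads(sam, both, strandedness = "rf")
  expect_equal(cnt_rf$donor, c(2L, 0L))
  expect_equal(cnt_rf$acceptor, c(0L, 3L))
})

test_that("mates of one fragment are pooled per class", {
  intron <- grIntron("chr1", 101, 200, "+")
  ## one properly paired fragment: first mate forward covering the donor
  ## bond, second mate reverse covering the acceptor bond ("fr" protocol)
  r1 <- samRead("frag1", 91, "20M", flag = 99L)    # paired, first, mate rev
  r2 <- samRead("frag1", 191, "20M", flag = 147L)  # paired, second, reverse
  sam <- writeSam(c(r1, r2))
  cnt <- countBondReads(sam, intron, strandedness = "fr")
  expect_equal(cnt$donor, 1L)
  expect_equal(cnt$acceptor, 1L)
  ## two mates both covering the donor bond still count once
  r3 <- samRead("frag2", 91, "20M", flag = 99L)
  r4 <- samRead("frag2", 95, "20M", flag = 147L)
  sam2 <- writeSam(c(r3, r4))
  cnt2 <- countBondReads(sam2, intron, strandedness = "fr")
  expect_equal(cnt2$donor, 1L)
})

test_that("a read spanning the whole intron is donor only (class
           disjointness)", {
  intron <- grIntron("chr1", 191, 210, "+")  # short intron
  sam <- writeSam(samRead("r1", 181, "40M"))  # covers both bonds
  cnt <- countBondReads(sam, intron, strandedness = "fr")
  expect_equal(unlist(cnt[, c("donor", "acceptor", "junction")]),
               c(donor = 1L, acceptor = 0L, junction = 0L))
})

test_that("package counts equal a brute-force scan on a mixed fixture", {
  introns <- c(grIntron("chr1", 101, 200, "+"),
               grIntron("chr1", 401, 520, "-"),
               grIntron("chr1", 101, 300, "+"))
  withr::with_seed(17, {
    pool <- list()
    for (i in 1:44) {
      kind <- sample(4, 1)
      flag <- sample(c(0L, 16L), 1)
      pool[[i]] <- switch(kind,
        samRead(paste0("x", i), sample(80:220, 1),
                sprintf("%dM", sample(c(15, 25, 40), 1)), flag = flag),
        samRead(paste0("x", i), 81, "20M100N20M", flag = flag),
        samRead(paste0("x", i), 381, "20M120N20M", flag = flag),
        samRead(paste0("x", i), sample(380:530, 1), "30M", flag = flag))
    }
    sam <- writeSam(unlist(pool))
    got <- countBondReads(sam, introns, strandedness = "fr")
    oracle <- bruteForceBondCounts(sam, intronsDf(introns),
                                   strandedness = "fr")
    expect_equal(got$donor, oracle$donor)
    expect_equal(got$acceptor, oracle$acceptor)
    expect_equal(got$junction, oracle$junction)
    ## class disjointness: per-intron totals never exceed passing reads
    expect_true(all(got$donor + got$acceptor + got$junction <= 44))
  })
})

test_that("malformed alignment input raises a format error", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "not\ta\tvalid\trecord"), bad)
  expect_error(discoverIntrons(bad), "malformed")
})

test_that("bond count tables assemble into a SummarizedExperiment", {
  intron <- c(grIntron("chr1", 101, 200, "+"),
              grIntron("chr1", 401, 520, "-"))
  sam <- writeSam(c(samReads(3, 91, "20M", prefix = "d"),
                    samReads(2, 81, "20M100N20M", prefix = "j")))
  design <- labelingDesign(c("ttseq", "rnaseq"), c(5, 5), c(1, 1))
  tabs <- list(countBondReads(sam, intron, strandedness = "fr"),
               countBondReads(sam, intron, strandedness = "fr"))
  names(tabs) <- design$sample_id
  se <- bondCountsExperiment(tabs, design, intron)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(2L, 2L))
  expect_equal(unname(SummarizedExperiment::assay(se, "donor")[1, ]),
               c(3L, 3L))
  long <- bondCountsLong(se)
  expect_equal(nrow(long), 4)
  expect_equal(sort(names(long)),
               sort(c("intron_id", "sample_id", "donor", "acceptor",
                      "junction")))
})
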