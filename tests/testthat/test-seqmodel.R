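## Context extraction uses a deterministic toy genome (helper); windows are
## verified against hand-extracted substrings of the same sequence.

test_that("context windows equal hand-read substrings on the plus strand", {
  genome <- toyGenome()
  chr <- as.character(genome[[1]])
  intron <- grIntron("chr1", 501, 700, "+")
  bp <- stats::setNames(660, names(intron))
  ctx <- extractContext(genome, intron, bp)
  expect_equal(ctx$donor_window, substr(chr, 481, 520))
  expect_equal(ctx$acceptor_window, substr(chr, 681, 720))
  expect_equal(ctx$branchpoint_window, substr(chr, 640, 680))
  expect_equal(ctx$intron_length, 200L)
  expect_equal(ctx$bp_offset, 160L)
  ## GC fractions computed over the stated spans
  expect_equal(ctx$gc_intron,
               mean(strsplit(substr(chr, 501, 700), "")[[1]] %in% c("G", "C")))
  expect_equal(ctx$gc_donor,
               mean(strsplit(substr(chr, 481, 520), "")[[1]] %in% c("G", "C")))
})

test_that("minus-strand windows are reverse complements", {
  genome <- toyGenome()
  chr <- as.character(genome[[1]])
  intron <- grIntron("chr1", 501, 700, "-")
  bp <- stats::setNames(540, names(intron))  # within intron, 3' half on -
  ctx <- extractContext(genome, intron, bp)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ## donor bond on minus strand sits at the genomic right edge
  expect_equal(ctx$donor_window, rc(substr(chr, 681, 720)))
  expect_equal(ctx$acceptor_window, rc(substr(chr, 481, 520)))
  expect_equal(ctx$branchpoint_window, rc(substr(chr, 520, 560)))
  expect_equal(ctx$bp_offset, 161L)
})

test_that("context extraction validates branchpoints and bounds", {
  genome <- toyGenome()
  intron <- grIntron("chr1", 501, 700, "+")
  expect_error(extractContext(genome, intron,
                              stats::setNames(800, names(intron))),
               "outside")
  edge <- grIntron("chr1", 5, 50, "+")
  expect_error(extractContext(genome, edge,
                              stats::setNames(30, names(edge))),
               "off contig")
})

test_that("GC of a pure GC intron is 1", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("A", 100), collapse = ""),
    paste(rep("GC", 100), collapse = ""),
    paste(rep("A", 100), collapse = ""))))
  intron <- grIntron("chr1", 101, 300, "+")
  ctx <- extractContext(genome, intron, stats::setNames(250, names(intron)))
  expect_equal(ctx$gc_intron, 1)
})

test_that("octamer regions are cropped to the intron and exclude the
           single-nucleotide windows", {
  genome <- toyGenome()
  chr <- as.character(genome[[1]])
  intron <- grIntron("chr1", 1001, 1400, "+")  # length 400
  bp <- stats::setNames(1370, names(intron))   # offset 370
  reg <- intronRegions(genome, intron, bp)
  intr <- substr(chr, 1001, 1400)
  expect_equal(reg$donor_downstream, substr(intr, 16, 100))
  expect_equal(reg$branchpoint_upstream, substr(intr, 270, 369))
  expect_equal(reg$polyY, substr(intr, 371, 395))
  expect_equal(reg$acceptor_upstream, substr(intr, 301, 395))
  ## a short intron crops the donor-downstream region
  short <- grIntron("chr1", 2001, 2080, "+")  # length 80
  regs <- intronRegions(genome, short, stats::setNames(2060, names(short)))
  expect_equal(nchar(regs$donor_downstream), 80 - 15)
})

test_that("octamer counting matches a brute-force Hamming scan", {
  expect_equal(as.vector(countOctamers("AAAAAAAAAA", "AAAAAAAA", 0)), 3L)
  expect_equal(as.vector(countOctamers("ACGTACGT", "ACGTACGT", 2)), 1L)
  expect_equal(as.vector(countOctamers("", "ACGTACGT", 2)), 0L)
  expect_error(countOctamers("ACGTACGT", "ACGT"), "length 8")
  expect_error(countOctamers("ACGTACGT", "ACGTACGT", 3), "max_mismatch")

  bruteCount <- function(seq, oct, m) {
    n <- nchar(seq)
    if (n < 8) return(0L)
    hits <- 0L
    ob <- strsplit(oct, "")[[1]]
    for (off in 1:(n - 7)) {
      w <- strsplit(substr(seq, off, off + 7), "")[[1]]
      if (sum(w != ob) <= m) hits <- hits + 1L
    }
    hits
  }
  withr::with_seed(29, {
    seqs <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
            collapse = ""), character(1))
    octs <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
            collapse = ""), character(1))
    for (m in 0:2) {
      got <- countOctamers(seqs, octs, m)
      want <- outer(seqs, octs, Vectorize(function(s, o) bruteCount(s, o, m)))
      expect_equal(unname(got), unname(want))
    }
    ## counts never decrease with the mismatch allowance
    c0 <- countOctamers(seqs, octs, 0)
    c1 <- countOctamers(seqs, octs, 1)
    c2 <- countOctamers(seqs, octs, 2)
    expect_true(all(c1 >= c0) && all(c2 >= c1))
  })
})

## synthetic contexts with planted single-nucleotide effects
plantedContexts <- function(n, seed = 51) {
  withr::with_seed(seed, {
    rand <- function(k) vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE,
                   prob = c(0.4, 0.2, 0.25, 0.15)), collapse = ""),
      character(1))
    data.frame(intron_id = sprintf("i%04d", seq_len(n)),
               donor_window = rand(40), acceptor_window = rand(40),
               branchpoint_window = rand(41),
               gc_intron = runif(n, 0.3, 0.6),
               gc_donor = runif(n, 0.3, 0.6),
               gc_acceptor = runif(n, 0.3, 0.6),
               intron_length = sample(100:5000, n, TRUE),
               first_intron = sample(c(TRUE, FALSE), n, TRUE),
               stringsAsFactors = FALSE)
  })
}

test_that("planted single-nucleotide effects are selected and recovered", {
  n <- 600
  ctx <- plantedContexts(n)
  ## plant effects at donor positions 21 and 25, acceptor position 19
  mat_d <- do.call(rbind, strsplit(ctx$donor_window, ""))
  mat_a <- do.call(rbind, strsplit(ctx$acceptor_window, ""))
  y <- withr::with_seed(52,
    0.8 * (mat_d[, 21] == "C") - 0.6 * (mat_d[, 25] == "T") +
    0.7 * (mat_a[, 19] == "G") + rnorm(n, 0, 0.15))
  fit <- fitSingleNtModel(ctx, y, seed = 3)
  kept <- fit$retained_positions
  expect_true(any(grepl("donor_p21", kept)))
  expect_true(any(grepl("donor_p25", kept)))
  expect_true(any(grepl("acceptor_p19", kept)))
  cf <- fit$coefficients
  pick <- function(w, p, b)
    cf$effect[cf$window == w & cf$position == p & cf$base == b]
  expect_equal(pick("donor", 21, "C"), 0.8, tolerance = 0.15)
  expect_equal(pick("acceptor", 19, "G"), 0.7, tolerance = 0.15)
  expect_gt(fit$r_squared, 0.5)
  ## consensus-base coefficients are zero by construction
  expect_true(all(cf$effect[cf$base == cf$consensus] == 0))
})

test_that("degenerate single-nucleotide fits behave as specified", {
  ctx <- plantedContexts(120, seed = 61)
  y <- withr::with_seed(62, rnorm(120))
  ## infinite penalty: intercept-only model, variance explained 0
  fit0 <- fitSingleNtModel(ctx, y, lambda = Inf)
  expect_length(fit0$retained_positions, 0)
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(predict(fit0, ctx)), rep(fit0$intercept, 120))
  ## perfect predictions give multiplicative median error 1
  expect_equal(fit0$median_mult_error,
               median(exp(abs(y - mean(y)))), tolerance = 1e-12)
  fitP <- fitSingleNtModel(ctx, rep(c(1, 2), 60), lambda = Inf)
  expect_error(fitSingleNtModel(ctx, rep(1, 120)), "constant")
})

test_that("a consensus sequence predicts exactly the intercept", {
  ctx <- plantedContexts(300, seed = 71)
  mat_d <- do.call(rbind, strsplit(ctx$donor_window, ""))
  y <- withr::with_seed(72, 0.9 * (mat_d[, 21] == "C") + rnorm(300, 0, 0.2))
  fit <- fitSingleNtModel(ctx, y, seed = 5)
  cons <- data.frame(
    intron_id = "cons",
    donor_window = paste(fit$consensus$donor, collapse = ""),
    acceptor_window = paste(fit$consensus$acceptor, collapse = ""),
    branchpoint_window = paste(fit$consensus$branchpoint, collapse = ""))
  expect_equal(predict(fit, cons), fit$intercept, tolerance = 1e-12)
})

test_that("lasso selection is monotone in the penalty", {
  ctx <- plantedContexts(250, seed = 81)
  mat_d <- do.call(rbind, strsplit(ctx$donor_window, ""))
  y <- withr::with_seed(82,
    0.5 * (mat_d[, 21] == "C") - 0.4 * (mat_d[, 30] == "A") +
      rnorm(250, 0, 0.3))
  sizes <- vapply(c(0.005, 0.05, 0.5), function(l) {
    f <- fitSingleNtModel(ctx, y, lambda = l, seed = 2)
    length(f$retained_positions)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("rpm scores match exhaustive enumeration and its invariances", {
  ## consensus octamer scores exactly 1
  pwm8 <- matrix(0.05, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "A", "C", "G", "T")
  for (j in 1:8) pwm8[cons[j], j] <- 0.85
  expect_equal(rpmScore(paste(cons, collapse = ""), pwm8), 1)
  ## uniform PWM scores every octamer 1
  uni <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(rpmScore("ACGTACGT", uni), 1)
  ## short PWM: best alignment over all offsets equals brute force
  pwm2 <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 2,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  withr::with_seed(91, {
    for (i in 1:20) {
      oct <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      b <- strsplit(oct, "")[[1]]
      want <- max(vapply(1:7, function(k)
        pwm2[b[k], 1] * pwm2[b[k + 1], 2], numeric(1))) / (0.7 * 0.7)
      expect_equal(rpmScore(oct, pwm2), want)
    }
  })
  ## invariant to scaling a PWM column by a positive constant
  pwm8b <- pwm8; pwm8b[, 3] <- pwm8b[, 3] * 5
  expect_equal(rpmScore("ACGAACGT", pwm8), rpmScore("ACGAACGT", pwm8b))
  ## long PWM: octamer padded with neutral Ns on both sides
  pwm10 <- matrix(0.25, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(rpmScore("ACGTACGT", pwm10), 1)
  expect_error(rpmScore("ACGT", pwm8), "length 8")
  zero <- pwm8; zero[, 2] <- 0
  expect_error(rpmScore("ACGTACGT", zero), "zero column")
})

test_that("attract matching keeps the top 5% then applies the 0.9 floor", {
  pwm8 <- matrix(0.04, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:8) pwm8["A", j] <- 0.88
  octs <- withr::with_seed(93, vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, TRUE, prob = c(.7, .1, .1, .1)),
          collapse = ""), character(1)))
  octs <- unique(c("AAAAAAAA", octs))
  hits <- matchAttract(octs, list(polyA = pwm8))
  expect_true(all(hits$rpm_score >= 0.9))
  expect_lte(nrow(hits), ceiling(0.05 * length(octs)))
  expect_true("AAAAAAAA" %in% hits$octamer)
  ## PWMs shorter than the minimum length are dropped
  short <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(nrow(matchAttract(octs, list(s = short))), 0)
})

test_that("attract-format PWM files round-trip", {
  f <- tempfile()
  writeLines(c(">M001 RBP1", "0.7 0.1 0.1 0.1", "0.1 0.7 0.1 0.1",
               "0.1 0.1 0.7 0.1", "0.1 0.1 0.1 0.7", "0.25 0.25 0.25 0.25",
               ">M002", "0.9 0.03 0.03 0.04", "0.9 0.03 0.03 0.04",
               "0.2 0.3 0.3 0.2", "0.25 0.25 0.25 0.25",
               "0.25 0.25 0.25 0.25"), f)
  pwms <- readAttractPwms(f)
  expect_equal(names(pwms), c("M001", "M002"))
  expect_equal(dim(pwms$M001), c(4L, 5L))
  expect_equal(unname(pwms$M001["A", 1]), 0.7)
  expect_equal(unname(pwms$M002["C", 3]), 0.3)
})

test_that("planted octamer effects survive both selection stages", {
  n <- 800
  withr::with_seed(95, {
    regions <- data.frame(
      intron_id = sprintf("i%04d", seq_len(n)),
      donor_downstream = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 85, TRUE), collapse = ""),
        character(1)),
      branchpoint_upstream = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
        character(1)),
      polyY = vapply(seq_len(n), function(i)
        paste(sample(c("C", "T", "A"), 25, TRUE), collapse = ""),
        character(1)),
      acceptor_upstream = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 95, TRUE), collapse = ""),
        character(1)),
      stringsAsFactors = FALSE)
    for (r in c("donor_downstream", "branchpoint_upstream", "polyY",
                "acceptor_upstream"))
      regions[[paste0("gc_", r)]] <- vapply(regions[[r]], function(s)
        mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1),
        USE.NAMES = FALSE)
    planted <- "ACGTTGCA"
    universe <- unique(c(planted, vapply(1:60, function(i)
      paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
      character(1))))
    cnt <- countOctamers(regions$donor_downstream, planted, 2)
    y <- 0.9 * log2(cnt + 1) + rnorm(n, 0, 0.25)
  })
  fit <- fitOctamerModel(regions, as.vector(y), octamers = universe,
                         seed = 7)
  expect_true(planted %in% fit$region_selected$donor_downstream)
  sel <- grep(paste0("donor_downstream\\.", planted), fit$joint_selected)
  expect_length(sel, 1)
  expect_gt(fit$coefficients[[paste0("donor_downstream.", planted)]], 0)
  expect_gt(fit$r_squared, 0.4)
})

test_that("octamer model null behavior and collinear drop-one ledger", {
  n <- 500
  withr::with_seed(97, {
    regions <- data.frame(
      intron_id = sprintf("i%04d", seq_len(n)),
      donor_downstream = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 85, TRUE), collapse = ""),
        character(1)),
      branchpoint_upstream = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
        character(1)),
      polyY = "", acceptor_upstream = "",
      stringsAsFactors = FALSE)
    for (r in c("donor_downstream", "branchpoint_upstream", "polyY",
                "acceptor_upstream"))
      regions[[paste0("gc_", r)]] <- vapply(regions[[r]], function(s)
        if (nchar(s) == 0) NA_real_
        else mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1),
        USE.NAMES = FALSE)
    universe <- unique(vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
      character(1)))
    y_null <- rnorm(n)
  })
  ## response independent of sequence: joint variance explained ~ 0
  fit0 <- suppressWarnings(
    fitOctamerModel(regions, y_null, octamers = universe, seed = 9))
  expect_lt(fit0$r_squared, 0.02)

  ## constructed collinearity across feature groups: the octamer count in
  ## one region carries (nearly) the same information as a single-nt
  ## feature, so its individual variance explained is large while its
  ## drop-one contribution to the joint model is small
  planted <- "ACGTTGCA"
  regions2 <- regions
  withr::with_seed(98, {
    k <- sample(0:6, n, TRUE)
    regions2$donor_downstream <- vapply(seq_len(n), function(i) {
      filler <- paste(sample(c("A", "C"), 90 - 8 * k[i], TRUE),
                      collapse = "")
      paste0(paste(rep(planted, k[i]), collapse = ""), filler)
    }, character(1))
    regions2$gc_donor_downstream <- vapply(regions2$donor_downstream,
      function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1),
      USE.NAMES = FALSE)
    snt <- matrix(log2(k + 1), ncol = 1,
                  dimnames = list(NULL, "planted_signal"))
    y2 <- log2(k + 1) + rnorm(n, 0, 0.2)
  })
  fit2 <- suppressWarnings(
    fitOctamerModel(regions2, as.vector(y2), single_nt_features = snt,
                    octamers = unique(c(planted, universe)),
                    max_mismatch = 0, seed = 9))
  led <- fit2$variance_ledger
  oct_row <- led[led$feature == "octamers_donor_downstream", ]
  expect_gt(oct_row$individual_r2, 0.5)
  expect_lt(oct_row$drop_r2, 0.1)
})
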