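test_that("candidate filter requires strictly more than half overlap", {
  chip <- gr1("c1", 1000, 1999)
  gro_in <- gr1("c1", 1949, 2048, "+")    # 51 of 100 nt inside
  gro_edge <- gr1("c1", 1950, 2049, "+")  # exactly 50 nt inside
  expect_length(overlap_filter(gro_in, chip), 1L)
  expect_length(overlap_filter(gro_edge, chip), 0L)
  expect_length(overlap_filter(gro_in, GRanges()), 0L)
  # fraction is judged against the best single Pol II peak
  two <- c(gr1("c1", 1900, 1974), gr1("c1", 1985, 2100))
  expect_length(overlap_filter(gro_edge, two), 1L)
})

test_that("noiseless power-law tabulation returns the generating parameters", {
  x <- 3:100
  freq <- 0.965 * x^(-2.443)
  fit <- fit_powerlaw_null(data.frame(coverage = x, freq = freq))
  expect_equal(fit$a, 0.965, tolerance = 1e-6)
  expect_equal(fit$b, 2.443, tolerance = 1e-6)

  flat <- fit_powerlaw_null(data.frame(coverage = x, freq = rep(0.01, 98)))
  expect_equal(flat$b, 0, tolerance = 1e-9)

  expect_error(fit_powerlaw_null(data.frame(coverage = 3:8, freq = 1:6)),
               "10 distinct")
})

test_that("parameters are recovered from large samples within fit error", {
  set.seed(19)
  lo <- 3; hi <- 100; b <- 2.443; a <- 0.965
  x <- seq_len(hi)
  p <- a * x^(-b)
  p[1:2] <- (1 - sum(p[lo:hi])) * (1:2)^(-b) / sum((1:2)^(-b))
  draws <- sample.int(hi, 1e6, replace = TRUE, prob = p)
  tab <- table(draws)
  freq <- data.frame(coverage = as.numeric(names(tab)),
                     freq = as.numeric(tab) / length(draws))
  fit <- fit_powerlaw_null(freq)
  expect_lt(abs(fit$b - b), 3 * fit$b_err + 0.02)
  expect_lt(abs(fit$a - a), 3 * fit$a_err + 0.02)
})

test_that("tail probabilities and the FDR filter behave at the extremes", {
  null <- fit_powerlaw_null(
    data.frame(coverage = 3:100, freq = 0.965 * (3:100)^(-2.443)))
  expect_identical(pl_tail_prob(null, 0), 1)
  expect_identical(pl_tail_prob(null, 2), 1)
  expect_equal(pl_tail_prob(null, 3), 1)  # whole support
  expect_true(all(diff(pl_tail_prob(null, 3:500)) <= 0))

  # one locus at 10x the null's extreme tail among 100 null-level loci
  loci <- gr1("c1", seq(1000, 100000, by = 1000), seq(1199, 100199, by = 1000))
  cov <- c(rep(3, 99), 5000)
  kept <- mnet_fdr_filter(loci, cov, null, fdr = 0.05)
  expect_length(kept, 1L)
  expect_identical(GenomicRanges::start(kept), 100000L)
  expect_lte(kept$mnet_fdr_q, 0.05)

  # zero coverage is never retained
  none <- mnet_fdr_filter(loci, rep(0, 100), null, fdr = 0.05)
  expect_length(none, 0L)
})

test_that("BH filtering of pure-null coverage keeps the false rate at bay", {
  null <- fit_powerlaw_null(
    data.frame(coverage = 3:100, freq = 0.965 * (3:100)^(-2.443)))
  set.seed(77)
  x <- 3:100
  p <- x^(-null$b)
  frac <- vapply(1:5, function(s) {
    cov <- sample(x, 2000, replace = TRUE, prob = p)
    pv <- pl_tail_prob(null, cov)
    mean(p.adjust(pv, "BH") <= 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 3 * sqrt(0.05 * 0.95 / (5 * 2000)))
})

test_that("rank summation orders loci and ignores monotone rescaling", {
  sizes <- c(c1 = 10000L)
  loci <- gr1("c1", c(1000, 3000, 5000), c(1199, 3199, 5199), "+")
  mk_tracks <- function(f = identity) {
    v <- function(h) {
      x <- numeric(10000)
      x[1000:1199] <- f(h[1]); x[3000:3199] <- f(h[2]); x[5000:5199] <- f(h[3])
      x
    }
    list(chip = coverage_track(list(c1 = v(c(9, 6, 3)))),
         gro = coverage_track(list("+" = list(c1 = v(c(8, 5, 2))),
                                   "-" = list(c1 = numeric(10000))),
                              stranded = TRUE),
         net = coverage_track(list(c1 = v(c(7, 4, 1)))),
         mnet = coverage_track(list("+" = list(c1 = v(c(6, 3, 1))),
                                    "-" = list(c1 = numeric(10000))),
                               stranded = TRUE))
  }
  r <- rank_loci(loci, mk_tracks())
  expect_identical(r$sum_rank, c(4, 8, 12))
  expect_identical(r$final_rank, 1:3)
  expect_identical(GenomicRanges::start(r), c(1000L, 3000L, 5000L))

  # strictly increasing transform of one track leaves the order unchanged
  r2 <- rank_loci(loci, mk_tracks(function(h) h^3 + 1))
  expect_identical(GenomicRanges::start(r2), GenomicRanges::start(r))
  expect_identical(r2$sum_rank, r$sum_rank)

  expect_error(rank_loci(loci, mk_tracks()[c("chip", "gro")]), "mnet")

  # all-equal signals: average ranks, stable positional tie-break
  flat <- list(chip = flat_track(sizes), gro = flat_track(sizes, stranded = TRUE),
               net = flat_track(sizes), mnet = flat_track(sizes, stranded = TRUE))
  rt <- rank_loci(loci, flat)
  expect_identical(unique(rt$sum_rank), 8)
  expect_identical(GenomicRanges::start(rt), c(1000L, 3000L, 5000L))
})

test_that("strongest spike takes the 5-prime-most maximum on each strand", {
  v <- numeric(1000)
  v[200] <- 10; v[300] <- 10; v[250] <- 4
  mnet <- coverage_track(list("+" = list(c1 = v), "-" = list(c1 = v)),
                         stranded = TRUE)
  plus <- strongest_spike(gr1("c1", 100, 400, "+"), mnet)
  expect_identical(plus$spike_pos, 200L)
  expect_identical(plus$second_spike_pos, 300L)
  expect_identical(plus$spike_distance, 100L)
  minus <- strongest_spike(gr1("c1", 100, 400, "-"), mnet)
  expect_identical(minus$spike_pos, 300L)  # 5'-most in transcription sense
  expect_identical(minus$spike_distance, 100L)

  single <- numeric(1000); single[500] <- 2
  one <- strongest_spike(gr1("c1", 400, 600, "+"),
                         coverage_track(list("+" = list(c1 = single),
                                             "-" = list(c1 = numeric(1000))),
                                        stranded = TRUE))
  expect_identical(one$spike_pos, 500L)
  expect_true(is.na(one$second_spike_pos))

  empty <- strongest_spike(gr1("c1", 700, 800, "+"),
                           coverage_track(list("+" = list(c1 = single),
                                               "-" = list(c1 = numeric(1000))),
                                          stranded = TRUE))
  expect_true(is.na(empty$spike_pos))
})

test_that("genic classification splits loci by midpoint and signs distances", {
  genes <- c(gr1("c1", 10000, 15000, "+", gene_id = "g1"),
             gr1("c1", 30000, 36000, "-", gene_id = "g2"))
  loci <- suppressWarnings(
    c(gr1("c1", 10050, 10150, "+"),  # midpoint at TSS+100 of g1
      gr1("c1", 50000, 50100, "+"),  # intergenic
      gr1("c2", 100, 200, "+"),      # empty chromosome
      gr1("c1", 35850, 35950, "-"))) # inside g2, near its TSS
  out <- classify_genic(loci, genes)
  expect_identical(out$genic_class,
                   c("intragenic", "intergenic", "intergenic", "intragenic"))
  expect_identical(out$dist_tss[1], 100)
  expect_gt(out$dist_tss[4], 0)       # downstream of the minus-strand TSS
  expect_true(is.na(out$dist_tss[3])) # no gene on the chromosome
  expect_lt(out$dist_tts[1], 0)       # upstream of g1's TTS

  # a constructed 6/4 split is recovered exactly
  mids_in <- gr1("c1", seq(11000, 14000, length.out = 6),
                 seq(11000, 14000, length.out = 6) + 10, "+")
  mids_out <- gr1("c1", seq(60000, 90000, length.out = 4),
                  seq(60000, 90000, length.out = 4) + 10, "+")
  split_out <- classify_genic(c(mids_in, mids_out), genes)
  expect_identical(sum(split_out$genic_class == "intragenic"), 6L)
  expect_identical(sum(split_out$genic_class == "intergenic"), 4L)
})

test_that("the end-to-end caller recovers planted pauses at the top ranks", {
  sim <- shared_sim()
  ps <- call_pause_sites(sim$gro_peaks, sim$chip_peaks, sim$tracks)
  truth <- sim$manifest[sim$manifest$state == "PAU", ]
  expect_gte(mean(truth$pause_pos %in% ps$spike_pos), 0.9)
  expect_identical(ps$final_rank, seq_along(ps))
  # every locus retained by the filter satisfies the FDR bound
  expect_true(all(ps$mnet_fdr_q <= 0.05))
})
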