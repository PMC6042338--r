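test_that("affected windows follow the sliding-window union rule", {
  # interior mutation: all 30 windows containing it
  expect_length(affected_windows(300, 150), 30L)
  # mutations 2 nt apart share most windows: union of 32 starts
  expect_length(affected_windows(300, c(62, 64)), 32L)
  # edge clipping: position 1 sits in a single complete window
  expect_identical(affected_windows(300, 1), 1L)
  expect_identical(affected_windows(40, 40), 11L:11L)
  expect_error(affected_windows(300, 301))
  # brute-force cross-check
  p <- c(10, 95, 96, 250)
  brute <- which(vapply(seq_len(300 - 30 + 1), function(s)
    any(p >= s & p <= s + 29), logical(1)))
  expect_identical(affected_windows(300, p), brute)
})

test_that("cumulative ddG is zero for identity and tracks stem completion", {
  set.seed(61)
  s <- random_dna(200)
  expect_identical(cumulative_ddg(s, s), 0)

  # toy hairpin with one mismatched stem position; the point mutation that
  # completes the stem stabilizes every affected window
  stem5 <- "GCCGGCATGCCG"
  loop <- "TTTT"
  stem3 <- as.character(reverseComplement(DNAString(stem5)))
  broken <- sub("ATG", "AAG", stem5)  # breaks one pair
  wt <- paste0(strrep("A", 60), broken, loop, stem3, strrep("A", 60))
  mut <- paste0(strrep("A", 60), stem5, loop, stem3, strrep("A", 60))
  ddg <- cumulative_ddg(wt, mut)
  expect_lt(ddg, 0)

  # equals the direct window-by-window subtraction
  pos <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
  wins <- affected_windows(nchar(wt), pos)
  direct <- sum(vapply(wins, function(w) {
    mfe_fold(substr(mut, w, w + 29), preset_in_vitro())$delta_g -
      mfe_fold(substr(wt, w, w + 29), preset_in_vitro())$delta_g
  }, numeric(1)))
  expect_equal(ddg, direct, tolerance = 1e-9)

  expect_error(cumulative_ddg("ACGT", "ACGTA"), "equal length")
})

test_that("cumulative ddG is additive over well-separated mutations", {
  set.seed(63)
  s <- random_dna(400)
  b <- strsplit(s, "")[[1]]
  flip <- function(x) c(A = "G", C = "T", G = "A", T = "C")[x]
  m1 <- b; m1[100] <- flip(b[100])
  m2 <- b; m2[300] <- flip(b[300])  # > 29 nt apart: disjoint window sets
  m12 <- b; m12[100] <- m1[100]; m12[300] <- m2[300]
  j <- function(x) paste(x, collapse = "")
  expect_equal(cumulative_ddg(s, j(m12)),
               cumulative_ddg(s, j(m1)) + cumulative_ddg(s, j(m2)),
               tolerance = 1e-9)
})

test_that("Huber regression matches OLS on clean data and resists outliers", {
  set.seed(65)
  x <- seq(-7, 7, length.out = 15)
  y <- 0.6 - 0.03 * x
  clean <- robust_fit(x, y)
  expect_equal(clean$slope, -0.03, tolerance = 1e-9)
  expect_true(all(clean$weights == 1))
  expect_false(any(clean$outliers))

  # one gross outlier among 15 collinear points
  y_noise <- y + rnorm(15, sd = 0.004)
  clean_slope <- robust_fit(x, y_noise)$slope
  y_bad <- y_noise
  y_bad[15] <- y_noise[15] + 0.8  # outlier at an end point to lever the slope
  rob <- robust_fit(x, y_bad)
  ols <- coef(lm(y_bad ~ x))[2]
  expect_lt(abs(rob$slope - clean_slope) / abs(clean_slope), 0.05)
  expect_gt(abs(ols - clean_slope) / abs(clean_slope), 0.2)
  expect_true(rob$outliers[15])

  expect_error(robust_fit(1:3, 1:3), "at least 4")
})

test_that("stability-driven mutant panels regress with negative slope", {
  # variants strengthening/weakening a stem drive ddG both ways; pausing is
  # generated to rise with stability (more negative ddG)
  set.seed(67)
  stem5 <- "GCCGACATGCCG"
  stem3 <- as.character(reverseComplement(DNAString("GCCGGCATGCCG")))
  wt <- paste0(strrep("A", 50), stem5, "TTTT", stem3, strrep("A", 50))
  alts <- list(c(55, "A", "G"), c(56, "C", "G"), c(52, "C", "A"),
               c(53, "G", "T"), c(51, "C", "T"), c(58, "T", "G"),
               c(60, "C", "A"), c(54, "A", "C"))
  b <- strsplit(wt, "")[[1]]
  ddg <- vapply(alts, function(a) {
    m <- b; m[as.integer(a[1])] <- a[3]
    cumulative_ddg(wt, paste(m, collapse = ""))
  }, numeric(1))
  pf <- pmin(pmax(0.5 - 0.05 * ddg + rnorm(8, sd = 0.01), 0), 1)
  variants <- data.frame(
    variant_id = paste0("v", seq_along(alts)),
    offset = vapply(alts, function(a) as.integer(a[1]), integer(1)),
    ref = vapply(alts, function(a) b[as.integer(a[1])], character(1)),
    alt = vapply(alts, function(a) a[3], character(1)),
    paused_fraction = pf
  )
  panel <- mutant_panel(wt, variants)
  expect_lt(panel$fit$slope, 0)
  expect_identical(nrow(panel$records), 8L)
  expect_equal(panel$records$cumulative_ddg, unname(ddg))
})
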