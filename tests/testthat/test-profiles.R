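test_that("anchored matrices orient rows by strand and pad edges", {
  sizes <- c(c1 = 10000L)
  cons <- flat_track(sizes, 3)
  anchors <- gr1("c1", c(500, 900), c(500, 900), c("+", "-"),
                 name = c("a", "b"))
  m <- anchored_matrix(anchors, cons, flank = 50)
  expect_identical(dim(m), c(2L, 101L))
  expect_true(all(m == 3))

  # spike 75 nt upstream of a minus-strand anchor in genomic terms lands
  # downstream (+75) after orientation flipping
  v <- numeric(10000)
  v[900 + 75] <- 9  # for the minus anchor at 900, genomic +75 = oriented -75
  v[900 - 75] <- 5  # genomic -75 = oriented +75
  tr <- coverage_track(list(c1 = v))
  m2 <- anchored_matrix(anchors[2], tr, flank = 100)
  expect_identical(unname(m2[1, "75"]), 5)
  expect_identical(unname(m2[1, "-75"]), 9)

  # reversing the strand flips the row exactly
  m_plus <- anchored_matrix(gr1("c1", 900, 900, "+"), tr, flank = 100)
  expect_identical(unname(rev(m_plus[1, ])), unname(m2[1, ]))

  # anchor close to the chromosome start pads with NA
  edge <- anchored_matrix(gr1("c1", 20, 20, "+"), tr, flank = 50)
  expect_true(all(is.na(edge[1, 1:31])))
})

test_that("average profiles are missing-aware column means", {
  m <- matrix(c(1, 3, NA, 5, 2, 4), nrow = 2,
              dimnames = list(NULL, c(-1, 0, 1)))
  av <- average_profile(m)
  expect_equal(av$mean, c(2, 5, 3))
  expect_equal(av$n, c(2, 1, 2))
  one <- average_profile(m[1, , drop = FALSE])
  expect_equal(one$mean, unname(m[1, ]))
})

test_that("locate_min finds the vertex and flags flat profiles", {
  offs <- -100:100
  v <- abs(offs + 25) / 10 - 3
  lm_ <- locate_min(setNames(v, offs))
  expect_identical(lm_$offset, -25)
  expect_true(lm_$interval[1] <= -25 && lm_$interval[2] >= -25)
  expect_false(lm_$degenerate)

  flat <- locate_min(setNames(rep(-1, 201), offs))
  expect_true(flat$degenerate)
  expect_identical(flat$interval, c(-100, 100))

  win <- locate_min(setNames(v, offs), search = c(-10, 50))
  expect_identical(win$offset, -10)
})

test_that("strand bias vanishes on palindromes and favors G4-rich coding strands", {
  # palindromic promoter: both strands read the same sequence
  set.seed(41)
  half <- random_dna(120)
  pal <- paste0(half, as.character(reverseComplement(DNAString(half))))
  g <- DNAStringSet(c(c1 = paste0(strrep("A", 200), pal, strrep("A", 200))))
  gene <- gr1("c1", 201, 201 + nchar(pal) - 1, "+", gene_id = "gp")
  sb <- strand_bias(gene, g, region = c(0, nchar(pal) - 1))
  expect_equal(sb$mean_difference, 0, tolerance = 1e-9)

  # G-rich non-template strand with G4 scoring on: non-template dG lower
  g4block <- paste(rep("GGGTTAGGGTTAGGGTTAGGGTTTTT", 6), collapse = "")
  g2 <- DNAStringSet(c(c1 = paste0(strrep("A", 200), g4block, strrep("A", 200))))
  gene2 <- gr1("c1", 201, 200 + nchar(g4block), "+", gene_id = "gq")
  sb2 <- strand_bias(gene2, g2, params = fold_params(allow_g4 = TRUE),
                     region = c(0, nchar(g4block) - 1))
  expect_lt(sb2$per_gene$dg_non_template, sb2$per_gene$dg_template)
})

test_that("extreme-density bands integrate to their mass share", {
  set.seed(51)
  m <- matrix(runif(200 * 101, -10, 0), 200, 101,
              dimnames = list(NULL, -50:50))
  low <- extreme_density(m, "low", frac = 0.02)
  high <- extreme_density(m, "high", frac = 0.02)
  expect_equal(mean(low$frequency), 0.02, tolerance = 0.005)
  expect_equal(mean(high$frequency), 0.02, tolerance = 0.005)
  # uniform random values: no positional structure
  expect_lt(max(low$frequency), 0.1)

  # planting deep values in one column concentrates the band there
  m2 <- m
  m2[, "-30"] <- -50
  low2 <- extreme_density(m2, "low", frac = 0.02)
  expect_identical(low2$offset[which.max(low2$frequency)], -30)
  expect_equal(max(low2$frequency), 1)
})

test_that("anchored dG matrices localize planted hairpins upstream of spikes", {
  sim <- shared_sim()
  tp <- sim$manifest[sim$manifest$state == "PAU", ]
  anchors <- GRanges(tp$chrom, IRanges(tp$pause_pos, tp$pause_pos),
                     strand = tp$strand, gene_id = tp$gene_id)
  m <- anchored_dg_matrix(anchors, sim$genome, flank = 100)
  av <- average_profile(m)
  lm_ <- locate_min(av, search = c(-80, 40))
  expect_gte(lm_$interval[1], -50)
  expect_lte(lm_$interval[2], -10)

  # the same geometry on GC content peaks at the same place (GC-rich stems)
  gc <- anchored_dg_matrix(anchors, sim$genome, flank = 100, what = "gc")
  gcav <- average_profile(gc)
  expect_lt(abs(gcav$offset[which.max(gcav$mean)] - lm_$offset), 25)
})
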