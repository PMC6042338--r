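test_that("transcript selection keeps the longest isoform and filters", {
  set.seed(15)
  g <- DNAStringSet(c(c1 = random_dna(30000)))
  genes <- c(
    gr1("c1", 5000, 9999, "+", gene_id = "gA", tx_id = "tA1"),   # 5 kb
    gr1("c1", 5000, 12999, "+", gene_id = "gA", tx_id = "tA2"),  # 8 kb kept
    gr1("c1", 16000, 16599, "+", gene_id = "gB", tx_id = "tB1"), # 600 nt out
    gr1("c1", 20000, 22000, "-", gene_id = "gC", tx_id = "tC1")
  )
  sel <- select_transcripts(genes, g)
  expect_identical(sort(sel$gene_id), c("gA", "gC"))
  expect_identical(GenomicRanges::width(sel[sel$gene_id == "gA"]), 8000L)

  # a 660-nt transcript survives the length filter exactly
  g660 <- gr1("c1", 4000, 4659, "+", gene_id = "gD", tx_id = "tD")
  expect_identical(select_transcripts(g660, g)$gene_id, "gD")

  # one N within TSS +/- 2 knt removes the gene
  s <- as.character(g[["c1"]])
  substr(s, 20000 + 1500, 20000 + 1500) <- "N"
  gN <- DNAStringSet(c(c1 = s))
  selN <- select_transcripts(genes, gN)
  expect_false("gC" %in% selN$gene_id)
  expect_true("gA" %in% selN$gene_id)
})

test_that("traveling ratio arithmetic and boundary conventions", {
  sizes <- c(c1 = 10000L)
  gene <- gr1("c1", 2000, 4000, "+", gene_id = "g1")

  # uniform coverage -> densities equal -> TR = 1 -> non-paused
  tr_u <- traveling_ratio(gene, flat_track(sizes, 3))
  expect_equal(tr_u$tr, 1)

  # densities 10 vs 2 -> TR = 5
  v <- numeric(10000)
  v[(2000 - 30):(2000 + 300)] <- 10
  v[(2000 + 301):4000] <- 2
  tr5 <- traveling_ratio(gene, coverage_track(list(c1 = v)))
  expect_equal(tr5$tr, 5)

  # TR exactly 2 is non-paused under TR <= 2
  v2 <- numeric(10000)
  v2[(2000 - 30):(2000 + 300)] <- 4
  v2[(2000 + 301):4000] <- 2
  cl <- classify_pausing(gene, gr1("c1", 2000, 2400),
                         coverage_track(list(c1 = v2)))
  expect_equal(cl$tr, 2)
  expect_identical(as.character(cl$state), "NPA")

  # zero body signal with TSS signal -> infinite TR -> paused
  v3 <- numeric(10000)
  v3[2000:2100] <- 6
  cl3 <- classify_pausing(gene, gr1("c1", 2000, 2400),
                          coverage_track(list(c1 = v3)))
  expect_identical(cl3$tr, Inf)
  expect_identical(as.character(cl3$state), "PAU")

  # TR is invariant to global coverage scaling
  tr_scaled <- traveling_ratio(gene, coverage_track(list(c1 = 7 * v)))
  expect_equal(tr_scaled$tr, tr5$tr)

  # minus-strand gene: TSS window sits at the right end
  gene_m <- gr1("c1", 6000, 8000, "-", gene_id = "gm")
  vm <- numeric(10000)
  vm[(8000 - 300):(8000 + 30)] <- 10
  vm[6000:(8000 - 301)] <- 1
  trm <- traveling_ratio(gene_m, coverage_track(list(c1 = vm)))
  expect_equal(trm$tr, 10)
})

test_that("pausing classification stratifies by binding then TR", {
  sizes <- c(c1 = 10000L)
  genes <- gr1("c1", c(1000, 4000, 7000), c(2999, 5999, 8999),
               rep("+", 3), gene_id = c("g1", "g2", "g3"))
  cov <- flat_track(sizes, 1)

  # no peaks anywhere -> every gene NP2
  none <- classify_pausing(genes, GRanges(), cov)
  expect_identical(as.character(none$state), rep("NP2", 3))
  expect_equal(sum(attr(none, "fractions")), 1)

  # bound gene with zero coverage -> NPA by the binding-only rule
  zero <- coverage_track(list(c1 = numeric(10000)))
  z <- classify_pausing(genes[1], gr1("c1", 1000, 1200), zero)
  expect_identical(as.character(z$state), "NPA")
})

test_that("planted pausing states are recovered from simulated tracks", {
  sim <- shared_sim()
  cl <- classify_pausing(sim$genes, sim$chip_peaks, sim$tracks$chip)
  truth <- sim$manifest$state[match(cl$gene_id, sim$manifest$gene_id)]
  expect_gte(mean(as.character(cl$state) == truth), 0.95)
})

test_that("concordance is exact on self-comparison and monotone transforms", {
  sim <- shared_sim()
  cl <- classify_pausing(sim$genes, sim$chip_peaks, sim$tracks$chip)
  self <- concordance(list(a = cl, b = cl))
  expect_equal(self$correlation["a", "b"], 1)
  expect_identical(self$switched$n_switched, 0L)

  # a rank-preserving monotone transform leaves Spearman at 1
  cl2 <- cl
  cl2$tr <- ifelse(is.finite(cl$tr), exp(cl$tr / 10), cl$tr)
  mono <- concordance(list(a = cl, b = cl2))
  expect_equal(mono$correlation["a", "b"], 1)

  # independent TRs decorrelate
  set.seed(31)
  cl3 <- cl
  cl3$tr <- sample(cl$tr)
  rnd <- concordance(list(a = cl, b = cl3))
  expect_lt(abs(rnd$correlation["a", "b"]), 0.5)
})
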