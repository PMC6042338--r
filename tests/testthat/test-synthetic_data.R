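test_that("genome generation is seeded, GC-calibrated and gap-aware", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chrS1 = 40000L), n_genes = 4)
  g1 <- make_genome(cfg)$genome
  g2 <- make_genome(cfg)$genome
  expect_identical(as.character(g1), as.character(g2))

  gc <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / 40000
  se <- sqrt(0.5 * 0.5 / 40000)
  expect_lt(abs(gc - 0.5), 3 * se)

  gaps <- gr1("chrS1", c(1000, 9000), c(1999, 9499))
  gg <- make_genome(cfg, gaps = gaps)$genome
  expect_identical(as.character(Biostrings::subseq(gg[[1]], 1000, 1999)),
                   strrep("N", 1000))
  expect_equal(unname(Biostrings::letterFrequency(gg, "N")[1, 1]), 1500)
})

test_that("manifest bookkeeping matches the configuration and round-trips", {
  sim <- shared_sim()
  m <- sim$manifest
  expect_equal(nrow(m), sim$config$n_genes)
  expect_equal(sum(m$state == "PAU"),
                   round(sim$config$n_genes * sim$config$paused_fraction))
  expect_equal(sum(m$state == "NP2"),
                   round(sim$config$n_genes * sim$config$np2_fraction))

  path <- tempfile(fileext = ".tsv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(m, m2)

  # genes never overlap and TSS regions keep their guard gaps
  expect_identical(
    length(GenomicRanges::reduce(sim$genes, ignore.strand = TRUE)),
    length(sim$genes))
})

test_that("planted hairpins dominate the background free-energy landscape", {
  sim <- shared_sim()
  pau <- sim$manifest[sim$manifest$state == "PAU", ]
  npa <- sim$manifest[sim$manifest$state == "NPA", ]
  chrom <- as.character(sim$genome[["chrS1"]])

  hairpin_dg <- vapply(seq_len(nrow(pau)), function(i) {
    s <- substr(chrom, pau$hairpin_start[i], pau$hairpin_end[i])
    if (pau$strand[i] == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    mfe_fold(s)$delta_g
  }, numeric(1))

  set.seed(9)
  bg_starts <- sample.int(nchar(chrom) - 30, 400)
  bg_dg <- vapply(bg_starts, function(s)
    mfe_fold(substr(chrom, s, s + 29))$delta_g, numeric(1))
  expect_lt(max(hairpin_dg), quantile(bg_dg, 0.01))

  # NPA promoters are background-like: no planted structure
  npa_dg <- vapply(seq_len(nrow(npa)), function(i) {
    span <- if (npa$strand[i] == "-") c(npa$tss[i] - 74, npa$tss[i] - 45) else
      c(npa$tss[i] + 45, npa$tss[i] + 74)
    mfe_fold(substr(chrom, span[1], span[2]))$delta_g
  }, numeric(1))
  expect_gt(min(npa_dg), max(hairpin_dg))
})

test_that("minus-strand planting appears reverse-complemented on the reference", {
  sim <- shared_sim()
  pau <- sim$manifest[sim$manifest$state == "PAU" &
                        sim$manifest$strand == "-", ]
  expect_gt(nrow(pau), 0)
  chrom <- as.character(sim$genome[["chrS1"]])
  s <- substr(chrom, pau$hairpin_start[1], pau$hairpin_end[1])
  nt <- as.character(reverseComplement(DNAString(s)))
  # non-template rendering is stem + T-loop + complement of the stem
  loop <- sim$config$hairpin_loop
  stem <- sim$config$hairpin_stem
  expect_identical(substr(nt, stem + 1, stem + loop), strrep("T", loop))
  expect_identical(substr(nt, stem + loop + 1, 2 * stem + loop),
                   as.character(reverseComplement(DNAString(
                     substr(nt, 1, stem)))))
})

test_that("simulated tracks respect the manifest by construction", {
  sim <- shared_sim()
  pau <- sim$manifest[sim$manifest$state == "PAU", ]
  # mNET argmax within each paused gene is the planted pause
  for (i in seq_len(nrow(pau))) {
    gi <- sim$genes[sim$genes$gene_id == pau$gene_id[i]]
    v <- pausefold:::.cov_get(sim$tracks$mnet, pau$chrom[i],
                              GenomicRanges::start(gi) - 200,
                              GenomicRanges::end(gi),
                              strand = pau$strand[i])
    expect_equal(GenomicRanges::start(gi) - 200 + which.max(v) - 1,
                 pau$pause_pos[i])
  }
  # TR separates the planted states under the default coverage geometry
  tr <- traveling_ratio(sim$genes, sim$tracks$chip)
  st <- sim$manifest$state[match(tr$gene_id, sim$manifest$gene_id)]
  expect_true(all(tr$tr[st == "PAU"] > 2))
  expect_true(all(tr$tr[st == "NPA"] <= 2))
})

test_that("mNET noise reproduces the generating power law within fit error", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  draws <- pausefold:::.sample_noise_values(5e5, cfg)
  tab <- table(draws)
  freq <- data.frame(coverage = as.numeric(names(tab)),
                     freq = as.numeric(tab) / length(draws))
  fit <- fit_powerlaw_null(freq)
  expect_lt(abs(fit$b - cfg$noise_b), 3 * fit$b_err + 0.05)
  expect_lt(abs(fit$a - cfg$noise_a), 3 * fit$a_err + 0.05)
})

test_that("emitted files parse back with the standard readers", {
  sim <- shared_sim()
  dir <- tempfile("simout")
  out <- simulate_dataset(sim$config, dir = dir)
  g <- read_genome(out$files[["genome"]])
  expect_identical(chrom_sizes(g), out$sizes)
  genes <- read_genes_bed(out$files[["genes"]])
  expect_identical(length(genes), length(out$genes))
  expect_identical(GenomicRanges::start(genes), GenomicRanges::start(out$genes))
  pk <- read_narrowpeak(out$files[["chip_peaks"]])
  expect_identical(length(pk), length(out$chip_peaks))
  expect_true(all(pk$peak >= 0))
  cov <- read_bedgraph(out$files[["chip"]], out$sizes)
  expect_equal(cov$data$chrS1, out$tracks$chip$data$chrS1)
  mn <- read_bedgraph(file.path(dir, c("mnet_plus.bedgraph",
                                       "mnet_minus.bedgraph")),
                      out$sizes)
  expect_equal(mn$data[["+"]]$chrS1, out$tracks$mnet$data[["+"]]$chrS1)
  unlink(dir, recursive = TRUE)
})
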