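test_that("zone classification is strand-aware with inclusive boundaries", {
  plus <- mk_annotation("chr1", 10001, 12000, seqlen = c(chr1 = 100000L))
  expect_equal(classify_zone(c(9500, 11000, 12500, 7001, 7000, 13501),
                             plus[1]),
               c("promoter", "transcribed", "downstream", "promoter",
                 "outside", "outside"))
  minus <- mk_annotation("chr1", 10001, 12000, strand = "-",
                         seqlen = c(chr1 = 100000L))
  expect_equal(classify_zone(c(12500, 11000, 9500), minus[1]),
               c("promoter", "transcribed", "downstream"))
})

test_that("metagene histogram bins offsets and conserves counts", {
  ann <- mk_annotation("chr1", 10001, 12000, seqlen = c(chr1 = 100000L))
  one <- data.frame(region_id = "r1", gene_id = "g1", zone = "promoter",
                    offset = -250L, chrom = "chr1", center = 9751L)
  h <- metagene_histogram(one, ann, bin_width = 100)
  expect_equal(nrow(h), 1L)
  expect_equal(h$anchor, "start")
  expect_equal(h$bin_start, -300L)  # offset -250 falls in [-300, -200)
  expect_equal(h$bin_end, -200L)
  expect_equal(h$count, 1L)

  expect_equal(nrow(metagene_histogram(one[0, ], ann)), 0L)

  # conservation over many random in-window assignments
  params <- simulation_params(seed = 71)
  ann2 <- simulate_genome(params)
  sim <- simulate_peaksets(ann2, params)
  sites <- sim$truth$latent_sites
  many <- data.frame(region_id = sprintf("r%03d", seq_len(nrow(sites))),
                     gene_id = sites$gene_id, zone = sites$zone,
                     offset = 0L, chrom = sites$chrom,
                     center = sites$position)
  h2 <- metagene_histogram(many, ann2)
  expect_equal(sum(h2$count), nrow(many))
  # 5' half anchors at the start, 3' half and downstream at the end
  expect_setequal(unique(h2$anchor), c("start", "end"))
})

test_that("bootstrap null reproduces window base composition", {
  # one + strand gene: window composition is 3000 / len / 1500 exactly
  ann <- mk_annotation("chr1", 10001, 12000, seqlen = c(chr1 = 100000L))
  null <- bootstrap_null(ann, "g1", n_observed = 10000, B = 1, seed = 5)
  W <- 3000 + 2000 + 1500
  for (z in c("promoter", "transcribed", "downstream")) {
    frac <- c(promoter = 3000, transcribed = 2000, downstream = 1500)[[z]] / W
    se <- sqrt(frac * (1 - frac) / 10000)
    expect_lt(abs(null[[z]] / null$total - frac), 3 * se)
  }
  expect_equal(null$total, 10000L)
})

test_that("bootstrap null handles degenerate and forced compositions", {
  ann <- mk_annotation("chr1", 10001, 12000, seqlen = c(chr1 = 100000L))
  z0 <- bootstrap_null(ann, "g1", n_observed = 0, B = 3, seed = 1)
  expect_equal(dim(z0), c(3L, 4L))
  expect_true(all(z0 == 0L))
  # 1-bp anchor, no downstream: every base of the window is promoter or the
  # single transcribed base
  tiny <- mk_annotation("chr1", 5000, 5000, seqlen = c(chr1 = 100000L))
  n1 <- bootstrap_null(tiny, "g1", n_observed = 500, B = 2, seed = 2,
                       downstream_bp = 0L)
  expect_true(all(n1$downstream == 0L))
  expect_equal(n1$promoter + n1$transcribed, c(500L, 500L))
  expect_error(bootstrap_null(ann, "nope", 10, B = 1, seed = 1), "target genes")
})

test_that("bootstrap null is deterministic in its seed", {
  params <- simulation_params(seed = 3)
  ann <- simulate_genome(params)
  targets <- ann$gene_id[1:40]
  a <- bootstrap_null(ann, targets, 100, B = 50, seed = 99)
  b <- bootstrap_null(ann, targets, 100, B = 50, seed = 99)
  expect_identical(a, b)
  c <- bootstrap_null(ann, targets, 100, B = 50, seed = 100)
  expect_false(identical(a, c))
})

test_that("empirical p-values follow the add-one rule", {
  obs <- data.frame(promoter = 80, transcribed = 10, downstream = 10,
                    total = 100)
  # observed promoter fraction above every null fraction
  null <- data.frame(promoter = rep(40, 200), transcribed = rep(40, 200),
                     downstream = rep(20, 200), total = rep(100, 200))
  res <- enrichment_test(obs, null)
  pe <- res$p_enriched[res$zone == "promoter"]
  expect_equal(pe, 1 / 201)
  expect_equal(res$p_depleted[res$zone == "promoter"], 1)
  expect_equal(res$direction[res$zone == "promoter"], "enriched")
  # all null fractions exactly equal the observed fraction
  tie <- data.frame(promoter = rep(80, 200), transcribed = rep(10, 200),
                    downstream = rep(10, 200), total = rep(100, 200))
  res_tie <- enrichment_test(obs, tie)
  expect_true(all(res_tie$p_enriched == 1))
  expect_true(all(res_tie$p_depleted == 1))
  expect_true(all(res_tie$direction == "neither"))
  expect_error(enrichment_test(obs, null[0, ]), "empty")
})

test_that("enrichment test matches an independent counting oracle", {
  params <- simulation_params(seed = 7)
  ann <- simulate_genome(params)
  targets <- ann$gene_id[1:50]
  null <- bootstrap_null(ann, targets, 120, B = 200, seed = 11)
  obs <- bootstrap_null(ann, targets, 120, B = 1, seed = 12)
  res <- enrichment_test(obs, null)
  for (z in c("promoter", "transcribed", "downstream")) {
    of <- obs[[z]] / obs$total
    ge <- 0L; le <- 0L
    for (b in seq_len(nrow(null))) {       # one-pass counting, written plainly
      nf <- null[[z]][b] / null$total[b]
      if (nf >= of) ge <- ge + 1L
      if (nf <= of) le <- le + 1L
    }
    expect_equal(res$p_enriched[res$zone == z], (ge + 1) / 201)
    expect_equal(res$p_depleted[res$zone == z], (le + 1) / 201)
  }
  # p never 0 and monotone non-increasing in the observed fraction
  expect_true(all(res$p_enriched >= 1 / 201 & res$p_depleted >= 1 / 201))
  fr <- seq(0, 1, by = 0.1)
  ps <- vapply(fr, function(f) {
    o <- data.frame(promoter = round(120 * f),
                    transcribed = 120 - round(120 * f),
                    downstream = 0, total = 120)
    enrichment_test(o, null)$p_enriched[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
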