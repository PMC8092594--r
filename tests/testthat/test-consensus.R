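test_that("FDR filtering is a strict inequality on the q-value scale", {
  p <- mk_peaks("chr1", c(100, 300, 500), c(200, 400, 600),
                qscore = c(3.5, 3.0, 2.9))
  kept <- filter_by_fdr(p, 0.001)
  expect_equal(kept$name, "p1")  # exactly -log10(0.001) = 3 is removed
  expect_length(filter_by_fdr(p[0], 0.001), 0L)
  expect_error(filter_by_fdr(p, 0), "fdr_threshold")
  expect_error(filter_by_fdr(p, 1), "fdr_threshold")
})

test_that("FDR filter agrees with the direct 10^(-q) comparison", {
  set.seed(31)
  q <- round(stats::runif(1000, 0, 6), 3)
  p <- mk_peaks("chr1", seq(1, by = 50, length.out = 1000),
                seq(30, by = 50, length.out = 1000), qscore = q)
  for (thr in c(0.001, 0.01, 0.05)) {
    expect_equal(filter_by_fdr(p, thr)$name, p$name[10^(-q) < thr])
  }
})

test_that("replicate intersection returns the common overlap with support", {
  reps <- list(r1 = mk_peaks("chr1", 101, 200),
               r2 = mk_peaks("chr1", 151, 250),
               r3 = mk_peaks("chr1", 121, 220))
  cons <- intersect_replicates(reps)
  expect_equal(length(cons), 1L)
  expect_equal(start(cons), 151L)
  expect_equal(end(cons), 200L)
  expect_equal(cons$support, "r1:p1,r2:p1,r3:p1")
  expect_equal(cons$center, (151L + 200L) %/% 2L)

  # a replicate with no overlapping peak kills the region
  reps$r2 <- mk_peaks("chr1", 501, 600)
  expect_length(intersect_replicates(reps), 0L)
})

test_that("intersection equals the per-base AND oracle on random instances", {
  seqlens <- c(c1 = 50000L, c2 = 50000L)
  set.seed(101)
  for (i in 1:50) {
    reps <- lapply(1:3, function(r) {
      n <- sample(20:60, 1)
      s <- sample.int(49000L, n, replace = TRUE)
      mk_peaks(sample(names(seqlens), n, TRUE), s, s + sample.int(800L, n),
               name = sprintf("r%dp%03d", r, seq_len(n)))
    })
    got <- intersect_replicates(reps)
    want <- oracle_consensus(reps, seqlens)
    expect_equal(as.character(seqnames(got)), as.character(seqnames(want)))
    expect_equal(start(got), start(want))
    expect_equal(end(got), end(want))
  }
})

test_that("intersection is order-invariant, monotone and identity at k=1", {
  set.seed(55)
  reps <- lapply(1:4, function(r) {
    s <- sample.int(20000L, 40, replace = TRUE)
    mk_peaks("chr1", s, s + sample.int(500L, 40),
             name = sprintf("r%dp%03d", r, 1:40))
  })
  base <- intersect_replicates(reps[1:3])
  perm <- intersect_replicates(reps[c(3, 1, 2)])
  expect_equal(granges(base), granges(perm), ignore_attr = TRUE)
  # adding a replicate only shrinks coverage
  more <- intersect_replicates(reps)
  expect_true(all(overlapsAny(more, base)))
  expect_lte(sum(width(more)), sum(width(base)))
  expect_true(all(countOverlaps(more, base) >= 1L))
  # k = 1: merged intervals of the single replicate
  one <- intersect_replicates(reps[1])
  expect_equal(granges(one), GenomicRanges::reduce(granges(reps[[1]])),
               ignore_attr = TRUE)
})

test_that("control exclusion removes 1-bp overlaps and is idempotent", {
  regions <- intersect_replicates(list(r1 = mk_peaks("chr1", 151, 200)))
  # control peak overlapping the last base, passing the FDR filter
  ctl <- list(mk_peaks("chr1", 200, 300, qscore = 5))
  expect_length(exclude_control(regions, ctl, 0.001), 0L)
  # a sub-threshold control peak does not exclude
  ctl_weak <- list(mk_peaks("chr1", 200, 300, qscore = 2))
  expect_equal(length(exclude_control(regions, ctl_weak, 0.001)), 1L)
  # no control peaks: unchanged; second application: no-op
  expect_identical(exclude_control(regions, list(), 0.001), regions)
  once <- exclude_control(regions, ctl_weak, 0.001)
  expect_identical(exclude_control(once, ctl_weak, 0.001), once)
})

test_that("consensus then control exclusion matches a per-base oracle", {
  seqlens <- c(c1 = 30000L)
  set.seed(77)
  for (i in 1:60) {
    reps <- lapply(1:3, function(r) {
      s <- sample.int(29000L, 30, replace = TRUE)
      mk_peaks("c1", s, s + sample.int(400L, 30),
               name = sprintf("r%dp%03d", r, 1:30))
    })
    ctl_s <- sample.int(29000L, 10, replace = TRUE)
    ctl <- list(mk_peaks("c1", ctl_s, ctl_s + sample.int(400L, 10),
                         qscore = sample(c(2, 5), 10, TRUE)))
    got <- exclude_control(intersect_replicates(reps), ctl, 0.001)
    want <- oracle_consensus(reps, seqlens)
    strong <- ctl[[1]][ctl[[1]]$qValue > 3]
    want <- want[!overlapsAny(want, strong)]
    expect_equal(start(got), start(want))
    expect_equal(end(got), end(want))
  }
})

test_that("zero-noise simulation yields one consensus region per latent site", {
  params <- simulation_params(seed = 13, n_true_targets = 25, jitter_sd = 0,
                              n_background_peaks_per_rep = 0,
                              n_artifact_sites = 0,
                              ref_set_size = 0, ref_overlap = 0)
  ann <- simulate_genome(params)
  sim <- simulate_peaksets(ann, params)
  cons <- intersect_replicates(lapply(sim$treatment, filter_by_fdr))
  expect_equal(length(cons), 25L)
  sites <- GRanges(sim$truth$latent_sites$chrom,
                   IRanges(sim$truth$latent_sites$position,
                           sim$truth$latent_sites$position))
  expect_equal(unname(countOverlaps(cons, sites)), rep(1L, 25))
})

test_that("consensus regions survive a BED round-trip", {
  reps <- list(r1 = mk_peaks("chr1", c(101, 1001), c(300, 1400)),
               r2 = mk_peaks("chr1", c(151, 901), c(350, 1200)))
  cons <- intersect_replicates(reps)
  f <- withr::local_tempfile(fileext = ".bed")
  write_consensus_bed(cons, f)
  back <- read_consensus_bed(f)
  expect_equal(start(back), start(cons))
  expect_equal(end(back), end(cons))
  expect_equal(back$region_id, cons$region_id)
  expect_equal(back$support, cons$support)
  expect_equal(back$center, cons$center)
})
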