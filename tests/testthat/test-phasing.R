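test_that("EM on fully homozygous samples returns observed proportions", {
  gm <- toy_genotypes(list(c("A|A|A", "A|A|A"),
                           c("A|A|A", "A|A|A"),
                           c("G|G|G", "G|G|G"),
                           c("A|A|A", "A|A|A")))
  pool <- em_frequencies(gm, seed = 1)
  expect_equal(sort(names(pool$freq)), c("A|A|A", "G|G|G"))
  expect_equal(unname(pool$freq["A|A|A"]), 0.75, tolerance = 1e-8)
  expect_true(pool$converged)
})

test_that("EM matches exhaustive likelihood maximization on the 2-site toy", {
  # 4 samples AB/AB double-homozygous, 2 double-heterozygous
  gm <- toy_genotypes(list(c("A|B", "A|B"), c("A|B", "A|B"),
                           c("A|B", "A|B"), c("A|B", "A|B"),
                           c("A|B", "a|b"), c("A|B", "a|b")),
                      alleles_per_site = list(c("A", "a"), c("B", "b")))
  pool <- em_frequencies(gm, seed = 1, prune_floor = 1e-9)
  # exhaustive grid over the 4-haplotype simplex (independent oracle)
  haps <- c("A|B", "A|b", "a|B", "a|b")
  ll_of <- function(f) {
    names(f) <- haps
    4 * 2 * log(f["A|B"]) +
      2 * log(2 * f["A|B"] * f["a|b"] + 2 * f["A|b"] * f["a|B"])
  }
  step <- 0.02
  best <- -Inf
  for (x in seq(0, 1, step)) for (y in seq(0, 1 - x, step))
    for (z in seq(0, 1 - x - y, step)) {
      v <- ll_of(c(x, y, z, 1 - x - y - z))
      if (is.finite(v) && v > best) best <- v
    }
  expect_gte(pool$ll, best - 1e-6)
  # the analytic optimum puts 5/6 on A|B and 1/6 on a|b
  expect_equal(unname(pool$freq["A|B"]), 5 / 6, tolerance = 1e-3)
  expect_equal(unname(pool$freq["a|b"]), 1 / 6, tolerance = 1e-3)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  ref <- ref_cache()
  haps <- ref$haplotypes$utr3
  truth <- sample_diplotypes(haps, haps$global_freq, 60, seed = 21)
  ad <- simulate_depths(truth, simulation_config(mean_depth = 6,
                                                 error_rate = 0.01),
                        seed = 22)
  gm <- refine_genotypes(ad)$genotypes
  pool <- em_frequencies(gm, sites = 1:6, seed = 3)
  expect_true(all(diff(pool$ll_trace) > -1e-9))
  expect_equal(sum(pool$freq), 1, tolerance = 1e-8)
})

test_that("random restarts reach the same optimum on a small panel", {
  gm <- toy_genotypes(list(c("A|B", "A|B"), c("A|B", "A|B"),
                           c("A|B", "a|b"), c("A|B", "a|b"),
                           c("a|b", "a|b")),
                      alleles_per_site = list(c("A", "a"), c("B", "b")))
  p1 <- em_frequencies(gm, restarts = 1, seed = 5)
  p2 <- em_frequencies(gm, restarts = 5, seed = 17)
  common <- intersect(names(p1$freq), names(p2$freq))
  expect_equal(p1$freq[common], p2$freq[common], tolerance = 1e-4)
  expect_equal(p1$ll, p2$ll, tolerance = 1e-6)
})

test_that("phasing a het-free, gap-free matrix is the identity", {
  gm <- toy_genotypes(list(c("A|B|C", "A|B|C"),
                           c("a|B|C", "a|B|C"),
                           c("A|b|C", "A|b|C")))
  ph <- partition_ligation_phase(gm, window_size = 2, seed = 1)
  expect_equal(hap_keys_of(ph$hap1), c("A|B|C", "a|B|C", "A|b|C"))
  expect_equal(ph$hap1, ph$hap2)
  expect_true(all(ph$posterior == 1))
})

test_that("single-window phasing equals windowed ligation on a small panel", {
  ref <- ref_cache()
  haps <- ref$haplotypes$utr3
  truth <- sample_diplotypes(haps, haps$global_freq, 80, seed = 31)
  ad <- simulate_depths(truth, simulation_config(mean_depth = 25,
                                                 error_rate = 0,
                                                 mismap_rate = 0),
                        seed = 32)
  gm <- refine_genotypes(ad)$genotypes
  one <- partition_ligation_phase(gm, window_size = 9, seed = 2)
  two <- partition_ligation_phase(gm, window_size = 5, seed = 2)
  common <- intersect(names(one$pool$freq), names(two$pool$freq))
  expect_gt(sum(one$pool$freq[common]), 0.99)
  expect_equal(one$pool$freq[common], two$pool$freq[common],
               tolerance = 1e-3)
  expect_equal(hap_keys_of(one$hap1), hap_keys_of(two$hap1))
})

test_that("phasing recovers the generating frequencies and phase", {
  ref <- ref_cache()
  haps <- ref$haplotypes$utr3
  truth <- sample_diplotypes(haps, haps$global_freq, 250, seed = 41)
  ad <- simulate_depths(truth, simulation_config(mean_depth = 30,
                                                 error_rate = 0,
                                                 mismap_rate = 0),
                        seed = 42)
  gm <- refine_genotypes(ad)$genotypes
  ph <- partition_ligation_phase(gm, window_size = 5, seed = 4)
  ev <- evaluate_calls(truth, ph)
  expect_lt(ev$switch_error, 0.05)
  # estimated frequencies within 3 binomial SE of the truth table
  est <- ph$pool$freq
  truth_keys <- apply(truth$pool$alleles, 1, paste, collapse = "|")
  tr <- tapply(truth$pool$freq, truth_keys, sum)
  n2 <- 2 * length(truth$samples)
  for (k in names(tr)[tr > 0.02]) {
    se <- sqrt(tr[[k]] * (1 - tr[[k]]) / n2)
    e <- if (k %in% names(est)) est[[k]] else 0
    expect_lt(abs(e - tr[[k]]), 3 * se + 0.01, label = k)
  }
})

test_that("posteriors summarize correctly and rise with coverage", {
  expect_equal(phasing_summary(c(0.8, 1.0))$mean_posterior, 0.9)
  expect_equal(phasing_summary(c(0.8, 1.0))$frac_above_0.9, 0.5)
  expect_error(phasing_summary(numeric(0)), "no assignments")

  ref <- ref_cache()
  haps <- ref$haplotypes$utr3
  truth <- sample_diplotypes(haps, haps$global_freq, 60, seed = 51)
  mp <- vapply(c(3, 30), function(lam) {
    ad <- simulate_depths(truth, simulation_config(mean_depth = lam,
                                                   error_rate = 0,
                                                   mismap_rate = 0),
                          seed = 52)
    gm <- refine_genotypes(ad)$genotypes
    ph <- partition_ligation_phase(gm, window_size = 5, seed = 5)
    phasing_summary(ph)$mean_posterior
  }, numeric(1))
  expect_gt(mp[2], mp[1])
})

test_that("region extraction projects and aggregates frequencies", {
  pool <- structure(list(freq = c("A|B|C" = 0.5, "A|B|c" = 0.3,
                                  "a|B|C" = 0.2),
                         sites = c(10L, 20L, 30L)),
                    class = "hlag_pool")
  # identity projection
  full <- extract_region(pool, c(10L, 20L, 30L))
  expect_equal(sort(names(full$freq)), sort(names(pool$freq)))
  # haplotypes differing only outside the kept sites merge
  sub <- extract_region(pool, c(10L, 20L))
  expect_equal(unname(sub$freq["A|B"]), 0.8)
  expect_equal(unname(sub$freq["a|B"]), 0.2)
  expect_error(extract_region(pool, c(10L, 99L)), "unknown")
})
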