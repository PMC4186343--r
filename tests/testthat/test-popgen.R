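test_that("haplotype diversity follows the unbiased closed form", {
  expect_equal(haplotype_diversity(1, 100), 0)
  expect_equal(haplotype_diversity(c(0.5, 0.5), 1e6), 0.5,
               tolerance = 1e-5)
  ref <- ref_cache()
  expect_equal(haplotype_diversity(ref$haplotypes$utr3$global_freq, 2152),
               0.8223, tolerance = 0.001)
  expect_equal(haplotype_diversity(ref$extended$global_freq, 2152),
               0.9068, tolerance = 0.001)
  expect_error(haplotype_diversity(c(0.9, 0.3), 100), "invalid")
  expect_error(haplotype_diversity(0.5, 1), "chromosomes")
})

test_that("gene diversity averages per-site heterozygosity", {
  expect_equal(gene_diversity(list(c(1, 0), c(1)), 1000)$mean, 0)
  big <- gene_diversity(list(c(0.5, 0.5)), 1e9)
  expect_equal(big$mean, 0.5, tolerance = 1e-6)
  # triallelic promoter site -725 with its printed frequencies
  h <- gene_diversity(list(c(0.8550, 0.0953, 0.0497)), 2152)$mean
  expect_equal(h, 0.2575425, tolerance = 1e-5)
})

test_that("nucleotide diversity matches the pairwise oracle to 1e-10", {
  set.seed(99)
  for (rep in 1:5) {
    nh <- sample(3:6, 1)
    np <- sample(3:7, 1)
    alleles <- matrix(sample(c("A", "C", "G", "T"), nh * np,
                             replace = TRUE), nh, np)
    f <- stats::rgamma(nh, 1)
    f <- f / sum(f)
    w <- sample(c(1, 1, 1, 14), np, replace = TRUE)
    n2 <- 500
    site_freqs <- lapply(seq_len(np), function(j)
      as.numeric(tapply(f, alleles[, j], sum)))
    k_freq <- nucleotide_diversity(site_freqs, w, n2)$k
    k_pair <- pairwise_k_oracle(alleles, f, w, n2)
    expect_equal(k_freq, k_pair, tolerance = 1e-10)
  }
  # two equifrequent haplotypes, one unit-weight difference
  k <- nucleotide_diversity(list(c(0.5, 0.5)), 1, 1e9)$k
  expect_equal(k, 0.5, tolerance = 1e-6)
})

test_that("the 3'UTR weighting choices reproduce the published contrast", {
  ref <- ref_cache()
  s <- ref$sites$utr3
  fr <- lapply(seq_len(nrow(s)), function(i) c(s$ref_freq[i],
                                               s$alt_freq[i]))
  w14 <- ifelse(s$gene_pos == 2960, 14, 1)
  k14 <- nucleotide_diversity(fr, w14, 2152, L = 286)
  expect_equal(k14$k, 8.19, tolerance = 0.002)
  expect_equal(k14$pi_percent, 2.864, tolerance = 0.002)
  k1 <- nucleotide_diversity(fr, rep(1, nrow(s)), 2152, L = 286)
  expect_equal(k1$k, 2.80, tolerance = 0.002)
})

test_that("private haplotypes equal a brute-force scan", {
  set.seed(7)
  counts <- matrix(rpois(60, 1.2), 15, 4,
                   dimnames = list(NULL, paste0("P", 1:4)))
  got <- private_haplotypes(counts)
  want <- integer(4)
  for (h in seq_len(nrow(counts))) {
    pres <- which(counts[h, ] > 0)
    if (length(pres) == 1) want[pres] <- want[pres] + 1L
  }
  expect_equal(unname(got), want)
  # presence in two populations counts for neither
  m <- matrix(c(3, 1, 0, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(private_haplotypes(m)), c(1L, 0L))
  # grouping pools columns first
  g <- private_haplotypes(counts, grouping = c(P1 = "x", P2 = "x",
                                               P3 = "y", P4 = "y"))
  expect_equal(names(g), c("x", "y"))
  expect_error(private_haplotypes(counts[, 1, drop = FALSE]), "two")
})

test_that("the HWE chain agrees with full enumeration on biallelic data", {
  cases <- list(c(10, 21, 5), c(3, 5, 40), c(8, 24, 4))
  for (cs in cases) {
    g <- matrix(0, 2, 2)
    g[1, 1] <- cs[1]; g[2, 1] <- cs[2]; g[2, 2] <- cs[3]
    r <- hwe_exact_test(g, steps = 60000, dememorization = 6000,
                        seed = 3)
    want <- hwe_enum_oracle(cs[1], cs[2], cs[3])
    expect_lt(abs(r$p - want), 3 * r$se + 0.01,
              label = paste(cs, collapse = "/"))
  }
  # the all-heterozygote extreme is essentially impossible under HWE
  g <- matrix(0, 2, 2); g[2, 1] <- 50
  expect_lt(hwe_exact_test(g, steps = 60000, dememorization = 6000,
                           seed = 3)$p, 0.001)
  # HWE-proportioned counts sit at the mode
  g2 <- matrix(0, 2, 2); g2[1, 1] <- 25; g2[2, 1] <- 50; g2[2, 2] <- 25
  expect_gt(hwe_exact_test(g2, steps = 30000, dememorization = 3000,
                           seed = 1)$p, 0.5)
  # monomorphic convention
  g3 <- matrix(0, 2, 2); g3[1, 1] <- 30
  r3 <- hwe_exact_test(g3)
  expect_equal(r3$p, 1)
  expect_true(r3$flagged)
})

test_that("pairwise theta behaves at the extremes and matches hand sums", {
  fixed <- matrix(c(50, 0, 0, 50), 2, 2,
                  dimnames = list(NULL, c("P1", "P2")))
  f <- pairwise_fst(fixed, permutations = 99, seed = 1)
  expect_equal(f$theta["P1", "P2"], 1)
  expect_lt(f$p["P1", "P2"], 0.05)

  same <- matrix(c(30, 20, 30, 20), 2, 2,
                 dimnames = list(NULL, c("P1", "P2")))
  f2 <- pairwise_fst(same, permutations = 199, seed = 1)
  expect_lt(abs(f2$theta["P1", "P2"]), 0.05)
  expect_gt(f2$p["P1", "P2"], 0.5)

  # hand-computed decomposition for a 3-haplotype toy
  c1 <- c(30, 20, 10); c2 <- c(15, 25, 10)
  n1 <- 60; n2 <- 50; N <- 110
  m <- c1 + c2
  ssd_t <- (N^2 - sum(m^2)) / (2 * N)
  ssd_w <- (n1^2 - sum(c1^2)) / (2 * n1) + (n2^2 - sum(c2^2)) / (2 * n2)
  ms_a <- ssd_t - ssd_w
  ms_w <- ssd_w / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  sig_a <- (ms_a - ms_w) / nc
  want <- sig_a / (sig_a + ms_w)
  toy <- cbind(P1 = c1, P2 = c2)
  f3 <- pairwise_fst(toy, permutations = 0, seed = 1)
  expect_equal(f3$theta["P1", "P2"], want, tolerance = 1e-12)

  expect_error(pairwise_fst(fixed[, 1, drop = FALSE]), "two")
})

test_that("Reynolds distance is the clamped log-linearization of theta", {
  fixed <- matrix(c(50, 0, 0, 50), 2, 2,
                  dimnames = list(NULL, c("P1", "P2")))
  d <- reynolds_distance(fixed)$d
  expect_equal(d["P1", "P2"], -log(1e-12), tolerance = 1e-6)
  same <- matrix(c(30, 20, 30, 20), 2, 2,
                 dimnames = list(NULL, c("P1", "P2")))
  expect_equal(reynolds_distance(same)$d["P1", "P2"], 0)  # theta < 0

  set.seed(11)
  counts <- matrix(rpois(40, 4) + 1, 10, 4,
                   dimnames = list(NULL, paste0("P", 1:4)))
  d2 <- reynolds_distance(counts)$d
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  expect_true(all(d2 >= 0))
})

test_that("the differentiation exact test matches Fisher on 2x2 tables", {
  tabs <- list(matrix(c(12, 3, 5, 10), 2, 2),
               matrix(c(4, 1, 2, 8), 2, 2),
               matrix(c(20, 20, 20, 20), 2, 2))
  for (tb in tabs) {
    got <- exact_differentiation_test(tb)
    expect_equal(got$p, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
  # identical columns: no evidence of differentiation
  eq <- matrix(c(30, 10, 5, 30, 10, 5), 3, 2)
  expect_gt(exact_differentiation_test(eq, B = 4000, seed = 1)$p, 0.5)
  # disjoint supports: p near zero
  dis <- matrix(c(30, 0, 5, 0, 28, 7), 3, 2)
  expect_lt(exact_differentiation_test(dis, B = 4000, seed = 1)$p,
            0.001)
  # r x k Monte-Carlo agrees with enumeration via fisher.test on a
  # small 3 x 2 table
  small <- matrix(c(5, 3, 2, 1, 4, 6), 3, 2)
  got <- exact_differentiation_test(small, B = 20000, seed = 2)
  want <- stats::fisher.test(small)$p.value
  expect_lt(abs(got$p - want), 3 * got$se + 0.005)
  # degenerate margins
  deg <- matrix(c(10, 0, 0, 0), 2, 2)
  expect_true(exact_differentiation_test(deg)$flagged)
})

test_that("AMOVA components match a first-principles decomposition", {
  counts <- matrix(c(40, 10, 35, 15, 5, 45, 10, 40), 2, 4,
                   dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  grouping <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  am <- amova(counts, grouping, permutations = 0)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)

  hap <- rep(rep(1:2, 4), as.vector(counts))
  pop <- rep(colnames(counts)[rep(1:4, each = 2)], as.vector(counts))
  grp <- grouping[pop]
  ss <- amova_ss_oracle(hap, pop, grp)
  expect_equal(unname(am$ssd["WP"]), ss$ssd_wp, tolerance = 1e-9)
  expect_equal(unname(am$ssd["AP"]), ss$ssd_ap, tolerance = 1e-9)
  expect_equal(unname(am$ssd["AG"]), ss$ssd_ag, tolerance = 1e-9)

  # identical populations: everything within
  flat <- matrix(rep(c(25, 25), 4), 2, 4,
                 dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  # (components other than within-populations go to ~0; unbiased
  # estimators may dip slightly negative on perfectly flat designs)
  am0 <- amova(flat, grouping, permutations = 0)
  expect_gt(unname(am0$percent["within_pops"]), 98)
  expect_lt(abs(unname(am0$percent["among_groups"])), 3)
  expect_equal(sum(am0$percent), 100, tolerance = 1e-9)

  # groups fixed for different haplotypes: all among groups
  split <- matrix(c(50, 0, 50, 0, 0, 50, 0, 50), 2, 4,
                  dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  am1 <- amova(split, grouping, permutations = 0)
  expect_gt(unname(am1$percent["among_groups"]), 99)
  expect_equal(unname(am1$phi["F_CT"]), 1, tolerance = 0.01)

  # two-population two-level AMOVA equals pairwise theta
  two <- counts[, c("A1", "B1")]
  am2 <- amova(two, c(A1 = "g", B1 = "g"), permutations = 0)
  th <- pairwise_fst(two, permutations = 0)$theta["A1", "B1"]
  expect_equal(unname(am2$phi["F_ST"]), th, tolerance = 1e-12)

  # permutation p-values are seed-stable and detect the split design
  amp <- amova(split, grouping, permutations = 100, seed = 9)
  amp2 <- amova(split, grouping, permutations = 100, seed = 9)
  expect_identical(amp$p, amp2$p)
  expect_lt(amp$p[["F_ST"]], 0.05)
})

test_that("Bonferroni thresholds mirror the published correction", {
  b <- bonferroni_threshold(0.05, 91)
  expect_equal(b$raw, 0.05 / 91)
  expect_equal(b$reported, 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1)$raw, 0.05)
  expect_equal(choose(14, 2), 91)
})

test_that("classical MDS recovers planted planar configurations", {
  set.seed(13)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(pts))
  fit <- classical_mds(d, 2)
  expect_lt(procrustes_resid(fit$points, pts), 1e-8)
  expect_equal(colMeans(fit$points), c(0, 0), tolerance = 1e-10)

  # two points at distance d sit at +-d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  fit2 <- classical_mds(d2, 1)
  expect_equal(sort(fit2$points[, 1]), c(-1.5, 1.5))

  z <- matrix(0, 4, 4)
  fitz <- suppressWarnings(classical_mds(z, 2))
  expect_true(all(abs(fitz$points) < 1e-10))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(bad), "symmetric")
})
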