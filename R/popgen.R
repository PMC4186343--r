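#' Unbiased haplotype diversity
#'
#' Nei's unbiased expected heterozygosity applied to haplotype
#' frequencies: `H = (2n/(2n-1)) (1 - sum p_i^2)`.  Residual mass from
#' haplotypes absent from `p` contributes its own sum of squares only if
#' passed via `residual_sq`; otherwise it is treated as negligible (many
#' rare distinct haplotypes) and flagged with a message when `p` sums
#' clearly below 1.
#'
#' @param p Numeric vector of haplotype frequencies (sum <= 1 + 1e-9).
#' @param n2 Number of chromosomes (2n), at least 2.
#' @param residual_sq Optional sum of squared frequencies of unlisted
#'   haplotypes.
#' @param quiet Suppress the residual-mass message.
#' @return Scalar diversity in [0, 1].
#' @export
#' @examples
#' haplotype_diversity(c(0.5, 0.5), 100)
haplotype_diversity <- function(p, n2, residual_sq = NULL, quiet = TRUE) {
  if (any(p < 0) || sum(p) > 1 + 1e-9)
    stop("invalid frequencies")
  if (n2 < 2) stop("need at least two chromosomes")
  sq <- sum(p^2)
  if (!is.null(residual_sq)) sq <- sq + residual_sq
  else if (sum(p) < 1 - 1e-3 && !quiet)
    message("residual mass ", format(1 - sum(p)),
            " treated as negligible")
  (n2 / (n2 - 1)) * (1 - sq)
}

#' Gene diversity: average unbiased heterozygosity across sites
#'
#' @param site_freqs List with one numeric vector of allele frequencies
#'   per variation site.
#' @param n2 Number of chromosomes (2n).
#' @return A list: `per_site` vector, `mean` and `sd` across sites.
#' @export
gene_diversity <- function(site_freqs, n2) {
  if (!length(site_freqs)) stop("no sites")
  h <- vapply(site_freqs, function(p) {
    if (any(p < 0) || sum(p) > 1 + 1e-6) stop("invalid site frequencies")
    (n2 / (n2 - 1)) * (1 - sum(p^2))
  }, numeric(1))
  list(per_site = h, mean = mean(h),
       sd = if (length(h) > 1) stats::sd(h) else NA_real_)
}

#' Nucleotide diversity from per-site frequencies
#'
#' Mean number of weighted pairwise differences between two randomly
#' drawn haplotypes, in the unbiased frequency form
#' `k = (2n/(2n-1)) sum_s w_s (1 - sum_a p_{s,a}^2)`, and the
#' per-nucleotide percentage `pi = 100 k / L`.  Site weights express how
#' many nucleotide differences a mismatch at the site represents: 1 for
#' SNVs, 14 for the 14-bp insertion/deletion.  The frequency form equals
#' the frequency-weighted pairwise Hamming average exactly (linearity
#' over sites), which the test suite checks against a brute-force pairwise
#' oracle.
#'
#' @param site_freqs List of per-site allele frequency vectors, or an
#'   `hlag_pool` whose per-site frequencies are derived from the
#'   haplotype frequencies.
#' @param weights Numeric vector of per-site weights (>= 1), recycled
#'   from 1.
#' @param n2 Number of chromosomes (2n).
#' @param L Region length in bp used for the percentage (e.g. 286 for
#'   the 3'UTR span 2942..3227).
#' @return A list with `k` (mean pairwise differences) and `pi_percent`.
#' @export
nucleotide_diversity <- function(site_freqs, weights = NULL, n2,
                                 L = NULL) {
  if (inherits(site_freqs, "hlag_pool")) {
    pool <- site_freqs
    mats <- hap_unkey(names(pool$freq))
    site_freqs <- lapply(seq_len(ncol(mats)), function(j)
      as.numeric(tapply(pool$freq, mats[, j], sum)))
  }
  ns <- length(site_freqs)
  if (is.null(weights)) weights <- rep(1, ns)
  if (length(weights) != ns) stop("one weight per site required")
  if (any(weights < 1)) stop("weights must be >= 1")
  het <- vapply(site_freqs, function(p) 1 - sum(p^2), numeric(1))
  k <- (n2 / (n2 - 1)) * sum(weights * het)
  list(k = k, pi_percent = if (is.null(L)) NA_real_ else 100 * k / L)
}

#' Count private haplotypes per population (or group)
#'
#' A haplotype is private when observed in exactly one population (or,
#' under a grouping, exactly one group).
#'
#' @param counts Integer matrix: haplotypes x populations.
#' @param grouping Optional named vector population -> group.
#' @return Named integer vector of private-haplotype counts.
#' @export
private_haplotypes <- function(counts, grouping = NULL) {
  if (ncol(counts) < 2) stop("need at least two populations")
  if (!is.null(grouping)) {
    groups <- unique(grouping[colnames(counts)])
    counts <- vapply(groups, function(g)
      rowSums(counts[, grouping[colnames(counts)] == g, drop = FALSE]),
      numeric(nrow(counts)))
    colnames(counts) <- groups
  }
  present <- counts > 0
  npops <- rowSums(present)
  out <- integer(ncol(counts))
  names(out) <- colnames(counts)
  for (j in seq_len(ncol(counts)))
    out[j] <- sum(present[, j] & npops == 1L)
  out
}

# log conditional probability of a genotype (diplotype) count matrix
# given its allele counts, up to terms constant over the chain
hwe_log_prob <- function(g) {
  het <- sum(g[lower.tri(g)])
  het * log(2) - sum(lgamma(g + 1)[lower.tri(g, diag = TRUE)])
}

#' Guo--Thompson exact test of Hardy--Weinberg equilibrium
#'
#' Markov-chain exact test for multi-allelic loci (haplotypes treated as
#' alleles of a single locus).  The chain walks genotype configurations
#' with fixed allele counts via allele swaps between two random
#' individuals, with Metropolis acceptance under the conditional
#' distribution; the p-value is the fraction of visited states whose
#' conditional probability does not exceed the observed one.
#'
#' @param g Square genotype count matrix (allele x allele); upper and
#'   lower triangles are combined, so either a lower-triangular or a
#'   symmetric heterozygote layout is accepted.
#' @param steps Chain length after dememorization.
#' @param dememorization Burn-in steps.
#' @param seed Integer seed.
#' @return A list: `p`, `se` (batch-means Monte-Carlo standard error),
#'   `flagged` (TRUE for the monomorphic convention p = 1).
#' @export
hwe_exact_test <- function(g, steps = 100000L, dememorization = 10000L,
                           seed = 1L) {
  g <- as.matrix(g)
  stopifnot(nrow(g) == ncol(g))
  g <- g + t(g)
  diag(g) <- diag(g) / 2
  g[upper.tri(g)] <- 0
  if (any(g < 0) || any(g != round(g))) stop("invalid genotype counts")
  allele_counts <- rowSums(g) + colSums(g)  # diagonal counted twice
  if (sum(allele_counts > 0) < 2)
    return(list(p = 1, se = 0, flagged = TRUE))

  set.seed(seed)
  lp_obs <- hwe_log_prob(g)
  lp <- lp_obs
  cells <- which(lower.tri(g, diag = TRUE), arr.ind = TRUE)
  ncell <- nrow(cells)
  is_het <- cells[, 1] != cells[, 2]
  ind <- numeric(steps)
  cur <- g
  log2c <- log(2)
  for (t in seq_len(dememorization + steps)) {
    # propose a switch between two genotype cells picked uniformly
    # (same cell allowed: two heterozygotes of one class can become two
    # homozygotes); infeasible picks are rejected, which together with
    # the heterozygote proposal correction below keeps detailed balance
    pick <- sample.int(ncell, 2L, replace = TRUE)
    a <- cells[pick[1], ]
    b <- cells[pick[2], ]
    feasible <- if (pick[1] == pick[2]) cur[a[1], a[2]] >= 2 else
      cur[a[1], a[2]] >= 1 && cur[b[1], b[2]] >= 1
    if (feasible) {
      # each source genotype gives away one of its alleles
      give_a <- if (stats::runif(1) < 0.5) a[1] else a[2]
      keep_a <- if (give_a == a[1]) a[2] else a[1]
      give_b <- if (stats::runif(1) < 0.5) b[1] else b[2]
      keep_b <- if (give_b == b[1]) b[2] else b[1]
      new_a <- sort(c(keep_a, give_b), decreasing = TRUE)
      new_b <- sort(c(keep_b, give_a), decreasing = TRUE)
      prop <- cur
      prop[a[1], a[2]] <- prop[a[1], a[2]] - 1
      prop[b[1], b[2]] <- prop[b[1], b[2]] - 1
      prop[new_a[1], new_a[2]] <- prop[new_a[1], new_a[2]] + 1
      prop[new_b[1], new_b[2]] <- prop[new_b[1], new_b[2]] + 1
      if (all(prop >= 0)) {
        # Hastings factor: 1/2 per heterozygous source (allele choice),
        # mirrored for the reverse move; the 2^H terms of the target
        # cancel against it, leaving the factorial ratio plus the
        # explicit correction below
        h_fwd <- is_het[pick[1]] + is_het[pick[2]]
        h_rev <- (new_a[1] != new_a[2]) + (new_b[1] != new_b[2])
        lp_new <- hwe_log_prob(prop)
        log_acc <- (lp_new - lp) + (h_fwd - h_rev) * log2c
        if (log(stats::runif(1)) < log_acc) {
          cur <- prop
          lp <- lp_new
        }
      }
    }
    if (t > dememorization)
      ind[t - dememorization] <- (lp <= lp_obs + 1e-12)
  }
  p <- mean(ind)
  nb <- 100L
  bm <- colMeans(matrix(ind[seq_len(steps %/% nb * nb)], ncol = nb))
  se <- stats::sd(bm) / sqrt(nb)
  list(p = p, se = se, flagged = FALSE)
}

# haploid two-level variance decomposition on haplotype identity
# (identity distance: 0 same haplotype, 1 otherwise)
theta_two_pop <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("population with no chromosomes")
  m <- c1 + c2
  ssd_t <- (N^2 - sum(m^2)) / (2 * N)
  ssd_w <- (n1^2 - sum(c1^2)) / (2 * n1) + (n2^2 - sum(c2^2)) / (2 * n2)
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a / 1
  ms_w <- ssd_w / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  sig_a <- (ms_a - ms_w) / nc
  denom <- sig_a + ms_w
  if (denom <= 0) return(0)
  sig_a / denom
}

#' Pairwise FST between populations from haplotype counts
#'
#' Haplotypes are treated as alleles of one locus; for each population
#' pair, theta is the among-population fraction of the haploid
#' variance decomposition on identity distances (the two-population
#' special case of the hierarchical molecular-variance analysis), and the
#' p-value is the proportion of chromosome-label permutations with a
#' theta at least as large as observed.  Slightly negative estimates are
#' possible and retained.
#'
#' @param counts Integer matrix: haplotypes x populations.
#' @param permutations Number of permutations per pair.
#' @param seed Integer seed.
#' @return A list of class `hlag_dist`: `metric = "FST"`, `theta`
#'   (symmetric matrix, zero diagonal), `p` (permutation p-values,
#'   NA diagonal), `permutations`.
#' @export
pairwise_fst <- function(counts, permutations = 1000L, seed = 1L) {
  npop <- ncol(counts)
  if (npop < 2) stop("need at least two populations")
  if (any(colSums(counts) < 2)) stop("population with fewer than 2 chromosomes")
  set.seed(seed)
  theta <- matrix(0, npop, npop,
                  dimnames = list(colnames(counts), colnames(counts)))
  pmat <- matrix(NA_real_, npop, npop, dimnames = dimnames(theta))
  for (i in seq_len(npop - 1)) {
    for (j in (i + 1):npop) {
      c1 <- counts[, i]; c2 <- counts[, j]
      obs <- theta_two_pop(c1, c2)
      theta[i, j] <- theta[j, i] <- obs
      n1 <- sum(c1)
      labels <- c(rep(seq_along(c1), c1), rep(seq_along(c2), c2))
      hit <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(labels)
        p1 <- tabulate(perm[seq_len(n1)], nbins = nrow(counts))
        p2 <- tabulate(perm[-seq_len(n1)], nbins = nrow(counts))
        if (theta_two_pop(p1, p2) >= obs - 1e-12) hit <- hit + 1L
      }
      pmat[i, j] <- pmat[j, i] <- hit / permutations
    }
  }
  structure(list(metric = "FST", theta = theta, p = pmat,
                 permutations = permutations),
            class = "hlag_dist")
}

#' Reynolds genetic distance between populations
#'
#' Coancestry-based linearized distance `D = -ln(1 - theta)` with the
#' pairwise theta of [pairwise_fst()]; theta is clamped to [0, 1 - 1e-12]
#' before the logarithm, so slightly negative estimates give D = 0.
#'
#' @param counts Integer matrix: haplotypes x populations.
#' @return An `hlag_dist` with `metric = "Reynolds"` and matrix `d`.
#' @export
reynolds_distance <- function(counts) {
  npop <- ncol(counts)
  d <- matrix(0, npop, npop,
              dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(npop - 1)) {
    for (j in (i + 1):npop) {
      th <- theta_two_pop(counts[, i], counts[, j])
      th <- min(max(th, 0), 1 - 1e-12)
      d[i, j] <- d[j, i] <- -log(1 - th)
    }
  }
  structure(list(metric = "Reynolds", d = d), class = "hlag_dist")
}

table_log_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact test of population differentiation
#'
#' Probability of observing a haplotype-by-population contingency table
#' as or less probable than the data under fixed margins (the
#' Fisher-exact probability-mass criterion generalized to r x k).  The
#' null distribution is sampled with Patefield's algorithm
#' (`stats::r2dtable`), which draws tables from the conditional
#' (multiple hypergeometric) distribution; 2 x 2 tables are fully
#' enumerated instead.
#'
#' @param tab Integer contingency matrix (haplotypes x populations).
#' @param B Monte-Carlo table draws.
#' @param seed Integer seed.
#' @return A list: `p`, `se` (binomial Monte-Carlo error, 0 for the
#'   enumerated case), `flagged` (degenerate-margin convention p = 1).
#' @export
exact_differentiation_test <- function(tab, B = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  if (!sum(tab)) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2)
    return(list(p = 1, se = 0, flagged = TRUE))
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  lp_obs <- table_log_prob(tab)
  if (all(dim(tab) == c(2L, 2L))) {
    # enumerate over the single free cell
    a_max <- min(rowSums(tab)[1], colSums(tab)[1])
    a_min <- max(0, rowSums(tab)[1] - colSums(tab)[2])
    p <- 0
    for (a in a_min:a_max) {
      t2 <- matrix(c(a, rowSums(tab)[1] - a, colSums(tab)[1] - a,
                     sum(tab) - rowSums(tab)[1] - colSums(tab)[1] + a),
                   2, 2, byrow = TRUE)
      lp <- table_log_prob(t2)
      if (lp <= lp_obs + 1e-9) p <- p + exp(lp)
    }
    return(list(p = min(p, 1), se = 0, flagged = FALSE))
  }
  set.seed(seed)
  sims <- stats::r2dtable(B, rowSums(tab), colSums(tab))
  hits <- vapply(sims, function(t2) table_log_prob(t2) <= lp_obs + 1e-9,
                 logical(1))
  p <- mean(hits)
  list(p = p, se = sqrt(p * (1 - p) / B), flagged = FALSE)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Two- or three-level AMOVA on haplotype identity distances (0 within a
#' haplotype, 1 between different haplotypes): chromosomes within
#' populations within groups.  Variance components follow the standard
#' coefficient equations; fixation indices are `F_CT` (among groups),
#' `F_SC` (among populations within groups) and `F_ST` (overall).
#' P-values use the three standard permutation schemes: whole populations
#' among groups for `F_CT`; chromosomes among populations within their
#' group for `F_SC`; chromosomes among all populations for `F_ST`.
#'
#' @param counts Integer matrix: haplotypes x populations.
#' @param grouping Named vector population -> group.  With a single
#'   group, the among-group level is dropped and a two-level result is
#'   returned (`F_CT` absent).
#' @param permutations Permutations per test (0 skips p-values).
#' @param seed Integer seed.
#' @return A list of class `hlag_amova`: `components` (named variance
#'   components), `percent` (summing to 100), `phi` (fixation indices),
#'   `p` (permutation p-values), `df`, `ssd`.
#' @export
amova <- function(counts, grouping, permutations = 1000L, seed = 1L) {
  pops <- colnames(counts)
  if (is.null(pops)) stop("counts must have population column names")
  grouping <- grouping[pops]
  if (anyNA(grouping)) stop("grouping must cover every population")
  groups <- unique(grouping)
  obs <- amova_decompose(counts, grouping)

  out <- obs
  if (permutations > 0) {
    set.seed(seed)
    chrom <- rep(seq_len(nrow(counts)), rowSums(counts))
    pop_of <- rep(pops, colSums(counts))
    p_ct <- p_sc <- p_st <- NA_real_
    if (length(groups) > 1) {
      hits <- 0L
      for (b in seq_len(permutations)) {
        g2 <- stats::setNames(sample(grouping), pops)
        v <- amova_decompose(counts, g2)
        if (!is.na(v$phi["F_CT"]) &&
            v$phi["F_CT"] >= obs$phi["F_CT"] - 1e-12) hits <- hits + 1L
      }
      p_ct <- hits / permutations
      # chromosomes among populations within groups
      if (!is.na(obs$phi["F_SC"])) {
        hits <- 0L
        for (b in seq_len(permutations)) {
          new_pop <- pop_of
          for (g in groups) {
            in_g <- pop_of %in% pops[grouping == g]
            new_pop[in_g] <- sample(pop_of[in_g])
          }
          c2 <- hap_pop_counts(chrom, new_pop, nrow(counts), pops)
          v <- amova_decompose(c2, grouping)
          if (v$phi["F_SC"] >= obs$phi["F_SC"] - 1e-12) hits <- hits + 1L
        }
        p_sc <- hits / permutations
      }
    }
    hits <- 0L
    for (b in seq_len(permutations)) {
      c2 <- hap_pop_counts(chrom, sample(pop_of), nrow(counts), pops)
      v <- amova_decompose(c2, grouping)
      if (v$phi["F_ST"] >= obs$phi["F_ST"] - 1e-12) hits <- hits + 1L
    }
    p_st <- hits / permutations
    out$p <- c(F_CT = p_ct, F_SC = p_sc, F_ST = p_st)
  }
  structure(out, class = "hlag_amova")
}

hap_pop_counts <- function(chrom, pop_of, nhap, pops) {
  m <- matrix(0L, nhap, length(pops), dimnames = list(NULL, pops))
  tb <- table(factor(chrom, levels = seq_len(nhap)),
              factor(pop_of, levels = pops))
  m[] <- as.integer(tb)
  m
}

amova_decompose <- function(counts, grouping) {
  pops <- colnames(counts)
  groups <- unique(grouping[pops])
  n_p <- colSums(counts)
  N <- sum(n_p)
  P <- length(pops)
  G <- length(groups)

  ssd_within_set <- function(cmat) {
    # pooled SSD of a set of chromosomes given its haplotype counts
    n <- sum(cmat)
    (n^2 - sum(rowSums(cmat)^2)) / (2 * n)
  }
  ssd_t <- ssd_within_set(counts)
  ssd_wp <- sum(vapply(pops, function(p)
    ssd_within_set(counts[, p, drop = FALSE]), numeric(1)))

  if (G == 1) {
    ssd_ap <- ssd_t - ssd_wp
    ms_ap <- ssd_ap / (P - 1)
    ms_wp <- ssd_wp / (N - P)
    nc <- (N - sum(n_p^2) / N) / (P - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - ms_wp) / nc
    tot <- sig_b + sig_c
    phi <- c(F_CT = NA_real_, F_SC = NA_real_,
             F_ST = if (tot > 0) sig_b / tot else 0)
    comps <- c(among_groups = NA_real_, among_pops = sig_b,
               within_pops = sig_c)
    pct <- 100 * c(NA_real_, sig_b, sig_c) / tot
    names(pct) <- names(comps)
    return(list(components = comps, percent = pct, phi = phi,
                df = c(AP = P - 1, WP = N - P),
                ssd = c(AP = ssd_ap, WP = ssd_wp), p = NULL))
  }

  if (P == G) {
    # one population per group: the among-populations-within-groups
    # level vanishes and the design collapses to two levels over groups
    two <- amova_decompose(counts, stats::setNames(rep("all", P),
                                                   pops))
    comps <- c(among_groups = unname(two$components["among_pops"]),
               among_pops = 0,
               within_pops = unname(two$components["within_pops"]))
    tot <- sum(comps)
    pct <- 100 * comps / tot
    phi <- c(F_CT = unname(two$phi["F_ST"]), F_SC = NA_real_,
             F_ST = unname(two$phi["F_ST"]))
    return(list(components = comps, percent = pct, phi = phi,
                df = c(AG = G - 1, AP = 0, WP = N - P),
                ssd = c(AG = unname(two$ssd["AP"]), AP = 0,
                        WP = unname(two$ssd["WP"])), p = NULL))
  }

  ssd_ag_terms <- vapply(groups, function(g) {
    sel <- pops[grouping[pops] == g]
    ssd_within_set(counts[, sel, drop = FALSE])
  }, numeric(1))
  ssd_apwg <- sum(ssd_ag_terms) - ssd_wp
  ssd_ag <- ssd_t - ssd_apwg - ssd_wp

  N_g <- vapply(groups, function(g)
    sum(n_p[grouping[pops] == g]), numeric(1))
  sum_np2_over_Ng <- sum(vapply(groups, function(g) {
    sel <- grouping[pops] == g
    sum(n_p[sel]^2) / sum(n_p[sel])
  }, numeric(1)))
  n1 <- (N - sum_np2_over_Ng) / (P - G)
  n2c <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)

  ms_wp <- ssd_wp / (N - P)
  ms_ap <- ssd_apwg / (P - G)
  ms_ag <- ssd_ag / (G - 1)
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2c * sig_b) / n3
  tot <- sig_a + sig_b + sig_c

  comps <- c(among_groups = sig_a, among_pops = sig_b,
             within_pops = sig_c)
  pct <- 100 * comps / tot
  phi <- c(F_CT = if (tot != 0) sig_a / tot else 0,
           F_SC = if ((sig_b + sig_c) != 0) sig_b / (sig_b + sig_c)
           else 0,
           F_ST = if (tot != 0) (sig_a + sig_b) / tot else 0)
  list(components = comps, percent = pct, phi = phi,
       df = c(AG = G - 1, AP = P - G, WP = N - P),
       ssd = c(AG = ssd_ag, AP = ssd_apwg, WP = ssd_wp), p = NULL)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of comparisons (e.g. `choose(14, 2) = 91` population
#'   pairs).
#' @return A list: `raw` (`alpha/m`) and `reported` (rounded to one
#'   significant figure, the conventional way such thresholds are
#'   quoted).
#' @export
#' @examples
#' bonferroni_threshold(0.05, 91)  # raw 0.000549..., reported 5e-04
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0)
  raw <- alpha / m
  list(raw = raw, reported = signif(raw, 1))
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centering eigendecomposition of a symmetric zero-diagonal
#' distance matrix (Torgerson scaling, via `stats::cmdscale`), returning
#' the top-`k` coordinates centered at the origin.  Negative eigenvalues
#' (non-Euclidean input) are clipped with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal, or an
#'   `hlag_dist` from [reynolds_distance()] / [pairwise_fst()].
#' @param k Output dimensions.
#' @return A list: `points` (n x k), `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2L) {
  if (inherits(d, "hlag_dist"))
    d <- if (!is.null(d$d)) d$d else d$theta
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12))
    stop("need a symmetric matrix with zero diagonal")
  n <- nrow(d)
  k <- min(k, n - 1)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("negative eigenvalues clipped (non-Euclidean distances)")
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < k) {
    # degenerate (e.g. all-zero distances): pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, k - NCOL(pts)))
  }
  pts <- sweep(pts, 2, colMeans(pts))
  rownames(pts) <- rownames(d)
  list(points = pts, eig = fit$eig)
}

#' Haplotype-by-population count matrix from phased assignments
#'
#' @param phased A result from [partition_ligation_phase()].
#' @return Integer matrix of chromosome counts, haplotype keys x
#'   populations.
#' @export
count_haplotypes <- function(phased) {
  keys <- c(hap_key(phased$hap1), hap_key(phased$hap2))
  pop <- rep(phased$genotypes$population, 2)
  tb <- table(keys, pop)
  m <- matrix(as.integer(tb), nrow(tb), ncol(tb),
              dimnames = dimnames(tb))
  m
}
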