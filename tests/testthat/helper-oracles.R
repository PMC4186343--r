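# Independent oracles used across the suite.  These are deliberately
# written from first principles (literal rule transcriptions, closed
# forms, brute-force enumeration) and never call the implementation paths
# they check.

# Literal transcription of the four depth/proportion genotype rules for a
# two-allele count composition; returns the call kind.
refine_rule_oracle <- function(n_major, n_minor) {
  stopifnot(n_major >= n_minor)
  depth <- n_major + n_minor
  if (depth == 0) return("missing")
  if (n_minor == 0) {
    if (depth >= 7) return("hom") else return("missing")
  }
  prop <- n_minor / depth
  if (prop < 0.05 && depth >= 20) return("hom")
  if (prop >= 0.05 && prop <= 0.20) return("half")
  if (prop > 0.20) return("het")
  # minor under 5% at depth < 20: unreachable with integer counts
  "half"
}

# Full-enumeration biallelic exact HWE test (conditional on allele
# counts); p is the total probability of configurations no more probable
# than the observed heterozygote count.
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  lp <- function(h) {
    a <- (na - h) / 2
    b <- (nb - h) / 2
    if (h < 0 || a < 0 || b < 0 || a != round(a)) return(-Inf)
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }
  hs <- seq(na %% 2, min(na, nb), by = 2)
  ps <- vapply(hs, function(h) exp(lp(h)), numeric(1))
  sum(ps[ps <= exp(lp(n_ab)) + 1e-12])
}

# Brute-force frequency-weighted pairwise difference oracle: haplotypes
# as rows of an allele matrix with frequencies f; weighted Hamming
# distance summed over all ordered haplotype pairs.
pairwise_k_oracle <- function(alleles, f, weights, n2) {
  nh <- nrow(alleles)
  acc <- 0
  for (i in seq_len(nh)) {
    for (j in seq_len(nh)) {
      if (i == j) next
      d <- sum(weights[alleles[i, ] != alleles[j, ]])
      acc <- acc + f[i] * f[j] * d
    }
  }
  (n2 / (n2 - 1)) * acc
}

# Least-squares Procrustes residual after optimal rotation/reflection
# and centering (no scaling).
procrustes_resid <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$v %*% t(s$u)
  sum((X - Y %*% t(R))^2)
}

# Direct three-level sum-of-squares decomposition on haplotype identity
# distances, written independently of amova(): operates on an explicit
# vector of haplotype ids per chromosome.
amova_ss_oracle <- function(hap, pop, grp) {
  ss_of <- function(ids) {
    n <- length(ids)
    d <- outer(ids, ids, "!=") * 1
    sum(d) / (2 * n)
  }
  N <- length(hap)
  pops <- unique(pop)
  groups <- unique(grp)
  ssd_t <- ss_of(hap)
  ssd_wp <- sum(vapply(pops, function(p) ss_of(hap[pop == p]),
                       numeric(1)))
  ssd_wg <- sum(vapply(groups, function(g) ss_of(hap[grp == g]),
                       numeric(1)))
  list(ssd_t = ssd_t, ssd_wp = ssd_wp, ssd_ap = ssd_wg - ssd_wp,
       ssd_ag = ssd_t - ssd_wg)
}

# Small deterministic genotype matrix builder for phasing tests:
# `rows` is a list of length-2 character vectors of "|"-collapsed
# haplotypes per sample.
toy_genotypes <- function(rows, alleles_per_site = NULL) {
  h1 <- do.call(rbind, lapply(rows, function(r)
    strsplit(r[1], "|", fixed = TRUE)[[1]]))
  h2 <- do.call(rbind, lapply(rows, function(r)
    strsplit(r[2], "|", fixed = TRUE)[[1]]))
  np <- ncol(h1)
  sites <- data.frame(gene_pos = seq_len(np))
  sites$alleles <- if (is.null(alleles_per_site))
    lapply(seq_len(np), function(j) sort(unique(c(h1[, j], h2[, j]))))
  else alleles_per_site
  # unordered genotypes: larger allele in slot a for hets is irrelevant
  genotype_matrix(sites, h1, h2)
}

hap_keys_of <- function(m) apply(m, 1, paste, collapse = "|")

ref_cache <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- load_reference_tables()
    ref
  }
})
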