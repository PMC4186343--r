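#' Configuration for the low-coverage cohort simulator
#'
#' The simulator emulates 1000Genomes-like low-coverage sequencing of a
#' single locus: per sample and site, read depth is Poisson with mean
#' `mean_depth`, each read copies one of the two true alleles with equal
#' probability and is corrupted to a uniformly chosen other allele of the
#' site's panel dictionary with probability `error_rate`, and an
#' independent Poisson number of miss-mapped contaminant reads (mean
#' `mismap_rate`) carries a uniformly random panel allele.
#'
#' @param mean_depth Mean reads per site (lambda), default 4 as typical of
#'   low-coverage whole-genome data.
#' @param error_rate Per-read allele corruption probability, default 0.005.
#' @param mismap_rate Expected contaminant reads per site, default 0.1.
#' @param others_bins Number of unnamed pseudo-haplotypes over which any
#'   residual ("others") frequency mass is spread.
#' @return A list of class `hlag_sim_config`.
#' @export
simulation_config <- function(mean_depth = 4, error_rate = 0.005,
                              mismap_rate = 0.1, others_bins = 5L) {
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 0.5,
            mismap_rate >= 0, others_bins >= 1)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 mismap_rate = mismap_rate,
                 others_bins = as.integer(others_bins)),
            class = "hlag_sim_config")
}

# Expand a frequency vector that carries residual ("others") mass into a
# fully specified pool: the residual is spread uniformly over pseudo-
# haplotypes generated by single edits of the most frequent haplotype,
# flagged as unnamed.  Editing uses the per-site allele dictionary.
expand_pool <- function(haps, freq, site_alleles, others_bins,
                        tol = 1e-9) {
  alleles <- haps$alleles
  if ("others" %in% names(freq)) {
    resid <- unname(freq[["others"]])
    freq <- freq[names(freq) != "others"]
  } else {
    resid <- 1 - sum(freq)
    if (resid < 0 && resid > -tol) resid <- 0
  }
  if (any(freq < 0) || resid < -tol)
    stop("negative haplotype frequencies")
  missing_names <- setdiff(names(freq), rownames(alleles))
  if (length(missing_names))
    stop("frequencies name unknown haplotypes: ",
         paste(missing_names, collapse = ", "))
  alleles <- alleles[names(freq), , drop = FALSE]

  if (resid > tol) {
    top <- names(freq)[which.max(freq)]
    seen <- apply(alleles, 1, paste, collapse = "|")
    pseudo <- matrix(NA_character_, 0, ncol(alleles))
    guard <- 0L
    while (nrow(pseudo) < others_bins && guard < 1000L) {
      guard <- guard + 1L
      vec <- alleles[top, ]
      j <- sample.int(ncol(alleles), 1L)
      opts <- setdiff(site_alleles[[j]], vec[j])
      if (!length(opts)) next
      vec[j] <- if (length(opts) == 1L) opts else sample(opts, 1L)
      key <- paste(vec, collapse = "|")
      if (key %in% c(seen, apply(pseudo, 1, paste, collapse = "|")))
        next
      pseudo <- rbind(pseudo, vec)
    }
    if (nrow(pseudo) == 0L)
      stop("could not generate pseudo-haplotypes for residual mass")
    rownames(pseudo) <- paste0("unnamed", seq_len(nrow(pseudo)))
    colnames(pseudo) <- colnames(alleles)
    alleles <- rbind(alleles, pseudo)
    freq <- c(freq, stats::setNames(rep(resid / nrow(pseudo),
                                        nrow(pseudo)),
                                    rownames(pseudo)))
  }
  freq <- freq / sum(freq)
  list(alleles = alleles, freq = freq)
}

#' Draw true diplotypes from a haplotype frequency table
#'
#' Samples `n` individuals as independent random unions of gametes
#' (Hardy-Weinberg): each chromosome is an i.i.d. draw from the haplotype
#' pool.  Residual frequency mass not covered by the named haplotypes is
#' spread over unnamed single-edit pseudo-haplotypes so the pool sums to
#' one while still exercising the new/unknown nomenclature path.
#'
#' @param haps Regional haplotype table: a list with `sites` (gene
#'   positions) and `alleles` (matrix with haplotype rownames), e.g. one
#'   entry of `load_reference_tables()$haplotypes`.
#' @param freq Named frequency vector over the haplotype names, optionally
#'   including an `others` entry; must sum to 1 within tolerance after
#'   residual expansion.
#' @param n Number of individuals.
#' @param site_alleles Per-site allele dictionaries (list, one character
#'   vector per site); defaults to the alleles observed in `haps$alleles`.
#' @param population Population label stored with the samples.
#' @param seed Integer seed; the draw is reproducible.
#' @param config Simulator configuration (for `others_bins`).
#' @return An object of class `hlag_truth`: sites, sample ids, population
#'   labels, haplotype name pairs (`name1`, `name2`) and allele matrices
#'   (`hap1`, `hap2`, samples x sites).
#' @export
sample_diplotypes <- function(haps, freq, n, site_alleles = NULL,
                              population = "POP", seed = 1L,
                              config = simulation_config()) {
  if (!length(freq)) stop("empty frequency table")
  set.seed(seed)
  if (is.null(site_alleles))
    site_alleles <- lapply(seq_len(ncol(haps$alleles)),
                           function(j) unique(haps$alleles[, j]))
  pool <- expand_pool(haps, freq, site_alleles, config$others_bins)
  if (abs(sum(pool$freq) - 1) > 1e-9)
    stop("frequencies do not sum to 1")
  idx1 <- sample.int(nrow(pool$alleles), n, replace = TRUE,
                     prob = pool$freq)
  idx2 <- sample.int(nrow(pool$alleles), n, replace = TRUE,
                     prob = pool$freq)
  sites <- data.frame(gene_pos = haps$sites)
  sites$alleles <- site_alleles
  structure(list(sites = sites,
                 samples = sprintf("%s_%04d", population, seq_len(n)),
                 population = rep(population, n),
                 name1 = rownames(pool$alleles)[idx1],
                 name2 = rownames(pool$alleles)[idx2],
                 hap1 = pool$alleles[idx1, , drop = FALSE],
                 hap2 = pool$alleles[idx2, , drop = FALSE],
                 pool = pool),
            class = "hlag_truth")
}

#' Draw a multi-population cohort from a per-population frequency table
#'
#' Convenience wrapper over [sample_diplotypes()] looping populations with
#' derived seeds (fixed offsets from the global seed).
#'
#' @param haps Regional haplotype table (see [sample_diplotypes()]).
#' @param popfreq Data frame: column `name` plus one frequency column per
#'   population (the bundled `popfreq` tables).
#' @param populations Data frame with `population` and `n2` (chromosome
#'   counts); individuals drawn are `n2/2` per population.
#' @param site_alleles Per-site allele dictionaries.
#' @param seed Global integer seed.
#' @param config Simulator configuration.
#' @return A single `hlag_truth` with all populations concatenated.
#' @export
sample_cohort <- function(haps, popfreq, populations, site_alleles = NULL,
                          seed = 1L, config = simulation_config()) {
  parts <- vector("list", nrow(populations))
  for (i in seq_len(nrow(populations))) {
    pop <- populations$population[i]
    if (!pop %in% names(popfreq))
      stop("no frequency column for population ", pop)
    fr <- stats::setNames(popfreq[[pop]], popfreq$name)
    parts[[i]] <- sample_diplotypes(haps, fr, populations$n2[i] %/% 2L,
                                    site_alleles, population = pop,
                                    seed = seed + 1000L * i,
                                    config = config)
  }
  out <- parts[[1]]
  for (p in parts[-1]) {
    out$samples <- c(out$samples, p$samples)
    out$population <- c(out$population, p$population)
    out$name1 <- c(out$name1, p$name1)
    out$name2 <- c(out$name2, p$name2)
    out$hap1 <- rbind(out$hap1, p$hap1)
    out$hap2 <- rbind(out$hap2, p$hap2)
  }
  out
}

#' Simulate allele-depth observations from true diplotypes
#'
#' @param truth A `hlag_truth` from [sample_diplotypes()].
#' @param config Simulator configuration from [simulation_config()].
#' @param seed Integer seed.
#' @return Allele-depth records (`hlag_ad`, see [ad_records()]).
#' @export
simulate_depths <- function(truth, config = simulation_config(),
                            seed = 1L) {
  set.seed(seed)
  ns <- length(truth$samples)
  np <- nrow(truth$sites)
  dict <- truth$sites$alleles
  counts <- vector("list", ns)
  for (i in seq_len(ns)) {
    row <- vector("list", np)
    for (j in seq_len(np)) {
      truth_pair <- c(truth$hap1[i, j], truth$hap2[i, j])
      depth <- stats::rpois(1L, config$mean_depth)
      reads <- character(0)
      if (depth > 0) {
        reads <- truth_pair[sample.int(2L, depth, replace = TRUE)]
        err <- stats::runif(depth) < config$error_rate
        if (any(err)) {
          for (k in which(err)) {
            opts <- setdiff(dict[[j]], reads[k])
            if (length(opts))
              reads[k] <- if (length(opts) == 1L) opts else
                sample(opts, 1L)
          }
        }
      }
      ncont <- stats::rpois(1L, config$mismap_rate)
      if (ncont > 0)
        reads <- c(reads, sample(dict[[j]], ncont, replace = TRUE))
      row[[j]] <- if (length(reads)) table_counts(reads) else integer(0)
    }
    counts[[i]] <- row
  }
  ad_records(truth$sites, truth$samples, counts, truth$population)
}

table_counts <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' Concordance of calls against simulated truth
#'
#' Compares refined (and optionally phased) calls with the generating
#' diplotypes.  Genotype concordance is the fraction of fully called
#' genotypes whose unordered allele pair equals the truth; half-call and
#' missing rates are genotype-level fractions.  For phased output the
#' switch-error rate is computed per sample over sites that are truly
#' heterozygous and called heterozygous with the correct alleles
#' (unambiguous sites), as the fraction of adjacent such site pairs whose
#' relative phase disagrees with the truth.
#'
#' @param truth A `hlag_truth`.
#' @param calls An `hlag_gm` genotype matrix, or a phased result from
#'   [partition_ligation_phase()].
#' @return A list with `concordance`, `half_rate`, `missing_rate` and,
#'   for phased input, `switch_error`.
#' @export
evaluate_calls <- function(truth, calls) {
  phased <- inherits(calls, "hlag_phased")
  gm <- if (phased) calls$genotypes else calls
  if (!identical(as.integer(gm$sites$gene_pos),
                 as.integer(truth$sites$gene_pos)) ||
      nrow(gm$allele_a) != length(truth$samples))
    stop("sample/site panel mismatch between truth and calls")

  kinds <- call_kinds(gm)
  full <- kinds %in% c("hom", "het")
  tr1 <- truth$hap1
  tr2 <- truth$hap2
  match_full <- (gm$allele_a == tr1 & gm$allele_b == tr2) |
    (gm$allele_a == tr2 & gm$allele_b == tr1)
  conc <- if (any(full)) mean(match_full[full]) else NA_real_

  out <- list(concordance = conc,
              half_rate = mean(kinds == "half"),
              missing_rate = mean(kinds == "missing"))
  if (phased) {
    h1 <- calls$hap1
    h2 <- calls$hap2
    sw_err <- 0L
    sw_tot <- 0L
    for (i in seq_len(nrow(h1))) {
      het <- tr1[i, ] != tr2[i, ]
      called_ok <- het & ((h1[i, ] == tr1[i, ] & h2[i, ] == tr2[i, ]) |
                            (h1[i, ] == tr2[i, ] & h2[i, ] == tr1[i, ]))
      js <- which(called_ok)
      if (length(js) < 2L) next
      # orientation of each unambiguous het site: TRUE if hap1 carries
      # the truth hap1 allele
      orient <- h1[i, js] == tr1[i, js]
      sw_err <- sw_err + sum(orient[-1] != orient[-length(orient)])
      sw_tot <- sw_tot + length(js) - 1L
    }
    out$switch_error <- if (sw_tot > 0) sw_err / sw_tot else NA_real_
  }
  out
}
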