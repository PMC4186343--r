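#' Configuration for a full pipeline run
#'
#' @param region Which regional panel to run end to end: `"utr3"`,
#'   `"promoter"` or `"coding"`.
#' @param populations Character vector of population labels (default: all
#'   fourteen bundled populations).
#' @param stages Ordered subset of
#'   `c("simulate", "refine", "phase", "name", "stats")`; later stages
#'   require their input stage to be enabled.
#' @param sim Simulator configuration ([simulation_config()]).
#' @param refine Refinement thresholds ([refinement_config()]).
#' @param window_size,top_k Phasing controls
#'   ([partition_ligation_phase()]).
#' @param permutations Permutations for FST/AMOVA.
#' @param hwe_steps,hwe_burnin Chain controls for the HWE exact test.
#' @param seed Global seed; all stage seeds derive from it by fixed
#'   offsets.
#' @param out_dir Optional directory; when set, stage artifacts are
#'   written as TSV and checksummed in the manifest.
#' @return A list of class `hlag_run_config`.
#' @export
run_config <- function(region = "utr3", populations = NULL,
                       stages = c("simulate", "refine", "phase", "name",
                                  "stats"),
                       sim = simulation_config(),
                       refine = refinement_config(),
                       window_size = 8L, top_k = 50L,
                       permutations = 200L, hwe_steps = 20000L,
                       hwe_burnin = 2000L, seed = 1L, out_dir = NULL) {
  known <- c("simulate", "refine", "phase", "name", "stats")
  if (!all(stages %in% known)) stop("unknown stage")
  need <- c(refine = "simulate", phase = "refine", name = "phase",
            stats = "phase")
  for (s in intersect(stages, names(need)))
    if (!need[[s]] %in% stages)
      stop("stage '", s, "' requires stage '", need[[s]], "'")
  structure(list(region = region, populations = populations,
                 stages = stages, sim = sim, refine = refine,
                 window_size = window_size, top_k = top_k,
                 permutations = permutations, hwe_steps = hwe_steps,
                 hwe_burnin = hwe_burnin, seed = seed,
                 out_dir = out_dir),
            class = "hlag_run_config")
}

#' Run the simulate -> refine -> phase -> name -> stats pipeline
#'
#' Executes the enabled stages in order on one regional panel, drawing
#' the cohort from the bundled per-population haplotype frequency table.
#' Every stage seed is derived from the global seed by a fixed offset, so
#' a rerun with the same configuration reproduces identical outputs; when
#' `out_dir` is set, artifacts are written as TSV and their MD5 checksums
#' recorded in the manifest.
#'
#' @param config A [run_config()].
#' @return A list of class `hlag_run`: `manifest` (parameters, seeds,
#'   checksums), and the stage outputs `truth`, `ad`, `genotypes`,
#'   `filtered`, `phased`, `names`, `stats` (those enabled).
#' @export
run_pipeline <- function(config = run_config()) {
  ref <- load_reference_tables()
  region <- config$region
  haps <- ref$haplotypes[[region]]
  pops <- ref$populations
  if (!is.null(config$populations))
    pops <- pops[pops$population %in% config$populations, , drop = FALSE]
  if (!nrow(pops)) stop("no populations selected")
  dict <- site_alleles(ref$sites)[as.character(haps$sites)]

  out <- list()
  artifacts <- list()

  if ("simulate" %in% config$stages) {
    out$truth <- sample_cohort(haps, ref$popfreq[[region]], pops,
                               site_alleles = dict,
                               seed = config$seed, config = config$sim)
    out$ad <- simulate_depths(out$truth, config$sim,
                              seed = config$seed + 7L)
  }
  if ("refine" %in% config$stages) {
    refined <- refine_genotypes(out$ad, config$refine)
    out$genotypes <- refined$genotypes
    out$audit <- refined$audit
    filt <- apply_site_filters(out$genotypes)
    out$filtered <- filt$genotypes
    out$removed_sites <- filt$removed
    out$missing <- missing_rate(out$genotypes)
  }
  if ("phase" %in% config$stages) {
    out$phased <- partition_ligation_phase(
      out$filtered, window_size = config$window_size,
      top_k = config$top_k, seed = config$seed + 13L)
    out$phasing_summary <- phasing_summary(out$phased)
    artifacts$phased <- data.frame(
      sample = rownames(out$phased$hap1),
      hap1 = hap_key(out$phased$hap1),
      hap2 = hap_key(out$phased$hap2),
      posterior = out$phased$posterior, stringsAsFactors = FALSE)
    artifacts$pool <- data.frame(
      haplotype = names(out$phased$pool$freq),
      frequency = as.numeric(out$phased$pool$freq),
      stringsAsFactors = FALSE)
  }
  if ("name" %in% config$stages) {
    # project phased haplotypes (filtered panel) onto the reference
    # site list; sites dropped by filtering are restored from the
    # population-major allele of the reference table
    keys <- unique(c(hap_key(out$phased$hap1), hap_key(out$phased$hap2)))
    proj <- project_to_sites(keys, out$filtered$sites$gene_pos,
                             haps, ref$popfreq[[region]])
    cls <- classify_haplotype(proj, haps, region = region)
    cls$key <- keys
    out$names <- cls
    artifacts$names <- cls
  }
  if ("stats" %in% config$stages) {
    counts <- count_haplotypes(out$phased)
    counts <- counts[, pops$population, drop = FALSE]
    grouping <- stats::setNames(pops$group, pops$population)
    out$stats <- cohort_statistics(
      out$phased, counts, grouping,
      weights = site_weights(out$filtered$sites$gene_pos),
      L = region_length(region),
      permutations = config$permutations,
      hwe_steps = config$hwe_steps, hwe_burnin = config$hwe_burnin,
      seed = config$seed + 29L)
    artifacts$fst <- as.data.frame(out$stats$fst$theta)
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("hlagdiv")),
                   seed = config$seed, region = region,
                   stages = config$stages,
                   populations = pops$population,
                   parameters = config[c("window_size", "top_k",
                                         "permutations")],
                   sim = unclass(config$sim),
                   refine = unclass(config$refine))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    sums <- character(0)
    for (nm in names(artifacts)) {
      f <- file.path(config$out_dir, paste0(nm, ".tsv"))
      utils::write.table(artifacts[[nm]], f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      sums[nm] <- unname(tools::md5sum(f))
    }
    manifest$checksums <- sums
  }
  out$manifest <- manifest
  structure(out, class = "hlag_run")
}

# length in bp of each analyzed region: span between the first and last
# analyzed site, inclusive (3'UTR 2942..3227 = 286 bp)
region_length <- function(region) {
  switch(region,
         utr3 = 286L,
         promoter = 29795566L - 29794317L + 1L,
         coding = 29798459L - 29795636L + 1L,
         stop("unknown region"))
}

# per-site nucleotide-difference weights: the 14-bp indel (gene position
# +2960) counts as 14 differences, every other site as 1
site_weights <- function(gene_pos) {
  ifelse(gene_pos == 2960L, 14, 1)
}

# restore filtered-out reference sites with the table's modal allele so a
# phased haplotype spans the full reference site list
project_to_sites <- function(keys, have_sites, haps, popfreq) {
  mats <- hap_unkey(keys)
  full <- matrix(NA_character_, length(keys), length(haps$sites))
  idx <- match(have_sites, haps$sites)
  if (anyNA(idx)) stop("phased sites not in the reference site list")
  full[, idx] <- mats
  fill <- setdiff(seq_along(haps$sites), idx)
  for (j in fill) {
    col <- haps$alleles[, j]
    modal <- names(sort(table(col), decreasing = TRUE))[1]
    full[, j] <- modal
  }
  full
}

# per-population diversity panel + differentiation statistics
cohort_statistics <- function(phased, counts, grouping, weights, L,
                              permutations, hwe_steps, hwe_burnin,
                              seed) {
  pops <- colnames(counts)
  n2 <- colSums(counts)
  divers <- data.frame(population = pops, n2 = as.integer(n2),
                       haplotype_diversity = NA_real_,
                       nucleotide_diversity_pct = NA_real_,
                       k = NA_real_, private = NA_integer_,
                       p_hwe = NA_real_, stringsAsFactors = FALSE)
  priv <- private_haplotypes(counts)
  pop_of_sample <- phased$genotypes$population
  sites_n <- ncol(phased$hap1)
  for (i in seq_along(pops)) {
    p <- counts[, i] / n2[i]
    divers$haplotype_diversity[i] <- haplotype_diversity(p, n2[i])
    # per-site frequencies of this population's chromosomes
    sel <- pop_of_sample == pops[i]
    chroms <- rbind(phased$hap1[sel, , drop = FALSE],
                    phased$hap2[sel, , drop = FALSE])
    site_freqs <- lapply(seq_len(sites_n), function(j)
      as.numeric(table(chroms[, j])) / nrow(chroms))
    nd <- nucleotide_diversity(site_freqs, weights, n2[i], L)
    divers$k[i] <- nd$k
    divers$nucleotide_diversity_pct[i] <- nd$pi_percent
    divers$private[i] <- priv[pops[i]]
    g <- diplotype_counts(hap_key(phased$hap1[sel, , drop = FALSE]),
                          hap_key(phased$hap2[sel, , drop = FALSE]))
    divers$p_hwe[i] <- hwe_exact_test(g, steps = hwe_steps,
                                      dememorization = hwe_burnin,
                                      seed = seed + i)$p
  }
  fst <- pairwise_fst(counts, permutations = permutations, seed = seed)
  rey <- reynolds_distance(counts)
  # Reynolds matrices are routinely non-Euclidean; clipping is expected
  mds <- suppressWarnings(classical_mds(rey))
  res <- list(diversity = divers, fst = fst, reynolds = rey, mds = mds,
              amova = amova(counts, grouping,
                            permutations = permutations, seed = seed))
  groups <- unique(grouping)
  if ("Admixed" %in% groups && length(setdiff(groups, "Admixed")) > 1) {
    keep <- names(grouping)[grouping != "Admixed"]
    res$amova_no_admixed <- amova(counts[, keep, drop = FALSE],
                                  grouping[keep],
                                  permutations = permutations,
                                  seed = seed + 1L)
  }
  res
}

#' Diplotype count matrix from per-sample haplotype pairs
#'
#' @param k1,k2 Character vectors of haplotype keys (one pair per
#'   sample).
#' @return Square lower-triangular genotype count matrix suitable for
#'   [hwe_exact_test()].
#' @export
diplotype_counts <- function(k1, k2) {
  alleles <- sort(unique(c(k1, k2)))
  m <- matrix(0L, length(alleles), length(alleles),
              dimnames = list(alleles, alleles))
  for (s in seq_along(k1)) {
    i <- match(max(k1[s], k2[s]), alleles)
    j <- match(min(k1[s], k2[s]), alleles)
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Render report tables from a pipeline run
#'
#' Produces the familiar table shapes: per-population diversity panel,
#' the pairwise FST matrix with significance marks after Bonferroni
#' correction over all pairs, AMOVA blocks for the full grouping and the
#' admixed-removed variant, and MDS coordinates.
#'
#' @param run A result of [run_pipeline()] with the stats stage enabled.
#' @param alpha Family-wise significance level before correction.
#' @return A list of data frames: `diversity`, `fst` (upper triangle
#'   p-values, lower triangle theta, `*` marks p below the
#'   Bonferroni-adjusted threshold), `amova`, `mds`.
#' @export
render_report <- function(run, alpha = 0.05) {
  if (is.null(run$stats)) stop("missing artifact: stats")
  st <- run$stats
  npop <- ncol(st$fst$theta)
  m <- npop * (npop - 1) / 2
  thr <- bonferroni_threshold(alpha, m)$raw
  fst_tab <- matrix("", npop, npop, dimnames = dimnames(st$fst$theta))
  for (i in seq_len(npop)) {
    for (j in seq_len(npop)) {
      if (i < j)
        fst_tab[i, j] <- paste0(format(st$fst$p[i, j], digits = 3),
                                ifelse(st$fst$p[i, j] < thr, "*", ""))
      if (i > j)
        fst_tab[i, j] <- format(st$fst$theta[i, j], digits = 3)
    }
  }
  amova_block <- function(a, label) {
    data.frame(scheme = label,
               level = names(a$percent),
               percent = as.numeric(a$percent),
               p = if (!is.null(a$p)) as.numeric(a$p) else NA_real_,
               stringsAsFactors = FALSE)
  }
  am <- amova_block(st$amova, "all_groups")
  if (!is.null(st$amova_no_admixed))
    am <- rbind(am, amova_block(st$amova_no_admixed, "no_admixed"))
  list(diversity = st$diversity,
       fst = as.data.frame(fst_tab, stringsAsFactors = FALSE),
       amova = am,
       mds = data.frame(population = rownames(st$mds$points),
                        st$mds$points))
}
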