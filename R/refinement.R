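#' Refinement thresholds for depth-based genotype calling
#'
#' The four rules operate on per-allele read counts at one sample and
#' site.  Defaults encode the published thresholds: homozygosity requires
#' at least 7 reads of a single observed allele; a minor allele below 5%
#' of reads is discarded as likely miss-mapping, but only at depth 20 or
#' more; a minor allele between 5% and 20% (inclusive) yields a half call
#' (major allele plus one explicit missing allele); above 20% the site is
#' heterozygous.
#'
#' @param min_hom_depth Minimum reads to call homozygosity from a single
#'   observed allele.
#' @param low_prop Strict upper bound of the discard band.
#' @param high_prop Inclusive upper bound of the half-call band.
#' @param high_depth_threshold Minimum total depth for the discard rule.
#' @return A list of class `hlag_refine_config`.
#' @export
refinement_config <- function(min_hom_depth = 7L, low_prop = 0.05,
                              high_prop = 0.20,
                              high_depth_threshold = 20L) {
  stopifnot(min_hom_depth >= 1, low_prop > 0, low_prop < high_prop,
            high_prop < 0.5)
  structure(list(min_hom_depth = as.integer(min_hom_depth),
                 low_prop = low_prop, high_prop = high_prop,
                 high_depth_threshold = as.integer(high_depth_threshold)),
            class = "hlag_refine_config")
}

#' Refine one allele-depth record into a genotype call
#'
#' Applies the depth/proportion rules to a named vector of per-allele read
#' counts.  With a single observed allele, depth >= `min_hom_depth` gives
#' a homozygous call, less gives a fully missing genotype.  With several
#' observed alleles, every non-major allele is banded by its proportion of
#' the total depth: below `low_prop` (at depth >=
#' `high_depth_threshold`) it is discarded; within
#' [`low_prop`, `high_prop`] it becomes an explicit missing allele (half
#' call); above `high_prop` it is genuine and the call is heterozygous for
#' the two best-supported alleles.  Per-allele banding handles triallelic
#' records (e.g. the promoter -725 C/T/G site).  Zero depth yields a
#' missing genotype, not an error.  Ties for the major allele are broken
#' by count and then by allele string, for determinism.
#'
#' @param counts Named numeric vector of read counts per observed allele.
#' @param config Thresholds from [refinement_config()].
#' @return A list with `kind` (hom/het/half/missing), `allele_a`,
#'   `allele_b` (NA for missing slots) and `rule`, a short audit label of
#'   the rule that fired.
#' @export
#' @examples
#' refine_call(c(A = 7))            # hom A
#' refine_call(c(A = 9, G = 1))     # half call: A plus a missing allele
#' refine_call(c(A = 5, G = 5))     # het A/G
refine_call <- function(counts, config = refinement_config()) {
  if (any(counts < 0)) stop("negative read counts")
  counts <- counts[counts > 0]
  depth <- sum(counts)
  if (depth == 0)
    return(list(kind = "missing", allele_a = NA_character_,
                allele_b = NA_character_, rule = "zero_depth"))

  # deterministic major-allele order: by count desc, then allele string
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  alleles <- names(counts)

  if (length(counts) == 1L) {
    if (depth >= config$min_hom_depth)
      return(list(kind = "hom", allele_a = alleles, allele_b = alleles,
                  rule = "hom_depth"))
    return(list(kind = "missing", allele_a = NA_character_,
                allele_b = NA_character_, rule = "hom_low_depth"))
  }

  props <- counts / depth
  minor <- props[-1]
  keep <- minor > config$high_prop
  half <- minor >= config$low_prop & minor <= config$high_prop
  drop <- minor < config$low_prop
  if (any(drop) && depth < config$high_depth_threshold) {
    # the discard rule applies only at high depth; at lower depth an
    # observed minor read cannot fall under low_prop with the default
    # thresholds, but guard anyway: treat it as the half-call band
    half <- half | drop
    drop <- drop & FALSE
  }

  if (any(keep)) {
    second <- alleles[-1][which(keep)[1]]
    return(list(kind = "het", allele_a = alleles[1], allele_b = second,
                rule = "het_prop"))
  }
  if (any(half))
    return(list(kind = "half", allele_a = alleles[1],
                allele_b = NA_character_, rule = "half_band"))
  list(kind = "hom", allele_a = alleles[1], allele_b = alleles[1],
       rule = "hom_minor_discarded")
}

#' Refine a full allele-depth record set
#'
#' Applies [refine_call()] to every sample x site record, producing a
#' genotype matrix with explicit missing alleles, plus an audit trail of
#' which rule fired where.
#'
#' @param ad Records from [ad_records()] or [simulate_depths()].
#' @param config Thresholds from [refinement_config()].
#' @return A list with `genotypes` (an `hlag_gm`) and `audit` (character
#'   matrix of rule labels, samples x sites).
#' @export
refine_genotypes <- function(ad, config = refinement_config()) {
  ns <- length(ad$samples)
  np <- nrow(ad$sites)
  a <- matrix(NA_character_, ns, np,
              dimnames = list(ad$samples, ad$sites$gene_pos))
  b <- a
  audit <- a
  for (i in seq_len(ns)) {
    for (j in seq_len(np)) {
      cl <- refine_call(ad$counts[[i]][[j]], config)
      a[i, j] <- cl$allele_a
      b[i, j] <- cl$allele_b
      audit[i, j] <- cl$rule
    }
  }
  list(genotypes = genotype_matrix(ad$sites, a, b, ad$population),
       audit = audit)
}

#' Drop monomorphic and singleton sites after refinement
#'
#' Removes sites that are no longer variable once low-confidence alleles
#' were recoded missing, and sites whose minor allele is observed exactly
#' once among the non-missing alleles (singletons).
#'
#' @param gm A genotype matrix.
#' @return A list with `genotypes` (the filtered matrix) and `removed`
#'   (data frame of dropped sites and the reason: monomorphic/singleton).
#' @export
apply_site_filters <- function(gm) {
  np <- nrow(gm$sites)
  reason <- character(np)
  for (j in seq_len(np)) {
    al <- c(gm$allele_a[, j], gm$allele_b[, j])
    al <- al[!is.na(al)]
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) <= 1L) reason[j] <- "monomorphic"
    else if (sum(tab[-1]) == 1L) reason[j] <- "singleton"
  }
  keep <- reason == ""
  removed <- data.frame(gene_pos = gm$sites$gene_pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  sites <- gm$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  list(genotypes = genotype_matrix(sites,
                                   gm$allele_a[, keep, drop = FALSE],
                                   gm$allele_b[, keep, drop = FALSE],
                                   gm$population),
       removed = removed)
}

#' Fraction of allele slots coded as missing
#'
#' Each genotype has two allele slots; a half call contributes one missing
#' slot and a fully missing genotype two.
#'
#' @param gm A genotype matrix.
#' @return A list with `overall` (scalar in [0,1]), `per_site` and
#'   `per_sample` fractions.
#' @export
missing_rate <- function(gm) {
  miss <- is.na(gm$allele_a) + is.na(gm$allele_b)
  list(overall = sum(miss) / (2 * length(miss)),
       per_site = colSums(miss) / (2 * nrow(miss)),
       per_sample = rowSums(miss) / (2 * ncol(miss)))
}
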