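#' Allele-depth record set
#'
#' Container for per-sample, per-site observed allele read counts, the raw
#' input of genotype refinement.  Counts are keyed by the observed allele
#' string, so SNV and indel alleles (e.g. the 15-character allele carrying
#' the 14-bp insertion) are handled uniformly.
#'
#' @param sites Data frame with at least `gene_pos` and a list column
#'   `alleles` (the per-site allele dictionary).
#' @param samples Character vector of sample identifiers.
#' @param counts List of length `length(samples)`; each element a list of
#'   length `nrow(sites)` of named non-negative integer vectors
#'   (allele -> read count).
#' @param population Optional population label per sample.
#' @return An object of class `hlag_ad`.
#' @export
ad_records <- function(sites, samples, counts,
                       population = rep(NA_character_, length(samples))) {
  stopifnot(length(counts) == length(samples),
            length(population) == length(samples))
  for (cs in counts) {
    stopifnot(length(cs) == nrow(sites))
    for (x in cs)
      if (length(x) && (any(x < 0) || is.null(names(x))))
        stop("allele counts must be named and non-negative")
  }
  structure(list(sites = sites, samples = samples, counts = counts,
                 population = population),
            class = "hlag_ad")
}

#' @export
print.hlag_ad <- function(x, ...) {
  cat("Allele-depth records:", length(x$samples), "samples x",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Genotype matrix with explicit missing alleles
#'
#' Unordered genotype calls per sample and site.  Each call is a pair of
#' allele strings in `allele_a` / `allele_b`; `NA` marks a missing allele,
#' so a half call has exactly one `NA` (by convention in `allele_b`) and a
#' fully missing genotype has two.
#'
#' @param sites Data frame with `gene_pos` and list column `alleles`.
#' @param allele_a,allele_b Character matrices, samples x sites.
#' @param population Population label per sample (rows).
#' @return An object of class `hlag_gm`.
#' @export
genotype_matrix <- function(sites, allele_a, allele_b,
                            population = rep(NA_character_,
                                             nrow(allele_a))) {
  stopifnot(identical(dim(allele_a), dim(allele_b)),
            ncol(allele_a) == nrow(sites),
            length(population) == nrow(allele_a))
  # half calls keep their known allele in slot a
  swap <- is.na(allele_a) & !is.na(allele_b)
  if (any(swap)) {
    tmp <- allele_a[swap]
    allele_a[swap] <- allele_b[swap]
    allele_b[swap] <- tmp
  }
  structure(list(sites = sites, allele_a = allele_a, allele_b = allele_b,
                 population = population),
            class = "hlag_gm")
}

#' @export
print.hlag_gm <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$allele_a), "samples x", nrow(x$sites),
      "sites;", sprintf("%.2f%%", 100 * missing_rate(x)$overall),
      "missing alleles\n")
  invisible(x)
}

#' @param x A genotype matrix.
#' @return `call_kinds()`: a character matrix (samples x sites) with values
#'   `hom`, `het`, `half` or `missing`.
#' @rdname genotype_matrix
#' @export
call_kinds <- function(x) {
  a <- x$allele_a
  b <- x$allele_b
  k <- matrix("missing", nrow(a), ncol(a))
  k[!is.na(a) & !is.na(b) & a == b] <- "hom"
  k[!is.na(a) & !is.na(b) & a != b] <- "het"
  k[!is.na(a) & is.na(b)] <- "half"
  dimnames(k) <- dimnames(a)
  k
}
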