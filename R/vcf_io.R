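#' Write allele-depth records as a VCF with per-sample AD fields
#'
#' One record per panel site on chromosome 6 (hg19 coordinates), with the
#' site dictionary's first allele as REF and the rest as ALT, and a
#' sample column carrying `DP:AD` (total depth and per-allele depths in
#' REF,ALT order).
#'
#' @param ad Records from [ad_records()] / [simulate_depths()].
#' @param path Output file path.
#' @param model Gene model used for the hg19 coordinates.
#' @return `path`, invisibly.
#' @export
write_ad_vcf <- function(ad, path, model = build_gene_model()) {
  sites <- ad$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hlagdiv",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                      "Description=\"Allelic depths\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ad$samples),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(sites))) {
    dict <- sites$alleles[[j]]
    fields <- vapply(seq_along(ad$samples), function(i) {
      cnt <- ad$counts[[i]][[j]]
      depths <- vapply(dict, function(a)
        if (a %in% names(cnt)) cnt[[a]] else 0L, integer(1))
      paste0(sum(depths), ":", paste(depths, collapse = ","))
    }, character(1))
    pos <- gene_to_genomic(sites$gene_pos[j], model)
    id <- if ("rsid" %in% names(sites) && !is.na(sites$rsid[j]))
      sites$rsid[j] else "."
    writeLines(paste(c("6", pos, id, dict[1],
                       paste(dict[-1], collapse = ","), ".", ".", ".",
                       "DP:AD", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF with AD fields back into allele-depth records
#'
#' Uses `vcfR` for parsing; gene positions are recovered from the hg19
#' coordinates via [genomic_to_gene()].
#'
#' @param path VCF file path.
#' @param model Gene model for the coordinate conversion.
#' @return An `hlag_ad` record set.
#' @export
read_ad_vcf <- function(path, model = build_gene_model()) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  nsite <- nrow(fix)
  dicts <- lapply(seq_len(nsite), function(j)
    c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1]]))
  sites <- data.frame(gene_pos = genomic_to_gene(as.integer(fix[, "POS"]),
                                                 model))
  sites$alleles <- dicts
  sites$rsid <- fix[, "ID"]
  counts <- lapply(seq_along(samples), function(i) {
    lapply(seq_len(nsite), function(j) {
      x <- as.integer(strsplit(ad[j, i], ",", fixed = TRUE)[[1]])
      cnt <- stats::setNames(x, dicts[[j]])
      cnt[cnt > 0]
    })
  })
  ad_records(sites, samples, counts)
}
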