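#' Load the bundled HLA-G reference tables
#'
#' Reads the package's transcription of the worldwide HLA-G reference data:
#' per-region variant site lists with global allele frequencies (promoter,
#' coding, 3'UTR --- 35 + 81 + 17 = 133 sites), the named regional
#' haplotypes over their site lists (promoter lineages such as `010101a`,
#' coding alleles such as `G*01:01:01:01`, 3'UTR haplotypes `UTR-n`), the
#' per-population haplotype frequency tables for the fourteen 1000Genomes
#' Phase 1 populations, and the extended (promoter/coding/3'UTR) haplotype
#' table with its HG lineage assignments.
#'
#' All tables are integrity-checked on load: gene positions must round-trip
#' to the printed hg19 coordinates, haplotype alleles must belong to each
#' site's allele dictionary, and the extended table's component names must
#' resolve against the regional tables (rare components absent from the
#' >1% regional tables are flagged `unresolved` rather than failing).
#'
#' @return An object of class `hlag_reference`: a list with elements
#'   `sites` (per-region data frames), `haplotypes` (per-region lists with
#'   `sites`, `alleles` matrix and `global_freq`), `popfreq` (per-region
#'   haplotype-by-population frequency data frames), `populations`
#'   (population labels, continental group, chromosome counts `n2`) and
#'   `extended` (the extended haplotype table with a `promoter_resolved`
#'   column applying the short-form promoter aliases).
#' @export
load_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "hlagdiv",
                                  mustWork = TRUE)
  tsv <- function(f) utils::read.delim(path(f), check.names = FALSE,
                                       stringsAsFactors = FALSE)

  sites <- list(promoter = tsv("sites_promoter.tsv"),
                coding = tsv("sites_coding.tsv"),
                utr3 = tsv("sites_utr3.tsv"))

  model <- build_gene_model()
  for (rg in names(sites)) {
    s <- sites[[rg]]
    if (anyDuplicated(s$gene_pos))
      stop("reference integrity: duplicated site in ", rg)
    if (!all(gene_to_genomic(s$gene_pos, model) == s$genomic_pos))
      stop("reference integrity: hg19 coordinate mismatch in ", rg)
  }
  panel <- c(sites$promoter$gene_pos, sites$coding$gene_pos,
             sites$utr3$gene_pos)
  if (length(unique(panel)) != 133L)
    stop("reference integrity: site panel union is not 133 sites")

  read_haps <- function(allele_file, freq_file) {
    wide <- tsv(allele_file)
    fr <- tsv(freq_file)
    mat <- t(as.matrix(wide[, -1, drop = FALSE]))
    colnames(mat) <- wide$gene_pos
    if (!identical(sort(rownames(mat)), sort(fr$name)))
      stop("reference integrity: haplotype names disagree between ",
           allele_file, " and ", freq_file)
    fq <- fr$global_freq
    names(fq) <- fr$name
    list(sites = as.integer(wide$gene_pos),
         alleles = mat[fr$name, , drop = FALSE],
         global_freq = fq)
  }
  haplotypes <- list(
    promoter = read_haps("hap_promoter.tsv", "hap_freq_promoter.tsv"),
    coding = read_haps("hap_coding.tsv", "hap_freq_coding.tsv"),
    utr3 = read_haps("hap_utr3.tsv", "hap_freq_utr3.tsv"))

  # every haplotype allele must be in the site's allele dictionary
  dict <- site_alleles(sites)
  for (rg in names(haplotypes)) {
    h <- haplotypes[[rg]]
    for (j in seq_along(h$sites)) {
      ok <- h$alleles[, j] %in% dict[[as.character(h$sites[j])]]
      if (!all(ok))
        stop("reference integrity: allele outside site dictionary at ",
             h$sites[j], " (", rg, ")")
    }
  }

  popfreq <- list(promoter = tsv("popfreq_promoter.tsv"),
                  coding = tsv("popfreq_coding.tsv"),
                  utr3 = tsv("popfreq_utr3.tsv"))
  populations <- tsv("populations.tsv")

  extended <- tsv("hap_extended.tsv")
  extended$promoter_resolved <- promoter_alias(extended$promoter)

  ref <- structure(list(sites = sites, haplotypes = haplotypes,
                        popfreq = popfreq, populations = populations,
                        extended = extended),
                   class = "hlag_reference")
  extended$resolution <- vapply(seq_len(nrow(extended)), function(i) {
    ok <- c(resolve_name(extended$promoter_resolved[i],
                         rownames(haplotypes$promoter$alleles))$status,
            resolve_name(extended$coding[i],
                         rownames(haplotypes$coding$alleles))$status,
            resolve_name(extended$utr3[i],
                         rownames(haplotypes$utr3$alleles))$status)
    paste(ok, collapse = "/")
  }, character(1))
  ref$extended <- extended
  ref
}

# allele dictionary keyed by gene position (includes the optional third
# allele of the triallelic promoter site)
site_alleles <- function(sites) {
  dict <- list()
  for (s in sites) {
    for (i in seq_len(nrow(s))) {
      al <- c(s$ref[i], s$alt[i])
      if ("alt2" %in% names(s) && !is.na(s$alt2[i]) && s$alt2[i] != ".")
        al <- c(al, s$alt2[i])
      dict[[as.character(s$gene_pos[i])]] <- al
    }
  }
  dict
}

# the extended table prints promoter lineage names in a short form
promoter_alias <- function(x) {
  alias <- c("0104a" = "010104a", "0104b" = "010104b")
  ifelse(x %in% names(alias), alias[x], x)
}

# resolve a (possibly qualified) component name against a table's rows
resolve_name <- function(name, table_names) {
  if (name %in% table_names)
    return(list(base = name, qualifier = "exact", status = "exact"))
  if (grepl("-Like$", name)) {
    base <- sub("-Like$", "", name)
    if (base %in% table_names)
      return(list(base = base, qualifier = "like", status = "like"))
    return(list(base = base, qualifier = "like", status = "unresolved"))
  }
  if (grepl("(?i)unknown|new", name, perl = TRUE) &&
      !(name %in% table_names))
    return(list(base = name, qualifier = "new", status = "new"))
  list(base = name, qualifier = "exact", status = "unresolved")
}

#' The 133-site HLA-G variant panel
#'
#' @param ref Reference tables from [load_reference_tables()].
#' @return A data frame of the 133 analyzed sites (promoter, coding and
#'   3'UTR lists combined) ordered by gene position, with the per-site
#'   allele dictionary in a list column `alleles` and global allele
#'   frequencies in `freqs`.
#' @export
site_panel <- function(ref = load_reference_tables()) {
  rows <- lapply(names(ref$sites), function(rg) {
    s <- ref$sites[[rg]]
    data.frame(gene_pos = s$gene_pos, genomic_pos = s$genomic_pos,
               rsid = s$rsid, region = rg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_pos), ]
  rownames(out) <- NULL
  dict <- site_alleles(ref$sites)
  out$alleles <- dict[as.character(out$gene_pos)]
  out$freqs <- lapply(seq_len(nrow(out)), function(i) {
    rg <- out$region[i]
    s <- ref$sites[[rg]]
    j <- match(out$gene_pos[i], s$gene_pos)
    fq <- c(s$ref_freq[j], s$alt_freq[j])
    if ("alt2_freq" %in% names(s) && !is.na(s$alt2_freq[j]) &&
        s$alt2_freq[j] != ".")
      fq <- c(fq, as.numeric(s$alt2_freq[j]))
    as.numeric(fq)
  })
  out
}

#' Allele vectors of the extended reference haplotypes
#'
#' Joins the promoter, coding and 3'UTR reference tables by the component
#' names of the extended haplotype table, producing one allele vector per
#' extended haplotype over the union of the three regional haplotype site
#' lists (87 sites).  Only rows whose three components resolve exactly are
#' returned; `-Like`, `new` and unresolved components have no bundled
#' allele vector.
#'
#' @param ref Reference tables from [load_reference_tables()].
#' @return A list with `sites` (ordered gene positions) and `alleles`
#'   (matrix, one row per fully resolved extended haplotype, rownames are
#'   the extended labels).
#' @export
extended_allele_vectors <- function(ref = load_reference_tables()) {
  h <- ref$haplotypes
  ext <- ref$extended
  keep <- ext$resolution == "exact/exact/exact"
  sites <- c(h$promoter$sites, h$coding$sites, h$utr3$sites)
  region_of <- rep(c("promoter", "coding", "utr3"),
                   c(length(h$promoter$sites), length(h$coding$sites),
                     length(h$utr3$sites)))
  # +15 occurs in both the promoter and coding haplotype site lists; the
  # two tables agree there, keep the first occurrence
  first <- !duplicated(sites)
  ord <- order(sites[first])
  mat <- matrix(NA_character_, sum(keep), sum(first),
                dimnames = list(ext$label[keep],
                                sites[first][ord]))
  rows <- which(keep)
  for (k in seq_along(rows)) {
    i <- rows[k]
    vec <- c(h$promoter$alleles[ext$promoter_resolved[i], ],
             h$coding$alleles[ext$coding[i], ],
             h$utr3$alleles[ext$utr3[i], ])
    mat[k, ] <- vec[first][ord]
  }
  list(sites = sites[first][ord], alleles = mat)
}
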