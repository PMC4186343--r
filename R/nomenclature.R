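#' Assign nomenclature to haplotype allele vectors
#'
#' Matches each haplotype against a regional reference table (promoter,
#' coding or 3'UTR) and names it following the field's convention: an
#' exact allele-vector match takes the reference name; a vector at Hamming
#' distance exactly 1 from a unique nearest reference takes that name with
#' the suffix `-Like` (a "single nucleotide modification"); anything
#' further away is `new` and receives a deterministic identifier
#' (`<region>.new<ordinal>` by first occurrence, so repeated runs produce
#' identical names).  When two references are equidistant at distance 1,
#' the tie is broken by the higher reference global frequency, then by
#' name order; the tie is recorded in the output.
#'
#' Hamming distance counts sites, not nucleotides: an indel allele (for
#' instance the 14-bp insertion) differing from the reference counts as
#' one mismatch here, regardless of its length.
#'
#' @param haplotypes A character matrix (rows = haplotypes, columns in the
#'   order of the table's site list) or a single character vector.
#' @param table One regional entry of
#'   `load_reference_tables()$haplotypes`, i.e. a list with `sites`,
#'   `alleles` and `global_freq`.
#' @param region Prefix used for names of new haplotypes.
#' @return A data frame with columns `name`, `base`, `qualifier`
#'   (exact/like/new), `distance`, `tied` (TRUE when a distance-1 tie was
#'   broken by frequency/name order).
#' @export
#' @examples
#' ref <- load_reference_tables()
#' classify_haplotype(ref$haplotypes$utr3$alleles["UTR-2", ],
#'                    ref$haplotypes$utr3)
classify_haplotype <- function(haplotypes, table, region = "hap") {
  if (is.null(dim(haplotypes)))
    haplotypes <- matrix(haplotypes, nrow = 1)
  if (ncol(haplotypes) != length(table$sites))
    stop("haplotype length ", ncol(haplotypes),
         " does not match the table's site list (", length(table$sites), ")")
  if (any(is.na(haplotypes)))
    stop("haplotypes with missing alleles cannot be named; impute first")

  refs <- table$alleles
  freqs <- table$global_freq[rownames(refs)]
  n <- nrow(haplotypes)
  out <- data.frame(name = character(n), base = character(n),
                    qualifier = character(n), distance = integer(n),
                    tied = logical(n), stringsAsFactors = FALSE)
  new_seen <- character(0)

  for (i in seq_len(n)) {
    d <- colSums(t(refs) != haplotypes[i, ])
    dmin <- min(d)
    if (dmin == 0L) {
      j <- which(d == 0L)[1]
      out[i, ] <- list(rownames(refs)[j], rownames(refs)[j], "exact", 0L,
                       FALSE)
    } else if (dmin == 1L) {
      cand <- which(d == 1L)
      tied <- length(cand) > 1L
      ord <- order(-freqs[cand], rownames(refs)[cand])
      j <- cand[ord[1]]
      base <- rownames(refs)[j]
      out[i, ] <- list(paste0(base, "-Like"), base, "like", 1L, tied)
    } else {
      key <- paste(haplotypes[i, ], collapse = "|")
      k <- match(key, new_seen)
      if (is.na(k)) {
        new_seen <- c(new_seen, key)
        k <- length(new_seen)
      }
      nm <- paste0(region, ".new", k)
      out[i, ] <- list(nm, nm, "new", as.integer(dmin), FALSE)
    }
  }
  out
}

#' Label an extended haplotype from its regional component names
#'
#' Joins promoter, coding and 3'UTR component names into the slash-joined
#' extended label (`G<promoter>/<coding>/<utr>`) and looks up the HG
#' lineage from the bundled extended haplotype table when the triple
#' matches one of its rows (short-form promoter aliases are accepted);
#' unseen triples are labelled but carry no lineage.
#'
#' @param promoter,coding,utr Component names (exact, `-Like` or new names
#'   are all accepted).
#' @param ref Reference tables from [load_reference_tables()].
#' @return A data frame with columns `label` and `lineage` (NA when the
#'   triple is not in the bundled table).
#' @export
#' @examples
#' name_extended("010101a", "G*01:01:01:01", "UTR-1")$lineage  # HG010101a
name_extended <- function(promoter, coding, utr,
                          ref = load_reference_tables()) {
  stopifnot(length(promoter) == length(coding),
            length(coding) == length(utr))
  ext <- ref$extended
  key <- paste(promoter_alias(promoter), coding, utr, sep = "/")
  ext_key <- paste(ext$promoter_resolved, ext$coding, ext$utr3, sep = "/")
  j <- match(key, ext_key)
  data.frame(label = paste0("G", promoter, "/", coding, "/", utr),
             lineage = ifelse(is.na(j), NA_character_, ext$lineage[j]),
             stringsAsFactors = FALSE)
}
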