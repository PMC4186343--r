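#' HLA-G gene model
#'
#' Builds the locus model of the HLA-G gene (6p21.3): eight exons and seven
#' introns spanning 4144 nucleotides, anchored on a CDS-relative coordinate
#' system in which the adenine of the main translation-start ATG is position
#' +1 and the base immediately upstream is -1 (there is no position 0).
#' Positions are interconvertible with 1-based hg19 genomic coordinates.
#'
#' The coding sequence (1017 nt, 339 codons including the stop) is spliced
#' from six exons: the last 73 nt of exon 2 (which also carries 112 nt of
#' 5'UTR and encodes the 24-codon leader peptide), exons 3-6 in full, and
#' the first 5 nt of exon 7, whose stop codon occupies gene positions
#' +2536..+2538.  The remainder of exon 7 and all of exon 8 form the 3'UTR.
#' Exon/intron numbering follows NCBI/Ensembl; the IMGT numbering (shifted
#' by one because IMGT starts at the first translated exon) is carried as an
#' alias column.
#'
#' @return An object of class `hlag_gene_model`: a data frame of segments
#'   (`name`, `imgt_alias`, `role`, `length`, `gene_start`, `gene_end`,
#'   `cds_start`, `cds_end`) with attributes `anchor` (hg19 coordinate of
#'   gene position +1), `leader_codons` (24), `exon2_coding` (73),
#'   `cds_length` (1017) and `span` (gene positions covered by segments).
#' @export
#' @examples
#' m <- build_gene_model()
#' sum(m$length)  # 4144
build_gene_model <- function() {
  segs <- data.frame(
    name = c("exon1", "intron1", "exon2", "intron2", "exon3", "intron3",
             "exon4", "intron4", "exon5", "intron5", "exon6", "intron6",
             "exon7", "intron7", "exon8"),
    imgt_alias = c(NA, NA, "exon1", "intron1", "exon2", "intron2", "exon3",
                   "intron3", "exon4", "intron4", "exon5", "intron5",
                   "exon6", NA, NA),
    role = c("exon", "intron", "exon", "intron", "exon", "intron", "exon",
             "intron", "exon", "intron", "exon", "intron", "exon", "intron",
             "exon"),
    length = c(66L, 688L, 185L, 129L, 270L, 226L, 276L, 599L, 276L, 122L,
               117L, 445L, 33L, 357L, 355L),
    stringsAsFactors = FALSE
  )

  total <- sum(segs$length)
  if (total != 4144L)
    stop("gene model integrity: segment lengths sum to ", total,
         ", expected 4144")

  # Segment limits on the CDS-anchored axis.  Exon 2 contributes its last
  # 73 nt to the CDS, so it spans -112..+73 and everything upstream follows
  # by cumulative lengths: intron 1 ends at -113, exon 1 starts at -866.
  exon2_coding <- 73L
  ofs_start <- cumsum(c(0L, segs$length[-nrow(segs)])) + 1L
  ofs_end <- cumsum(segs$length)
  # offset 1 corresponds to gene position -866 (start of exon 1)
  upstream <- 866L
  ofs_to_gene <- function(o) ifelse(o <= upstream, o - upstream - 1L,
                                    o - upstream)
  segs$gene_start <- ofs_to_gene(ofs_start)
  segs$gene_end <- ofs_to_gene(ofs_end)

  # coding stretch of each exon (gene positions), NA for non-coding pieces
  coding <- data.frame(
    name = c("exon2", "exon3", "exon4", "exon5", "exon6", "exon7"),
    start = c(1L, 203L, 699L, 1574L, 1972L, 2534L),
    len = c(73L, 270L, 276L, 276L, 117L, 5L),
    stringsAsFactors = FALSE
  )
  coding$cds_start <- cumsum(c(0L, coding$len[-6])) + 1L
  coding$cds_end <- cumsum(coding$len)
  cds_length <- sum(coding$len)

  utr5 <- 66L + (185L - exon2_coding)
  utr3 <- (33L - 5L) + 355L
  if (utr5 != 178L)
    stop("gene model integrity: 5'UTR length ", utr5, ", expected 178")
  if (cds_length != 1017L)
    stop("gene model integrity: CDS length ", cds_length, ", expected 1017")
  if (utr3 != 383L)
    stop("gene model integrity: 3'UTR length ", utr3, ", expected 383")

  segs$cds_start <- coding$cds_start[match(segs$name, coding$name)]
  segs$cds_end <- coding$cds_end[match(segs$name, coding$name)]

  structure(segs,
            anchor = 29795622L,
            indel14_after = 2960L,
            leader_codons = 24L,
            exon2_coding = exon2_coding,
            cds_length = cds_length,
            coding_segments = coding,
            span = c(-866L, 3278L),
            upstream_limit = -1500L,
            class = c("hlag_gene_model", "data.frame"))
}

check_gene_pos <- function(p) {
  if (any(!is.finite(p)) || any(p != trunc(p)))
    stop("gene positions must be integers")
  if (any(p == 0))
    stop("gene position 0 does not exist: -1 and +1 are adjacent")
  as.integer(p)
}

#' Convert CDS-anchored gene positions to hg19 coordinates
#'
#' Position +1 maps to the anchor coordinate 29795622; positive positions
#' map to `anchor - 1 + p` and negative ones to `anchor + p`, so the axis
#' has no zero and round-trips exactly with [genomic_to_gene()].
#'
#' One wrinkle: the 14-bp 3'UTR insertion allele (after gene position
#' +2960) is regarded as ancestral and is counted in the gene numbering,
#' but it is absent from the hg19 reference.  Gene positions beyond the
#' inserted segment are therefore shifted by 14 relative to hg19 (e.g.
#' +3003 maps to 29798610, not 29798624), and the 14 inserted positions
#' +2961..+2974 have no hg19 coordinate at all.
#'
#' @param p Integer vector of nonzero gene positions.
#' @param model A gene model from [build_gene_model()].
#' @return Integer vector of 1-based hg19 coordinates on chromosome 6.
#' @export
#' @examples
#' gene_to_genomic(15)     # 29795636
#' gene_to_genomic(-1305)  # 29794317
gene_to_genomic <- function(p, model = build_gene_model()) {
  p <- check_gene_pos(p)
  lo <- attr(model, "upstream_limit")
  hi <- attr(model, "span")[2]
  if (any(p < lo | p > hi))
    stop("gene position outside the modeled locus span (", lo, "..", hi, ")")
  ins <- attr(model, "indel14_after")
  if (any(p > ins & p <= ins + 14L))
    stop("positions ", ins + 1L, "..", ins + 14L,
         " lie inside the 14-bp insertion and have no hg19 coordinate")
  anchor <- attr(model, "anchor")
  ifelse(p > ins + 14L, anchor - 1L + p - 14L,
         ifelse(p > 0, anchor - 1L + p, anchor + p))
}

#' @rdname gene_to_genomic
#' @param g Integer vector of hg19 coordinates within the locus span.
#' @export
genomic_to_gene <- function(g, model = build_gene_model()) {
  anchor <- attr(model, "anchor")
  lo <- anchor + attr(model, "upstream_limit")
  hi <- anchor - 1L + attr(model, "span")[2] - 14L
  if (any(!is.finite(g)) || any(g != trunc(g)))
    stop("genomic coordinates must be integers")
  if (any(g < lo | g > hi))
    stop("genomic coordinate outside the modeled locus span")
  g <- as.integer(g)
  ins <- attr(model, "indel14_after")
  q <- ifelse(g >= anchor, g - anchor + 1L, g - anchor)
  ifelse(q > ins, q + 14L, q)
}

#' Locate a gene position within the locus structure
#'
#' Maps CDS-anchored positions to their segment (exon/intron), functional
#' region, and --- for coding positions --- the CDS offset, CDS codon,
#' codon phase and mature-protein codon.  Mature-protein numbering follows
#' HLA convention: codons are counted after removal of the 24-residue
#' leader peptide, so CDS codon 134 is mature codon 110.
#'
#' @param p Integer vector of nonzero gene positions; positions upstream of
#'   exon 1 (below -866) are reported as region `"promoter"`.
#' @param model A gene model from [build_gene_model()].
#' @return A data frame with one row per position: `gene_pos`, `region`
#'   (one of promoter, 5UTR, coding, intron, 3UTR), `segment`,
#'   `cds_pos`, `cds_codon`, `mature_codon`, `codon_phase` (coding rows
#'   only, otherwise NA).
#' @export
#' @examples
#' locate_site(c(755, 1799))$mature_codon  # 110, 258
locate_site <- function(p, model = build_gene_model()) {
  p <- check_gene_pos(p)
  lo <- attr(model, "upstream_limit")
  hi <- attr(model, "span")[2]
  if (any(p < lo | p > hi))
    stop("gene position outside the modeled locus span (", lo, "..", hi, ")")

  leader <- attr(model, "leader_codons")
  coding <- attr(model, "coding_segments")
  out <- data.frame(gene_pos = p, region = NA_character_,
                    segment = NA_character_, cds_pos = NA_integer_,
                    cds_codon = NA_integer_, mature_codon = NA_integer_,
                    codon_phase = NA_integer_, stringsAsFactors = FALSE)

  for (i in seq_along(p)) {
    pos <- p[i]
    if (pos < model$gene_start[1]) {
      out$region[i] <- "promoter"
      out$segment[i] <- "upstream"
      next
    }
    j <- which(model$gene_start <= pos & model$gene_end >= pos)
    stopifnot(length(j) == 1L)
    out$segment[i] <- model$name[j]
    if (model$role[j] == "intron") {
      out$region[i] <- "intron"
      next
    }
    k <- match(model$name[j], coding$name)
    if (!is.na(k) && pos >= coding$start[k] &&
        pos <= coding$start[k] + coding$len[k] - 1L) {
      cds <- coding$cds_start[k] + (pos - coding$start[k])
      out$region[i] <- "coding"
      out$cds_pos[i] <- cds
      out$cds_codon[i] <- (cds - 1L) %/% 3L + 1L
      out$mature_codon[i] <- out$cds_codon[i] - leader
      out$codon_phase[i] <- (cds - 1L) %% 3L + 1L
    } else {
      out$region[i] <- if (pos < 1L) "5UTR" else "3UTR"
    }
  }
  out
}

#' Classify the functional effect of a variant
#'
#' Assigns an effect class to a ref/alt allele pair at a gene position:
#' `intronic` (or `splice_acceptor` / `splice_donor` within the terminal
#' dinucleotides of an intron, the canonical AG/GT signals), `utr` for any
#' non-coding transcribed or upstream regulatory position, `frameshift` for
#' coding indels whose length difference is not a multiple of 3, and ---
#' when a CDS reference sequence is supplied --- `synonymous`,
#' `non_synonymous` or `stop_gained` by codon substitution.  Coding SNVs
#' without a CDS sequence degrade to `indeterminate` rather than failing.
#'
#' @param p A single nonzero gene position.
#' @param ref,alt Reference and alternative allele strings (A/C/G/T runs).
#' @param model A gene model from [build_gene_model()].
#' @param cds_sequence Optional character vector of 1017 single bases (or a
#'   single 1017-character string) giving the coding sequence carrying the
#'   reference alleles.
#' @return A single effect string.
#' @export
classify_effect <- function(p, ref, alt, model = build_gene_model(),
                            cds_sequence = NULL) {
  stopifnot(length(p) == 1L, length(ref) == 1L, length(alt) == 1L)
  if (!nzchar(ref) || !nzchar(alt) ||
      grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be non-empty A/C/G/T strings")
  loc <- locate_site(p, model)

  # everything upstream of the CDS is treated as regulatory (promoter /
  # 5'UTR), following the convention that all variants before the main
  # translation start are promoter-region variants; splice classes apply
  # only to the introns interrupting the CDS
  if (p < 1L || loc$region %in% c("promoter", "5UTR", "3UTR"))
    return("utr")

  if (loc$region == "intron") {
    j <- match(loc$segment, model$name)
    if (p >= model$gene_end[j] - 1L) return("splice_acceptor")
    if (p <= model$gene_start[j] + 1L) return("splice_donor")
    return("intronic")
  }

  # coding exon
  dlen <- nchar(ref) - nchar(alt)
  if (dlen != 0L) {
    if (dlen %% 3L != 0L) return("frameshift")
    return("indeterminate")  # in-frame indel: not resolved further
  }
  if (nchar(ref) != 1L) return("indeterminate")
  if (is.null(cds_sequence)) return("indeterminate")

  cds <- cds_sequence
  if (length(cds) == 1L && nchar(cds) > 1L)
    cds <- strsplit(cds, "")[[1]]
  cds <- toupper(cds)
  if (length(cds) != attr(model, "cds_length"))
    stop("cds_sequence must have length ", attr(model, "cds_length"))

  i <- loc$cds_pos
  codon_start <- (loc$cds_codon - 1L) * 3L + 1L
  ref_codon <- cds[codon_start:(codon_start + 2L)]
  alt_codon <- ref_codon
  alt_codon[loc$codon_phase] <- alt
  aa_ref <- translate_codon(paste(ref_codon, collapse = ""))
  aa_alt <- translate_codon(paste(alt_codon, collapse = ""))
  if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
  if (aa_ref == aa_alt) return("synonymous")
  "non_synonymous"
}

# standard genetic code, stops as "*"
translate_codon <- function(codon) {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa <- code[[toupper(codon)]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

#' Read a CDS reference sequence from FASTA
#'
#' Thin wrapper around `seqinr::read.fasta` returning the first record as
#' an upper-case character vector of single bases.
#'
#' @param path Path to a FASTA file whose first record is the 1017-nt CDS.
#' @return Character vector of single bases.
#' @export
read_cds_fasta <- function(path) {
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("reading FASTA requires the 'seqinr' package")
  toupper(as.character(seqinr::read.fasta(path)[[1]]))
}
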