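test_that("gene model satisfies the published structural invariants", {
  m <- build_gene_model()
  expect_equal(sum(m$length), 4144L)
  expect_equal(nrow(m), 15L)
  # 5'UTR = exon 1 + non-coding exon 2; CDS from six exons; 3'UTR from
  # the post-stop tail of exon 7 plus exon 8
  expect_equal(66L + 185L - attr(m, "exon2_coding"), 178L)
  expect_equal(attr(m, "cds_length"), 1017L)
  expect_equal((33L - 5L) + 355L, 383L)
  expect_equal(m$length[m$name == "exon7"], 33L)
  expect_equal(m$length[m$name == "exon8"], 355L)
  # coding part of exon 7 is 5 nt, so the stop codon sits at +2536..+2538
  cs <- attr(m, "coding_segments")
  expect_equal(cs$len[cs$name == "exon7"], 5L)
  stop_codon <- locate_site(c(2536, 2537, 2538))
  expect_equal(stop_codon$cds_pos, c(1015L, 1016L, 1017L))
  expect_equal(unique(stop_codon$cds_codon), 339L)
})

test_that("segment boundaries follow the cumulative segment lengths", {
  m <- build_gene_model()
  seg_of <- function(p) locate_site(p)$segment
  expect_equal(seg_of(-866), "exon1")
  expect_equal(seg_of(-801), "exon1")
  expect_equal(seg_of(-800), "intron1")
  expect_equal(seg_of(-112), "exon2")
  expect_equal(seg_of(73), "exon2")
  expect_equal(seg_of(74), "intron2")
  expect_equal(seg_of(202), "intron2")
  expect_equal(seg_of(203), "exon3")
  expect_equal(seg_of(472), "exon3")
  expect_equal(seg_of(699), "exon4")
  expect_equal(seg_of(974), "exon4")
  expect_equal(seg_of(1574), "exon5")
  expect_equal(seg_of(1849), "exon5")
  expect_equal(seg_of(1972), "exon6")
  expect_equal(seg_of(2088), "exon6")
  expect_equal(seg_of(2534), "exon7")
  expect_equal(seg_of(2566), "exon7")
  expect_equal(seg_of(2924), "exon8")
  expect_equal(seg_of(3278), "exon8")
  # region classes across the same boundaries
  expect_equal(locate_site(-867)$region, "promoter")  # upstream of exon 1
  expect_equal(locate_site(-500)$region, "intron")    # intron 1
  expect_equal(locate_site(-1000)$region, "promoter")
  expect_equal(locate_site(-50)$region, "5UTR")
  expect_equal(locate_site(2539)$region, "3UTR")
})

test_that("codon mapping reproduces the published anchors", {
  loc <- locate_site(c(755, 1799, 292, 813))
  expect_equal(loc$cds_pos, c(400L, 845L, 163L, 458L))
  expect_equal(loc$mature_codon, c(110L, 258L, 31L, 129L))
  expect_equal(locate_site(99)$region, "intron")
})

test_that("coordinate conversion matches printed pairs and round-trips", {
  expect_equal(gene_to_genomic(15), 29795636L)
  expect_equal(gene_to_genomic(-1305), 29794317L)
  expect_equal(gene_to_genomic(2960), 29798581L)
  # positions downstream of the (ancestral, hg19-absent) 14-bp insertion
  # shift by 14 relative to hg19
  expect_equal(gene_to_genomic(3003), 29798610L)
  expect_equal(gene_to_genomic(3227), 29798834L)
  expect_error(gene_to_genomic(0), "position 0")
  expect_error(gene_to_genomic(2965), "14-bp insertion")
  expect_error(genomic_to_gene(29790000), "span")

  p <- c(-1500:-1, 1:2960, 2975:3278)
  expect_equal(genomic_to_gene(gene_to_genomic(p)), p)
})

test_that("all 133 bundled site rows round-trip to their hg19 coordinates", {
  ref <- ref_cache()
  for (rg in names(ref$sites)) {
    s <- ref$sites[[rg]]
    expect_equal(gene_to_genomic(s$gene_pos), s$genomic_pos,
                 info = rg)
    expect_equal(genomic_to_gene(s$genomic_pos), s$gene_pos,
                 info = rg)
  }
  expect_equal(sum(vapply(ref$sites, nrow, integer(1))), 133L)
})

test_that("printed coding-region annotations agree with the gene model", {
  s <- ref_cache()$sites$coding
  loc <- locate_site(s$gene_pos)
  expect_true(all(loc$region[s$annotation == "Intronic"] == "intron"))
  coding_ann <- s$annotation %in% c("Synonymous", "Non-synonymous",
                                    "Frame Shift")
  expect_true(all(loc$region[coding_ann] == "coding"))
  # the single splice-acceptor row sits in an intron's last dinucleotide
  sp <- s$gene_pos[s$annotation == "Splice site acceptor"]
  expect_equal(sp, 201L)
  expect_equal(classify_effect(sp, "A", "G"), "splice_acceptor")
  # 70 of the 81 sites are intronic or synonymous
  expect_equal(sum(s$annotation %in% c("Intronic", "Synonymous")), 70L)
  expect_equal(nrow(s), 81L)
})

test_that("effect classification handles indels, splice sites and UTRs", {
  expect_equal(classify_effect(813, "AC", "A"), "frameshift")
  expect_equal(classify_effect(1574, "A", "AC"), "frameshift")
  expect_equal(classify_effect(2942, "T", "C"), "utr")
  expect_equal(classify_effect(-725, "C", "G"), "utr")
  expect_equal(classify_effect(126, "G", "C"), "intronic")
  expect_equal(classify_effect(505, "A", "AC"), "intronic")
  # donor side: first two intron bases
  expect_equal(classify_effect(74, "A", "G"), "splice_donor")
  expect_equal(classify_effect(202, "A", "G"), "splice_acceptor")
  expect_error(classify_effect(15, "", "A"), "alleles")
  expect_error(classify_effect(15, "G", "X"), "alleles")
})

test_that("codon substitution decides synonymous/non-synonymous/stop", {
  cds <- rep("A", 1017)
  # codon 134 = CDS 400..402; make it CTC (Leu); +755 is its first base
  cds[400:402] <- c("C", "T", "C")
  expect_equal(classify_effect(755, "C", "A", cds_sequence = cds),
               "non_synonymous")  # CTC -> ATC, Leu -> Ile
  expect_equal(classify_effect(757, "C", "G", cds_sequence = cds),
               "synonymous")      # CTC -> CTG, both Leu (third base)
  cds3 <- rep("A", 1017)
  cds3[400:402] <- c("T", "A", "C")  # Tyr
  expect_equal(classify_effect(757, "C", "A", cds_sequence = cds3),
               "stop_gained")     # TAC -> TAA
  # without a CDS sequence the call degrades, never fails
  expect_equal(classify_effect(755, "C", "A"), "indeterminate")
  expect_error(classify_effect(755, "C", "A", cds_sequence = rep("A", 10)),
               "1017")
})
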