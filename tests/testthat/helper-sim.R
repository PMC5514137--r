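# Shared simulated study, built once per test run. Two 500-kb chromosomes,
# 40 genes, 3 genotypes at a 1% variant rate keep the suite fast while
# leaving every stage non-trivial.
.studyCache <- new.env()

sharedStudy <- function() {
  if (!is.null(.studyCache$study)) return(.studyCache$study)
  spec <- simulationSpec(rngSeed = 42, nChromosomes = 2,
                         chromosomeLength = 5e5, nGenes = 40,
                         nGenotypes = 3, variantRate = 0.01,
                         snpIndelRatio = 12, hetFraction = 0.6,
                         nFixedBlocks = 1, blockLength = 1e5,
                         nPavGenes = 4)
  ref <- simulateReference(spec)
  vars <- simulateVariants(ref, spec)
  .studyCache$study <- list(spec = spec, ref = ref, vars = vars,
                            chromLengths = stats::setNames(
                              Biostrings::width(ref$genome),
                              names(ref$genome)))
  .studyCache$study
}

# Independent oracle for CDS SNP classification: rebuild the entire mutant
# coding sequence, translate reference and mutant proteins codon by codon
# with the standard code, and classify from the first differing residue.
# Shares no code with classifyCdsVariant beyond the genome object.
oracleCdsClass <- function(chrom, pos, refBase, altBase, txId, gms, genome) {
  tx <- as.data.frame(transcriptInfo(gms))
  cds <- cdsIntervals(gms)[[txId]]
  strand <- tx$strand[tx$tx_id == txId]
  st <- BiocGenerics::start(cds); en <- BiocGenerics::end(cds)
  full <- paste(vapply(seq_along(cds), function(i)
    as.character(Biostrings::subseq(genome[[chrom]], st[i], en[i])),
    character(1)), collapse = "")
  cum <- cumsum(en - st + 1)
  iv <- which(pos >= st & pos <= en)
  fwd <- (if (iv > 1) cum[iv - 1] else 0) + pos - st[iv] + 1
  mut <- full
  substr(mut, fwd, fwd) <- altBase
  if (strand == "-") {
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    full <- rc(full); mut <- rc(mut)
  }
  tr <- function(s) vapply(seq_len(nchar(s) / 3), function(k)
    Biostrings::GENETIC_CODE[[substr(s, 3 * k - 2, 3 * k)]], character(1))
  p0 <- tr(full); p1 <- tr(mut)
  if (identical(p0, p1)) return("synonymous")
  k <- which(p0 != p1)[1]
  if (p0[k] == "*") return("stop_lost")
  if (p1[k] == "*") return("nonsense")
  if (k == 1 && p0[k] == "M") return("start_lost")
  "missense"
}

# A tiny hand-built gene-model fixture with a true UTR: exon 101-220,
# CDS 131-190 (60 bp), intron 221-320, second exon 321-380 all CDS-free.
utrFixture <- function() {
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                              strand = "+")
  new("GeneModelSet",
      transcripts = S4Vectors::DataFrame(tx_id = "t1", gene_id = "g1",
                                         chrom = "chr1", strand = "+"),
      cds = GenomicRanges::GRangesList(t1 = gr(c(131, 331), c(190, 390))),
      exons = GenomicRanges::GRangesList(t1 = gr(c(101, 321), c(220, 400))))
}
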