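.vsAt <- function(pos, ref = "A", alt = "T", zyg = "het") {
  variantSet("g", data.frame(chrom = "chr1", pos = pos, ref = ref,
                             alt = alt, zygosity = zyg, qual = 50,
                             depth = 50), 1e6)
}

test_that("region assignment follows the CDS > UTR > splice > intron order", {
  gms <- utrFixture()  # exon 101-220/321-400, CDS 131-190/331-390
  pos <- c(110,  # 5' UTR
           150,  # CDS
           200,  # 3' UTR of exon 1
           222,  # 2 bp into the intron: splice donor
           250,  # deep intron
           319,  # 2 bp before intron end: splice acceptor
           50000)  # far away
  vs <- .vsAt(pos)
  expect_equal(assignRegion(vs, gms),
               c("UTR", "CDS", "UTR", "splice_site", "intron",
                 "splice_site", "intergenic"))
  # a chromosome with no models warns and yields intergenic
  off <- variantSet("g", data.frame(chrom = "chrX", pos = 5, ref = "A",
                                    alt = "T", zygosity = "het", qual = 50,
                                    depth = 50), 1e6)
  suppressWarnings(expect_warning(reg <- assignRegion(off, gms), "chrX"))
  expect_equal(reg, "intergenic")
})

test_that("codon-level classification: degenerate, nonsense and frameshift", {
  # hand-built gene: chr1 1..12, + strand, CDS = ATG GAA TGG TAA
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGGAATGGTAA"))
  gms <- new("GeneModelSet",
    transcripts = S4Vectors::DataFrame(tx_id = "t1", gene_id = "g1",
                                       chrom = "chr1", strand = "+"),
    cds = GenomicRanges::GRangesList(
      t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                                  strand = "+")),
    exons = GenomicRanges::GRangesList(
      t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                                  strand = "+")))
  # GAA -> GAG : third-position change, synonymous (Glu)
  expect_equal(classifyCdsVariant("chr1", 6, "A", "G", "t1", gms, genome),
               "synonymous")
  # TGG -> TGA : tryptophan codon to stop
  expect_equal(classifyCdsVariant("chr1", 9, "G", "A", "t1", gms, genome),
               "nonsense")
  # GAA -> GTA : missense (Glu -> Val)
  expect_equal(classifyCdsVariant("chr1", 5, "A", "T", "t1", gms, genome),
               "missense")
  # stop codon TAA -> CAA : stop lost
  expect_equal(classifyCdsVariant("chr1", 10, "T", "C", "t1", gms, genome),
               "stop_lost")
  # start codon ATG -> CTG : start lost
  expect_equal(classifyCdsVariant("chr1", 1, "A", "C", "t1", gms, genome),
               "start_lost")
  # 2-bp deletion shifts the frame; 3-bp deletion does not
  expect_equal(classifyCdsVariant("chr1", 4, "GAA", "G", "t1", gms, genome),
               "frameshift")
  expect_equal(classifyCdsVariant("chr1", 3, "GGAA", "G", "t1", gms, genome),
               "inframe_indel")
  # mismatching REF against the genome is caught
  expect_error(classifyCdsVariant("chr1", 6, "C", "G", "t1", gms, genome),
               "mismatch")
})

test_that("minus-strand codons are rebuilt on the coding strand", {
  # genomic TTACCATTCCAT is revcomp of ATGGAATGGTAA
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTACCATTCCAT"))
  gms <- new("GeneModelSet",
    transcripts = S4Vectors::DataFrame(tx_id = "t1", gene_id = "g1",
                                       chrom = "chr1", strand = "-"),
    cds = GenomicRanges::GRangesList(
      t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                                  strand = "-")),
    exons = GenomicRanges::GRangesList(
      t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                                  strand = "-")))
  # genomic pos 7 (T) is coding pos 6 (A of GAA); T->C genomic = A->G coding
  expect_equal(classifyCdsVariant("chr1", 7, "T", "C", "t1", gms, genome),
               "synonymous")
  # genomic pos 4 (C) is coding pos 9 (G of TGG); C->T genomic = G->A coding
  expect_equal(classifyCdsVariant("chr1", 4, "C", "T", "t1", gms, genome),
               "nonsense")
})

test_that("impact tiers are a total function of region and class", {
  regions <- c("CDS", "UTR", "splice_site", "intron", "intergenic")
  classes <- c("synonymous", "missense", "nonsense", "stop_lost",
               "start_lost", "frameshift", "inframe_indel", "none")
  grid <- expand.grid(region = regions, class = classes,
                      stringsAsFactors = FALSE)
  imp <- assignImpact(grid$region, grid$class)
  expect_true(all(imp %in% c("high", "moderate", "low", "modifier")))
  expect_equal(assignImpact("CDS", "synonymous"), "low")
  expect_equal(assignImpact("CDS", "missense"), "moderate")
  expect_equal(assignImpact("CDS", "inframe_indel"), "moderate")
  expect_equal(assignImpact("intron", "none"), "modifier")
  expect_equal(assignImpact("UTR", "none"), "modifier")
  expect_equal(assignImpact("intergenic", "none"), "modifier")
  expect_equal(assignImpact("splice_site", "none"), "high")
  for (cl in c("nonsense", "stop_lost", "start_lost", "frameshift"))
    expect_equal(assignImpact("CDS", cl), "high")
})

test_that("effect fractions sum to one per zygosity subset", {
  ann <- data.frame(
    chrom = "chr1", pos = 1:10, ref = "A", alt = "T",
    zygosity = c(rep("hom", 10)),
    region = c(rep("intergenic", 9), "CDS"),
    class = c(rep("none", 9), "missense"))
  ann$impact <- assignImpact(ann$region, ann$class)
  se <- summarizeEffects(ann)
  expect_equal(unname(se$hom$byImpact[["modifier"]]), 0.9)
  expect_equal(unname(se$hom$byImpact[["moderate"]]), 0.1)
  expect_equal(length(se$het$byImpact), 0L)  # empty het subset
  expect_equal(sum(se$hom$byImpact), 1)
  expect_equal(sum(se$hom$byRegion), 1)
})

test_that("annotation of simulated variants matches an independent tally", {
  st <- sharedStudy()
  vs <- filterVariants(st$vars$variantSets[[1]])
  ann <- annotateVariants(vs, st$ref$models, st$ref$genome)
  expect_equal(nrow(ann), length(vs))
  for (zyg in c("hom", "het")) {
    sub <- ann[ann$zygosity == zyg, ]
    se <- summarizeEffects(ann)[[zyg]]
    # brute-force recount
    expect_equal(unname(se$byImpact[["modifier"]]),
                 mean(sub$impact == "modifier"))
    expect_equal(sum(se$byImpact), 1, tolerance = 1e-12)
    expect_equal(sum(se$byRegion), 1, tolerance = 1e-12)
  }
  # every CDS SNP classification agrees with the full-translation oracle
  cdsSnps <- which(ann$region == "CDS" & nchar(ann$ref) == 1 &
                     nchar(ann$alt) == 1)
  cds <- cdsIntervals(st$ref$models)
  cdsAll <- unlist(cds)
  txOf <- rep(names(cds), lengths(cds))
  for (i in cdsSnps) {
    hit <- which(as.character(GenomeInfoDb::seqnames(cdsAll)) == ann$chrom[i] &
                   ann$pos[i] >= BiocGenerics::start(cdsAll) &
                   ann$pos[i] <= BiocGenerics::end(cdsAll))
    want <- vapply(unique(txOf[hit]), function(tx)
      oracleCdsClass(ann$chrom[i], ann$pos[i], ann$ref[i], ann$alt[i], tx,
                     st$ref$models, st$ref$genome), character(1))
    expect_true(ann$class[i] %in% want)
  }
})

test_that("pathway deleterious aggregation reproduces published fractions", {
  cqa <- data.frame(pathway = "CQA", variant_id = paste0("v", 1:33),
                    score = c(rep(-3.1, 10), rep(-1, 23)))
  sl <- data.frame(pathway = "SL", variant_id = paste0("w", 1:417),
                   score = c(rep(-4, 83), rep(0.5, 334)))
  res <- flagDeleterious(rbind(cqa, sl))
  expect_equal(res$pct[res$pathway == "CQA"], 30.3)
  expect_equal(res$n_deleterious[res$pathway == "CQA"], 10)
  expect_equal(res$pct[res$pathway == "SL"], 19.9)

  # the -2.5 boundary itself is deleterious; missing scores are excluded
  b <- data.frame(pathway = "P", variant_id = c("a", "b", "c"),
                  score = c(-2.5, -2.49, NA))
  expect_warning(rb <- flagDeleterious(b), "without a score")
  expect_equal(rb$n, 2)
  expect_equal(rb$n_deleterious, 1)
  expect_equal(rb$n_missing_score, 1)
})
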