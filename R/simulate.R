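#' Simulation parameters for a synthetic resequencing study
#'
#' Defines the statistical structure of a simulated multi-genotype
#' resequencing experiment: genome size and GC content, gene count,
#' per-genotype variant rate with a fixed SNP:indel ratio, heterozygous
#' fraction, planted homozygous-fixed chromosomal blocks, planted
#' absent (PAV) genes with Poisson read counts, and domain
#' architectures drawn from the published combination table.
#'
#' Defaults mirror the study conditions the generator emulates: GC 35%,
#' a 2% per-bp variant rate, a 12:1 SNP:indel ratio, five resequenced
#' genotypes with ~60% heterozygous calls, and per-gene mean read
#' counts of 100 against Poisson(0.5) for absent genes.
#'
#' @slot nChromosomes,chromosomeLength genome shape.
#' @slot gcFraction target G+C fraction of the simulated reference.
#' @slot nGenes number of non-overlapping gene models to place.
#' @slot nGenotypes number of resequenced genotypes.
#' @slot variantRate expected variants per bp per genotype.
#' @slot snpIndelRatio expected ratio of SNP to indel counts.
#' @slot hetFraction fraction of variant calls that are heterozygous
#'   (outside fixed blocks).
#' @slot nFixedBlocks,blockLength homozygous-fixed regions planted per
#'   genotype: all variants emitted inside them are homozygous.
#' @slot nPavGenes genes planted absent per genotype.
#' @slot filterViolationFraction fraction of records drawn with QUAL or
#'   depth outside the filter bounds, to exercise the filter.
#' @slot meanGeneReadCount Poisson mean of per-gene read counts for
#'   present genes at unit library factor.
#' @slot rgaArchitectureWeights named weights over the 25 published
#'   architecture keys (see [rgaArchitectureTable()]) plus optionally
#'   `"unlisted"`; must sum to 1.
#' @slot rngSeed integer seed; every output is deterministic given it.
#' @export
setClass("SimulationSpec",
  representation(
    nChromosomes = "integer", chromosomeLength = "numeric",
    gcFraction = "numeric", nGenes = "integer", nGenotypes = "integer",
    variantRate = "numeric", snpIndelRatio = "numeric",
    hetFraction = "numeric", nFixedBlocks = "integer",
    blockLength = "numeric", nPavGenes = "integer",
    filterViolationFraction = "numeric", meanGeneReadCount = "numeric",
    rgaArchitectureWeights = "numeric", rngSeed = "integer"
  ),
  prototype(
    nChromosomes = 2L, chromosomeLength = 5e5, gcFraction = 0.35,
    nGenes = 60L, nGenotypes = 5L, variantRate = 0.02,
    snpIndelRatio = 12, hetFraction = 0.6, nFixedBlocks = 1L,
    blockLength = 1e5, nPavGenes = 5L, filterViolationFraction = 0.1,
    meanGeneReadCount = 100, rgaArchitectureWeights = numeric(),
    rngSeed = 1L
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@variantRate <= 0 || object@variantRate >= 1)
    msg <- c(msg, "variantRate must be in (0,1)")
  if (object@gcFraction <= 0 || object@gcFraction >= 1)
    msg <- c(msg, "gcFraction must be in (0,1)")
  if (object@hetFraction < 0 || object@hetFraction > 1)
    msg <- c(msg, "hetFraction must be in [0,1]")
  if (object@chromosomeLength <= 0 || object@blockLength <= 0)
    msg <- c(msg, "lengths must be positive")
  if (length(object@rgaArchitectureWeights) &&
      abs(sum(object@rgaArchitectureWeights) - 1) > 1e-8)
    msg <- c(msg, "rgaArchitectureWeights must sum to 1")
  if (object@nPavGenes > object@nGenes)
    msg <- c(msg, "nPavGenes must be <= nGenes")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' @param ... named slot overrides; see [SimulationSpec-class].
#' @return A validated [SimulationSpec-class].
#' @export
simulationSpec <- function(...) {
  args <- list(...)
  for (f in c("nChromosomes", "nGenes", "nGenotypes", "nFixedBlocks",
              "nPavGenes", "rngSeed"))
    if (f %in% names(args)) args[[f]] <- as.integer(args[[f]])
  do.call(new, c(list("SimulationSpec"), args))
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec: ", object@nChromosomes, " chromosome(s) x ",
      format(object@chromosomeLength, big.mark = ","), " bp, ",
      object@nGenes, " genes, ", object@nGenotypes, " genotypes, rate ",
      object@variantRate, ", SNP:indel ", object@snpIndelRatio,
      ":1, seed ", object@rngSeed, "\n", sep = "")
})

## one RNG stream per output stage: regenerating one file does not shift
## the draws of another
.stageSeed <- function(spec, stage) {
  offset <- c(reference = 11L, variants = 23L, counts = 37L,
              domains = 53L)[[stage]]
  spec@rngSeed + offset
}

.chromNames <- function(spec) paste0("chr", seq_len(spec@nChromosomes))

#' Simulate a reference genome and gene models
#'
#' Draws each chromosome i.i.d. with the target GC fraction (G and C
#' each at gc/2) and places `nGenes` non-overlapping two-exon gene
#' models, alternating strand. Each CDS has total length divisible by
#' 3, starts with ATG and ends with TAA on the coding strand (planted
#' into the sequence), and is separated by an intron of at least 50 bp
#' so that splice-site and intron positions exist. Deterministic given
#' the seed.
#'
#' @param spec a [SimulationSpec-class].
#' @return A list: `genome` (named `DNAStringSet`), `models`
#'   (a [GeneModelSet-class]).
#' @export
simulateReference <- function(spec) {
  validObject(spec)
  set.seed(.stageSeed(spec, "reference"))
  gc <- spec@gcFraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chrs <- .chromNames(spec)
  seqs <- lapply(chrs, function(ch)
    sample(names(p), spec@chromosomeLength, replace = TRUE, prob = p))

  nGenes <- spec@nGenes
  tx <- list(); cdsl <- list(); exl <- list()
  if (nGenes > 0) {
    # deterministic slotting: genes spread round-robin over chromosomes
    perChr <- table(factor(rep(chrs, length.out = nGenes), levels = chrs))
    geneIdx <- 0L
    for (ci in seq_along(chrs)) {
      k <- perChr[[ci]]
      if (k == 0) next
      slot <- floor(spec@chromosomeLength / k)
      for (g in seq_len(k)) {
        geneIdx <- geneIdx + 1L
        nCodons1 <- sample(30:80, 1)
        nCodons2 <- sample(30:80, 1)
        intronLen <- sample(80:300, 1)
        len1 <- nCodons1 * 3L; len2 <- nCodons2 * 3L
        need <- len1 + intronLen + len2
        if (need + 10 > slot)
          stop("genes cannot be placed without overlap; ",
               "use fewer or shorter genes")
        s1 <- (g - 1L) * slot + sample(1:(slot - need - 5), 1)
        e1 <- s1 + len1 - 1L
        s2 <- e1 + intronLen + 1L
        e2 <- s2 + len2 - 1L
        strand <- if (geneIdx %% 2L == 1L) "+" else "-"
        gid <- sprintf("g%03d", geneIdx)
        tid <- paste0(gid, ".t1")
        # plant start/stop codons on the coding strand
        ch <- chrs[ci]
        if (strand == "+") {
          seqs[[ci]][s1:(s1 + 2)] <- c("A", "T", "G")
          seqs[[ci]][(e2 - 2):e2] <- c("T", "A", "A")
        } else {
          seqs[[ci]][(e2 - 2):e2] <- c("C", "A", "T")  # revcomp ATG
          seqs[[ci]][s1:(s1 + 2)] <- c("T", "T", "A")  # revcomp TAA
        }
        gr <- GRanges(ch, IRanges(c(s1, s2), c(e1, e2)), strand = strand)
        tx[[tid]] <- data.frame(tx_id = tid, gene_id = gid, chrom = ch,
                                strand = strand, stringsAsFactors = FALSE)
        cdsl[[tid]] <- gr
        exl[[tid]] <- gr
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chrs
  txdf <- if (length(tx)) DataFrame(do.call(rbind, tx)) else
    DataFrame(tx_id = character(), gene_id = character(),
              chrom = character(), strand = character())
  models <- new("GeneModelSet", transcripts = txdf,
                cds = GenomicRanges::GRangesList(cdsl),
                exons = GenomicRanges::GRangesList(exl))
  list(genome = genome, models = models)
}

#' Simulate per-genotype variant sets
#'
#' Each genotype receives Poisson(rate x L) variants at uniform
#' positions; a variant is a SNP with probability ratio/(ratio + 1)
#' (expected SNP:indel count ratio equal to `snpIndelRatio`), otherwise
#' a 1-10 bp insertion or deletion of uniform length. Calls are
#' heterozygous with probability `hetFraction` — except inside the
#' planted fixed blocks, where every emitted call is homozygous. A
#' `filterViolationFraction` of records draw QUAL below the quality
#' cut-off or depth outside the depth window, the rest pass the filter.
#' Reference alleles are read from the simulated genome so that effect
#' annotation is consistent.
#'
#' Fixed blocks are placed at the start of chromosome 1 (and following
#' chromosomes for more blocks), one block layout shared by all
#' genotypes, recorded in the ground truth.
#'
#' @param reference output of [simulateReference()].
#' @param spec a [SimulationSpec-class].
#' @param cfg a [RunConfig-class] giving the filter bounds that the
#'   violation fraction is drawn against.
#' @return A list: `variantSets` (named list of [VariantSet-class]) and
#'   `truth` (list with `fixedBlocks` data.frame and per-genotype
#'   `counts` of emitted records by type and zygosity, plus planted
#'   filter-violation counts).
#' @export
simulateVariants <- function(reference, spec, cfg = runConfig()) {
  validObject(spec)
  set.seed(.stageSeed(spec, "variants"))
  genome <- reference$genome
  chrs <- names(genome)
  chrLen <- stats::setNames(Biostrings::width(genome), chrs)
  Ltot <- sum(chrLen)
  nBlocks <- min(spec@nFixedBlocks, length(chrs))
  blocks <- if (nBlocks > 0)
    data.frame(chrom = chrs[seq_len(nBlocks)], start = 1,
               end = pmin(spec@blockLength, chrLen[seq_len(nBlocks)]),
               stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = numeric(), end = numeric())

  lambda <- spec@variantRate * Ltot
  if (lambda < 1)
    warning("expected variant count below 1; sets may be empty")
  genotypes <- paste0("G", seq_len(spec@nGenotypes))
  pSnp <- spec@snpIndelRatio / (spec@snpIndelRatio + 1)
  baseSet <- c("A", "C", "G", "T")

  truthCounts <- list()
  sets <- lapply(genotypes, function(gt) {
    n <- stats::rpois(1, lambda)
    chrom <- sample(chrs, n, replace = TRUE, prob = chrLen / Ltot)
    pos <- floor(stats::runif(n, 1, chrLen[chrom] - 12)) + 1L
    # unique positions per genotype keep VCF rows well-formed
    dup <- duplicated(paste(chrom, pos))
    chrom <- chrom[!dup]; pos <- pos[!dup]; n <- length(pos)
    isSnpV <- stats::runif(n) < pSnp
    inBlock <- rep(FALSE, n)
    for (b in seq_len(nrow(blocks)))
      inBlock <- inBlock | (chrom == blocks$chrom[b] &
                              pos >= blocks$start[b] & pos <= blocks$end[b])
    het <- stats::runif(n) < spec@hetFraction & !inBlock
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      base <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                              pos[i], pos[i]))
      if (isSnpV[i]) {
        ref[i] <- base
        alt[i] <- sample(setdiff(baseSet, base), 1)
      } else if (stats::runif(1) < 0.5) {  # insertion
        l <- sample(1:10, 1)
        ref[i] <- base
        alt[i] <- paste0(base, paste(sample(baseSet, l, TRUE),
                                     collapse = ""))
      } else {                              # deletion
        l <- sample(1:10, 1)
        ref[i] <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                                  pos[i], pos[i] + l))
        alt[i] <- base
      }
    }
    violate <- stats::runif(n) < spec@filterViolationFraction
    qual <- ifelse(violate & stats::runif(n) < 0.5,
                   stats::runif(n, 0, cfg@qualMin - 1e-6),
                   stats::runif(n, cfg@qualMin, 60))
    lowDepth <- violate & qual >= cfg@qualMin
    depth <- ifelse(lowDepth,
                    ifelse(stats::runif(n) < 0.5,
                           sample(seq_len(max(cfg@depthMin - 1, 1)), n,
                                  TRUE),
                           cfg@depthMax + sample(1:50, n, TRUE)),
                    sample(cfg@depthMin:min(cfg@depthMax, 100), n, TRUE))
    rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      zygosity = ifelse(het, "het", "hom"),
                      qual = round(qual, 1), depth = depth,
                      stringsAsFactors = FALSE)
    truthCounts[[gt]] <<- list(
      n = n, nSnp = sum(isSnpV), nIndel = sum(!isSnpV),
      nHet = sum(het), nHom = sum(!het), nViolations = sum(violate))
    variantSet(gt, rec, Ltot)
  })
  names(sets) <- genotypes
  list(variantSets = sets,
       truth = list(fixedBlocks = blocks, counts = truthCounts))
}

#' Simulate a per-gene read-count table with planted absences
#'
#' Present genes draw counts Poisson(mean x library factor) with
#' per-genotype library factors uniform in [0.8, 1.2]; each genotype
#' has `nPavGenes` planted absent genes drawing Poisson(0.5). Library
#' totals are recorded as 20x the expected gene-space total for the
#' genotype, emulating reads mapping outside gene space.
#'
#' @param models a [GeneModelSet-class] (gene ids are taken from it).
#' @param spec a [SimulationSpec-class].
#' @return A list: `table` (a [GeneCountTable-class]) and `truth`
#'   (data.frame `gene_id`, `genotype` of planted absences).
#' @export
simulateGeneCounts <- function(models, spec) {
  validObject(spec)
  set.seed(.stageSeed(spec, "counts"))
  genes <- unique(as.character(transcriptInfo(models)$gene_id))
  if (!length(genes)) stop("no gene models to count")
  genotypes <- paste0("G", seq_len(spec@nGenotypes))
  factors <- stats::runif(length(genotypes), 0.8, 1.2)
  m <- matrix(0, length(genes), length(genotypes),
              dimnames = list(genes, genotypes))
  planted <- list()
  for (j in seq_along(genotypes)) {
    m[, j] <- stats::rpois(length(genes), spec@meanGeneReadCount * factors[j])
    if (spec@nPavGenes > 0) {
      absent <- sample(genes, spec@nPavGenes)
      m[absent, j] <- stats::rpois(spec@nPavGenes, 0.5)
      planted[[j]] <- data.frame(gene_id = absent,
                                 genotype = genotypes[j],
                                 stringsAsFactors = FALSE)
    }
  }
  totals <- stats::setNames(
    round(20 * spec@meanGeneReadCount * length(genes) * factors),
    genotypes)
  truth <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_id = character(), genotype = character())
  list(table = geneCountTable(m, totals), truth = truth)
}

#' Simulate domain-evidence tables with known architectures
#'
#' Samples protein domain architectures from the published combination
#' table under the supplied weights (default: uniform over the 25
#' combinations), emits hmmscan-style hit rows with E-values at or
#' below 1e-10 and CC/TM flags consistent with the architecture, and
#' records the true acronym per protein. With weight on an `"unlisted"`
#' bucket, a TIR+Pkinase architecture (absent from the table) is
#' emitted so that the generation rule is exercised.
#'
#' @param spec a [SimulationSpec-class]; `rgaArchitectureWeights` may
#'   name a subset of architecture keys.
#' @param nProteins number of proteins to draw.
#' @return A list: `hits` (`data.frame` protein_id, accession, evalue),
#'   `flags` (`data.frame` protein_id, passed_homology, has_cc,
#'   has_tm), `truth` (`data.frame` protein_id, acronym).
#' @export
simulateDomainTables <- function(spec, nProteins = 200) {
  validObject(spec)
  set.seed(.stageSeed(spec, "domains"))
  tab <- rgaArchitectureTable()
  keys <- tab$domains
  w <- spec@rgaArchitectureWeights
  if (!length(w))
    w <- stats::setNames(rep(1 / length(keys), length(keys)), keys)
  unknownKeys <- setdiff(names(w), c(keys, "unlisted"))
  if (length(unknownKeys))
    stop("unknown architecture key(s): ", paste(unknownKeys, collapse = ", "))
  accOf <- list(
    `NB-ARC` = "PF00931", TIR = "PF01582", Pkinase = "PF00069",
    ABC_tran = "PF00005", WD40 = "PF00400",
    LRR = c("PF00560", "PF07723", "PF07725", "PF08263", "PF12799",
            "PF13306", "PF13516", "PF13855", "PF14580"))
  draw <- sample(names(w), nProteins, replace = TRUE, prob = w)
  hits <- list(); flags <- list(); truth <- list()
  for (i in seq_len(nProteins)) {
    pid <- sprintf("prot%04d", i)
    doms <- if (draw[i] == "unlisted") c("TIR", "Pkinase") else
      strsplit(draw[i], ":", fixed = TRUE)[[1]]
    hmm <- setdiff(doms, c("CC", "TM"))
    if (length(hmm))
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = pid,
        accession = vapply(hmm, function(d) sample(accOf[[d]], 1),
                           character(1)),
        evalue = 10^-stats::runif(length(hmm), 10, 50),
        stringsAsFactors = FALSE)
    flags[[i]] <- data.frame(protein_id = pid, passed_homology = TRUE,
                             has_cc = "CC" %in% doms,
                             has_tm = "TM" %in% doms,
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(protein_id = pid,
                             acronym = classifyArchitecture(doms),
                             stringsAsFactors = FALSE)
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(protein_id = character(), accession = character(),
                    evalue = numeric()),
       flags = do.call(rbind, flags),
       truth = do.call(rbind, truth))
}

## --- file emission -------------------------------------------------------

.writeFastaGff <- function(reference, dir) {
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(reference$genome, fa)
  gff <- file.path(dir, "genes.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  tx <- as.data.frame(transcriptInfo(reference$models))
  cds <- cdsIntervals(reference$models)
  for (i in seq_len(nrow(tx))) {
    iv <- cds[[tx$tx_id[i]]]
    gs <- min(start(iv)); ge <- max(end(iv))
    writeLines(c(
      paste(tx$chrom[i], "sim", "gene", gs, ge, ".", tx$strand[i], ".",
            paste0("ID=", tx$gene_id[i]), sep = "\t"),
      paste(tx$chrom[i], "sim", "mRNA", gs, ge, ".", tx$strand[i], ".",
            paste0("ID=", tx$tx_id[i], ";Parent=", tx$gene_id[i]),
            sep = "\t"),
      vapply(seq_along(iv), function(k)
        paste(tx$chrom[i], "sim", "exon", start(iv)[k], end(iv)[k], ".",
              tx$strand[i], ".", paste0("Parent=", tx$tx_id[i]),
              sep = "\t"), character(1)),
      vapply(seq_along(iv), function(k)
        paste(tx$chrom[i], "sim", "CDS", start(iv)[k], end(iv)[k], ".",
              tx$strand[i], "0", paste0("Parent=", tx$tx_id[i]),
              sep = "\t"), character(1))), con)
  }
  close(con)
  c(fasta = fa, gff3 = gff)
}

.writeVcf <- function(vs, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  gt <- genotypeLabel(vs)
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(genome), ",length=",
           Biostrings::width(genome), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", gt, sep = "\t")), con)
  r <- as.data.frame(variantRecords(vs))
  if (nrow(r)) {
    gtf <- ifelse(r$zygosity == "het", "0/1", "1/1")
    writeLines(paste(r$chrom, r$pos, ".", r$ref, r$alt, r$qual, "PASS",
                     ".", "GT:DP", paste0(gtf, ":", r$depth), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Run the full simulation and write its files
#'
#' Generates reference FASTA + GFF3, one VCF per genotype, the gene
#' count TSV, the domain-evidence tables and a JSON-lines ground-truth
#' manifest into `dir`. Rerunning with the same spec is byte-identical.
#'
#' @param spec a [SimulationSpec-class].
#' @param dir output directory (created if needed).
#' @param cfg a [RunConfig-class] for filter bounds.
#' @return Invisibly, a list with the in-memory objects (`reference`,
#'   `variants`, `counts`, `domains`) and the written file paths.
#' @export
simulateStudy <- function(spec, dir, cfg = runConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(spec)
  paths <- .writeFastaGff(ref, dir)
  vars <- simulateVariants(ref, spec, cfg)
  vcfs <- vapply(names(vars$variantSets), function(gt) {
    p <- file.path(dir, paste0(gt, ".vcf"))
    .writeVcf(vars$variantSets[[gt]], ref$genome, p)
    p
  }, character(1))
  cnt <- simulateGeneCounts(ref$models, spec)
  cntPath <- file.path(dir, "gene_counts.tsv")
  writeGeneCountTable(cnt$table, cntPath)
  dom <- simulateDomainTables(spec)
  domPath <- file.path(dir, "domain_flags.tsv")
  utils::write.table(dom$flags, domPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hitPath <- file.path(dir, "domain_hits.tsv")
  utils::write.table(dom$hits, hitPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- file.path(dir, "truth.jsonl")
  con <- file(manifest, "w")
  .json <- function(tag, x)
    paste0("{\"record\":\"", tag, "\",", x, "}")
  writeLines(c(
    vapply(seq_len(nrow(vars$truth$fixedBlocks)), function(i)
      .json("fixed_block", paste0(
        "\"chrom\":\"", vars$truth$fixedBlocks$chrom[i], "\",",
        "\"start\":", vars$truth$fixedBlocks$start[i], ",",
        "\"end\":", vars$truth$fixedBlocks$end[i])), character(1)),
    vapply(seq_len(nrow(cnt$truth)), function(i)
      .json("pav_absent", paste0(
        "\"gene_id\":\"", cnt$truth$gene_id[i], "\",",
        "\"genotype\":\"", cnt$truth$genotype[i], "\"")), character(1)),
    vapply(seq_len(nrow(dom$truth)), function(i)
      .json("rga_truth", paste0(
        "\"protein_id\":\"", dom$truth$protein_id[i], "\",",
        "\"acronym\":\"", dom$truth$acronym[i], "\"")), character(1))),
    con)
  close(con)
  invisible(list(reference = ref, variants = vars, counts = cnt,
                 domains = dom,
                 paths = c(paths, vcfs, counts = cntPath,
                           flags = domPath, hits = hitPath,
                           truth = manifest)))
}
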