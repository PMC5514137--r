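#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Pipeline configuration
#'
#' Holds every numeric cut-off used across the pipeline: the variant
#' quality/depth filter, the PAV read-count thresholds, the domain-evidence
#' E-value cut-offs, the deleteriousness score threshold, the window width
#' for density tracks, and the reference genome length used as the
#' denominator of all variant rates.
#'
#' @slot windowBp window width in bp for density tracks (default 1e6).
#' @slot pavAbsentThreshold normalized read count below which a gene is
#'   called absent in a genotype (default 6, exclusive: absent iff < 6).
#' @slot pavPresentThreshold normalized read count above which a gene is
#'   called confidently present (default 29, exclusive: > 29).
#' @slot qualMin minimum call quality retained by the filter (default 20,
#'   inclusive).
#' @slot depthMin,depthMax inclusive depth bounds (defaults 8 and 450).
#' @slot hmmEvalueMax maximum HMM hit E-value accepted as domain evidence
#'   (default 1e-10, inclusive).
#' @slot blastEvalueMax homology-screen E-value bound carried for the
#'   record; the screen itself is upstream (default 1e-60).
#' @slot proveanCutoff score at or below which a substitution is flagged
#'   deleterious (default -2.5, inclusive).
#' @slot genomeLength reference assembly length in bp used as the rate
#'   denominator (default 724,700,000).
#' @slot hetMaxPerMb,homMinPerMb window densities (per Mb) defining a
#'   homozygous-fixed window: het density <= hetMaxPerMb and hom density
#'   >= homMinPerMb (defaults 10 and 100).
#' @slot minClusterSize minimum per-window gene count that makes an RGA
#'   cluster (default 4).
#' @slot rngSeed integer seed recorded with a run.
#'
#' @examples
#' cfg <- runConfig(qualMin = 30)
#' cfg@depthMin
#' @export
setClass("RunConfig",
  representation(
    windowBp = "numeric",
    pavAbsentThreshold = "numeric",
    pavPresentThreshold = "numeric",
    qualMin = "numeric",
    depthMin = "numeric",
    depthMax = "numeric",
    hmmEvalueMax = "numeric",
    blastEvalueMax = "numeric",
    proveanCutoff = "numeric",
    genomeLength = "numeric",
    hetMaxPerMb = "numeric",
    homMinPerMb = "numeric",
    minClusterSize = "numeric",
    rngSeed = "integer"
  ),
  prototype(
    windowBp = 1e6,
    pavAbsentThreshold = 6,
    pavPresentThreshold = 29,
    qualMin = 20,
    depthMin = 8,
    depthMax = 450,
    hmmEvalueMax = 1e-10,
    blastEvalueMax = 1e-60,
    proveanCutoff = -2.5,
    genomeLength = 724700000,
    hetMaxPerMb = 10,
    homMinPerMb = 100,
    minClusterSize = 4,
    rngSeed = 1L
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  pos <- c(
    windowBp = object@windowBp,
    pavAbsentThreshold = object@pavAbsentThreshold,
    pavPresentThreshold = object@pavPresentThreshold,
    qualMin = object@qualMin,
    depthMin = object@depthMin,
    depthMax = object@depthMax,
    hmmEvalueMax = object@hmmEvalueMax,
    blastEvalueMax = object@blastEvalueMax,
    genomeLength = object@genomeLength
  )
  if (any(pos <= 0))
    msg <- c(msg, paste0("thresholds must be positive: ",
                         paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@depthMin >= object@depthMax)
    msg <- c(msg, "depthMin must be < depthMax")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param ... named slot overrides, e.g. `qualMin = 30`.
#' @return A [RunConfig-class] object with defaults for unnamed slots.
#' @export
runConfig <- function(...) {
  args <- list(...)
  if ("rngSeed" %in% names(args)) args$rngSeed <- as.integer(args$rngSeed)
  do.call(new, c(list("RunConfig"), args))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  filter: qual >=", object@qualMin,
      ", depth in [", object@depthMin, ",", object@depthMax, "]\n")
  cat("  PAV: absent <", object@pavAbsentThreshold,
      ", present >", object@pavPresentThreshold, "\n")
  cat("  windows:", format(object@windowBp, big.mark = ","), "bp;",
      "genome length:", format(object@genomeLength, big.mark = ","), "bp\n")
  cat("  HMM E <=", object@hmmEvalueMax,
      "; deleterious score <=", object@proveanCutoff, "\n")
})

#' A genotype's variant calls against the reference
#'
#' One resequenced genotype's set of called differences versus the
#' reference assembly, with zygosity, call quality and depth per record.
#' Records are kept sorted by (chromosome, position).
#'
#' @slot genotype label of the genotype.
#' @slot records `DataFrame` with columns `chrom`, `pos` (1-based position
#'   of the first reference base), `ref`, `alt`, `zygosity`
#'   (`"hom"`/`"het"`), `qual`, `depth`.
#' @slot refLength reference length in bp used as rate denominator.
#' @export
setClass("VariantSet",
  representation(
    genotype = "character",
    records = "DataFrame",
    refLength = "numeric"
  )
)

.variantCols <- c("chrom", "pos", "ref", "alt", "zygosity", "qual", "depth")

setValidity("VariantSet", function(object) {
  msg <- character()
  r <- object@records
  if (!all(.variantCols %in% colnames(r)))
    msg <- c(msg, paste("records must have columns:",
                        paste(.variantCols, collapse = ", ")))
  else {
    if (nrow(r)) {
      if (any(nchar(r$ref) == 0) || any(nchar(r$alt) == 0))
        msg <- c(msg, "ref/alt alleles must be non-empty")
      if (any(r$ref == r$alt))
        msg <- c(msg, "ref and alt must differ")
      if (!all(r$zygosity %in% c("hom", "het")))
        msg <- c(msg, "zygosity must be 'hom' or 'het'")
      o <- order(r$chrom, r$pos)
      if (!identical(o, seq_len(nrow(r))))
        msg <- c(msg, "records must be sorted by (chrom, pos)")
    }
  }
  if (length(object@refLength) != 1L || object@refLength <= 0)
    msg <- c(msg, "refLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantSet
#'
#' @param genotype genotype label.
#' @param records a data.frame or DataFrame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity`, `qual`, `depth`. Rows are sorted by
#'   (chrom, pos) on construction.
#' @param refLength reference length in bp.
#' @return A [VariantSet-class].
#' @export
variantSet <- function(genotype, records, refLength) {
  records <- DataFrame(as.data.frame(records))
  if ("pos" %in% colnames(records)) records$pos <- as.numeric(records$pos)
  if (nrow(records))
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  new("VariantSet", genotype = as.character(genotype),
      records = records, refLength = as.numeric(refLength))
}

#' @describeIn VariantSet-class number of variant records.
#' @param x a `VariantSet`.
#' @export
setMethod("length", "VariantSet", function(x) nrow(x@records))

#' Accessors for VariantSet
#'
#' @param x a [VariantSet-class].
#' @return `variantRecords()` the records `DataFrame`; `genotypeLabel()`
#'   the genotype label; `refLength()` the reference length in bp.
#' @export
variantRecords <- function(x) x@records

#' @rdname variantRecords
#' @export
genotypeLabel <- function(x) x@genotype

#' @rdname variantRecords
#' @export
refLength <- function(x) x@refLength

#' Is a record a SNP?
#'
#' A record is a SNP iff both alleles have length 1; anything else is an
#' indel.
#'
#' @param x a [VariantSet-class].
#' @return logical vector, one per record.
#' @export
isSnp <- function(x) {
  r <- variantRecords(x)
  nchar(r$ref) == 1L & nchar(r$alt) == 1L
}

setMethod("show", "VariantSet", function(object) {
  s <- sum(isSnp(object))
  cat("VariantSet '", object@genotype, "': ", length(object),
      " records (", s, " SNPs, ", length(object) - s, " indels) on ",
      length(unique(object@records$chrom)), " chromosome(s); L = ",
      format(object@refLength, big.mark = ","), " bp\n", sep = "")
})

#' Fixed-width per-window count track
#'
#' A genome tiled into fixed-width windows (last window of each chromosome
#' truncated) with one non-negative count per window. Windows are 1-based
#' inclusive internally; bedGraph conversion happens only at I/O.
#'
#' @slot windows a `GRanges` tiling each chromosome, sorted, with a
#'   numeric `score` metadata column.
#' @slot windowBp nominal window width in bp.
#' @export
setClass("WindowTrack",
  representation(windows = "GRanges", windowBp = "numeric")
)

setValidity("WindowTrack", function(object) {
  gr <- object@windows
  msg <- character()
  if (!"score" %in% colnames(S4Vectors::mcols(gr)))
    msg <- c(msg, "windows must carry a 'score' column")
  else if (any(S4Vectors::mcols(gr)$score < 0))
    msg <- c(msg, "window values must be >= 0")
  if (length(gr) > 1) {
    bychr <- split(gr, GenomeInfoDb::seqnames(gr))
    for (chr in names(bychr)) {
      g <- bychr[[chr]]
      if (length(g) < 2) next
      st <- BiocGenerics::start(g); en <- BiocGenerics::end(g)
      if (any(st[-1] != en[-length(en)] + 1L))
        msg <- c(msg, paste0("windows on ", chr,
                             " must tile without gap or overlap"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn WindowTrack-class number of windows.
#' @param x a `WindowTrack`.
#' @export
setMethod("length", "WindowTrack", function(x) length(x@windows))

#' Accessors for WindowTrack
#'
#' @param x a [WindowTrack-class].
#' @return `trackWindows()` the `GRanges` of windows; `trackValues()` the
#'   numeric per-window counts.
#' @export
trackWindows <- function(x) x@windows

#' @rdname trackWindows
#' @export
trackValues <- function(x) S4Vectors::mcols(x@windows)$score

setMethod("show", "WindowTrack", function(object) {
  cat("WindowTrack: ", length(object), " windows of ",
      format(object@windowBp, big.mark = ","), " bp on ",
      length(GenomeInfoDb::seqlevels(object@windows)),
      " chromosome(s); total count ",
      sum(trackValues(object)), "\n", sep = "")
})

#' Gene models parsed from GFF3
#'
#' Chromosome-anchored transcript structures: per-mRNA CDS and exon
#' intervals (1-based inclusive, sorted, non-overlapping) with strand.
#'
#' @slot transcripts `DataFrame` with columns `tx_id`, `gene_id`,
#'   `chrom`, `strand`.
#' @slot cds named `GRangesList`, CDS intervals per transcript.
#' @slot exons named `GRangesList`, exon intervals per transcript.
#' @export
setClass("GeneModelSet",
  representation(
    transcripts = "DataFrame",
    cds = "CompressedGRangesList",
    exons = "CompressedGRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  tx <- object@transcripts
  if (!all(c("tx_id", "gene_id", "chrom", "strand") %in% colnames(tx)))
    msg <- c(msg, "transcripts needs tx_id, gene_id, chrom, strand")
  else {
    if (!identical(as.character(names(object@cds)),
                   as.character(tx$tx_id)))
      msg <- c(msg, "cds list must be named by tx_id in transcript order")
    if (!all(tx$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class number of transcripts.
#' @param x a `GeneModelSet`.
#' @export
setMethod("length", "GeneModelSet", function(x) nrow(x@transcripts))

#' Accessors for GeneModelSet
#'
#' @param x a [GeneModelSet-class].
#' @return `transcriptInfo()` the transcript `DataFrame`; `cdsIntervals()`
#'   and `exonIntervals()` the per-transcript `GRangesList`s.
#' @export
transcriptInfo <- function(x) x@transcripts

#' @rdname transcriptInfo
#' @export
cdsIntervals <- function(x) x@cds

#' @rdname transcriptInfo
#' @export
exonIntervals <- function(x) x@exons

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet: ", length(object), " transcript(s) on ",
      length(unique(object@transcripts$chrom)), " chromosome(s)\n",
      sep = "")
})

#' Per-gene x per-genotype mapped-read-count table
#'
#' Raw counts of reads mapped at each gene location for each genotype,
#' plus the per-genotype genome-wide mapped-read totals used for
#' normalization. The substrate of PAV calling.
#'
#' @slot counts integer-like matrix, genes x genotypes, `dimnames` set.
#' @slot libraryTotals named numeric, genome-wide mapped reads per
#'   genotype; must be >= the corresponding column sums.
#' @export
setClass("GeneCountTable",
  representation(counts = "matrix", libraryTotals = "numeric")
)

setValidity("GeneCountTable", function(object) {
  msg <- character()
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have gene rownames and genotype colnames")
  if (any(m < 0)) msg <- c(msg, "counts must be >= 0")
  lt <- object@libraryTotals
  if (!identical(names(lt), colnames(m)))
    msg <- c(msg, "libraryTotals must be named by genotype, in column order")
  else if (any(lt < colSums(m)))
    msg <- c(msg, "libraryTotals must be >= per-genotype column sums")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCountTable
#'
#' @param counts genes x genotypes matrix of raw mapped-read counts with
#'   dimnames.
#' @param libraryTotals named numeric vector of genome-wide mapped-read
#'   totals, one per genotype column.
#' @return A [GeneCountTable-class].
#' @export
geneCountTable <- function(counts, libraryTotals) {
  new("GeneCountTable", counts = as.matrix(counts),
      libraryTotals = libraryTotals[colnames(counts)])
}

#' Accessors for GeneCountTable
#'
#' @param x a [GeneCountTable-class].
#' @return `geneCounts()` the raw count matrix; `libraryTotals()` the
#'   named per-genotype totals.
#' @export
geneCounts <- function(x) x@counts

#' @rdname geneCounts
#' @export
libraryTotals <- function(x) x@libraryTotals

setMethod("dim", "GeneCountTable", function(x) dim(x@counts))

setMethod("show", "GeneCountTable", function(object) {
  cat("GeneCountTable: ", nrow(object@counts), " genes x ",
      ncol(object@counts), " genotypes (",
      paste(colnames(object@counts), collapse = ", "), ")\n", sep = "")
})

#' Site-by-genotype allele dosage matrix
#'
#' For relatedness: the union of variant sites across genotypes, with the
#' number of ALT allele copies (0, 1 or 2) carried by each genotype at
#' each site. A genotype with no record at a site is reference-homozygous
#' (dosage 0).
#'
#' @slot sites `DataFrame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @slot dosage numeric matrix, sites x genotypes, entries in {0,1,2}.
#' @export
setClass("GenotypeMatrix",
  representation(sites = "DataFrame", dosage = "matrix")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@sites) != nrow(object@dosage))
    msg <- c(msg, "sites and dosage must have the same number of rows")
  if (!all(object@dosage %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1 or 2")
  if (is.null(colnames(object@dosage)))
    msg <- c(msg, "dosage must have genotype colnames")
  if (length(msg)) msg else TRUE
})

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return `siteInfo()` the site `DataFrame`; `dosageMatrix()` the
#'   sites x genotypes dosage matrix.
#' @export
siteInfo <- function(x) x@sites

#' @rdname siteInfo
#' @export
dosageMatrix <- function(x) x@dosage

setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object@dosage), " sites x ",
      ncol(object@dosage), " genotypes\n", sep = "")
})
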