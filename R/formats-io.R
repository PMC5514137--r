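#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end width strand
#' @importFrom GenomeInfoDb seqnames seqlevels
NULL

#' Read gene models from GFF3
#'
#' Parses a GFF3 file with gene/mRNA/exon/CDS feature rows into a
#' [GeneModelSet-class]: one model per mRNA, CDS and exon intervals
#' sorted ascending, strand preserved. Coordinates stay 1-based
#' inclusive, the GFF3 convention used internally throughout.
#'
#' Transcripts with CDS rows but no exon rows get their CDS intervals as
#' exons. Malformed rows (wrong column count) and CDS rows without a
#' Parent are errors, not silent skips.
#'
#' @param path path to a GFF3 file.
#' @return A [GeneModelSet-class]; empty (zero transcripts) for a file
#'   with no mRNA features.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsim\tgene\t101\t160\t.\t+\t.\tID=g1",
#'   "chr1\tsim\tmRNA\t101\t160\t.\t+\t.\tID=g1.t1;Parent=g1",
#'   "chr1\tsim\tCDS\t101\t160\t.\t+\t0\tParent=g1.t1"), gff)
#' gm <- readGeneModels(gff)
#' cdsIntervals(gm)[["g1.t1"]]
#' @export
readGeneModels <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- body[which(nfield != 9L)[1]]
    stop("malformed GFF3: line ", bad, " has ", nfield[which(nfield != 9L)[1]],
         " columns (expected 9)")
  }
  empty <- DataFrame(tx_id = character(), gene_id = character(),
                     chrom = character(), strand = character())
  if (!length(body))
    return(new("GeneModelSet", transcripts = empty,
               cds = GenomicRanges::GRangesList(),
               exons = GenomicRanges::GRangesList()))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  cds <- gr[type == "CDS"]
  ex <- gr[type == "exon"]
  if (length(cds)) {
    noParent <- if (is.null(cds$Parent)) rep(TRUE, length(cds)) else
      lengths(cds$Parent) == 0
    if (any(noParent))
      stop("CDS feature without Parent at ",
           as.character(seqnames(cds))[noParent][1], ":",
           start(cds)[noParent][1])
  }
  if (!length(mrna))
    return(new("GeneModelSet", transcripts = empty,
               cds = GenomicRanges::GRangesList(),
               exons = GenomicRanges::GRangesList()))

  txid <- as.character(mrna$ID)
  geneid <- vapply(as.list(mrna$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  geneid[is.na(geneid)] <- txid[is.na(geneid)]
  tx <- DataFrame(tx_id = txid, gene_id = geneid,
                  chrom = as.character(seqnames(mrna)),
                  strand = as.character(strand(mrna)))

  .collect <- function(feat) {
    par <- rep(unlist(feat$Parent), lengths(feat$Parent))
    feat <- rep(feat, lengths(feat$Parent))
    lst <- S4Vectors::split(feat, factor(par, levels = txid))
    lst <- GenomicRanges::GRangesList(lapply(lst, function(g) {
      g <- BiocGenerics::sort(g)
      S4Vectors::mcols(g) <- NULL
      g
    }))
    lst
  }
  cdsl <- .collect(cds)
  exl <- .collect(ex)
  # exon-less transcripts inherit CDS intervals as exons
  noex <- lengths(exl) == 0 & lengths(cdsl) > 0
  exl[noex] <- cdsl[noex]
  new("GeneModelSet", transcripts = tx, cds = cdsl[txid], exons = exl[txid])
}

.gtSplit <- function(gt) strsplit(gt, "[/|]")

#' Read one genotype's variants from a VCF
#'
#' Reads a VCF 4.x file through `VariantAnnotation`, extracts the named
#' sample's genotype calls and returns a [VariantSet-class]. Sites where
#' the sample is reference-homozygous (`0/0`) or uncalled (`./.`) are
#' excluded. Multi-allelic rows are split into one record per ALT allele
#' before any downstream filtering; zygosity is `"het"` when the two GT
#' alleles differ and `"hom"` when both equal that ALT.
#'
#' Depth is taken from `FORMAT/DP` when present, else `INFO/DP`.
#'
#' @param path path to a VCF file.
#' @param sample sample name; must be present in the VCF.
#' @param refLength reference length in bp stored on the result (defaults
#'   to the sum of contig lengths declared in the VCF header, if any).
#' @return A [VariantSet-class].
#' @export
readVariants <- function(path, sample, refLength = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!sample %in% colnames(vcf))
    stop("sample '", sample, "' not found in VCF (have: ",
         paste(colnames(vcf), collapse = ", "), ")")
  if (!"GT" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no GT genotype field")
  gt <- VariantAnnotation::geno(vcf)$GT[, sample]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  ref <- as.character(rr$REF)
  altl <- VariantAnnotation::alt(vcf)
  qual <- rr$QUAL
  dp <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    dp <- VariantAnnotation::geno(vcf)$DP[, sample]
  else if ("DP" %in% names(VariantAnnotation::info(vcf)))
    dp <- VariantAnnotation::info(vcf)$DP
  if (is.null(dp)) dp <- rep(NA_real_, length(gt))

  alleles <- .gtSplit(gt)
  out <- vector("list", length(gt))
  for (i in seq_along(gt)) {
    a <- alleles[[i]]
    if (any(a == ".") || all(a == "0")) next
    ai <- as.integer(a)
    alts <- as.character(altl[[i]])
    hit <- sort(unique(ai[ai > 0]))
    zyg <- if (length(unique(ai)) > 1L) "het" else "hom"
    out[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i], ref = ref[i],
      alt = alts[hit], zygosity = zyg,
      qual = qual[i], depth = as.numeric(dp[i]),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  rec <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), zygosity = character(), qual = numeric(),
               depth = numeric())
  if (is.null(refLength)) {
    sl <- GenomeInfoDb::seqlengths(vcf)
    refLength <- if (all(is.na(sl))) NA_real_ else sum(sl, na.rm = TRUE)
  }
  variantSet(sample, rec, refLength)
}

#' Write / read a window track as bedGraph
#'
#' `writeWindowTrack()` serializes a [WindowTrack-class] in bedGraph
#' dialect (0-based half-open starts, one value column, `track` header
#' line); `readWindowTrack()` reads it back. The pair round-trips
#' exactly; internal coordinates remain 1-based inclusive and the
#' conversion happens only here, at the I/O boundary.
#'
#' @param track a [WindowTrack-class]; overlapping windows are rejected
#'   by the class validity.
#' @param path output (or input) file path.
#' @return `readWindowTrack()` returns a [WindowTrack-class].
#' @export
writeWindowTrack <- function(track, path) {
  stopifnot(is(track, "WindowTrack"))
  validObject(track)
  gr <- trackWindows(track)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeWindowTrack
#' @param windowBp nominal window width of the stored track.
#' @export
readWindowTrack <- function(path, windowBp) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- BiocGenerics::sort(gr)
  new("WindowTrack", windows = gr, windowBp = windowBp)
}

## --- dendrogram nodes ----------------------------------------------------

#' Build a dendrogram node
#'
#' Internal node constructor for the binary rooted ultrametric trees
#' produced by [upgma()]. A leaf has a `label` and height 0; an internal
#' node has `left`/`right` children and a height in distance units.
#'
#' @param label leaf label (leaves only).
#' @param left,right child nodes (internal nodes only).
#' @param height node height; 0 for leaves.
#' @return a `dendroNode` (S3 list).
#' @export
dendroNode <- function(label = NULL, left = NULL, right = NULL, height = 0) {
  if (is.null(label) && (is.null(left) || is.null(right)))
    stop("a dendroNode is a labelled leaf or has two children")
  structure(list(label = label, left = left, right = right,
                 height = height), class = "dendroNode")
}

#' @export
print.dendroNode <- function(x, ...) {
  cat("dendroNode:", length(dendroLeaves(x)), "leaf/leaves, root height",
      format(x$height, digits = 4), "\n")
  invisible(x)
}

#' Leaf labels of a dendrogram, left to right
#'
#' @param node a `dendroNode`.
#' @return character vector of leaf labels.
#' @export
dendroLeaves <- function(node) {
  if (!is.null(node$label)) return(node$label)
  c(dendroLeaves(node$left), dendroLeaves(node$right))
}

#' Convert a dendrogram to an ape \code{phylo}
#'
#' Branch lengths are parent height minus child height, so UPGMA trees
#' convert to ultrametric \code{phylo} objects.
#'
#' @param node a `dendroNode` with at least two leaves.
#' @return an [ape::read.tree()]-compatible `phylo`.
#' @export
dendroToPhylo <- function(node) {
  leaves <- dendroLeaves(node)
  n <- length(leaves)
  if (n < 2) stop("need at least two leaves to build a phylo")
  edge <- matrix(0L, 2 * n - 2, 2)
  elen <- numeric(2 * n - 2)
  env <- new.env()
  env$nextInternal <- n + 1L
  env$nextLeaf <- 1L
  env$row <- 0L
  assign1 <- function(nd) {
    if (!is.null(nd$label)) {
      id <- env$nextLeaf; env$nextLeaf <- env$nextLeaf + 1L
      return(id)
    }
    id <- env$nextInternal; env$nextInternal <- env$nextInternal + 1L
    for (child in list(nd$left, nd$right)) {
      cid <- assign1(child)
      env$row <- env$row + 1L
      edge[env$row, ] <<- c(id, cid)
      elen[env$row] <<- nd$height - child$height
    }
    id
  }
  assign1(node)
  ph <- structure(list(edge = edge, edge.length = elen,
                       tip.label = leaves, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(ph, "cladewise")
}

#' Write a dendrogram in Newick format
#'
#' Serializes a [upgma()] tree (or any `dendroNode`) as Newick through
#' `ape`, with branch lengths and a terminating semicolon. Duplicate
#' leaf names are rejected. A single leaf writes as `"label;"`.
#'
#' @param tree a `dendroNode`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  leaves <- dendroLeaves(tree)
  if (anyDuplicated(leaves))
    stop("duplicate leaf names: ",
         paste(unique(leaves[duplicated(leaves)]), collapse = ", "))
  if (length(leaves) == 1L) {
    writeLines(paste0(leaves, ";"), path)
    return(invisible(path))
  }
  ape::write.tree(dendroToPhylo(tree), file = path)
  invisible(path)
}
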