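#' Build a site-by-genotype allele dosage matrix
#'
#' The site universe is the union of all variant sites across the
#' supplied genotypes (whole-genome subset) or its intersection with
#' annotated CDS intervals (coding subset). Dosage is the number of ALT
#' allele copies: 2 for a homozygous call, 1 for heterozygous, 0 when a
#' genotype has no record at the site — in a resequencing VCF called
#' against a single reference, no record means reference-homozygous.
#'
#' A site is keyed by (chrom, pos, ref, alt); two genotypes reporting
#' different REF alleles at the same position is an input error.
#'
#' @param variantSets list of [VariantSet-class], at least two.
#' @param geneModels a [GeneModelSet-class]; required when
#'   `subset = "coding"`.
#' @param subset `"whole"` (default) or `"coding"`.
#' @param snpsOnly drop indel sites before building the matrix
#'   (default `FALSE`: indels are genotyped like SNPs).
#' @return A [GenotypeMatrix-class].
#' @export
buildGenotypeMatrix <- function(variantSets, geneModels = NULL,
                                subset = c("whole", "coding"),
                                snpsOnly = FALSE) {
  subset <- match.arg(subset)
  if (length(variantSets) < 2)
    stop("need at least two genotypes")
  labels <- vapply(variantSets, genotypeLabel, character(1))
  if (anyDuplicated(labels)) stop("duplicate genotype labels")
  recs <- lapply(variantSets, variantRecords)
  all <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- as.data.frame(recs[[i]])
    if (snpsOnly) r <- r[nchar(r$ref) == 1 & nchar(r$alt) == 1, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(gt = labels[i], chrom = r$chrom, pos = r$pos, ref = r$ref,
               alt = r$alt, zygosity = r$zygosity, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  if (is.null(all) || !nrow(all)) stop("zero sites across genotypes")

  # REF alleles at one position may differ in length (SNP vs deletion) but
  # must agree on their shared prefix: all describe the same reference.
  posKey <- paste(all$chrom, all$pos)
  conflict <- tapply(all$ref, posKey, function(x) {
    x <- unique(x)
    if (length(x) == 1) return(FALSE)
    longest <- x[which.max(nchar(x))]
    !all(startsWith(longest, x))
  })
  if (any(conflict))
    stop("conflicting REF alleles across genotypes at ",
         names(conflict)[conflict][1])

  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = ":")
  ukey <- !duplicated(key)
  sites <- DataFrame(chrom = all$chrom[ukey], pos = all$pos[ukey],
                     ref = all$ref[ukey], alt = all$alt[ukey])
  o <- order(sites$chrom, sites$pos, sites$alt)
  sites <- sites[o, , drop = FALSE]
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")

  if (subset == "coding") {
    if (is.null(geneModels))
      stop("coding subset requires gene models")
    cds <- unlist(cdsIntervals(geneModels))
    sgr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
    keep <- GenomicRanges::countOverlaps(sgr, cds) > 0
    sites <- sites[keep, , drop = FALSE]
    skey <- skey[keep]
    if (!nrow(sites)) stop("zero sites in the coding subset")
  }

  dosage <- matrix(0, nrow(sites), length(labels),
                   dimnames = list(skey, labels))
  for (i in seq_along(labels)) {
    r <- all[all$gt == labels[i], , drop = FALSE]
    k <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
    hit <- match(k, skey)
    keep <- !is.na(hit)
    dosage[hit[keep], i] <- ifelse(r$zygosity[keep] == "hom", 2, 1)
  }
  new("GenotypeMatrix", sites = sites, dosage = dosage)
}

#' Allele-sharing (1 - IBS) distance
#'
#' For genotypes a, b with per-site ALT dosages in {0,1,2},
#' `d(a,b) = mean over sites of |dosage_a - dosage_b| / 2`. This is the
#' standard identity-by-state allele-sharing distance: 0 for identical
#' dosage vectors, 1 when one genotype is reference-homozygous and the
#' other ALT-homozygous at every site.
#'
#' @param gm a [GenotypeMatrix-class] with at least one site.
#' @return A symmetric matrix of distances in `[0, 1]` with zero
#'   diagonal, labelled by genotype.
#' @examples
#' gm <- new("GenotypeMatrix",
#'   sites = S4Vectors::DataFrame(chrom = "c", pos = 1:3, ref = "A",
#'                                alt = "T"),
#'   dosage = cbind(a = c(2, 1, 0), b = c(0, 1, 2)))
#' ibsDistance(gm)["a", "b"]  # 0.667
#' @export
ibsDistance <- function(gm) {
  d <- dosageMatrix(gm)
  if (!nrow(d)) stop("zero sites: distance undefined")
  n <- ncol(d)
  out <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i) {
        out[i, j] <- mean(abs(d[, i] - d[, j])) / 2
        out[j, i] <- out[i, j]
      }
  out
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomerative clustering of a symmetric distance
#' matrix, producing an ultrametric binary rooted tree: each merge
#' creates a node at height equal to half the distance between the
#' merged clusters, and after a merge the distance from the new cluster
#' to any other is the size-weighted average of its members' distances
#' (classic UPGMA). When several pairs tie at the minimum distance the
#' pair whose sorted label pair is lexicographically smallest merges
#' first, making the output deterministic.
#'
#' @param dm symmetric numeric distance matrix with labelled rows and
#'   columns, zero diagonal, no NaN; n >= 2.
#' @return A `dendroNode` (see [dendroNode()]); leaf heights 0, root
#'   height = half the final merge distance.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
#' tr$height  # 0.3
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  if (any(is.nan(dm)) || anyNA(dm)) stop("NaN/NA distance")
  n <- nrow(dm)
  if (n < 2) stop("need at least two taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")

  clusters <- lapply(rownames(dm), function(l) dendroNode(label = l))
  names(clusters) <- rownames(dm)
  sizes <- stats::setNames(rep(1, n), rownames(dm))
  # representative label of a cluster = its lexicographically first leaf
  D <- dm

  while (length(clusters) > 1) {
    labs <- names(clusters)
    m <- length(labs)
    best <- NULL; bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- D[labs[i], labs[j]]
      pair <- sort(c(labs[i], labs[j]))
      if (dij < bestd ||
          (dij == bestd &&
           (pair[1] < best[1] || (pair[1] == best[1] && pair[2] < best[2])))) {
        bestd <- dij; best <- pair
      }
    }
    a <- best[1]; b <- best[2]
    node <- dendroNode(left = clusters[[a]], right = clusters[[b]],
                       height = bestd / 2)
    newlab <- min(a, b)
    others <- setdiff(labs, c(a, b))
    for (o in others) {
      D[o, a] <- (sizes[a] * D[o, a] + sizes[b] * D[o, b]) /
        (sizes[a] + sizes[b])
      D[a, o] <- D[o, a]
    }
    sizes[a] <- sizes[a] + sizes[b]
    clusters[[a]] <- node
    clusters[[b]] <- NULL
    if (newlab != a) {
      names(clusters)[names(clusters) == a] <- newlab
      rownames(D)[rownames(D) == a] <- newlab
      colnames(D)[colnames(D) == a] <- newlab
      names(sizes)[names(sizes) == a] <- newlab
    }
  }
  clusters[[1]]
}

#' Leaf depths of a dendrogram
#'
#' Distance from the root down to each leaf; under UPGMA all depths are
#' equal (the tree is ultrametric).
#'
#' @param node a `dendroNode`.
#' @return named numeric vector of root-to-leaf depths.
#' @export
dendroDepths <- function(node) {
  acc <- function(nd, fromRoot) {
    if (!is.null(nd$label))
      return(stats::setNames(fromRoot, nd$label))
    c(acc(nd$left, fromRoot + (nd$height - nd$left$height)),
      acc(nd$right, fromRoot + (nd$height - nd$right$height)))
  }
  acc(node, 0)[dendroLeaves(node)]
}
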