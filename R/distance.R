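#' Kosman-Leonard distance between two diploid genotype vectors
#'
#' Codominant allele-sharing dissimilarity. Per locus, the similarity is the
#' size of the multiset intersection of the two unordered allele pairs
#' divided by 2 (identical genotypes 1, one shared allele 0.5, disjoint 0);
#' the distance is one minus the mean similarity over loci called in both
#' individuals (pairwise deletion of missing loci).
#'
#' @param a1,b1 allele-index vectors (the two alleles) of individual 1
#' @param a2,b2 allele-index vectors of individual 2
#' @return list: `distance`, `n_loci`
#' @export
kosman_leonard_pair <- function(a1, b1, a2, b2) {
  stopifnot(length(a1) == length(b1), length(a1) == length(a2),
            length(a1) == length(b2))
  used <- !is.na(a1) & !is.na(a2)
  if (!any(used)) stop("no loci called in both individuals: pair unresolvable")
  a1 <- a1[used]; b1 <- b1[used]; a2 <- a2[used]; b2 <- b2[used]
  hom1 <- a1 == b1
  inter <- ifelse(hom1,
                  pmin(2, (a2 == a1) + (b2 == a1)),
                  ((a2 == a1) | (b2 == a1)) + ((a2 == b1) | (b2 == b1)))
  list(distance = 1 - mean(inter / 2), n_loci = sum(used))
}

#' Pairwise Kosman-Leonard distance matrix
#'
#' All accession pairs of a cohort, with per-pair used-locus counts for
#' transparency (pairwise deletion means each pair may rest on a different
#' locus set, so the distance is a semimetric: the triangle inequality is
#' not guaranteed under missing data).
#'
#' @param x a filtered [cohort()]
#' @param snps_only use SNP sites only (the analysis set)
#' @return a `kosman_dist` object: `labels`, `d` (square symmetric matrix),
#'   `n_loci_used`
#' @export
distance_matrix <- function(x, snps_only = TRUE) {
  keep <- if (snps_only) x$sites$is_snp else rep(TRUE, n_sites(x))
  ga <- x$gt_a[, keep, drop = FALSE]
  gb <- x$gt_b[, keep, drop = FALSE]
  n <- n_samples(x)
  if (n < 2) stop("need at least 2 accessions")
  labels <- x$samples$accession
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  nl <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(nl) <- as.integer(rowSums(!is.na(ga)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      kl <- tryCatch(
        kosman_leonard_pair(ga[i, ], gb[i, ], ga[j, ], gb[j, ]),
        error = function(e) stop("pair ", labels[i], " / ", labels[j], ": ",
                                 conditionMessage(e)))
      d[i, j] <- d[j, i] <- kl$distance
      nl[i, j] <- nl[j, i] <- kl$n_loci
    }
  }
  structure(list(labels = labels, d = d, n_loci_used = nl),
            class = "kosman_dist")
}

#' @export
print.kosman_dist <- function(x, ...) {
  cat(sprintf("<kosman_dist> %d accessions, %d-%d loci per pair\n",
              length(x$labels), min(x$n_loci_used[upper.tri(x$n_loci_used)]),
              max(x$n_loci_used[upper.tri(x$n_loci_used)])))
  print(round(x$d, 4))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Convenience summary of the distance matrix (the study's splits network is
#' built externally from the NEXUS export). Negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param dm a `kosman_dist` or square labelled matrix
#' @return Newick string (also returned with the `phylo` object as attribute
#'   `tree`)
#' @export
nj_tree <- function(dm) {
  m <- as_dist_matrix(dm)
  if (nrow(m) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  structure(ape::write.tree(tr), tree = tr)
}
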