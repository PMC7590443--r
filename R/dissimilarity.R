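#' Bray-Curtis dissimilarity matrix
#'
#' Computes d(i, j) = sum_c |x_ic - x_jc| / sum_c (x_ic + x_jc) between all
#' pairs of rows. On relative-amount profiles d lies in [0, 1]: 0 for
#' identical rows, 1 for rows with disjoint support. Pairs in which both rows
#' are all-zero have undefined dissimilarity; they are set to 0 with a
#' warning. Computation is delegated to \code{\link[vegan]{vegdist}}.
#'
#' @param profile A \code{\link{species_profile}} or non-negative matrix with
#'   row and column names.
#' @return Symmetric numeric matrix with zero diagonal, labelled by species.
#' @export
bray_curtis <- function(profile) {
  m <- unclass(as.matrix(profile))
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  if (is.null(rownames(m))) stop("profile rows must be labelled")
  zero <- rowSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (sum(zero) >= 2) {
    warning("pair(s) of all-zero rows: dissimilarity set to 0")
    d[zero, zero] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates scaled by
#' the square roots of the eigenvalues. Axes with eigenvalue below
#' \code{eigen_tolerance} times the largest eigenvalue are dropped; negative
#' eigenvalues (which arise for semimetric inputs such as Bray-Curtis) are
#' always dropped, without Cailliez or Lingoes correction (see Details).
#'
#' @details For a Euclidean distance matrix the pairwise Euclidean distances
#' between the returned scores reproduce the input exactly. For semimetric
#' inputs part of the variation sits on negative eigenvalues and the
#' reconstruction is approximate; the full eigenvalue spectrum is returned so
#' the discarded share can be inspected.
#'
#' @param d Symmetric distance matrix with zero diagonal and labels.
#' @param eigen_tolerance Relative tolerance below which positive axes are
#'   discarded; default 1e-8.
#' @return List of class \code{voc_pcoa}: \code{scores} (species x axis
#'   matrix, possibly 0 columns), \code{eigenvalues} (all eigenvalues, sorted
#'   decreasing), \code{retained} (indices of kept axes), \code{labels}.
#' @export
pcoa_scores <- function(d, eigen_tolerance = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be square and symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("obj", seq_len(nrow(d)))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  cutoff <- eigen_tolerance * max(vals, 0)
  keep <- which(vals > cutoff & vals > 0)
  scores <- if (length(keep)) {
    s <- e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(vals[keep]), length(keep))
    rownames(s) <- labels
    colnames(s) <- paste0("PCo", seq_along(keep))
    s
  } else {
    matrix(0, n, 0, dimnames = list(labels, NULL))
  }
  structure(list(scores = scores, eigenvalues = vals, retained = keep,
                 labels = labels),
            class = "voc_pcoa")
}

#' @export
print.voc_pcoa <- function(x, ...) {
  pos <- sum(x$eigenvalues > 0)
  cat("PCoA:", length(x$labels), "objects,", length(x$retained),
      "axes retained of", pos, "positive eigenvalues\n")
  invisible(x)
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with a choice of linkage. Rows are ordered
#' lexicographically by label before clustering so that ties in merge
#' heights are broken deterministically by label order.
#'
#' @param d Symmetric distance matrix with labels (e.g. from
#'   \code{\link{bray_curtis}}).
#' @param linkage One of \code{"UPGMA"} (average linkage, the default),
#'   \code{"complete"}, \code{"single"}, \code{"ward"} (Ward D2).
#' @return An \code{\link[stats]{hclust}} object.
#' @export
hierarchical_cluster <- function(d, linkage = c("UPGMA", "complete",
                                                "single", "ward")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 species to cluster")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  method <- c(UPGMA = "average", complete = "complete", single = "single",
              ward = "ward.D2")[[linkage]]
  stats::hclust(stats::as.dist(d), method = method)
}

#' Export a dendrogram as a Newick string or file
#'
#' Branch lengths are derived from the merge heights, so the exported tree is
#' ultrametric with tip-to-root distance equal to the root height.
#'
#' @param h An \code{\link[stats]{hclust}} object.
#' @param path Optional file path; if given the tree is written there.
#' @return The Newick string, invisibly if \code{path} is given.
#' @export
dendrogram_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (!is.null(path)) {
    ape::write.tree(phy, file = path)
    return(invisible(ape::write.tree(phy)))
  }
  ape::write.tree(phy)
}

#' Leaf order of a dendrogram
#'
#' The left-to-right tip ordering of the clustering, as used on one side of a
#' tanglegram.
#'
#' @param h An \code{\link[stats]{hclust}} object.
#' @return Character vector of labels in dendrogram order.
#' @export
leaf_order <- function(h) h$labels[h$order]

#' Write / read a labelled square distance matrix
#'
#' @param d Symmetric labelled matrix.
#' @param path File path (TSV; first column holds labels).
#' @return \code{path} invisibly (writer); the matrix (reader).
#' @export
write_dist_matrix <- function(d, path) {
  d <- as.matrix(d)
  utils::write.table(data.frame(label = rownames(d), d,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
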