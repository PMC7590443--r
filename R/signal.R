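# Shared eigendecomposition machinery for the phylogenetic covariance C.
# Eigenvalues below floor_rel * max(eigenvalue) are floored before inversion;
# zero-length branches from polytomies cannot make C singular on their own,
# but duplicated tips can, so near-singularity is reported.
.c_decomp <- function(C, floor_rel = 1e-10) {
  C <- as.matrix(C)
  N <- nrow(C)
  if (ncol(C) != N || max(abs(C - t(C))) > 1e-8 * max(abs(C), 1))
    stop("C must be a symmetric square matrix")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- e$values
  floor_val <- floor_rel * max(lam)
  if (floor_val <= 0) stop("C has no positive eigenvalue")
  n_floored <- sum(lam < floor_val)
  if (n_floored > 0)
    warning(n_floored, " eigenvalue(s) of C below the relative floor (",
            format(floor_rel), "); C is near-singular ",
            "(duplicated tips or zero-depth structure?)")
  lam <- pmax(lam, floor_val)
  V <- e$vectors
  inv <- V %*% (t(V) / lam)
  inv_sqrt <- V %*% (t(V) / sqrt(lam))
  w <- colSums(inv)                       # 1' C^-1
  denom <- sum(w)                         # 1' C^-1 1
  expected <- (sum(diag(C)) - N / denom) / (N - 1)
  list(N = N, inv = inv, inv_sqrt = inv_sqrt, w = w, denom = denom,
       expected = expected, labels = rownames(C))
}

.align_to_C <- function(Y, C) {
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C)))
      stop("row labels of the data do not match the covariance labels")
    Y <- Y[rownames(C), , drop = FALSE]
  } else if (nrow(Y) != nrow(C)) {
    stop("data rows and covariance dimension differ")
  }
  Y
}

#' Blomberg's K for a single trait
#'
#' K compares the observed partitioning of trait variance on a phylogeny with
#' the partitioning expected under Brownian motion:
#' \deqn{K = \frac{SS_0 / SS}{(\mathrm{tr}(C) - N / (1'C^{-1}1)) / (N-1)}}
#' where \eqn{\hat a = (1'C^{-1}y) / (1'C^{-1}1)} is the GLS estimate of the
#' root state, \eqn{SS_0 = (y-\hat a 1)'(y-\hat a 1)} and
#' \eqn{SS = (y-\hat a 1)'C^{-1}(y-\hat a 1)}. K = 1 matches the Brownian
#' expectation; K < 1 means less resemblance among relatives than Brownian
#' motion predicts, K > 1 more.
#'
#' @param y Numeric vector of per-species trait values, named by species when
#'   \code{C} has labels.
#' @param C Phylogenetic covariance matrix from \code{\link{phylo_cov}}, or a
#'   \code{phylo} tree (converted internally).
#' @return The K statistic (positive scalar).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' blomberg_k(c(A = 2, B = 1, C = 0), phylo_cov(tr))  # 101/96
#' @export
blomberg_k <- function(y, C) {
  if (inherits(C, "phylo")) C <- phylo_cov(C)
  Y <- matrix(as.numeric(y), ncol = 1,
              dimnames = list(names(y), NULL))
  kmult(Y, C)
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' The multivariate generalization of Blomberg's K for a species x variable
#' matrix Y (here typically PCoA scores of Bray-Curtis dissimilarities among
#' species scent profiles). With \eqn{\hat A = (1'C^{-1}1)^{-1} 1'C^{-1} Y}
#' the GLS root estimate and \eqn{R = Y - 1\hat A} the centred data,
#' \deqn{K_{mult} = \frac{\sum_{ij} R_{ij}^2 / \sum_{ij} (C^{-1/2}R)_{ij}^2}
#'   {(\mathrm{tr}(C) - N / (1'C^{-1}1)) / (N-1)}}
#' where \eqn{C^{-1/2}} is the symmetric inverse square root of the
#' phylogenetic covariance. For a single column this reduces exactly to
#' Blomberg's K.
#'
#' @param Y Numeric matrix, one row per species; rows are aligned to the
#'   labels of \code{C} when both are named. Constant columns are allowed
#'   (they contribute 0 to both sums of squares).
#' @param C Phylogenetic covariance matrix, or a \code{phylo} tree.
#' @return The Kmult statistic (positive scalar).
#' @export
kmult <- function(Y, C) {
  if (inherits(C, "phylo")) C <- phylo_cov(C)
  dec <- .c_decomp(C)
  Y <- .align_to_C(as.matrix(Y), C)
  .kmult_stat(Y, dec)
}

.kmult_stat <- function(Y, dec) {
  ranges <- apply(Y, 2, function(col) max(col) - min(col))
  if (all(ranges == 0))
    stop("all variables are constant across species; K is undefined")
  A <- (dec$w %*% Y) / dec$denom          # 1 x p GLS root estimate
  R <- Y - rep(1, dec$N) %*% A
  SS0 <- sum(R * R)
  PR <- dec$inv_sqrt %*% R
  SS <- sum(PR * PR)
  (SS0 / SS) / dec$expected
}

#' Permutation test for multivariate phylogenetic signal
#'
#' Builds the null distribution of Kmult by shuffling the species' data rows
#' across the tips of the phylogeny uniformly at random (equivalently,
#' shuffling tip labels), recomputing the statistic each time. The p-value
#' uses the add-one rule \eqn{p = (1 + \#\{K_{perm} \ge K_{obs}\}) /
#' (1 + n_{perm})}, so it is never exactly 0.
#'
#' @inheritParams kmult
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility (default 42). The global RNG
#'   state is restored on exit.
#' @return Object of class \code{signal_result}: list with
#'   \code{statistic}, \code{p_value}, \code{n_permutations},
#'   \code{null_sample} (the permuted statistics), \code{seed},
#'   \code{n_species}, \code{n_variables}.
#' @export
kmult_test <- function(Y, C, n_perm = 1000, seed = 42) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("'n_perm' must be >= 1")
  n_perm <- as.integer(n_perm)
  if (inherits(C, "phylo")) C <- phylo_cov(C)
  dec <- .c_decomp(C)
  Y <- .align_to_C(as.matrix(Y), C)
  obs <- .kmult_stat(Y, dec)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  null_sample <- vapply(seq_len(n_perm), function(i) {
    .kmult_stat(Y[sample.int(dec$N), , drop = FALSE], dec)
  }, numeric(1))
  p <- (1 + sum(null_sample >= obs)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 null_sample = null_sample, seed = seed,
                 n_species = dec$N, n_variables = ncol(Y)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Multivariate phylogenetic signal\n")
  cat(sprintf("  Kmult = %.4f   p = %.4g   (%d permutations, %d species, %d variables)\n",
              x$statistic, x$p_value, x$n_permutations, x$n_species,
              x$n_variables))
  invisible(x)
}

#' Serialize a signal result to a key/value report
#'
#' @param x A \code{signal_result}.
#' @param path Optional output path; plain \code{key<TAB>value} text.
#' @param extra Named list of extra fields to include (e.g. dataset label,
#'   axis count, dropped species).
#' @return The report as a named character vector, invisibly if written.
#' @export
write_signal_report <- function(x, path = NULL, extra = list()) {
  stopifnot(inherits(x, "signal_result"))
  fields <- c(list(statistic = x$statistic, p_value = x$p_value,
                   n_permutations = x$n_permutations, seed = x$seed,
                   n_species = x$n_species, n_variables = x$n_variables),
              extra)
  out <- vapply(fields, function(v) paste(format(v, digits = 15),
                                          collapse = ","), character(1))
  if (!is.null(path)) {
    writeLines(paste(names(out), out, sep = "\t"), path)
    return(invisible(out))
  }
  out
}
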