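#' Pair ripe and unripe class-level profiles
#'
#' Restricts two class-level species profiles to their common species, drops
#' the \code{unknown} class from both (without renormalizing the remaining
#' relative amounts: any relationship among unidentified compounds would be
#' uninterpretable, and their share is typically well under a few percent),
#' and records what was excluded.
#'
#' @param ripe,unripe Class-level \code{\link{species_profile}} objects.
#' @return List of class \code{paired_profiles}: \code{species},
#'   \code{ripe} and \code{unripe} (species x class matrices, same row
#'   order, unknown column removed), \code{dropped_species} (species present
#'   in only one stage), \code{unknown_share_mean} and
#'   \code{unknown_share_sd} (share of the unknown class across all retained
#'   rows of both stages, before exclusion).
#' @export
pair_ripe_unripe <- function(ripe, unripe) {
  for (p in list(ripe, unripe)) {
    stopifnot(inherits(p, "species_profile"))
    if (attr(p, "level") != "class")
      stop("pairing expects class-level profiles")
  }
  common <- intersect(rownames(ripe), rownames(unripe))
  if (!length(common)) stop("no species shared between ripe and unripe")
  dropped <- setdiff(union(rownames(ripe), rownames(unripe)), common)
  common <- sort(common)
  r <- unclass(ripe)[common, , drop = FALSE]
  u <- unclass(unripe)[common, , drop = FALSE]
  unk <- c(if ("unknown" %in% colnames(r)) r[, "unknown"],
           if ("unknown" %in% colnames(u)) u[, "unknown"])
  if (is.null(unk)) unk <- numeric()
  r <- r[, setdiff(colnames(r), "unknown"), drop = FALSE]
  u <- u[, setdiff(colnames(u), "unknown"), drop = FALSE]
  classes <- intersect(colnames(r), colnames(u))
  if (!length(classes)) stop("no shared known classes between the stages")
  structure(list(species = common,
                 ripe = r[, classes, drop = FALSE],
                 unripe = u[, classes, drop = FALSE],
                 dropped_species = dropped,
                 unknown_share_mean = if (length(unk)) mean(unk) else 0,
                 unknown_share_sd = if (length(unk) > 1) stats::sd(unk) else NA_real_),
            class = "paired_profiles")
}

#' Per-class ripe/unripe Spearman correlations
#'
#' For each known biochemical class, computes Spearman's rank correlation
#' (midranks for ties) between the per-species relative amounts in ripe and
#' unripe fruits, with a two-sided test of rho = 0. A class that is constant
#' in both stages has undefined rho and is reported as \code{NA}. The
#' abundance-weighted mean coefficient (weights = mean ripe relative amount
#' of each class) summarizes the overall developmental constraint.
#'
#' @param paired A \code{\link{pair_ripe_unripe}} result.
#' @param test \code{"asymptotic"} (t-approximation, default) or
#'   \code{"exact"} (exact permutation null, small n only, ties not allowed
#'   by the exact method).
#' @param normalize_weights Divide the weights by their sum (so they sum to 1
#'   over the classes entering the mean)? Default \code{TRUE}.
#' @return Object of class \code{devcorr_result}: list with \code{table}
#'   (data frame: class, rho, p, weight), \code{weighted_mean_rho},
#'   \code{n_species}, plus the unknown-share summary carried over from the
#'   pairing.
#' @export
spearman_by_class <- function(paired, test = c("asymptotic", "exact"),
                              normalize_weights = TRUE) {
  stopifnot(inherits(paired, "paired_profiles"))
  test <- match.arg(test)
  n <- length(paired$species)
  if (n < 3) stop("need at least 3 shared species")
  classes <- colnames(paired$ripe)
  rho <- p <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (k in classes) {
    x <- paired$unripe[, k]
    y <- paired$ripe[, k]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) next  # constant: undefined
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(
      x, y, method = "spearman", exact = (test == "exact"),
      alternative = "two.sided"))
    rho[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  w <- colMeans(paired$ripe)
  res <- data.frame(class = classes, rho = rho, p = p, weight = w,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = res,
                 weighted_mean_rho = weighted_mean_rho(res, normalize_weights),
                 n_species = n,
                 unknown_share_mean = paired$unknown_share_mean,
                 unknown_share_sd = paired$unknown_share_sd),
            class = "devcorr_result")
}

#' Abundance-weighted mean correlation coefficient
#'
#' Mean of the per-class Spearman coefficients weighted by the average ripe
#' relative amount of each class; classes with undefined rho are excluded
#' from numerator and denominator.
#'
#' @param x A \code{devcorr_result} or its \code{table} data frame (columns
#'   \code{rho} and \code{weight}).
#' @param normalize Divide by the sum of the weights used? Default
#'   \code{TRUE}; with \code{FALSE} the raw ripe shares (which sum to < 1
#'   after excluding the unknown class) are used as-is.
#' @return The weighted mean coefficient.
#' @export
weighted_mean_rho <- function(x, normalize = TRUE) {
  tab <- if (inherits(x, "devcorr_result")) x$table else x
  ok <- !is.na(tab$rho)
  if (!any(ok)) stop("no class has a defined correlation coefficient")
  w <- tab$weight[ok]
  denom <- if (normalize) sum(w) else 1
  if (normalize && denom == 0) stop("all weights are zero")
  sum(w * tab$rho[ok]) / denom
}

#' @export
print.devcorr_result <- function(x, ...) {
  cat("Ripe vs unripe class-composition correlations (",
      x$n_species, " species)\n", sep = "")
  tab <- x$table
  tab$rho <- round(tab$rho, 3)
  tab$p <- signif(tab$p, 3)
  tab$weight <- round(tab$weight, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Weighted mean rho: %.3f\n", x$weighted_mean_rho))
  if (!is.na(x$unknown_share_mean))
    cat(sprintf("Unknown-class share excluded: mean %.2f%%\n",
                100 * x$unknown_share_mean))
  invisible(x)
}

#' Write the per-class correlation table
#'
#' Tabular export (class, rho, p, weight) with the weighted mean appended as
#' a final row labelled \code{weighted_mean}.
#'
#' @param x A \code{devcorr_result}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_devcorr <- function(x, path) {
  stopifnot(inherits(x, "devcorr_result"))
  tab <- x$table
  tab <- rbind(tab, data.frame(class = "weighted_mean",
                               rho = x$weighted_mean_rho, p = NA_real_,
                               weight = NA_real_))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
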