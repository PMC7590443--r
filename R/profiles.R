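#' Species mean amounts
#'
#' Averages compound amounts over all samples of each species. Absences
#' (zeros) contribute to the mean, so a compound found in 1 of 4 samples at
#' amount 8 has a species mean of 2.
#'
#' @param x A \code{\link{scent_table}}.
#' @param ripeness Optional ripeness stage to restrict to before averaging.
#' @return Numeric matrix, species x compound, species sorted alphabetically.
#' @export
species_means <- function(x, ripeness = NULL) {
  stopifnot(inherits(x, "scent_table"))
  if (!is.null(ripeness)) x <- subset_samples(x, ripeness = ripeness)
  sp <- x$meta$species
  counts <- table(sp)
  m <- rowsum(x$amounts, sp, reorder = TRUE)
  m / as.vector(counts[rownames(m)])
}

#' Convert amounts to relative amounts (compositional profile)
#'
#' Divides each row by its row sum so that every species' profile sums to 1.
#' All-zero rows are left at zero and recorded in the \code{"zero_rows"}
#' attribute with a warning.
#'
#' @param m Non-negative numeric matrix (species x feature) or a
#'   \code{species_profile}.
#' @param level Feature level of the input, \code{"compound"} or
#'   \code{"class"}; stored on the result.
#' @return A \code{species_profile}: the row-normalized matrix with
#'   attributes \code{level} and \code{zero_rows}.
#' @export
relative_amounts <- function(m, level = c("compound", "class")) {
  level <- match.arg(level)
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0))
    stop("amounts must be finite and >= 0")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero))
    warning("all-zero profile row(s): ",
            paste(rownames(m)[zero], collapse = ", "))
  out <- m / ifelse(zero, 1, totals)
  species_profile(out, level = level, zero_rows = rownames(m)[zero])
}

#' Species profile container
#'
#' A species x feature matrix of relative amounts (rows sum to 1 unless
#' all-zero), with the feature level recorded.
#'
#' @param values Numeric matrix with species row names and feature column
#'   names; entries in [0, 1], rows summing to 1 or 0.
#' @param level \code{"compound"} or \code{"class"}.
#' @param zero_rows Character vector of all-zero species (default none).
#' @return An object of class \code{species_profile}.
#' @export
species_profile <- function(values, level = c("compound", "class"),
                            zero_rows = character()) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("profile needs species row names and feature column names")
  if (any(values < -1e-12) || any(values > 1 + 1e-9))
    stop("relative amounts must lie in [0, 1]")
  rs <- rowSums(values)
  ok <- abs(rs - 1) <= 1e-9 | rs == 0
  if (!all(ok))
    stop("profile rows must sum to 1 (or be all-zero); offending: ",
         paste(rownames(values)[!ok], collapse = ", "))
  structure(values, class = c("species_profile", class(values)),
            level = level, zero_rows = zero_rows)
}

#' @export
print.species_profile <- function(x, ...) {
  cat("Species profile (", attr(x, "level"), " level): ",
      nrow(x), " species x ", ncol(x), " features\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Aggregate a compound-level profile into biochemical classes
#'
#' Sums the relative amounts of member compounds within each of the seven
#' biochemical classes. Row sums are preserved exactly; output columns follow
#' the canonical class order of \code{\link{voc_classes}} (classes with no
#' member compound are omitted).
#'
#' @param profile A compound-level \code{\link{species_profile}}.
#' @param cmap A \code{\link{class_map}} covering every compound in
#'   \code{profile}.
#' @return A class-level \code{species_profile}.
#' @export
aggregate_classes <- function(profile, cmap) {
  stopifnot(inherits(profile, "species_profile"))
  if (attr(profile, "level") != "compound")
    stop("profile is already at class level")
  stopifnot(inherits(cmap, "class_map"))
  missing <- setdiff(colnames(profile), names(cmap))
  if (length(missing))
    stop("compound(s) missing from class map: ",
         paste(missing, collapse = ", "))
  cls <- as.character(cmap[colnames(profile)])
  present <- voc_classes()[voc_classes() %in% cls]
  out <- sapply(present, function(k)
    rowSums(unclass(profile)[, cls == k, drop = FALSE]))
  if (nrow(profile) == 1)
    out <- matrix(out, 1, dimnames = list(rownames(profile), present))
  species_profile(out, level = "class", zero_rows = attr(profile, "zero_rows"))
}
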