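#' Filter contaminant, ubiquitous and rare compounds from a scent table
#'
#' Applies up to four removal rules used when cleaning headspace GC-MS tables:
#' \describe{
#'   \item{control}{compounds predominantly present in control (empty-chamber)
#'     samples: mean amount across control samples >= mean amount across
#'     fruit samples. Only applied when \code{control_samples} is non-empty.}
#'   \item{ubiquity}{compounds present (amount > 0) in more than
#'     \code{ubiquity_threshold} of all non-control samples; a volatile found
#'     in essentially every sample of every species is more plausibly a
#'     contaminant than a genuine fruit compound.}
#'   \item{rare}{compounds present in exactly one species and in fewer than
#'     \code{rare_sample_fraction} of the dataset's non-control samples.}
#'   \item{max_share}{compounds whose share of a species' total emission
#'     (computed on species mean amounts) never exceeds
#'     \code{max_share_threshold} in any species.}
#' }
#' A compound is removed if any requested rule fires. Samples are never
#' removed; downstream analyses should drop control samples explicitly
#' (see \code{\link{subset_samples}}).
#'
#' @param x A \code{\link{scent_table}}.
#' @param control_samples Character vector of sample identifiers that are
#'   controls (may be empty).
#' @param ubiquity_threshold Fraction in (0, 1]; default 0.9.
#' @param rare_sample_fraction Fraction in (0, 1]; default 0.25.
#' @param max_share_threshold Fraction in (0, 1]; default 0.01.
#' @param rules Character vector choosing which rules to apply; any subset of
#'   \code{c("control", "ubiquity", "rare", "max_share")}.
#' @return A filtered \code{scent_table}. The removal log is attached as
#'   attribute \code{"removal_log"} (a data frame with columns
#'   \code{compound}, \code{rule}, \code{statistic}) and is retrievable with
#'   \code{\link{removal_log}}.
#' @export
filter_compounds <- function(x, control_samples = character(),
                             ubiquity_threshold = 0.9,
                             rare_sample_fraction = 0.25,
                             max_share_threshold = 0.01,
                             rules = c("control", "ubiquity", "rare",
                                       "max_share")) {
  stopifnot(inherits(x, "scent_table"))
  rules <- match.arg(rules, several.ok = TRUE)
  for (thr in c(ubiquity_threshold, rare_sample_fraction, max_share_threshold))
    if (!is.numeric(thr) || length(thr) != 1 || thr <= 0 || thr > 1)
      stop("thresholds must be single numbers in (0, 1]")
  if (ncol(x$amounts) == 0) stop("scent table has no compounds")

  is_control <- x$meta$sample %in% control_samples
  if (length(control_samples) && !any(is_control))
    warning("none of 'control_samples' found in the table")
  fruit <- x$amounts[!is_control, , drop = FALSE]
  fruit_species <- x$meta$species[!is_control]
  if (!nrow(fruit)) stop("no non-control samples in the table")

  log_rows <- list()
  note <- function(compounds, rule, stat) {
    if (length(compounds))
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        compound = compounds, rule = rule, statistic = stat,
        stringsAsFactors = FALSE)
  }

  if ("control" %in% rules && any(is_control)) {
    ctrl_mean <- colMeans(x$amounts[is_control, , drop = FALSE])
    fruit_mean <- colMeans(fruit)
    hit <- ctrl_mean >= fruit_mean & ctrl_mean > 0
    note(colnames(fruit)[hit], "control",
         (ctrl_mean / pmax(fruit_mean, .Machine$double.xmin))[hit])
  }

  present <- fruit > 0
  if ("ubiquity" %in% rules) {
    frac <- colMeans(present)
    hit <- frac > ubiquity_threshold
    note(colnames(fruit)[hit], "ubiquity", frac[hit])
  }

  if ("rare" %in% rules) {
    n_species_with <- apply(present, 2, function(p)
      length(unique(fruit_species[p])))
    frac <- colMeans(present)
    hit <- n_species_with == 1 & frac < rare_sample_fraction
    note(colnames(fruit)[hit], "rare", frac[hit])
  }

  if ("max_share" %in% rules) {
    sp_mean <- rowsum(fruit, fruit_species, reorder = TRUE) /
      as.vector(table(fruit_species)[sort(unique(fruit_species))])
    totals <- rowSums(sp_mean)
    share <- sp_mean / ifelse(totals > 0, totals, 1)
    max_share <- apply(share, 2, max)
    hit <- max_share <= max_share_threshold
    note(colnames(fruit)[hit], "max_share", max_share[hit])
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(compound = character(), rule = character(),
               statistic = numeric(), stringsAsFactors = FALSE)
  removed <- unique(log$compound)
  keep <- setdiff(colnames(x$amounts), removed)
  if (!length(keep)) stop("all compounds removed by filtering")

  out <- scent_table(x$amounts[, keep, drop = FALSE],
                     species = x$meta$species,
                     individual = x$meta$individual,
                     ripeness = x$meta$ripeness,
                     site = x$meta$site)
  attr(out, "removal_log") <- log
  out
}

#' Retrieve the compound-removal log of a filtered scent table
#'
#' @param x A \code{scent_table} returned by \code{\link{filter_compounds}}.
#' @return Data frame with columns \code{compound}, \code{rule},
#'   \code{statistic} (one row per compound-rule hit), or an empty data frame
#'   if nothing was removed.
#' @export
removal_log <- function(x) {
  log <- attr(x, "removal_log")
  if (is.null(log))
    log <- data.frame(compound = character(), rule = character(),
                      statistic = numeric(), stringsAsFactors = FALSE)
  log
}

#' Write a removal log as TSV
#'
#' @param x A filtered \code{scent_table} or a removal-log data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_removal_log <- function(x, path) {
  log <- if (is.data.frame(x)) x else removal_log(x)
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
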