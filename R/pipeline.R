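#' End-to-end phylogenetic-signal analysis of a scent dataset
#'
#' Runs the full chain used for a single study site: compound filtering,
#' species mean amounts, relative amounts, optional aggregation into
#' biochemical classes, Bray-Curtis dissimilarities among species, principal
#' coordinates, Kmult on the scores with a tip-shuffling permutation test,
#' and hierarchical clustering for tanglegram export. Each site's table is
#' analysed separately; no cross-site pooling is performed.
#'
#' @param table A \code{\link{scent_table}} (control samples may be present;
#'   they are used by the filtering rules and then dropped).
#' @param tree A \code{phylo} object whose tips cover the species.
#' @param cmap A \code{\link{class_map}}; required when
#'   \code{level = "class"}.
#' @param level Analyse at \code{"compound"} (default) or \code{"class"}
#'   level.
#' @param ripeness Stage analysed; default \code{"ripe"}.
#' @param control_samples Sample identifiers of blank/control samples.
#' @param filter_rules Filtering rules passed to
#'   \code{\link{filter_compounds}}; \code{NULL} disables filtering.
#' @param ubiquity_threshold,rare_sample_fraction,max_share_threshold
#'   Filtering thresholds (defaults 0.9, 0.25, 0.01).
#' @param normalize_first Normalize per sample before species averaging,
#'   instead of averaging absolute amounts and then normalizing (the
#'   default)?
#' @param n_perm Permutations for the signal test (default 1000).
#' @param seed Integer seed (default 42).
#' @param linkage Linkage for the dendrogram (default \code{"UPGMA"}).
#' @param eigen_tolerance Relative eigenvalue tolerance for PCoA axes.
#' @param output_dir Optional directory; when given, the distance matrix,
#'   PCoA scores, dendrogram and pruned-tree Newick files, leaf order,
#'   removal log and result report are written there.
#' @param dataset Label used in the report and file names.
#' @return List of class \code{signal_run}: \code{signal} (a
#'   \code{signal_result}), \code{profile}, \code{dist}, \code{pcoa},
#'   \code{cluster} (hclust), \code{tree} (pruned), \code{unmatched_species},
#'   \code{removal_log}, \code{config}.
#' @export
run_signal <- function(table, tree, cmap = NULL,
                       level = c("compound", "class"),
                       ripeness = "ripe",
                       control_samples = character(),
                       filter_rules = c("control", "ubiquity", "rare",
                                        "max_share"),
                       ubiquity_threshold = 0.9,
                       rare_sample_fraction = 0.25,
                       max_share_threshold = 0.01,
                       normalize_first = FALSE,
                       n_perm = 1000, seed = 42,
                       linkage = "UPGMA", eigen_tolerance = 1e-8,
                       output_dir = NULL, dataset = "dataset") {
  level <- match.arg(level)
  stopifnot(inherits(table, "scent_table"))
  if (level == "class" && is.null(cmap))
    stop("class-level analysis requires a class map")

  rlog <- NULL
  if (!is.null(filter_rules)) {
    table <- filter_compounds(table, control_samples = control_samples,
                              ubiquity_threshold = ubiquity_threshold,
                              rare_sample_fraction = rare_sample_fraction,
                              max_share_threshold = max_share_threshold,
                              rules = filter_rules)
    rlog <- removal_log(table)
  }
  keep <- !(table$meta$sample %in% control_samples) &
    table$meta$ripeness == ripeness
  if (!any(keep)) stop("stage [species_means]: no analysis samples left")
  table <- subset_samples(table, samples = keep)

  if (normalize_first) {
    rel_samp <- relative_amounts(table$amounts)
    table$amounts <- unclass(rel_samp)
  }
  means <- species_means(table)
  profile <- relative_amounts(means)
  if (level == "class") {
    profile <- aggregate_classes(profile, cmap)
    if (ncol(profile) < 2)
      stop("stage [aggregate_classes]: composition is degenerate ",
           "(single biochemical class); dissimilarities carry no variance")
  }

  pm <- prune_and_match(tree, rownames(profile))
  profile_m <- species_profile(
    unclass(profile)[names(pm$matched), , drop = FALSE],
    level = level, zero_rows = attr(profile, "zero_rows"))

  d <- bray_curtis(profile_m)
  ord <- pcoa_scores(d, eigen_tolerance = eigen_tolerance)
  if (ncol(ord$scores) == 0)
    stop("stage [pcoa]: no positive principal-coordinate axes")
  C <- phylo_cov(pm$tree)
  sig <- kmult_test(ord$scores, C, n_perm = n_perm, seed = seed)
  cl <- hierarchical_cluster(d, linkage = linkage)

  res <- structure(list(
    signal = sig, profile = profile_m, dist = d, pcoa = ord, cluster = cl,
    tree = pm$tree, unmatched_species = pm$unmatched, removal_log = rlog,
    config = list(dataset = dataset, level = level, ripeness = ripeness,
                  n_perm = n_perm, seed = seed, linkage = linkage,
                  eigen_tolerance = eigen_tolerance,
                  normalize_first = normalize_first,
                  filter_rules = filter_rules,
                  thresholds = c(ubiquity = ubiquity_threshold,
                                 rare = rare_sample_fraction,
                                 max_share = max_share_threshold))),
    class = "signal_run")
  if (!is.null(output_dir)) write_signal_run(res, output_dir)
  res
}

#' @export
print.signal_run <- function(x, ...) {
  cat("Signal run [", x$config$dataset, ", ", x$config$level,
      " level]\n", sep = "")
  print(x$signal)
  if (length(x$unmatched_species))
    cat("  species not in tree:",
        paste(x$unmatched_species, collapse = ", "), "\n")
  invisible(x)
}

#' Write the artifacts of a signal run
#'
#' Emits plain-text artifacts into a directory: Bray-Curtis matrix (TSV),
#' PCoA scores (TSV), cluster dendrogram and pruned phylogeny (Newick),
#' leaf orders of both trees (for tanglegram assembly), compound-removal log
#' (TSV) and a key/value result report echoing the configuration.
#'
#' @param x A \code{signal_run}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_signal_run <- function(x, dir) {
  stopifnot(inherits(x, "signal_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(x$config$dataset, "_", x$config$level)
  paths <- c(
    dist = file.path(dir, paste0(tag, "_braycurtis.tsv")),
    scores = file.path(dir, paste0(tag, "_pcoa_scores.tsv")),
    dendrogram = file.path(dir, paste0(tag, "_cluster.nwk")),
    phylogeny = file.path(dir, paste0(tag, "_phylogeny.nwk")),
    leaves = file.path(dir, paste0(tag, "_leaf_order.tsv")),
    report = file.path(dir, paste0(tag, "_signal_report.tsv")))
  write_dist_matrix(x$dist, paths["dist"])
  utils::write.table(
    data.frame(species = rownames(x$pcoa$scores), x$pcoa$scores,
               check.names = FALSE),
    paths["scores"], sep = "\t", row.names = FALSE, quote = FALSE)
  dendrogram_newick(x$cluster, paths["dendrogram"])
  ape::write.tree(x$tree, file = paths["phylogeny"])
  phylo_leaves <- x$tree$tip.label
  lo <- leaf_order(x$cluster)
  utils::write.table(
    data.frame(position = seq_along(lo), cluster = lo,
               phylogeny = phylo_leaves[seq_along(lo)]),
    paths["leaves"], sep = "\t", row.names = FALSE, quote = FALSE)
  write_signal_report(
    x$signal, paths["report"],
    extra = list(dataset = x$config$dataset, level = x$config$level,
                 ripeness = x$config$ripeness, linkage = x$config$linkage,
                 n_axes = ncol(x$pcoa$scores),
                 unmatched_species = if (length(x$unmatched_species))
                   paste(x$unmatched_species, collapse = ";") else "none"))
  if (!is.null(x$removal_log)) {
    paths["removal_log"] <- file.path(dir, paste0(tag, "_removal_log.tsv"))
    write_removal_log(x$removal_log, paths["removal_log"])
  }
  invisible(paths)
}

#' End-to-end developmental-constraint analysis
#'
#' From a scent table containing both ripe and unripe samples: species means
#' and relative amounts per stage, aggregation into biochemical classes,
#' pairing of the stages (dropping the unknown class), per-class Spearman
#' correlations with tests, and the abundance-weighted mean coefficient.
#'
#' @param table A \code{\link{scent_table}} with both ripeness stages (or
#'   \code{ripe}/\code{unripe} given directly).
#' @param cmap A \code{\link{class_map}}.
#' @param ripe,unripe Alternatively, ready-made class-level
#'   \code{\link{species_profile}} objects (then \code{table} and
#'   \code{cmap} are ignored).
#' @param test,normalize_weights Passed to \code{\link{spearman_by_class}}.
#' @param output_dir Optional directory for the tabular result export.
#' @param dataset Label used in file names.
#' @return A \code{devcorr_result} (see \code{\link{spearman_by_class}}),
#'   with the pairing stored in attribute \code{"paired"}.
#' @export
run_devcorr <- function(table = NULL, cmap = NULL, ripe = NULL, unripe = NULL,
                        test = "asymptotic", normalize_weights = TRUE,
                        output_dir = NULL, dataset = "dataset") {
  if (is.null(ripe) || is.null(unripe)) {
    stopifnot(inherits(table, "scent_table"), inherits(cmap, "class_map"))
    stage_profile <- function(stage) {
      m <- species_means(table, ripeness = stage)
      aggregate_classes(relative_amounts(m), cmap)
    }
    ripe <- stage_profile("ripe")
    unripe <- stage_profile("unripe")
  }
  paired <- pair_ripe_unripe(ripe, unripe)
  res <- spearman_by_class(paired, test = test,
                           normalize_weights = normalize_weights)
  attr(res, "paired") <- paired
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_devcorr(res, file.path(output_dir,
                                 paste0(dataset, "_devcorr.tsv")))
  }
  res
}
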