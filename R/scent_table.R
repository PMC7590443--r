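#' Canonical biochemical class labels
#'
#' The seven pathway-based classes used to group fruit volatiles: fatty-acid
#' derivatives (aliphatics), aromatics, C5-branched compounds, terpenoids,
#' nitrogen/sulfur-containing compounds, miscellaneous cyclic compounds, and
#' unknown. The order is fixed so that class-level outputs are byte-stable.
#'
#' @return Character vector of the seven class labels, in canonical order.
#' @export
voc_classes <- function() {
  c("aliphatics", "aromatics", "C5-branched", "terpenoids",
    "nitrogen_sulfur", "misc_cyclic", "unknown")
}

#' Construct a scent table
#'
#' A scent table holds a sample x compound matrix of non-negative,
#' internal-standard-normalized amounts together with per-sample metadata
#' (species, individual, ripeness stage, site).
#'
#' @param amounts Numeric matrix, samples in rows, compounds in columns.
#'   Row names are sample identifiers, column names compound identifiers.
#' @param species Character vector of species names, one per sample.
#' @param individual Optional character vector of individual plant identifiers.
#' @param ripeness Optional character vector, each element \code{"ripe"} or
#'   \code{"unripe"}.
#' @param site Optional character vector of site labels.
#' @return An object of class \code{scent_table}: a list with elements
#'   \code{amounts} (the matrix) and \code{meta} (a data frame with columns
#'   \code{sample}, \code{species}, \code{individual}, \code{ripeness},
#'   \code{site}).
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("hexanal", "limonene")))
#' scent_table(m, species = c("Ficus_lutea", "Ficus_lutea"))
#' @export
scent_table <- function(amounts, species, individual = NULL, ripeness = NULL,
                        site = NULL) {
  if (!is.matrix(amounts) || !is.numeric(amounts))
    stop("'amounts' must be a numeric matrix (samples x compounds)")
  if (is.null(rownames(amounts)))
    rownames(amounts) <- paste0("sample", seq_len(nrow(amounts)))
  if (is.null(colnames(amounts)))
    stop("'amounts' must have compound identifiers as column names")
  if (anyDuplicated(rownames(amounts)))
    stop("sample identifiers must be unique")
  if (anyDuplicated(colnames(amounts)))
    stop("compound identifiers must be unique")
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("all amounts must be finite and >= 0")
  n <- nrow(amounts)
  species <- as.character(species)
  if (length(species) != n)
    stop("'species' must have one entry per sample")
  if (anyNA(species) || any(!nzchar(species)))
    stop("every sample needs a species label")
  fill <- function(x, default) {
    if (is.null(x)) return(rep(default, n))
    x <- as.character(x)
    if (length(x) != n) stop("metadata vectors must have one entry per sample")
    x
  }
  ripeness <- fill(ripeness, "ripe")
  bad <- setdiff(unique(ripeness), c("ripe", "unripe"))
  if (length(bad))
    stop("ripeness must be 'ripe' or 'unripe'; got: ", paste(bad, collapse = ", "))
  meta <- data.frame(
    sample = rownames(amounts),
    species = species,
    individual = fill(individual, NA_character_),
    ripeness = ripeness,
    site = fill(site, NA_character_),
    stringsAsFactors = FALSE
  )
  structure(list(amounts = amounts, meta = meta), class = "scent_table")
}

#' @export
print.scent_table <- function(x, ...) {
  cat("Scent table:", nrow(x$amounts), "samples x", ncol(x$amounts),
      "compounds\n")
  cat("  species: ", length(unique(x$meta$species)),
      " | ripeness: ", paste(sort(unique(x$meta$ripeness)), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.scent_table <- function(x) dim(x$amounts)

#' Subset a scent table by sample
#'
#' @param x A \code{\link{scent_table}}.
#' @param samples Character vector of sample identifiers to keep, or a logical
#'   vector over samples.
#' @param ripeness Optional ripeness stage (\code{"ripe"} or \code{"unripe"});
#'   applied after \code{samples}.
#' @param drop_empty_compounds Drop compounds absent from every retained
#'   sample? Default \code{FALSE}.
#' @return A \code{scent_table} restricted to the selected samples.
#' @export
subset_samples <- function(x, samples = NULL, ripeness = NULL,
                           drop_empty_compounds = FALSE) {
  stopifnot(inherits(x, "scent_table"))
  keep <- rep(TRUE, nrow(x$amounts))
  if (!is.null(samples)) {
    if (is.logical(samples)) keep <- keep & samples
    else keep <- keep & (x$meta$sample %in% samples)
  }
  if (!is.null(ripeness)) keep <- keep & (x$meta$ripeness %in% ripeness)
  if (!any(keep)) stop("no samples left after subsetting")
  amounts <- x$amounts[keep, , drop = FALSE]
  if (drop_empty_compounds)
    amounts <- amounts[, colSums(amounts) > 0, drop = FALSE]
  out <- scent_table(amounts,
                     species = x$meta$species[keep],
                     individual = x$meta$individual[keep],
                     ripeness = x$meta$ripeness[keep],
                     site = x$meta$site[keep])
  out
}

# metadata columns recognized in delimited scent tables, in write order
.meta_cols <- c("sample", "species", "individual", "ripeness", "site")

#' Read a scent table from delimited text
#'
#' Expects a wide table: one row per sample, metadata columns (\code{sample}
#' and \code{species} required; \code{individual}, \code{ripeness},
#' \code{site} optional) followed by one numeric column per compound.
#' Empty cells are read as 0 (absence), matching the occurrence-style wide
#' tables these data are distributed in.
#'
#' @param path Path to a CSV or TSV file; the delimiter is chosen from the
#'   file extension (\code{.tsv}/\code{.txt} = tab, otherwise comma) unless
#'   \code{sep} is given.
#' @param sep Optional field delimiter override.
#' @return A \code{\link{scent_table}}.
#' @export
read_scent_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!all(c("sample", "species") %in% names(df)))
    stop("scent table file must contain 'sample' and 'species' columns")
  meta_present <- intersect(.meta_cols, names(df))
  comp_cols <- setdiff(names(df), meta_present)
  if (!length(comp_cols)) stop("no compound columns found")
  amounts <- as.matrix(df[comp_cols])
  amounts[is.na(amounts)] <- 0
  storage.mode(amounts) <- "double"
  rownames(amounts) <- as.character(df$sample)
  scent_table(amounts,
              species = df$species,
              individual = if ("individual" %in% names(df)) df$individual,
              ripeness = if ("ripeness" %in% names(df)) df$ripeness,
              site = if ("site" %in% names(df)) df$site)
}

#' Write a scent table to delimited text
#'
#' Mirrors the format read by \code{\link{read_scent_table}}.
#'
#' @param x A \code{\link{scent_table}}.
#' @param path Output path; extension selects the delimiter as in
#'   \code{\link{read_scent_table}}.
#' @return \code{path}, invisibly.
#' @export
write_scent_table <- function(x, path) {
  stopifnot(inherits(x, "scent_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(x$meta, as.data.frame(x$amounts, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a compound-to-class map
#'
#' @param class_of Named character vector: names are compound identifiers,
#'   values are class labels drawn from \code{\link{voc_classes}}.
#' @return A named character vector of class \code{class_map}.
#' @export
class_map <- function(class_of) {
  class_of <- unlist(class_of)
  if (is.null(names(class_of)) || any(!nzchar(names(class_of))))
    stop("'class_of' must be named by compound identifier")
  if (anyDuplicated(names(class_of)))
    stop("duplicate compound identifiers in class map")
  bad <- setdiff(unique(class_of), voc_classes())
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(voc_classes(), collapse = ", "))
  structure(class_of, class = "class_map")
}

#' Read a compound-to-class map from delimited text
#'
#' Expects two columns, \code{compound} and \code{class}.
#'
#' @inheritParams read_scent_table
#' @return A \code{\link{class_map}}.
#' @export
read_class_map <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("compound", "class") %in% names(df)))
    stop("class map file must contain 'compound' and 'class' columns")
  class_map(stats::setNames(df$class, df$compound))
}

#' Write a compound-to-class map
#'
#' @param x A \code{\link{class_map}}.
#' @param path Output path (CSV/TSV by extension).
#' @return \code{path}, invisibly.
#' @export
write_class_map <- function(x, path) {
  stopifnot(inherits(x, "class_map"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(
    data.frame(compound = names(x), class = as.character(x)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
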