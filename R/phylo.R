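#' Prune a phylogeny to a species set, with label matching
#'
#' Tip labels and species names are compared after normalization (spaces and
#' underscores interchangeable, case-insensitive). Optionally, species named
#' only to genus (or simply absent from the tree) can fall back to a random
#' congeneric tip, drawn reproducibly from \code{seed}.
#'
#' @param tree An \code{\link[ape]{ape}} \code{phylo} object with branch
#'   lengths; polytomies are allowed.
#' @param species Character vector of species names to retain.
#' @param match_genus Allow genus-level fallback for unmatched species?
#'   Default \code{FALSE}.
#' @param seed Integer seed used only for the genus fallback draw.
#' @return List with \code{tree} (the pruned \code{phylo}, tips renamed to
#'   the matched species names), \code{matched} (named character vector:
#'   species -> tip used), and \code{unmatched} (species not placed).
#' @export
prune_and_match <- function(tree, species, match_genus = FALSE, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || !length(tree$tip.label))
    stop("tree has no tips")
  norm <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))
  tipn <- norm(tree$tip.label)
  spn <- norm(species)
  idx <- match(spn, tipn)
  matched <- stats::setNames(tree$tip.label[idx], species)
  unmatched <- species[is.na(idx)]
  if (match_genus && length(unmatched)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    genus_of <- function(x) sub("_.*$", "", norm(x))
    tip_genus <- genus_of(tree$tip.label)
    still <- character()
    for (sp in unmatched) {
      cand <- which(tip_genus == genus_of(sp) &
                      !(tree$tip.label %in% matched))
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1)]
        matched[sp] <- tree$tip.label[pick]
      } else still <- c(still, sp)
    }
    unmatched <- still
  }
  matched <- matched[!is.na(matched)]
  if (length(matched) < 3)
    stop("fewer than 3 species matched to the tree")
  pruned <- ape::keep.tip(tree, unname(matched))
  # rename tips to the caller's species names so downstream labels align
  pruned$tip.label <- names(matched)[match(pruned$tip.label, matched)]
  list(tree = pruned, matched = matched, unmatched = unmatched)
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' C[i, j] is the shared root-to-tip branch length of tips i and j (the depth
#' of their most recent common ancestor); the diagonal holds root-to-tip
#' distances. This is the trait covariance implied by Brownian motion on the
#' tree. Polytomies are handled natively; no resolution is applied.
#'
#' @param tree A rooted \code{phylo} object with non-negative branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_cov <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}
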