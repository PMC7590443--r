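#' Configuration for the synthetic scent-data generators
#'
#' Collects the knobs shared by the generators. Defaults mirror the
#' developmental-constraint study system: 30 species with 3 sampled
#' individuals each, a few dozen volatiles dominated by aliphatics,
#' aromatics and terpenoids with a ~1% unknown share, strongly zero-inflated
#' occurrence, and a high ripe/unripe class correlation with high compound
#' turnover (species switch compounds within classes upon ripening).
#'
#' @param n_species Number of species (>= 3).
#' @param n_individuals Individuals sampled per species.
#' @param n_compounds Number of volatile compounds.
#' @param class_proportions Named 7-vector of expected class shares, summing
#'   to 1, in the order of \code{\link{voc_classes}}.
#' @param zero_inflation Probability that a compound is absent from a
#'   species' profile.
#' @param bm_sigma2 Brownian-motion rate (trait variance per unit branch
#'   length) used when traits are evolved on a tree.
#' @param target_class_rho Target Spearman correlation between ripe and
#'   unripe class compositions, in [-1, 1].
#' @param compound_turnover Probability that a compound present in unripe
#'   fruit is replaced by a different same-class compound in ripe fruit.
#' @param amount_sdlog,indiv_sdlog Log-scale standard deviations of the
#'   log-normal species amounts and of the multiplicative individual noise.
#' @param seed Integer seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 30, n_individuals = 3, n_compounds = 60,
                       class_proportions = c(
                         aliphatics = 0.30, aromatics = 0.20,
                         `C5-branched` = 0.05, terpenoids = 0.30,
                         nitrogen_sulfur = 0.05, misc_cyclic = 0.09,
                         unknown = 0.01),
                       zero_inflation = 0.6, bm_sigma2 = 1,
                       target_class_rho = 0.7, compound_turnover = 0.8,
                       amount_sdlog = 1, indiv_sdlog = 0.3, seed = 1) {
  if (n_species < 3) stop("'n_species' must be >= 3")
  if (length(class_proportions) != 7)
    stop("'class_proportions' must have 7 entries")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- voc_classes()
  if (!setequal(names(class_proportions), voc_classes()))
    stop("'class_proportions' names must be the seven canonical classes")
  class_proportions <- class_proportions[voc_classes()]
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-8)
    stop("'class_proportions' must be non-negative and sum to 1")
  if (all(class_proportions == 0)) stop("degenerate class proportions")
  for (pr in c(zero_inflation, compound_turnover))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  if (abs(target_class_rho) > 1)
    stop("'target_class_rho' must lie in [-1, 1]")
  if (bm_sigma2 < 0) stop("'bm_sigma2' must be >= 0")
  structure(list(n_species = as.integer(n_species),
                 n_individuals = as.integer(n_individuals),
                 n_compounds = as.integer(n_compounds),
                 class_proportions = class_proportions,
                 zero_inflation = zero_inflation, bm_sigma2 = bm_sigma2,
                 target_class_rho = target_class_rho,
                 compound_turnover = compound_turnover,
                 amount_sdlog = amount_sdlog, indiv_sdlog = indiv_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Generates a Yule tree and rescales branch lengths so the maximum
#' root-to-tip depth is 1. Tip labels are \code{sp001}, \code{sp002}, ...
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Integer seed.
#' @return A rooted \code{phylo} object of unit depth.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 3) stop("'n_species' must be >= 3")
  .with_seed(seed, {
    tr <- ape::rphylo(n_species, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
    tr
  })
}

#' Simulate continuous traits under Brownian motion on a tree
#'
#' Each column is an independent draw from a multivariate normal with mean 0
#' and covariance \code{bm_sigma2 * C}, where C is the phylogenetic
#' covariance of the tree; on a star tree the values are iid across species.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param p_axes Number of trait columns.
#' @param bm_sigma2 Brownian rate (>= 0); 0 gives constant (zero) columns.
#' @param seed Integer seed.
#' @return Species x axis matrix with tip labels as row names.
#' @export
simulate_bm_traits <- function(tree, p_axes, bm_sigma2 = 1, seed = 1) {
  if (bm_sigma2 < 0) stop("'bm_sigma2' must be >= 0")
  C <- phylo_cov(tree)
  N <- nrow(C)
  .with_seed(seed, {
    if (bm_sigma2 == 0) {
      Y <- matrix(0, N, p_axes)
    } else {
      e <- eigen(bm_sigma2 * C, symmetric = TRUE)
      L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), N)
      Y <- L %*% matrix(stats::rnorm(N * p_axes), N, p_axes)
    }
    dimnames(Y) <- list(rownames(C), paste0("trait", seq_len(p_axes)))
    Y
  })
}

#' Simulate a zero-inflated scent table with class structure
#'
#' Compounds are assigned to biochemical classes with probabilities
#' \code{class_proportions}. Each species carries each compound with
#' probability \code{1 - zero_inflation}; carried amounts are log-normal.
#' Individual samples are the species profile times multiplicative
#' log-normal noise. When a tree is supplied, the species log-amounts of
#' each compound evolve under Brownian motion on it (rate \code{bm_sigma2}),
#' so closely related species have correlated profiles; without a tree,
#' species are independent.
#'
#' @param config A \code{\link{sim_config}}.
#' @param tree Optional \code{phylo} with \code{config$n_species} tips; its
#'   tip labels become the species names.
#' @return List with \code{table} (a \code{\link{scent_table}} of ripe
#'   samples), \code{cmap} (a \code{\link{class_map}}), and \code{tree}
#'   (the tree used, or \code{NULL}).
#' @export
simulate_scent_table <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_species
  nc <- config$n_compounds
  ni <- config$n_individuals
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (length(tree$tip.label) != ns)
      stop("tree tip count does not match 'n_species'")
  }
  .with_seed(config$seed, {
    species <- if (is.null(tree)) sprintf("sp%03d", seq_len(ns)) else
      tree$tip.label
    compounds <- sprintf("voc%03d", seq_len(nc))
    cls <- sample(voc_classes(), nc, replace = TRUE,
                  prob = config$class_proportions)
    cmap <- class_map(stats::setNames(cls, compounds))
    # species-level log-amounts: BM on the tree, or iid
    if (!is.null(tree) && config$bm_sigma2 > 0) {
      loga <- simulate_bm_traits(tree, nc, config$bm_sigma2,
                                 seed = config$seed + 1L)
      loga <- loga[species, , drop = FALSE] * (config$amount_sdlog /
                                                 sqrt(config$bm_sigma2))
    } else {
      loga <- matrix(stats::rnorm(ns * nc, sd = config$amount_sdlog), ns, nc)
    }
    present <- matrix(stats::rbinom(ns * nc, 1, 1 - config$zero_inflation),
                      ns, nc)
    base <- exp(loga) * present
    if (all(base == 0)) warning("all species profiles are zero")
    rows <- vector("list", ns * ni)
    meta_sp <- meta_ind <- character(ns * ni)
    k <- 0
    for (s in seq_len(ns)) for (i in seq_len(ni)) {
      k <- k + 1
      noise <- exp(stats::rnorm(nc, sd = config$indiv_sdlog))
      rows[[k]] <- base[s, ] * noise
      meta_sp[k] <- species[s]
      meta_ind[k] <- sprintf("%s_ind%02d", species[s], i)
    }
    amounts <- do.call(rbind, rows)
    dimnames(amounts) <- list(paste0(meta_ind, "_r"), compounds)
    tab <- scent_table(amounts, species = meta_sp, individual = meta_ind,
                       ripeness = rep("ripe", ns * ni),
                       site = rep("synthetic", ns * ni))
    list(table = tab, cmap = cmap, tree = tree)
  })
}

# Spearman -> Pearson calibration for a bivariate Gaussian copula:
# rho_S = (6/pi) asin(r/2)  =>  r = 2 sin(pi rho_S / 6)
# pinned exactly at the endpoints so rho_s = 1 gives identical latents
.copula_pearson <- function(rho_s) {
  if (abs(rho_s) == 1) return(sign(rho_s))
  2 * sin(pi * rho_s / 6)
}

#' Simulate paired ripe/unripe profiles with controlled class correlation
#'
#' Class-level compositions for unripe fruits are drawn from log-normal
#' marginals keyed to \code{class_proportions}; ripe compositions are
#' generated from the same latent Gaussians through a Gaussian copula whose
#' Pearson parameter is calibrated (r = 2 sin(pi rho / 6)) so the expected
#' per-class Spearman correlation approximates \code{target_class_rho}.
#' Within each class, the class total is spread over member compounds; with
#' probability \code{compound_turnover} a species' ripe fruit swaps each
#' unripe compound for a different compound of the same class, reproducing
#' the pattern of conserved class composition with high compound turnover.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with class-level \code{ripe} and \code{unripe}
#'   \code{\link{species_profile}} objects, compound-level
#'   \code{ripe_compounds} and \code{unripe_compounds} profiles, and the
#'   \code{cmap}.
#' @export
simulate_paired_ripe_unripe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_species
  nc <- config$n_compounds
  if (nc < 7)
    stop("paired simulation needs at least 7 compounds (one per class)")
  r <- .copula_pearson(config$target_class_rho)
  .with_seed(config$seed, {
    species <- sprintf("sp%03d", seq_len(ns))
    compounds <- sprintf("voc%03d", seq_len(nc))
    # guarantee every class has at least one member compound
    cls <- c(voc_classes(),
             sample(voc_classes(), nc - 7, replace = TRUE,
                    prob = config$class_proportions))[seq_len(nc)]
    cls <- sample(cls)                    # shuffle positions
    cmap <- class_map(stats::setNames(cls, compounds))
    zu <- matrix(stats::rnorm(ns * 7), ns, 7)
    zr <- r * zu + sqrt(max(0, 1 - r^2)) * matrix(stats::rnorm(ns * 7), ns, 7)
    marginal <- function(z) {
      g <- sweep(exp(config$amount_sdlog * z), 2,
                 pmax(config$class_proportions, 1e-6), "*")
      g / rowSums(g)
    }
    wu <- marginal(zu)
    wr <- marginal(zr)
    dimnames(wu) <- dimnames(wr) <- list(species, voc_classes())
    # spread class totals over member compounds
    members <- split(compounds, factor(cls, levels = voc_classes()))
    spread <- function(w, support) {
      m <- matrix(0, ns, nc, dimnames = list(species, compounds))
      for (k in voc_classes()) {
        mem <- members[[k]]
        if (!length(mem)) next
        for (s in seq_len(ns)) {
          on <- support[[s]][[k]]
          sh <- stats::rgamma(length(on), shape = 1)
          m[s, on] <- w[s, k] * sh / sum(sh)
        }
      }
      m
    }
    # unripe support: subset of member compounds per species/class
    pick <- function(mem) {
      n_on <- max(1, stats::rbinom(1, length(mem),
                                   1 - config$zero_inflation))
      sample(mem, n_on)
    }
    support_u <- lapply(seq_len(ns), function(s)
      lapply(stats::setNames(voc_classes(), voc_classes()), function(k) {
        mem <- members[[k]]
        if (!length(mem)) character() else pick(mem)
      }))
    # ripe support: each unripe compound swapped with prob compound_turnover
    support_r <- lapply(seq_len(ns), function(s)
      lapply(stats::setNames(voc_classes(), voc_classes()), function(k) {
        mem <- members[[k]]
        on <- support_u[[s]][[k]]
        if (!length(mem)) return(character())
        swap <- stats::runif(length(on)) < config$compound_turnover
        repl <- vapply(seq_along(on), function(i) {
          if (!swap[i]) return(on[i])
          other <- setdiff(mem, on[i])
          if (!length(other)) on[i] else sample(other, 1)
        }, character(1))
        unique(repl)
      }))
    mu <- spread(wu, support_u)
    mr <- spread(wr, support_r)
    list(ripe = species_profile(wr, level = "class"),
         unripe = species_profile(wu, level = "class"),
         ripe_compounds = relative_amounts(mr),
         unripe_compounds = relative_amounts(mu),
         cmap = cmap)
  })
}
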