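# Fixture builders shared across the test files. Everything is generated in
# code so the suite needs no data files.

# 10 samples (2 species x 5) with hand-placed compounds exercising each
# filtering rule:
#   ubiq  - present in all 10 samples
#   rareX - 1 sample of species A only (1/10 of samples)
#   spreY - 3 samples of species A only (3/10 of samples)
#   tiny  - present everywhere but never > 1% of any species' mean emission
#   main  - ordinary dominant compound (8/10 samples)
toy_filter_table <- function() {
  compounds <- c("main", "ubiq", "rareX", "spreY", "tiny")
  m <- matrix(0, 10, 5, dimnames = list(paste0("s", 1:10), compounds))
  m[, "main"] <- 100
  m[c("s5", "s10"), "main"] <- 0
  m[, "ubiq"] <- 5
  m["s1", "rareX"] <- 2
  m[c("s1", "s2", "s3"), "spreY"] <- 2
  m[, "tiny"] <- 0.5          # 0.5 / (>100) < 1% in both species
  scent_table(m, species = rep(c("A", "B"), each = 5))
}

# balanced two-species table with ripe and unripe samples
toy_paired_table <- function() {
  set.seed(99)
  n_sp <- 6
  compounds <- sprintf("c%02d", 1:12)
  cls <- rep(c("aliphatics", "aromatics", "terpenoids", "unknown"), each = 3)
  cmap <- class_map(stats::setNames(cls, compounds))
  species <- sprintf("sp%d", 1:n_sp)
  rows <- list(); sp <- ripen <- character()
  for (s in species) for (stage in c("ripe", "unripe")) {
    rows[[length(rows) + 1]] <- stats::runif(12, 0, 10)
    sp <- c(sp, s); ripen <- c(ripen, stage)
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0(sp, "_", ripen), compounds)
  list(table = scent_table(m, species = sp, ripeness = ripen), cmap = cmap)
}

# strip species_profile attributes down to the bare matrix
as_mat <- function(x) {
  x <- unclass(x)
  attr(x, "level") <- NULL
  attr(x, "zero_rows") <- NULL
  x
}

random_profile <- function(n_species, n_features, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_species * n_features), n_species, n_features,
              dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                              sprintf("f%02d", seq_len(n_features))))
  relative_amounts(m)
}

# independent double-loop Bray-Curtis oracle
bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# textbook UPGMA: iterative merging of the closest pair with
# size-weighted average distances; returns the cophenetic matrix
upgma_cophenetic_oracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  active <- d
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  while (nrow(active) > 1) {
    m <- active; diag(m) <- Inf
    idx <- which(m == min(m), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    h <- active[i, j]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    newd <- (sizes[i] * active[i, ] + sizes[j] * active[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(nrow(active)), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], newd[keep]),
                    c(newd[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  coph
}

# naive Kmult oracle: dense solve() for C^-1 and an explicit symmetric
# matrix square root, no shared code with the package internals
kmult_oracle <- function(Y, C) {
  N <- nrow(C)
  one <- rep(1, N)
  iC <- solve(C)
  ahat <- (t(one) %*% iC %*% Y) / drop(t(one) %*% iC %*% one)
  R <- Y - one %*% ahat
  SS0 <- sum(R^2)
  e <- eigen(iC, symmetric = TRUE)
  iC_half <- e$vectors %*% diag(sqrt(e$values), N) %*% t(e$vectors)
  SS <- sum((iC_half %*% R)^2)
  expected <- (sum(diag(C)) - N / drop(t(one) %*% iC %*% one)) / (N - 1)
  (SS0 / SS) / expected
}
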