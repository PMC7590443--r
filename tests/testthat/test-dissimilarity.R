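test_that("Bray-Curtis hits its bounds and the toy value", {
  prof <- species_profile(rbind(a = c(x = 0.2, y = 0.8),
                                b = c(x = 0.5, y = 0.5),
                                c = c(x = 0.2, y = 0.8),
                                d = c(x = 1.0, y = 0.0),
                                e = c(x = 0.0, y = 1.0)))
  d <- bray_curtis(prof)
  expect_equal(d["a", "c"], 0)                       # identical rows
  expect_equal(d["d", "e"], 1)                       # disjoint support
  expect_equal(d["a", "b"], 0.3)                     # (0.3+0.3)/2
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
})

test_that("Bray-Curtis matches the double-loop oracle", {
  prof <- random_profile(6, 4, seed = 11)
  expect_equal(bray_curtis(prof), bray_oracle(unclass(prof)),
               tolerance = 1e-14)
})

test_that("Bray-Curtis is invariant to joint column permutation", {
  prof <- random_profile(5, 8, seed = 2)
  perm <- sample(ncol(prof))
  shuffled <- species_profile(unclass(prof)[, perm])
  expect_equal(bray_curtis(shuffled), bray_curtis(prof), tolerance = 1e-15)
})

test_that("all-zero row pairs get dissimilarity 0 with a warning", {
  m <- rbind(a = c(1, 1), z1 = c(0, 0), z2 = c(0, 0))
  colnames(m) <- c("x", "y")
  expect_warning(d <- bray_curtis(m), "all-zero")
  expect_equal(d["z1", "z2"], 0)
  expect_equal(d["a", "z1"], 1)
})

test_that("PCoA recovers points on a line and reconstructs Euclidean input", {
  # 3 points at coordinates 0, 1, 3
  pts <- c(p1 = 0, p2 = 1, p3 = 3)
  d <- abs(outer(pts, pts, "-"))
  ord <- pcoa_scores(d)
  expect_equal(length(ord$retained), 1)
  rec <- as.matrix(dist(ord$scores))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)

  set.seed(8)
  X <- matrix(rnorm(7 * 3), 7, 3, dimnames = list(paste0("p", 1:7), NULL))
  dE <- as.matrix(dist(X))
  ordE <- pcoa_scores(dE)
  expect_equal(unname(as.matrix(dist(ordE$scores))), unname(dE),
               tolerance = 1e-8)
})

test_that("PCoA matches an independent classical-scaling implementation", {
  prof <- random_profile(6, 10, seed = 21)
  d <- bray_curtis(prof)
  ord <- pcoa_scores(d)
  oracle <- ape::pcoa(as.dist(d))
  pos <- oracle$values$Eigenvalues[oracle$values$Eigenvalues > 1e-8]
  expect_equal(ord$eigenvalues[ord$retained], pos, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(ord$scores), abs(oracle$vectors[, seq_along(pos)]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("semimetric input produces negative eigenvalues, which are dropped", {
  prof <- random_profile(5, 12, seed = 33)
  d <- bray_curtis(prof)
  ord <- pcoa_scores(d)
  expect_true(any(ord$eigenvalues < 0))
  expect_true(all(ord$eigenvalues[ord$retained] > 0))
  # retained variance cannot exceed the total positive variance
  expect_lte(sum(ord$eigenvalues[ord$retained]),
             sum(ord$eigenvalues[ord$eigenvalues > 0]) + 1e-12)
})

test_that("PCoA of the Euclidean embedding of its own scores is idempotent", {
  prof <- random_profile(7, 9, seed = 44)
  ord <- pcoa_scores(bray_curtis(prof))
  again <- pcoa_scores(as.matrix(dist(ord$scores)))
  expect_equal(again$eigenvalues[again$retained],
               ord$eigenvalues[ord$retained], tolerance = 1e-8)
})

test_that("degenerate all-zero distances give an explicit empty ordination", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ord <- pcoa_scores(d)
  expect_equal(ncol(ord$scores), 0)
  expect_equal(length(ord$retained), 0)
  expect_error(pcoa_scores(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA clustering recovers forced topologies", {
  d <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hierarchical_cluster(d)
  nwk <- dendrogram_newick(h)
  phy <- ape::read.tree(text = nwk)
  expect_true(ape::is.monophyletic(phy, c("A", "B")))
  expect_error(hierarchical_cluster(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("identical profiles collapse to a height-zero dendrogram", {
  prof <- species_profile(matrix(0.25, 4, 4,
                                 dimnames = list(paste0("sp", 1:4),
                                                 paste0("c", 1:4))))
  h <- hierarchical_cluster(bray_curtis(prof))
  expect_equal(max(h$height), 0)
})

test_that("UPGMA matches the manual agglomeration oracle on a random matrix", {
  prof <- random_profile(6, 15, seed = 55)
  d <- bray_curtis(prof)
  h <- hierarchical_cluster(d, linkage = "UPGMA")
  coph <- as.matrix(stats::cophenetic(h))
  oracle <- upgma_cophenetic_oracle(d)
  expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-12)
})

test_that("distance matrix writer/reader round trips", {
  prof <- random_profile(5, 6, seed = 66)
  d <- bray_curtis(prof)
  f <- tempfile(fileext = ".tsv")
  write_dist_matrix(d, f)
  expect_equal(read_dist_matrix(f), d, tolerance = 1e-12)
})
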