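make_class_profile <- function(m) species_profile(m, level = "class")

test_that("pairing intersects species and drops the unknown class", {
  classes <- c("aliphatics", "terpenoids", "unknown")
  ripe <- make_class_profile(
    rbind(sp1 = c(0.6, 0.39, 0.01), sp2 = c(0.3, 0.68, 0.02),
          sp3 = c(0.5, 0.5, 0.0), sp4 = c(0.2, 0.8, 0.0)) |>
      `colnames<-`(classes))
  unripe <- make_class_profile(
    rbind(sp1 = c(0.5, 0.49, 0.01), sp2 = c(0.4, 0.58, 0.02),
          sp3 = c(0.45, 0.55, 0.0)) |> `colnames<-`(classes))
  paired <- pair_ripe_unripe(ripe, unripe)
  expect_equal(paired$species, c("sp1", "sp2", "sp3"))
  expect_equal(paired$dropped_species, "sp4")
  expect_false("unknown" %in% colnames(paired$ripe))
  # unknown share averaged over both stages' retained rows, pre-exclusion
  expect_equal(paired$unknown_share_mean,
               mean(c(0.01, 0.02, 0, 0.01, 0.02, 0)))
  # relative amounts are NOT renormalized after the exclusion
  expect_equal(unname(rowSums(paired$ripe)), c(0.99, 0.98, 1.0))
})

test_that("identical stages give rho = 1; reversed ranks give -1", {
  classes <- c("aliphatics", "aromatics")
  m <- cbind(aliphatics = c(0.9, 0.7, 0.5, 0.3, 0.1),
             aromatics = c(0.1, 0.3, 0.5, 0.7, 0.9))
  rownames(m) <- paste0("sp", 1:5)
  prof <- make_class_profile(m)
  res <- spearman_by_class(pair_ripe_unripe(prof, prof))
  expect_equal(res$table$rho, c(1, 1))
  expect_equal(res$weighted_mean_rho, 1)

  rev_prof <- make_class_profile(m[5:1, ] |> `rownames<-`(paste0("sp", 1:5)))
  res2 <- spearman_by_class(pair_ripe_unripe(prof, rev_prof))
  expect_equal(res2$table$rho, c(-1, -1))
})

test_that("a constant class is reported as missing, not an error", {
  m_r <- cbind(aliphatics = rep(0.5, 4),
               aromatics = c(0.1, 0.2, 0.3, 0.4),
               terpenoids = c(0.4, 0.3, 0.2, 0.1))
  m_u <- cbind(aliphatics = rep(0.5, 4),
               aromatics = c(0.2, 0.1, 0.15, 0.15),
               terpenoids = c(0.3, 0.4, 0.35, 0.35))
  rownames(m_r) <- rownames(m_u) <- paste0("sp", 1:4)
  res <- spearman_by_class(pair_ripe_unripe(make_class_profile(m_r),
                                            make_class_profile(m_u)))
  expect_true(is.na(res$table$rho[res$table$class == "aliphatics"]))
  expect_false(anyNA(res$table$rho[res$table$class != "aliphatics"]))
  # the undefined class is excluded from the weighted mean
  tab <- res$table[!is.na(res$table$rho), ]
  expect_equal(res$weighted_mean_rho,
               sum(tab$rho * tab$weight) / sum(tab$weight))
})

test_that("Spearman estimates equal the rank-and-Pearson oracle under ties", {
  set.seed(17)
  for (i in 1:5) {
    x <- round(runif(12), 1)     # rounding forces ties
    y <- round(runif(12), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    oracle <- stats::cor(rank(x), rank(y))   # midranks + Pearson
    expect_equal(unname(ct$estimate), oracle, tolerance = 1e-12)
  }
})

test_that("weighted mean rho follows the hand-computed toy values", {
  tab <- data.frame(class = c("a", "b"), rho = c(1, 0), p = NA,
                    weight = c(0.75, 0.25))
  expect_equal(weighted_mean_rho(tab), 0.75)
  expect_equal(weighted_mean_rho(tab, normalize = FALSE), 0.75)

  single <- data.frame(class = "a", rho = 0.42, p = NA, weight = 0.3)
  expect_equal(weighted_mean_rho(single), 0.42)

  equal_w <- data.frame(class = c("a", "b", "c"), rho = c(0.2, 0.5, 0.8),
                        p = NA, weight = rep(1 / 3, 3))
  expect_equal(weighted_mean_rho(equal_w), 0.5)

  all_na <- data.frame(class = "a", rho = NA_real_, p = NA, weight = 1)
  expect_error(weighted_mean_rho(all_na), "no class")
})

test_that("weighted mean lies between the extreme class coefficients", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    tab <- data.frame(class = letters[1:k], rho = runif(k, -1, 1), p = NA,
                      weight = runif(k))
    wm <- weighted_mean_rho(tab)
    expect_gte(wm, min(tab$rho) - 1e-12)
    expect_lte(wm, max(tab$rho) + 1e-12)
  }
})

test_that("results are invariant to species order", {
  pp <- simulate_paired_ripe_unripe(sim_config(n_species = 12,
                                               n_compounds = 20, seed = 31))
  res <- spearman_by_class(pair_ripe_unripe(pp$ripe, pp$unripe))
  perm <- sample(nrow(pp$ripe))
  ripe_p <- species_profile(unclass(pp$ripe)[perm, ], level = "class")
  res_p <- spearman_by_class(pair_ripe_unripe(ripe_p, pp$unripe))
  expect_equal(res_p$table, res$table, tolerance = 1e-12)
  expect_equal(res_p$weighted_mean_rho, res$weighted_mean_rho)
})

test_that("devcorr runs from a raw two-stage scent table", {
  tp <- toy_paired_table()
  res <- run_devcorr(tp$table, tp$cmap)
  expect_s3_class(res, "devcorr_result")
  expect_setequal(res$table$class,
                  c("aliphatics", "aromatics", "terpenoids"))
  expect_true(all(abs(res$table$rho[!is.na(res$table$rho)]) <= 1))
  f <- tempfile()
  dir.create(f)
  run_devcorr(tp$table, tp$cmap, output_dir = f, dataset = "toy")
  expect_true(file.exists(file.path(f, "toy_devcorr.tsv")))
})
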