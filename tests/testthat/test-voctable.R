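test_that("scent_table validates its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  storage.mode(m) <- "double"
  expect_s3_class(scent_table(m, species = c("x", "y")), "scent_table")
  expect_error(scent_table(m - 5, species = c("x", "y")), ">= 0")
  expect_error(scent_table(m, species = c("x", NA)), "species")
  dup <- m; colnames(dup) <- c("a", "a")
  expect_error(scent_table(dup, species = c("x", "y")), "unique")
  expect_error(scent_table(m, species = c("x", "y"),
                           ripeness = c("ripe", "rotten")), "ripeness")
})

test_that("scent table and class map survive a file round trip", {
  tp <- toy_paired_table()
  f1 <- tempfile(fileext = ".tsv")
  write_scent_table(tp$table, f1)
  back <- read_scent_table(f1)
  expect_equal(back$amounts, tp$table$amounts)
  expect_equal(back$meta$species, tp$table$meta$species)
  expect_equal(back$meta$ripeness, tp$table$meta$ripeness)
  f2 <- tempfile(fileext = ".csv")
  write_class_map(tp$cmap, f2)
  expect_equal(unclass(read_class_map(f2)), unclass(tp$cmap),
               ignore_attr = TRUE)
})

test_that("empty cells read as zero amounts", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample,species,a,b", "s1,x,1,", "s2,y,,2"), f)
  tab <- read_scent_table(f)
  expect_equal(unname(tab$amounts), rbind(c(1, 0), c(0, 2)))
})

test_that("filtering rules remove the right compounds on the toy table", {
  tab <- toy_filter_table()
  out <- filter_compounds(tab)
  log <- removal_log(out)
  # enumerated by hand over the 10x5 toy table:
  # ubiq: present in 10/10 > 90%; rareX: one species, 1/10 < 25%;
  # tiny: max within-species mean share 0.5/107.1 < 1%;
  # spreY: one species but 3/10 >= 25%? no, 30% >= 25% -> retained;
  # main: retained
  expect_setequal(colnames(out$amounts), c("main", "spreY"))
  expect_setequal(log$compound[log$rule == "ubiquity"], c("ubiq", "tiny"))
  expect_true("rareX" %in% log$compound[log$rule == "rare"])
  expect_true("tiny" %in% log$compound[log$rule == "max_share"])
  expect_false("spreY" %in% log$compound)
})

test_that("a fully ubiquitous compound is removed at the 0.9 threshold", {
  m <- matrix(1, 20, 2, dimnames = list(paste0("s", 1:20), c("x", "y")))
  m[1:5, "y"] <- 0
  tab <- scent_table(m, species = rep(c("A", "B"), 10))
  out <- filter_compounds(tab, rules = "ubiquity")
  expect_equal(colnames(out$amounts), "y")   # x present in 100% > 90%
})

test_that("control-predominant compounds are removed", {
  m <- matrix(c(10, 10, 1, 1,   # blankish: mean control 10 >= fruit 1
                0, 0, 5, 5),    # genuine: absent from controls
              4, 2, dimnames = list(c("c1", "c2", "f1", "f2"),
                                    c("contam", "fruity")))
  tab <- scent_table(m, species = c("blank", "blank", "A", "B"))
  out <- filter_compounds(tab, control_samples = c("c1", "c2"),
                          rules = "control")
  expect_equal(colnames(out$amounts), "fruity")
  expect_equal(removal_log(out)$compound, "contam")
})

test_that("filtering is idempotent", {
  tab <- toy_filter_table()
  once <- filter_compounds(tab)
  twice <- filter_compounds(once)
  expect_equal(twice$amounts, once$amounts)
  expect_equal(nrow(removal_log(twice)), 0)
})

test_that("filtering rejects thresholds outside (0, 1]", {
  tab <- toy_filter_table()
  expect_error(filter_compounds(tab, ubiquity_threshold = 0), "\\(0, 1\\]")
  expect_error(filter_compounds(tab, rare_sample_fraction = 1.2), "\\(0, 1\\]")
})

test_that("species means average with zeros included", {
  m <- rbind(s1 = c(A = 1, B = 3), s2 = c(A = 3, B = 1))
  tab <- scent_table(m, species = c("x", "x"))
  expect_equal(species_means(tab), rbind(x = c(A = 2, B = 2)))

  m2 <- matrix(c(8, 0, 0, 0), 4, 1, dimnames = list(paste0("s", 1:4), "A"))
  tab2 <- scent_table(m2, species = rep("x", 4))
  expect_equal(species_means(tab2)["x", "A"], 2)

  m3 <- rbind(only = c(A = 4, B = 6))
  tab3 <- scent_table(m3, species = "solo")
  expect_equal(species_means(tab3), rbind(solo = c(A = 4, B = 6)))
})

test_that("relative amounts normalize rows and keep zero rows", {
  m <- rbind(a = c(2, 3, 5), b = c(7, 0, 0), z = c(0, 0, 0))
  colnames(m) <- c("x", "y", "w")
  expect_warning(prof <- relative_amounts(m), "all-zero")
  expect_equal(unname(unclass(prof)["a", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(unclass(prof)["b", ]), c(1, 0, 0))
  expect_equal(unname(unclass(prof)["z", ]), c(0, 0, 0))
  expect_equal(attr(prof, "zero_rows"), "z")
  expect_error(relative_amounts(-m[1:2, ]), "amounts")
})

test_that("relative amounts are scale invariant row-wise", {
  set.seed(5)
  m <- matrix(rexp(20), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("c", 1:5)))
  scaled <- m * c(1, 10, 0.01, 1e6)  # recycled down columns: row scaling
  expect_equal(unclass(relative_amounts(scaled)),
               unclass(relative_amounts(m)), tolerance = 1e-12)
})

test_that("class aggregation sums member compounds and conserves row sums", {
  prof <- species_profile(
    rbind(sp1 = c(a = 0.3, b = 0.2, c = 0.5),
          sp2 = c(a = 0, b = 0, c = 1)))
  cmap <- class_map(c(a = "aliphatics", b = "aliphatics", c = "terpenoids"))
  agg <- aggregate_classes(prof, cmap)
  expect_equal(as_mat(agg),
               rbind(sp1 = c(aliphatics = 0.5, terpenoids = 0.5),
                     sp2 = c(aliphatics = 0, terpenoids = 1)))
  # one-class map collapses to a single unit column
  cmap1 <- class_map(c(a = "aromatics", b = "aromatics", c = "aromatics"))
  agg1 <- aggregate_classes(prof, cmap1)
  expect_equal(unname(unclass(agg1)[, "aromatics"]), c(1, 1))
  # unmapped compound is named in the error
  expect_error(aggregate_classes(prof, class_map(c(a = "aromatics"))), "b")
})

test_that("class aggregation matches a group-by oracle on random profiles", {
  for (seed in 1:3) {
    prof <- random_profile(8, 25, seed = seed)
    set.seed(seed + 100)
    cls <- sample(voc_classes(), 25, replace = TRUE)
    cmap <- class_map(stats::setNames(cls, colnames(prof)))
    agg <- aggregate_classes(prof, cmap)
    oracle <- t(rowsum(t(as_mat(prof)), cls))        # independent group-by
    expect_equal(as_mat(agg), oracle[, colnames(agg)], tolerance = 1e-14)
    expect_equal(rowSums(agg), rowSums(unclass(prof)), tolerance = 1e-12)
  }
})
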