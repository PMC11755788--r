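test_that("the canonical profile is 15 + 52 + 29 + 29 = 125 columns", {
  cols <- profile_columns()
  expect_length(cols, 125L)
  expect_equal(sum(startsWith(cols, "track.")), 15L)
  expect_equal(sum(startsWith(cols, "pose.")), 52L)
  expect_equal(sum(startsWith(cols, "syllfreq.")), 29L)
  expect_equal(sum(startsWith(cols, "sylldur.")), 29L)
  expect_false(any(duplicated(cols)))
})

test_that("profile rows concatenate the batteries in canonical order", {
  cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                      n_per_group = 1, hours = 2, seed = 11)
  rec <- filter_low_likelihood(simulate_homecage(cc)[[1]])
  s <- simulate_syllables(cc)[[1]]
  row <- profile_row(battery_track15(rec), battery_pose52(rec),
                     frequency_duration(s))
  expect_length(row, 125L)
  expect_equal(names(row), profile_columns())
})

test_that("group profiles are per-column means with median imputation", {
  rows <- rbind(a1 = c(x = 1, y = 10, z = 5),
                a2 = c(x = 3, y = NA, z = 7),
                b1 = c(x = 10, y = 2, z = NA))
  prof <- assemble_profiles(rows, c("A", "A", "B"))
  expect_equal(rownames(prof), c("A", "B"))
  expect_equal(unname(prof["A", "x"]), 2)
  # NA in group A's y imputed by the column median (6)
  expect_equal(unname(prof["A", "y"]), (10 + 6) / 2)
  expect_equal(attr(prof, "imputed"), 2L)
  # one animal per group: profile equals that animal's values
  one <- assemble_profiles(rows[c(1, 3), ], c("A", "B"))
  expect_equal(unname(one["A", "x"]), 1)
  # brute-force group mean oracle on random data
  set.seed(61)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("an", 1:10), paste0("p", 1:6)))
  g <- rep(c("G1", "G2"), 5)
  prof2 <- assemble_profiles(m, g)
  expect_equal(unname(prof2["G1", ]),
               unname(colMeans(m[g == "G1", ])))
  # errors: duplicates and empty groups
  dup <- m; rownames(dup)[2] <- "an1"
  expect_error(assemble_profiles(dup, g), "duplicate")
  expect_error(assemble_profiles(m, g, levels = c("G1", "G2", "G3")),
               "zero animals")
})

test_that("PCA weights follow the PC1 loadings", {
  set.seed(62)
  # after z-scoring every column has unit variance, so PC1 aligns with
  # the correlated block, not with an independent column
  m2 <- cbind(alone = rnorm(8), j1 = 0, j2 = 0, j3 = 0)
  base <- rnorm(8)
  m2[, "j1"] <- base + rnorm(8, sd = 0.1)
  m2[, "j2"] <- base + rnorm(8, sd = 0.1)
  m2[, "j3"] <- base + rnorm(8, sd = 0.1)
  pw <- pca_weights(m2)
  expect_lt(pw$weights[["alone"]], min(pw$weights[c("j1", "j2", "j3")]))
  expect_equal(mean(pw$weights), 1)
  expect_true(all(diff(pw$explained) <= 1e-12))

  # loadings match the eigenvector of the correlation matrix
  set.seed(63)
  x <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("c", 1:5)))
  pw2 <- pca_weights(x)
  ev <- eigen(stats::cor(x))$vectors[, 1]
  expect_equal(abs(unname(pw2$loadings[, 1])), abs(ev),
               tolerance = 1e-8)

  # zero-variance columns get weight 0 and are flagged
  xz <- cbind(x, flat = 1)
  pw3 <- pca_weights(xz)
  expect_equal(pw3$weights[["flat"]], 0)
  expect_equal(pw3$dropped, "flat")
  expect_error(pca_weights(x[1:2, ]), "at least 3")
  expect_error(pca_weights(matrix(1, 5, 3)), "constant")
})

test_that("weighted Ward clustering behaves canonically", {
  set.seed(64)
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("p", 1:5)))
  m["g2", ] <- m["g1", ]                  # two identical rows
  res <- weighted_ward(m, k = 3)
  h1 <- res$hclust$height[1]
  expect_equal(h1, 0)
  expect_equal(res$clusters[["g1"]], res$clusters[["g2"]])
  # heights are monotone non-decreasing (Ward)
  expect_true(all(diff(res$hclust$height) >= -1e-12))
  # equal weights give exactly the unweighted linkage
  res_w <- weighted_ward(m, weights = rep(1, 5))
  z <- scale(m)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  expect_equal(res_w$hclust$height, hc$height)
  # invariance to row order and to affine rescaling of a column
  perm <- sample(10)
  res_p <- weighted_ward(m[perm, ], k = 3)
  expect_equal(res_p$hclust$height, res$hclust$height)
  m_scaled <- m; m_scaled[, 1] <- 100 * m_scaled[, 1] - 7
  res_s <- weighted_ward(m_scaled, k = 3)
  expect_equal(res_s$hclust$height, res$hclust$height)
  expect_error(weighted_ward(m, weights = c(1, 2)), "one entry")
  expect_error(weighted_ward(m, weights = rep(-1, 5)), "non-negative")
})

test_that("planted two-block structure is always recovered at k = 2", {
  for (s in 1:10) {
    set.seed(s)
    block <- rep(c(0, 8), each = 5)
    m <- matrix(rnorm(10 * 20, mean = block), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("p", 1:20)))
    res <- weighted_ward(m, k = 2)
    cl <- res$clusters[paste0("g", 1:10)]
    expect_equal(length(unique(cl[1:5])), 1L)
    expect_equal(length(unique(cl[6:10])), 1L)
    expect_false(cl[[1]] == cl[[10]])
  }
})

test_that("dendrograms export to Newick and re-parse", {
  m <- matrix(c(0, 0, 10, 10, 0, 0, 10, 10), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  res <- weighted_ward(m + matrix(rnorm(8, sd = 0.01), 4, 2), k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  nwk <- export_dendrogram(res, path)
  expect_true(file.exists(path))
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("A", "B", "C", "D"))
  # topology round-trips: A/B vs C/D split preserved
  split_ab <- ape::getMRCA(phy, c("A", "B"))
  expect_false(identical(split_ab, ape::getMRCA(phy, c("A", "C"))))
  # 2-leaf tree has the "(A:h,B:h);" shape
  m2 <- matrix(c(0, 5, 1, 2), 2, 2, dimnames = list(c("A", "B"), NULL))
  res2 <- weighted_ward(m2, k = 2)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(res2, path2)
  expect_match(readLines(path2), "^\\(A:[0-9.]+,B:[0-9.]+\\);$")
  # a single leaf is not a tree
  leaf <- structure(list(merge = matrix(numeric(0), 0, 2),
                         height = numeric(0), order = 1L,
                         labels = "A"), class = "hclust")
  expect_error(export_dendrogram(leaf, "x"), "fewer than 2")
})
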