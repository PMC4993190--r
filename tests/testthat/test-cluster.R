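test_that("trivial cuts give singletons and one all-species group", {
  profiles <- tibble::tibble(
    species_id = letters[1:5],
    t0 = c(0, 1, 8, 9, 2), topt = c(25, 26, 33, 34, 28),
    tmax = c(35, 36, 42, 42, 37), psi_b = c(-1, -1.1, -0.8, -0.9, -2.3))
  singletons <- ward_cluster(profiles, k = 5)
  expect_equal(sort(unique(singletons$labels$group)), 1:5)
  all_in_one <- ward_cluster(profiles, k = 1)
  expect_equal(unique(all_in_one$labels$group), 1)
  expect_error(ward_cluster(profiles, k = 6), class = "germresp_argument_error")
  expect_error(ward_cluster(dplyr::select(profiles, -"psi_b"), k = 2),
               class = "germresp_feature_error")
  profiles$psi_b[2] <- NA
  expect_error(ward_cluster(profiles, k = 2), class = "germresp_feature_error")
})

test_that("ward linkage matches the exhaustive greedy oracle for small n", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(4:7, 1)
    profiles <- tibble::tibble(
      species_id = paste0("s", 1:n),
      t0 = runif(n, 0, 11), topt = runif(n, 20, 37),
      tmax = runif(n, 28, 43), psi_b = runif(n, -2.6, -0.1))
    X <- as.matrix(profiles[c("t0", "topt", "tmax", "psi_b")])
    oracle <- brute_ward(X)
    fit <- ward_cluster(profiles, k = 1)
    expect_equal(fit$merges$height, oracle$heights, tolerance = 1e-9)
    for (k in 1:(n - 1)) {
      got <- ward_cluster(profiles, k = k)$labels$group
      want <- oracle$partitions[[n - k]]
      expect_true(partition_agree(got, want))
    }
  }
})

test_that("merge heights are non-decreasing and cuts nest", {
  set.seed(17)
  profiles <- tibble::tibble(
    species_id = paste0("s", 1:12),
    t0 = runif(12, 0, 11), topt = runif(12, 20, 37),
    tmax = runif(12, 28, 43), psi_b = runif(12, -2.6, -0.1))
  fit <- ward_cluster(profiles, k = 5)
  expect_true(all(diff(fit$merges$height) >= -1e-12))
  # refining k to k-1 merges exactly two existing groups
  for (k in 2:11) {
    lab_k <- ward_cluster(profiles, k = k)$labels$group
    lab_k1 <- ward_cluster(profiles, k = k - 1)$labels$group
    tab <- table(lab_k, lab_k1)
    expect_equal(sum(tab > 0), k)  # every k-group maps into one coarser group
  }
})

test_that("a two-species pair oracle: obvious pairs merge first", {
  profiles <- tibble::tibble(
    species_id = c("a1", "a2", "b1", "b2", "far"),
    t0 = c(0, 0.2, 8, 8.1, 4), topt = c(25, 25.1, 33, 33.2, 40),
    tmax = c(35, 35.2, 42, 42.1, 50), psi_b = c(-1, -1.05, -0.8, -0.82, -2.5))
  fit <- ward_cluster(profiles, k = 3)
  g <- fit$labels$group
  expect_equal(g[1], g[2])
  expect_equal(g[3], g[4])
  expect_false(g[5] %in% g[1:4])
})

test_that("group and family summaries reproduce hand-averaged trait tables", {
  t1 <- load_table1()
  # the thermophilic pair: high optimum and maximum but high minimum too
  pair <- t1[t1$species_id %in% c("GA", "SI"), ]
  grouping <- list(
    labels = tibble::tibble(species_id = pair$species_id, group = 1L),
    feature_names = c("t0", "topt", "tmax"))
  class(grouping) <- "germ_grouping"
  gs <- group_summary(grouping, t1, features = c("t0", "topt", "tmax"))
  expect_equal(round(gs$tmax_mean, 1), 41.2)
  expect_equal(round(gs$t0_mean, 1), 10.0)
  expect_equal(round(gs$topt_mean, 1), 32.4)

  fam <- family_summary(t1, features = c("t0", "topt", "tmax", "tb"))
  expect_equal(round(fam$tb_mean[fam$family == "Brassicaceae"], 1), 5.4)
  expect_equal(round(fam$tb_mean[fam$family == "Fabaceae"], 1), 2.5)
  # a single-species family just echoes the species
  pt <- fam[fam$family == "Hydrophylaceae", ]
  expect_true(pt$singleton)
  expect_equal(pt$tmax_mean, 27.7)
  expect_equal(pt$tmax_sd, 0)

  # identical members give SD 0
  twin <- tibble::tibble(species_id = c("x", "y"), t0 = c(2, 2))
  twin_grouping <- list(labels = tibble::tibble(species_id = c("x", "y"),
                                                group = 1L),
                        feature_names = "t0")
  class(twin_grouping) <- "germ_grouping"
  expect_equal(group_summary(twin_grouping, twin, features = "t0")$t0_sd, 0)
})

test_that("trait correlations match the textbook Pearson formula", {
  x <- c(1, 3, 4, 6, 8); y <- c(2, 3, 6, 7, 12)
  ct <- trait_correlation(x, y)
  expect_equal(ct$r, 0.963599544975, tolerance = 1e-9)
  expect_equal(ct$r_squared, 0.928524083076, tolerance = 1e-9)
  expect_equal(ct$p_value, 0.00829103019828, tolerance = 1e-9)

  lin <- trait_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)

  set.seed(4)
  null <- trait_correlation(rnorm(500), rnorm(500))
  expect_lt(null$r_squared, 0.05)

  expect_error(trait_correlation(rep(1, 5), 1:5),
               class = "germresp_zero_variance_error")
  expect_error(trait_correlation(1:2, 1:2), class = "germresp_argument_error")

  m <- trait_multiple_r2(tibble::tibble(a = 1:8, b = c(2, 1, 4, 3, 6, 5, 8, 7),
                                        y = (1:8) * 2 + rnorm(8, 0, 0.1)),
                         "y", c("a", "b"))
  expect_gt(m$r_squared, 0.9)
})

test_that("groupings export to Newick readable by standard tree tools", {
  profiles <- tibble::tibble(
    species_id = paste0("s", 1:6),
    t0 = runif(6, 0, 11), topt = runif(6, 20, 37),
    tmax = runif(6, 28, 43), psi_b = runif(6, -2.6, -0.1))
  fit <- ward_cluster(profiles, k = 2)
  nwk <- grouping_newick(fit)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(profiles$species_id))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(tidy(fit)), 6)
  expect_equal(glance(fit)$k, 2)
})
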