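test_that("presence preparation drops empties, keeps stable tie order", {
  m <- matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  pm <- preparePresence(ObservationTable(m))
  expect_equal(pm@presence, m > 0)
  m2 <- rbind(m, r3 = c(0, 0))
  pm2 <- preparePresence(ObservationTable(m2))
  expect_equal(pm2@droppedRows, "r3")
  expect_equal(nrow(pm2@presence), 2)
  expect_error(preparePresence(matrix(0, 2, 2)), "all-zero")
})

test_that("nodf matches the brute-force oracle exactly on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    p <- randomPresence(sample(3:20, 1), sample(3:20, 1),
                        fill = runif(1, 0.2, 0.7))
    pm <- methods::new("PresenceMatrix", presence = p,
                       droppedRows = character(0),
                       droppedCols = character(0))
    expect_identical(nodf(pm), bruteNodf(p))
  }
})

test_that("nodf hits its closed-form anchors", {
  stair <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(unname(nodf(stair)), c(1, 1, 1))
  checker <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(unname(nodf(checker)), c(0, 0, 0))
  one_pair <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  v <- nodf(one_pair)
  expect_equal(unname(v["rows"]), 1)
  expect_equal(unname(v["cols"]), 1)
  # 0-100 scale flag
  expect_equal(unname(nodf(stair, scale100 = TRUE)), c(100, 100, 100))
})

test_that("nodf is invariant to input permutations and agrees with vegan", {
  set.seed(11)
  p <- randomPresence(10, 12)
  base <- nodf(p)
  for (i in 1:5)
    expect_equal(nodf(p[sample(10), sample(12)]), base)
  skip_if_not_installed("vegan")
  for (i in 1:10) {
    q <- randomPresence(sample(4:15, 1), sample(4:15, 1))
    ref <- vegan::nestednodf(q, order = TRUE, weighted = FALSE)$statistic
    mine <- nodf(q, scale100 = TRUE)
    expect_equal(unname(mine["rows"]), unname(ref["N.rows"]),
                 tolerance = 1e-10)
    expect_equal(unname(mine["cols"]), unname(ref["N.columns"]),
                 tolerance = 1e-10)
    expect_equal(unname(mine["overall"]), unname(ref["NODF"]),
                 tolerance = 1e-10)
  }
})

test_that("null shuffles preserve the fixed margin and hit uniform cells", {
  set.seed(5)
  p <- randomPresence(8, 10)
  pm <- preparePresence(p)
  for (i in 1:10) {
    sc <- nullShuffle(pm, "equiprobable_rows_fixed_cols", seed = i)
    expect_equal(colSums(sc@presence), colSums(pm@presence))
    sr <- nullShuffle(pm, "fixed_rows_equiprobable_cols", seed = i)
    expect_equal(rowSums(sr@presence), rowSums(pm@presence))
  }
  # a full row is invariant under the fixed-rows shuffle
  pf <- p; pf[1, ] <- TRUE
  pmf <- preparePresence(pf)
  sf <- nullShuffle(pmf, "fixed_rows_equiprobable_cols", seed = 3)
  expect_true(all(sf@presence[1, ]))
  # empirical cell inclusion frequency ~ colsum / n_rows
  p2 <- randomPresence(6, 5)
  pm2 <- preparePresence(p2)
  acc <- matrix(0, 6, 5)
  for (i in 1:3000)
    acc <- acc + nullShuffle(pm2, "equiprobable_rows_fixed_cols",
                             seed = i)@presence
  freq <- acc / 3000
  expected <- matrix(colSums(pm2@presence) / 6, 6, 5, byrow = TRUE)
  expect_lt(max(abs(freq - expected)), 4 * sqrt(0.25 / 3000))
})

test_that("hypergeometric pair moments match their closed forms", {
  # single qualifying pair with fills (3, 2) among R = 4 rows (the empty
  # fourth row is part of the category space, so bypass preparation)
  p <- matrix(FALSE, 4, 2)
  p[1:3, 1] <- TRUE; p[1:2, 2] <- TRUE
  pm <- methods::new("PresenceMatrix", presence = p,
                     droppedRows = character(0), droppedCols = character(0))
  mm <- nodfNullMoments(pm, "equiprobable_rows_fixed_cols")
  expect_equal(mm$axis, "cols")
  expect_equal(mm$mean, 0.75)          # (3/4)
  expect_equal(mm$variance, 0.0625)    # 2*(3/4)*(1/4)*(2/3) / 2^2
  # a full column forces complete overlap: mean 1, variance 0
  pf <- matrix(FALSE, 4, 2)
  pf[, 1] <- TRUE; pf[1:2, 2] <- TRUE
  mmf <- nodfNullMoments(preparePresence(pf), "equiprobable_rows_fixed_cols")
  expect_equal(mmf$mean, 1)
  expect_equal(mmf$variance, 0)
})

test_that("analytic null moments sit inside tight Monte-Carlo intervals", {
  set.seed(404)
  nshuf <- 3000
  for (rep in 1:5) {
    p <- randomPresence(12, 12, fill = runif(1, 0.25, 0.6))
    pm <- preparePresence(p)
    mm <- nodfNullMoments(pm, "equiprobable_rows_fixed_cols")
    draws <- vapply(seq_len(nshuf), function(i)
      nodf(nullShuffle(pm, "equiprobable_rows_fixed_cols",
                       seed = 7000 + i))[["cols"]], 0)
    z99 <- stats::qnorm(0.995)
    expect_lt(abs(mm$mean - mean(draws)), z99 * sd(draws) / sqrt(nshuf))
    dev2 <- (draws - mean(draws))^2
    expect_lt(abs(mm$variance - mean(dev2)), z99 * sd(dev2) / sqrt(nshuf))
  }
})

test_that("planted nesting is detected and the null is calibrated", {
  w <- generateWorld(worldConfig(nSamples = 100, nTags = 50, nu = 1,
                                 kappa = 0, noise = FALSE, seed = 17))
  res <- nodfTest(preparePresence(w$table), nNull = 199, seed = 1)
  expect_gt(res@ses, 2)
  expect_lte(res@pEmpirical, 0.01)
  # matrices drawn from the null itself give uniform empirical p
  set.seed(55)
  base <- preparePresence(randomPresence(12, 12))
  pvals <- vapply(1:120, function(i) {
    m <- nullShuffle(base, "equiprobable_rows_fixed_cols", seed = 5000 + i)
    nodfTest(m, nNull = 99, seed = i, mode = "empirical")@pEmpirical
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("recomputation is honest when the most prevalent taxon is removed", {
  set.seed(77)
  p <- randomPresence(10, 14)
  v1 <- nodf(p)
  top <- which.max(rowSums(p))
  v2 <- nodf(p[-top, , drop = FALSE])
  expect_identical(v2, bruteNodf(p[-top, , drop = FALSE]))
  expect_false(identical(v1, v2))
})

test_that("nestedness by level collapses, partitions, and matches tag level", {
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  res <- nestednessByLevel(w$table, w$taxonomy,
                           levels = c("phylum", "genus", "tag"),
                           metadata = w$metadata, partition = TRUE,
                           nNull = 99, seed = 4, mode = "analytic")
  expect_true(all(c("phylum", "genus", "tag") %in% res$level))
  expect_true(all(unique(res$partition) %in%
                    c("all", "Animal", "Plant", "Saline", "Non-saline")))
  # tag level equals the un-collapsed analysis
  tag_all <- res[res$level == "tag" & res$partition == "all", ]
  direct <- nodfTest(preparePresence(w$table), nNull = 99, seed = 4,
                     mode = "analytic")
  expect_equal(tag_all$nodf_overall, unname(direct@nodf["overall"]))
  expect_equal(tag_all$ses, direct@ses)
})
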