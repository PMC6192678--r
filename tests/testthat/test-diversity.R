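test_that("alpha metrics match closed forms on hand examples", {
  m <- cbind(uniform = c(1, 1, 1, 1), skew = c(5, 1, 1, 2))
  rownames(m) <- c("A", "B", "C", "D")
  al <- alphaMetrics(ObservationTable(m))
  expect_equal(unname(al$observed_features), c(4, 4))
  expect_equal(unname(al["uniform", "shannon"]), 2.0)  # uniform over 4, bits
  # chao1: 2 singletons, 1 doubleton -> 4 + 4/2 = 6
  expect_equal(unname(al["skew", "chao1"]), 6)
  # no doubletons -> bias-corrected form
  m2 <- matrix(c(1, 1, 3), 3, 1, dimnames = list(c("A", "B", "C"), "s"))
  expect_equal(unname(alphaMetrics(ObservationTable(m2))$chao1),
               3 + 2 * 1 / 2)
  expect_true(all(al$observed_features <= al$chao1))
})

test_that("Faith PD sums the root-to-tip path union and is monotone", {
  tr <- threeTipTree()
  m <- cbind(ab = c(1, 1, 0), abc = c(1, 1, 1), a = c(1, 0, 0))
  rownames(m) <- c("A", "B", "C")
  al <- alphaMetrics(ObservationTable(m), tr)
  expect_equal(unname(al$faith_pd), c(3, 5, 2))
  expect_true(all(al$faith_pd <= totalBranchLength(tr)))
  # missing tip -> error naming the feature
  m2 <- rbind(m, X = c(0, 1, 0))
  expect_error(alphaMetrics(ObservationTable(m2), tr), "X")
})

test_that("Faith PD agrees with picante on random worlds", {
  skip_if_not_installed("picante")
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  x <- w$table[, 1:10]
  mine <- faithPd(x, w$tree)
  ref <- picante::pd(t(as.matrix(counts(x))), w$tree,
                     include.root = TRUE)$PD
  expect_equal(unname(mine), ref, tolerance = 1e-10)
})

test_that("unweighted UniFrac reproduces hand-enumerated branch ratios", {
  tr <- threeTipTree()
  m <- cbind(ab = c(1, 1, 0), a = c(1, 0, 0), c = c(0, 0, 1),
             ab2 = c(2, 5, 0))
  rownames(m) <- c("A", "B", "C")
  d <- unifrac(ObservationTable(m), tr)
  expect_equal(d["ab", "ab2"], 0)        # same tip set
  expect_equal(d["a", "c"], 1.0)         # no shared branches
  expect_equal(d["ab", "a"], 1 / 3)      # unique B:1 over union 3
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(unifrac(ObservationTable(cbind(m, empty = c(0, 0, 0))), tr),
               "empty")
})

test_that("weighted UniFrac matches phyloseq on random communities", {
  skip_if_not_installed("phyloseq")
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  x <- w$table[, 1:8]
  x <- x[Matrix::rowSums(counts(x)) > 0, ]
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(as.matrix(counts(x)), taxa_are_rows = TRUE),
    ape::keep.tip(w$tree, featureIds(x)))
  for (wtd in c(FALSE, TRUE)) {
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = wtd,
                                       normalized = FALSE))
    mine <- unifrac(x, w$tree, weighted = wtd, normalized = FALSE)
    expect_equal(mine[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # normalized weighted stays within [0, 1]
  dn <- unifrac(x, w$tree, weighted = TRUE, normalized = TRUE)
  expect_true(all(dn >= 0 & dn <= 1 + 1e-12))
})

test_that("blocked UniFrac partitions pairs exactly once and matches full", {
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  x <- w$table[, 1:12]
  full <- unifrac(x, w$tree)
  for (bs in c(2, 5, 12)) {
    blk <- unifracBlocked(x, w$tree, blockSize = bs)
    expect_lt(max(abs(blk - full)), 1e-12)
  }
  fullw <- unifrac(x, w$tree, weighted = TRUE)
  blkw <- unifracBlocked(x, w$tree, weighted = TRUE, blockSize = 3)
  expect_lt(max(abs(blkw - fullw)), 1e-12)
})

test_that("PCoA recovers geometry and reports negative eigenvalues", {
  # collinear points: axis 1 recovers spacing up to sign/shift
  pts <- c(0, 1, 2, 5)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(letters[1:4], letters[1:4])
  ord <- pcoaOrdination(dm, 3)
  ax1 <- ord$coordinates[, 1]
  expect_equal(unname(abs(diff(ax1))), diff(pts), tolerance = 1e-8)
  expect_equal(ord$proportion_explained[1], 1, tolerance = 1e-8)
  # euclidean input: coordinate distances reproduce the input
  set.seed(1)
  y <- matrix(rnorm(20), 5, 4)
  dm2 <- as.matrix(dist(y))
  dimnames(dm2) <- list(paste0("s", 1:5), paste0("s", 1:5))
  ord2 <- pcoaOrdination(dm2, 4)
  expect_equal(as.matrix(dist(ord2$coordinates)), dm2,
               tolerance = 1e-8, ignore_attr = TRUE)
  # non-euclidean distances produce (reported) negative eigenvalues
  dm3 <- matrix(1, 4, 4) - diag(4)
  dm3[1, 2] <- dm3[2, 1] <- 0.1
  dimnames(dm3) <- list(letters[1:4], letters[1:4])
  expect_true(any(pcoaOrdination(dm3)$eigenvalues < 0))
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b")))),
               "symmetric")
})

test_that("PERMANOVA separates planted groups and matches vegan's F", {
  # maximal separation: zero within, positive between (groups big enough
  # that no permutation recreates an equally extreme partition)
  n <- 16
  g <- rep(c("x", "y"), each = n / 2)
  dm <- 1 - outer(g, g, "==")
  diag(dm) <- 0
  dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- permanova(dm, g, nPermutations = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
  # F is invariant to relabelling the groups
  res2 <- permanova(dm, rev(g), nPermutations = 99, seed = 1)
  expect_equal(res$pseudo_F, res2$pseudo_F)
  expect_error(permanova(dm, c("x", rep("y", n - 1)), 99, 1), "2 samples")

  skip_if_not_installed("vegan")
  set.seed(7)
  y <- matrix(rnorm(60), 12, 5)
  dmr <- as.matrix(dist(y))
  ids <- paste0("r", 1:12)
  dimnames(dmr) <- list(ids, ids)
  grp <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova(dmr, grp, nPermutations = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(dmr) ~ grp,
                        data = data.frame(grp = grp),
                        permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p values are uniform under the null", {
  set.seed(31)
  n <- 12
  pvals <- vapply(1:150, function(i) {
    y <- matrix(rnorm(n * 3), n, 3)
    dm <- as.matrix(dist(y))
    ids <- paste0("s", seq_len(n))
    dimnames(dm) <- list(ids, ids)
    permanova(dm, sample(rep(c("a", "b"), each = n / 2)),
              nPermutations = 49, seed = i)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
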