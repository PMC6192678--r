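mkMeta <- function(env) {
  SampleMetadata(data.frame(
    study_id = "s", empo_1 = "Free-living", empo_2 = "Non-saline",
    empo_3 = env, row.names = sprintf("smp%03d", seq_along(env))))
}

test_that("tag distributions count presences, not abundance, with threshold", {
  env <- rep(c("A", "B"), c(9, 3))
  md <- mkMeta(env)
  m <- matrix(0, 2, 12, dimnames = list(c("t1", "t2"), rownames(md)))
  m[1, 1:12] <- c(rep(1, 9), 10000, 1, 7)   # 9 in A, 3 in B
  m[2, 1:9] <- 1                            # 9 appearances only
  td <- tagEnvironmentDistribution(ObservationTable(m), md, minSamples = 10)
  expect_equal(rownames(td$W), "t1")        # t2 under the 10-sample rule
  expect_equal(unname(td$W["t1", ]), c(0.75, 0.25))
  # a count of 1 and a count of 10,000 contribute equally
  expect_equal(unname(td$counts["t1", "B"]), 3)
  expect_error(
    tagEnvironmentDistribution(
      ObservationTable(m),
      SampleMetadata(data.frame(study_id = "s",
                                empo_3 = rep(NA_character_, 12),
                                row.names = rownames(md)))),
    "empo_3")
})

test_that("entropy matches closed forms and validates its input", {
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(rep(0.25, 4)), 2)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannonEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("cluster pooling combines counts, not averages, by default", {
  td <- list(counts = rbind(t1 = c(A = 10, B = 0), t2 = c(A = 0, B = 10),
                            t3 = c(A = 30, B = 0)),
             W = rbind(t1 = c(1, 0), t2 = c(0, 1), t3 = c(1, 0)),
             nSamples = c(t1 = 10, t2 = 10, t3 = 30),
             environments = c("A", "B"))
  one <- clusterDistribution(td, "t1")
  expect_equal(unname(one$W), unname(td$W["t1", ]))
  two <- clusterDistribution(td, c("t1", "t2"))
  expect_equal(unname(two$W), c(0.5, 0.5))
  expect_equal(two$entropy, 1)
  # order invariance
  expect_equal(clusterDistribution(td, c("t2", "t1"))$W, two$W)
  # pooled counts weight by support; the mean-of-W variant does not
  pooled <- clusterDistribution(td, c("t2", "t3"))
  expect_equal(unname(pooled$W), c(0.75, 0.25))
  avg <- clusterDistribution(td, c("t2", "t3"), method = "mean")
  expect_equal(unname(avg$W), c(0.5, 0.5))
  expect_null(clusterDistribution(td, "absent"))
})

test_that("pooled cluster entropy is at least the member average (concavity)", {
  set.seed(88)
  for (i in 1:20) {
    cnt <- matrix(rpois(8, 6), 4, 2,
                  dimnames = list(paste0("t", 1:4), c("A", "B")))
    cnt[rowSums(cnt) == 0, 1] <- 1
    td <- list(counts = cnt, W = cnt / rowSums(cnt),
               nSamples = rowSums(cnt), environments = c("A", "B"))
    pooled <- clusterDistribution(td, rownames(cnt))
    member_ent <- apply(td$W, 1, entropy <- function(w) {
      w <- w[w > 0]; -sum(w * log2(w))
    })
    wmean <- sum(member_ent * rowSums(cnt)) / sum(cnt)
    expect_gte(pooled$entropy + 1e-12, wmean)
  }
})

test_that("planted specificity orders tag, genus, and permuted entropies", {
  w <- cachedWorld("spec",
                   worldConfig(nSamples = 320, nTags = 400, seed = 21))
  td <- tagEnvironmentDistribution(w$table, w$metadata, minSamples = 10)
  obs <- entropyByTaxonomicLevel(td, w$taxonomy, minTags = 5)
  tag_mean <- obs$mean_entropy[obs$level == "tag"]
  genus_mean <- obs$mean_entropy[obs$level == "genus"]
  expect_lt(tag_mean, genus_mean)
  perm_means <- vapply(1:5, function(i)
    permutedNull(td, taxonomy = w$taxonomy, mode = "taxonomy_labels",
                 seed = i, minTags = 5)$mean_entropy[obs$level == "genus"],
    0)
  expect_gt(mean(perm_means), genus_mean)
  # permutation preserves group sizes and the tag-level mean
  perm <- permutedNull(td, taxonomy = w$taxonomy, mode = "taxonomy_labels",
                       seed = 3, minTags = 5)
  expect_equal(perm$mean_entropy[perm$level == "tag"], tag_mean)
  expect_equal(perm$n_groups, obs$n_groups)
})

test_that("weighted mean equals unweighted for equal-size groups", {
  td <- list(counts = rbind(t1 = c(A = 4, B = 0), t2 = c(A = 0, B = 4),
                            t3 = c(A = 2, B = 2), t4 = c(A = 4, B = 4)),
             W = NULL, nSamples = c(4, 4, 4, 8),
             environments = c("A", "B"))
  td$W <- td$counts / rowSums(td$counts)
  tax <- data.frame(kingdom = "k", phylum = c("p1", "p1", "p2", "p2"),
                    class = "c", order = "o", family = "f",
                    genus = c("g1", "g1", "g2", "g2"),
                    row.names = paste0("t", 1:4))
  res <- entropyByTaxonomicLevel(td, tax, levels = "phylum", minTags = 2)
  groups <- attr(res, "groups")
  expect_equal(res$mean_entropy, mean(groups$entropy))
})

test_that("subtree entropy reproduces the root pool and the tip drop", {
  w <- cachedWorld("spec",
                   worldConfig(nSamples = 320, nTags = 400, seed = 21))
  td <- tagEnvironmentDistribution(w$table, w$metadata, minSamples = 10)
  prof <- entropyBySubtree(td, w$tree, minTips = 3)
  root_row <- prof[prof$n_tips == max(prof$n_tips), ]
  pooled <- clusterDistribution(td, rownames(td$counts))
  expect_equal(root_row$entropy[1], pooled$entropy)
  # entropy at the tips (branch length 0) sits below subtree entropies
  tag_mean <- mean(apply(td$W, 1, shannonEntropy))
  expect_lt(tag_mean, mean(prof$entropy))
  expect_true(all(prof$entropy <= log2(length(td$environments)) + 1e-9))
  # a cherry of two same-environment tags has zero entropy
  tr <- readTree("((x:1,y:1):1,z:2);")
  td2 <- list(counts = rbind(x = c(A = 5, B = 0), y = c(A = 3, B = 0),
                             z = c(A = 0, B = 4)),
              W = rbind(x = c(1, 0), y = c(1, 0), z = c(0, 1)),
              nSamples = c(5, 3, 4), environments = c("A", "B"))
  prof2 <- entropyBySubtree(td2, tr, minTips = 2)
  cherry <- prof2[prof2$n_tips == 2, ]
  expect_equal(cherry$entropy, 0)
  expect_equal(cherry$branch_length, 2)
})

test_that("sliding windows average what falls inside them", {
  flat <- slidingWindowProfile(x = 1:10, y = rep(3, 10), windowWidth = 2)
  expect_true(all(flat$mean == 3 & flat$p20 == 3 & flat$p80 == 3))
  single <- slidingWindowProfile(x = 5, y = 1.5, windowWidth = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$mean, 1.5)
  set.seed(4)
  x <- runif(50); y <- runif(50)
  prof <- slidingWindowProfile(x, y, windowWidth = 0.3, nGrid = 7)
  g <- prof$x[3]
  inside <- y[abs(x - g) <= 0.15]
  expect_equal(prof$mean[3], mean(inside))
  expect_equal(prof$p20[3], unname(quantile(inside, 0.2)))
  expect_equal(prof$p80[3], unname(quantile(inside, 0.8)))
  expect_error(slidingWindowProfile(1, 1, windowWidth = 0), "positive")
})

test_that("level branch lengths average the clade spans", {
  tr <- readTree("((x:1,y:1):1,z:2);")
  tax <- data.frame(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = c("f1", "f1", "f2"),
                    genus = c("g1", "g2", "g3"),
                    row.names = c("x", "y", "z"))
  # whole-tree group spans the diameter
  all_grp <- levelBranchLength(tr, tax, "phylum")
  expect_equal(all_grp$mean, 4)
  # two-tip group: their path; singleton: 0
  fam <- levelBranchLength(tr, tax, "family")
  expect_equal(sort(fam$groups$max_tip_to_tip), c(0, 2))
  expect_equal(fam$mean, 1)
  gen <- levelBranchLength(tr, tax, "genus")
  expect_equal(gen$mean, 0)
})
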