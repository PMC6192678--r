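test_that("observation tables round-trip through classic TSV exactly", {
  ot <- tinyTable()
  expect_equal(unname(sampleTotals(ot)), c(3, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeObservationTable(ot, path)
  back <- readObservationTable(path)
  expect_identical(featureIds(back), featureIds(ot))
  expect_identical(sampleIds(back), sampleIds(ot))
  expect_equal(as.matrix(counts(back)), as.matrix(counts(ot)))
})

test_that("malformed tables are rejected with the offending label", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "f1\t1\t2", "f1\t3\t4"), path)
  expect_error(readObservationTable(path), "f1")
  writeLines(c("#OTU ID\ts1\ts2", "f1\t1\t-2"), path)
  expect_error(readObservationTable(path), "negative")
  writeLines(c("#OTU ID\ts1\ts2", "f1\t1\t2.5"), path)
  expect_error(readObservationTable(path), "non-integer")
  expect_error(ObservationTable(matrix(-1, 1, 1,
                                       dimnames = list("f", "s"))),
               "negative")
})

test_that("mapping files parse missing tokens and report EMPO violations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tstudy_id\tempo_1\tempo_2\tempo_3\tph",
               "a\t1\tFree-living\tAnimal\tWater\t7.2",
               "b\t1\tFree-living\tSaline\tWater\tNA",
               "c\t2\tHost-associated\tAnimal\tGut\tnot applicable"),
             path)
  md <- readSampleMetadata(path)
  expect_s4_class(md, "SampleMetadata")
  iss <- validationIssues(md)
  expect_equal(iss$sample_id, "a")           # Free-living + Animal
  expect_equal(nrow(md), 3)                  # violators retained
  expect_true(is.na(md[["ph"]][2]) && is.na(md[["ph"]][3]))
  expect_equal(md[["ph"]][1], 7.2)
  # duplicate ids are a hard error
  writeLines(c("#SampleID\tstudy_id", "a\t1", "a\t2"), path)
  expect_error(readSampleMetadata(path), "duplicate")
})

test_that("distinct level-3 categories are enumerated as loaded", {
  df <- data.frame(study_id = "s", empo_1 = "Free-living",
                   empo_2 = "Non-saline",
                   empo_3 = sprintf("env%02d", rep(1:17, 2)),
                   row.names = sprintf("x%02d", 1:34))
  md <- SampleMetadata(df)
  expect_equal(length(unique(md[["empo_3"]])), 17)
})

test_that("newick reading validates tips and exposes distances", {
  tr <- threeTipTree()
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(totalBranchLength(tr), 5)
  d <- tipDistances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_error(readTree("((A:1,A:1):1,B:1);"), "duplicate")
})

test_that("feature and sample filters apply their thresholds exactly", {
  m <- matrix(c(25, 0, 24, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("keep", "drop"), c("s1", "s2")))
  out <- filterFeaturesMinTotal(ObservationTable(m), 25)
  expect_identical(featureIds(out), "keep")
  expect_equal(as.numeric(counts(out)[1, ]), c(25, 0))
  # min_total 1 is the identity when no feature is all-zero
  ot <- tinyTable()
  expect_equal(dim(filterFeaturesMinTotal(ot, 1)), dim(ot))
  # an empty result is allowed
  expect_equal(nrow(filterFeaturesMinTotal(ot, 100)), 0)

  m2 <- matrix(c(5000, 4999), 1, 2,
               dimnames = list("f", c("deep", "shallow")))
  expect_identical(sampleIds(qcFilterSamples(ObservationTable(m2), 5000)),
                   "deep")
})

test_that("rarefaction conserves depth, caps counts, and is reproducible", {
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  r1 <- rarefy(w$table, 3000, seed = 42)
  expect_true(all(sampleTotals(r1) == 3000))
  common <- intersect(sampleIds(r1), sampleIds(w$table))
  expect_true(all(as.matrix(counts(r1)[, common]) <=
                    as.matrix(counts(w$table)[, common])))
  r2 <- rarefy(w$table, 3000, seed = 42)
  expect_identical(as.matrix(counts(r1)), as.matrix(counts(r2)))
  # depth equal to the sample total leaves it unchanged; above drops it
  ot <- ObservationTable(matrix(c(3, 2), 2, 1,
                                dimnames = list(c("a", "b"), "s")))
  expect_equal(as.numeric(counts(rarefy(ot, 5))), c(3, 2))
  expect_equal(ncol(rarefy(ot, 6)), 0)
  expect_error(rarefy(ot, 0), "positive")
})

test_that("balanced subsets are round-robin across environments and studies", {
  df <- data.frame(
    study_id = c(rep("s1", 100), rep("s2", 100), rep("s3", 100)),
    empo_3 = c(rep("E1", 200), rep("E2", 100)),
    row.names = sprintf("smp%03d", 1:300))
  md <- SampleMetadata(df)
  sel <- balancedSubset(md, 40, seed = 1)
  env <- df[sel, "empo_3"]
  expect_equal(sum(env == "E1"), 20)
  expect_equal(sum(env == "E2"), 20)
  expect_equal(unname(table(df[sel, "study_id"])[c("s1", "s2")]),
               c(10L, 10L), ignore_attr = TRUE)
  # n = total returns everything
  expect_setequal(balancedSubset(md, 300, seed = 1), rownames(df))
  # exhausted environment hands its surplus to the others
  df2 <- data.frame(study_id = c(rep("s1", 4), rep("s2", 50)),
                    empo_3 = c(rep("E1", 4), rep("E2", 50)),
                    row.names = sprintf("y%02d", 1:54))
  sel2 <- balancedSubset(SampleMetadata(df2), 30, seed = 2)
  expect_equal(sum(df2[sel2, "empo_3"] == "E1"), 4)
  expect_equal(sum(df2[sel2, "empo_3"] == "E2"), 26)
  expect_warning(balancedSubset(SampleMetadata(df2), 100, seed = 1),
                 "available")
})

test_that("per-category balance never differs by more than one", {
  w <- cachedWorld("small", worldConfig(nSamples = 40, nTags = 60, seed = 9))
  md <- as.data.frame(w$metadata)
  for (n in c(9, 16, 23)) {
    sel <- balancedSubset(w$metadata, n, seed = n)
    envTab <- table(md[sel, "empo_3"])
    expect_lte(diff(range(envTab)), 1)
    for (e in names(envTab)) {
      stTab <- table(md[sel[md[sel, "empo_3"] == e], "study_id"])
      if (length(stTab) > 1) expect_lte(diff(range(stTab)), 1)
    }
  }
})

test_that("taxonomic collapse sums counts, pools unassigned, and composes", {
  tax <- data.frame(kingdom = "k", phylum = c("p1", "p1", NA),
                    class = c("c1", "c2", NA), order = "o", family = "f",
                    genus = c("g1", "g2", "g3"),
                    row.names = c("t1", "t2", "t3"))
  tax[is.na(tax)] <- "unassigned"
  m <- matrix(c(2, 1, 3, 0, 1, 4), 3, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  ot <- ObservationTable(m)
  ph <- collapseByTaxonomy(ot, tax, "phylum")
  expect_equal(as.numeric(counts(ph)["k; p1", ]), c(5, 1))
  expect_true("unassigned" %in% featureIds(ph))
  expect_equal(sum(counts(ph)), sum(counts(ot)))   # conservation
  # collapsing genus output at phylum == collapsing at phylum directly
  gen <- collapseByTaxonomy(ot, tax, "genus")
  # rebuild a genus-level taxonomy keyed by the collapsed row labels
  gtax2 <- tax
  rownames(gtax2) <- apply(tax[, 1:6], 1, paste, collapse = "; ")
  ph2 <- collapseByTaxonomy(gen, gtax2, "phylum")
  expect_equal(as.matrix(counts(ph2))[featureIds(ph), ],
               as.matrix(counts(ph))[featureIds(ph), ])
})

test_that("taxonomy loading enforces rank order and flags inconsistency", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tkingdom\tphylum\tclass\torder\tfamily\tgenus",
               "t1\tk\tp1\tc1\to1\tf1\tg1",
               "t2\tk\tp2\tc2\to2\tf2\tg1"), path)
  tax <- readTaxonomyMap(path)
  expect_equal(colnames(tax),
               c("kingdom", "phylum", "class", "order", "family", "genus"))
  iss <- attr(tax, "issues")
  expect_true("g1" %in% iss$label)   # same genus, different lineages
})
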