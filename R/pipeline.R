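# End-to-end driver chaining the analysis stages on file inputs or a
# simulated world, with a manifest recording every output, parameter and
# seed.

#' Read a flat key-value run configuration
#'
#' One \code{key = value} per line; \code{#} comments ignored. Keys are
#' those of \code{\link{runPipeline}}'s \code{config} list; the
#' \code{simulate.*} prefix fills a \code{\link{worldConfig}}.
#'
#' @param path file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    val <- p[2]
    num <- suppressWarnings(as.numeric(val))
    out[[p[1]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — filter, rarefy/subset, alpha
#' and beta diversity, then nestedness, specificity entropy, envelope
#' fits, mdFDR effect sizes and community metrics — on either file inputs
#' or a simulated world, writing flat TSV outputs and a manifest. All
#' randomness flows from \code{config$seed}; identical configs give
#' byte-identical outputs.
#'
#' @param config named list. Either \code{table}, \code{metadata},
#'   \code{tree}, \code{taxonomy}, \code{copy_numbers} file paths, or
#'   \code{simulate = TRUE} with optional \code{simulate.*} overrides
#'   (e.g. \code{simulate.nSamples}) — exactly one of the two.
#'   Optional parameters: \code{min_feature_total} (25),
#'   \code{min_depth} (1000), \code{rarefaction_depth} (5000, also the
#'   subset eligibility threshold), \code{subset_n}, \code{n_null} (999),
#'   \code{alpha} (0.05), \code{seed} (1).
#' @param outDir output directory.
#' @return invisibly, the manifest data.frame (also written to
#'   \code{manifest.tsv}).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  getp <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  seed <- as.integer(getp("seed", 1))
  simulate <- isTRUE(config$simulate) || identical(config$simulate, 1)
  haveFiles <- !is.null(config$table)
  if (simulate && haveFiles)
    .stopf("config must name input files or a simulate block, not both")
  if (!simulate && !haveFiles)
    .stopf("config must name input files or set simulate")
  manifest <- list()
  note <- function(file, stage, params) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, stage = stage, params = params, seed = seed,
      stringsAsFactors = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n)
    message(sprintf("[%6.1fs] %s: %s records",
                    proc.time()[["elapsed"]] - t0, stage, n))

  if (simulate) {
    ov <- config[startsWith(names(config), "simulate.")]
    names(ov) <- sub("^simulate\\.", "", names(ov))
    wc <- do.call(worldConfig, c(ov, list(seed = seed)))
    world <- generateWorld(wc)
    writeWorld(world, file.path(outDir, "world"))
    note("world", "simulate", sprintf("nSamples=%d nTags=%d",
                                      wc$nSamples, wc$nTags))
    tab <- world$table; meta <- world$metadata; tree <- world$tree
    tax <- world$taxonomy; cn <- world$copyNumbers
  } else {
    tab <- readObservationTable(config$table)
    meta <- readSampleMetadata(config$metadata)
    tree <- if (!is.null(config$tree)) readTree(path = config$tree)
    tax <- if (!is.null(config$taxonomy)) readTaxonomyMap(config$taxonomy)
    cn <- if (!is.null(config$copy_numbers))
      readCopyNumbers(config$copy_numbers)
  }
  log_stage("load", ncol(tab))

  minTot <- getp("min_feature_total", 25)
  minDepth <- getp("min_depth", 1000)
  rdepth <- getp("rarefaction_depth", 5000)
  tab <- qcFilterSamples(filterFeaturesMinTotal(tab, minTot), minDepth)
  log_stage("filter", ncol(tab))

  eligible <- sampleIds(tab)[sampleTotals(tab) >= rdepth]
  subN <- as.integer(getp("subset_n", length(eligible)))
  sel <- balancedSubset(meta, subN, seed = childSeed(seed, 1),
                        eligible = eligible)
  rare <- rarefy(tab[, sel], rdepth, seed = childSeed(seed, 2))
  writeObservationTable(rare, file.path(outDir, "table_rarefied.tsv"))
  note("table_rarefied.tsv", "rarefy",
       sprintf("depth=%d n=%d", rdepth, ncol(rare)))
  log_stage("subset+rarefy", ncol(rare))

  al <- alphaMetrics(rare, tree)
  adf <- cbind(sample_id = rownames(al), as.data.frame(al))
  write.table(adf, file.path(outDir, "alpha.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("alpha.tsv", "alpha", "metrics=observed,shannon,chao1,faith_pd")

  dm <- if (!is.null(tree)) unifracBlocked(rare, tree) else NULL
  if (!is.null(dm)) {
    writeDistanceMatrix(dm, file.path(outDir, "unifrac_unweighted.tsv"))
    note("unifrac_unweighted.tsv", "beta", "metric=unweighted_unifrac")
    ord <- pcoaOrdination(dm, 3)
    co <- cbind(sample_id = rownames(ord$coordinates),
                as.data.frame(ord$coordinates))
    write.table(co, file.path(outDir, "pcoa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("pcoa.tsv", "pcoa", "axes=3")
  }
  log_stage("diversity", ncol(rare))

  if (!is.null(tax)) {
    nst <- nestednessByLevel(rare, tax,
                             levels = c("phylum", "class", "order",
                                        "family", "genus"),
                             nNull = as.integer(getp("n_null", 999)),
                             seed = childSeed(seed, 3))
    write.table(nst, file.path(outDir, "nestedness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("nestedness.tsv", "nestedness",
         sprintf("n_null=%d model=equiprobable_rows_fixed_cols",
                 as.integer(getp("n_null", 999))))
    log_stage("nestedness", nrow(nst))

    td <- tagEnvironmentDistribution(rare, meta,
                                     minSamples = getp("min_samples", 10))
    ebl <- entropyByTaxonomicLevel(td, tax,
                                   minTags = getp("min_tags", 20))
    write.table(ebl, file.path(outDir, "entropy_by_level.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("entropy_by_level.tsv", "entropy",
         sprintf("min_samples=%d min_tags=%d",
                 as.integer(getp("min_samples", 10)),
                 as.integer(getp("min_tags", 20))))
    log_stage("entropy", nrow(ebl))
  }

  md <- as.data.frame(meta)[sampleIds(rare), ]
  rich <- setNames(al$observed_features, rownames(al))
  for (cv in c("ph", "temperature_deg_c")) {
    if (!cv %in% names(md)) next
    v <- md[[cv]]
    if (sum(is.finite(v)) < 40) next
    env <- binPercentile(v, rich[rownames(md)],
                         nBins = if (cv == "ph") 100 else 120,
                         minOccupancy = getp("min_bin_occupancy", 5))
    if (nrow(env) < 4) next
    cmpf <- compareFits(env)
    fit_tab <- do.call(rbind, lapply(c("laplace", "gaussian"), function(f) {
      ft <- cmpf[[f]]
      data.frame(covariate = cv, family = f, mu = ft@mu, scale = ft@scale,
                 amplitude = ft@amplitude, sse = ft@sse,
                 winner = cmpf$winner == f)
    }))
    write.table(fit_tab, file.path(outDir, paste0("envelope_", cv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note(paste0("envelope_", cv, ".tsv"), "envelope",
         sprintf("bins=%d percentile=99", if (cv == "ph") 100L else 120L))
  }
  log_stage("envelope", 2)

  preds <- intersect(c("empo_3", "study_id", "ph", "temperature_deg_c",
                       "latitude_deg"), names(md))
  eff <- tryCatch(
    mdfdrAlpha(rich, meta, preds, alpha = getp("alpha", 0.05),
               minFraction = getp("min_fraction", 0.003)),
    error = function(e) NULL)
  if (!is.null(eff)) {
    write.table(eff$predictors, file.path(outDir, "mdfdr_predictors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(eff$pairs))
      write.table(eff$pairs, file.path(outDir, "mdfdr_pairs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    note("mdfdr_predictors.tsv", "effect-size",
         sprintf("alpha=%.3f m=%d R=%d", eff$alpha, eff$m, eff$R))
  }
  log_stage("mdfdr", if (is.null(eff)) 0 else eff$m)

  if (!is.null(cn)) {
    av <- acn(tab, cn, minReads = getp("acn_min_reads", 10000))
    write.table(data.frame(sample_id = names(av), acn = av),
                file.path(outDir, "acn.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("acn.tsv", "acn", sprintf("min_reads=%d n=%d",
                                   as.integer(getp("acn_min_reads", 10000)),
                                   length(av)))
  }
  cards <- tradingCards(rare, meta, tax,
                        minSamples = getp("min_samples", 10))
  write.table(cards, file.path(outDir, "trading_cards.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("trading_cards.tsv", "cards", sprintf("n_tags=%d", nrow(cards)))
  log_stage("community", nrow(cards))

  man <- do.call(rbind, manifest)
  write.table(man, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}
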