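# Average community 16S copy number, prevalence statistics, and per-tag
# summary ("trading card") records.

#' Read a feature-to-copy-number table
#'
#' TSV with columns \code{feature_id} and \code{copy_number}
#' (real, >= 1). Copy numbers are consumed as an input (e.g. exported from
#' a reference database); inference is out of scope.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
readCopyNumbers <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  v <- as.numeric(df[[2]])
  if (any(!is.finite(v)) || any(v < 1)) .stopf("copy numbers must be >= 1")
  setNames(v, as.character(df[[1]]))
}

#' Abundance-weighted average community 16S copy number
#'
#' Per sample: each feature's count is divided by its copy number, and the
#' ACN is the raw sample sum divided by the normalized sample sum — a
#' weighted mean bounded by the observed features' copy numbers. Samples
#' with more than \code{minReads} reads are summed; shallower samples are
#' excluded.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param copyNumbers named numeric vector (or data.frame as read by
#'   \code{\link{readCopyNumbers}}) covering all observed features.
#' @param minReads inclusion threshold on the sample total (default
#'   10000; strictly greater than).
#' @return named numeric vector of per-sample ACN.
#' @export
acn <- function(x, copyNumbers, minReads = 10000) {
  if (is.data.frame(copyNumbers))
    copyNumbers <- setNames(as.numeric(copyNumbers[[2]]),
                            as.character(copyNumbers[[1]]))
  obs <- featureIds(x)[featureTotals(x) > 0]
  missing <- setdiff(obs, names(copyNumbers))
  if (length(missing))
    .stopf("features missing copy numbers: %s",
           paste(head(missing, 5), collapse = ", "))
  x <- x[, sampleTotals(x) > minReads]
  m <- counts(x)
  cn <- copyNumbers[featureIds(x)]
  raw <- Matrix::colSums(m)
  norm <- Matrix::colSums(m / cn)
  setNames(as.numeric(raw / norm), sampleIds(x))
}

#' Per-feature prevalence
#'
#' Fraction of samples in which the feature is observed (count > 0).
#'
#' @param x an \linkS4class{ObservationTable}.
#' @return named numeric vector in [0, 1].
#' @export
prevalence <- function(x) {
  setNames(Matrix::rowSums(counts(x) > 0) / ncol(counts(x)), featureIds(x))
}

#' Mean prevalence as a function of sequencing depth
#'
#' For each depth, rarefies the table (fresh seed per replicate), takes
#' the mean prevalence over features (features absent at that depth count
#' as zero), and averages over replicates. The caller is expected to
#' pre-filter samples to at least the maximum depth (the survey rule:
#' >= 50,000 reads) so the sample set does not change along the gradient;
#' samples below a given depth are excluded at that depth. Optionally a
#' per-study balanced draw (\code{perStudy} samples from each study,
#' discarding smaller studies) is applied first.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param depths subsampling depths (default 50, 500, 5000, 50000).
#' @param nReps replicate rarefactions per depth (default 3).
#' @param seed integer seed.
#' @param perStudy optional per-study sample count (survey convention 30).
#' @param metadata required when \code{perStudy} is set.
#' @return data.frame: depth, mean_prevalence, sd, n_samples (empty rows
#'   dropped when no sample meets a depth).
#' @export
prevalenceDepthProfile <- function(x, depths = c(50, 500, 5000, 50000),
                                   nReps = 3, seed = NULL, perStudy = NULL,
                                   metadata = NULL) {
  if (!is.null(perStudy)) {
    if (is.null(metadata)) .stopf("perStudy requires metadata")
    st <- as.character(as.data.frame(metadata)[sampleIds(x), "study_id"])
    keep <- withSeed(childSeed(seed, 0), {
      unlist(lapply(split(sampleIds(x), st), function(ids)
        if (length(ids) >= perStudy) sample(ids, perStudy) else character(0)))
    })
    x <- x[, sampleIds(x) %in% keep]
  }
  rows <- list()
  for (di in seq_along(depths)) {
    d <- depths[di]
    if (!any(sampleTotals(x) >= d)) next
    mp <- vapply(seq_len(nReps), function(r) {
      xr <- rarefy(x, d, childSeed(seed, di * 100 + r))
      mean(prevalence(xr))
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      depth = d, mean_prevalence = mean(mp),
      sd = if (nReps > 1) sd(mp) else 0,
      n_samples = sum(sampleTotals(x) >= d))
  }
  if (!length(rows))
    return(data.frame(depth = numeric(), mean_prevalence = numeric(),
                      sd = numeric(), n_samples = integer()))
  do.call(rbind, rows)
}

#' Per-tag summary cards
#'
#' For every tag: the number, fraction and rank of samples it occurs in;
#' its total observations, abundance fraction and rank; its lineage; its
#' environment distribution, entropy, dominant environment and that
#' environment's proportion. Ranks are dense 1-based with ties broken by
#' tag id. A tag is \code{selected} when it is in the top 10 by
#' prevalence or abundance, or when it is the most abundant tag of an
#' environment while having distribution entropy < \code{entropyMax}
#' (1 bit), dominant-environment proportion >= \code{proportionMin}
#' (25\%), and total observations >= \code{observationsMin} (1,000).
#'
#' The survey convention computes cards on a rarefied,
#' environment-balanced subset; supply such a table.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param metadata a \linkS4class{SampleMetadata} with \code{empo_3}.
#' @param taxonomy optional taxonomy data.frame.
#' @param minSamples distribution inclusion rule (default 10), see
#'   \code{\link{tagEnvironmentDistribution}}.
#' @param entropyMax,proportionMin,observationsMin selection thresholds.
#' @return data.frame, one row per tag, ordered by prevalence rank.
#' @export
tradingCards <- function(x, metadata, taxonomy = NULL, minSamples = 10,
                         entropyMax = 1.0, proportionMin = 0.25,
                         observationsMin = 1000) {
  ids <- featureIds(x)
  n_present <- Matrix::rowSums(counts(x) > 0)
  tot <- featureTotals(x)
  n_samp <- ncol(counts(x))
  ord_prev <- order(-n_present, ids)
  ord_ab <- order(-tot, ids)
  rank_prev <- integer(length(ids)); rank_prev[ord_prev] <- seq_along(ids)
  rank_ab <- integer(length(ids)); rank_ab[ord_ab] <- seq_along(ids)
  td <- tagEnvironmentDistribution(x, metadata, minSamples = minSamples)
  ent <- setNames(rep(NA_real_, length(ids)), ids)
  dom <- setNames(rep(NA_character_, length(ids)), ids)
  domp <- setNames(rep(NA_real_, length(ids)), ids)
  in_td <- ids %in% rownames(td$W)
  if (any(in_td)) {
    W <- td$W[ids[in_td], , drop = FALSE]
    ent[in_td] <- apply(W, 1, entropyBits)
    dom[in_td] <- colnames(W)[max.col(W, ties.method = "first")]
    domp[in_td] <- apply(W, 1, max)
  }
  lineage <- if (!is.null(taxonomy)) {
    l <- rep("unassigned", length(ids))
    hit <- ids %in% rownames(taxonomy)
    l[hit] <- do.call(paste, c(taxonomy[ids[hit], , drop = FALSE],
                               sep = "; "))
    l
  } else rep(NA_character_, length(ids))
  # most abundant eligible tag per environment
  env_sel <- rep(FALSE, length(ids))
  eligible <- !is.na(ent) & ent < entropyMax & domp >= proportionMin &
    tot >= observationsMin
  for (e in unique(dom[eligible])) {
    cand <- which(eligible & dom == e)
    if (!length(cand)) next
    best <- cand[order(-tot[cand], ids[cand])][1]
    env_sel[best] <- TRUE
  }
  selected <- rank_prev <= 10 | rank_ab <= 10 | env_sel
  data.frame(tag = ids, n_samples = as.integer(n_present),
             sample_fraction = n_present / n_samp,
             prevalence_rank = rank_prev,
             total_observations = as.integer(tot),
             abundance_fraction = tot / sum(tot), abundance_rank = rank_ab,
             lineage = lineage, entropy = unname(ent),
             dominant_env = unname(dom),
             dominant_proportion = unname(domp),
             env_selected = env_sel, selected = selected,
             stringsAsFactors = FALSE)[ord_prev, ]
}
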