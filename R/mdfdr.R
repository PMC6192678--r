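# Effect sizes of metadata predictors on alpha- and beta-diversity via the
# four-step mixed-directional FDR procedure.

#' Categorize metadata predictors
#'
#' Numeric predictors are converted to quartile categories (values on a
#' boundary fall in the lower bin); then every category must cover at
#' least \code{minFraction} of all samples (0.3\%, i.e. 75 of 25,000) or
#' it is dropped; predictors left with fewer than 2 categories are removed
#' with a notice.
#'
#' @param metadata a \linkS4class{SampleMetadata} (or data.frame).
#' @param predictors column names to test.
#' @param minFraction minimum category fraction (default 0.003).
#' @return named list, one element per retained predictor: factor of
#'   per-sample categories (NA = sample excluded for that predictor),
#'   with attribute \code{"provenance"}.
#' @export
categorizePredictors <- function(metadata, predictors, minFraction = 0.003) {
  df <- as.data.frame(metadata)
  n <- nrow(df)
  out <- list()
  for (p in predictors) {
    if (!p %in% names(df)) .stopf("predictor '%s' not in metadata", p)
    v <- df[[p]]
    if (is.numeric(v)) {
      qs <- unique(quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7))
      if (!length(qs) || length(unique(v[!is.na(v)])) < 2) {
        message("predictor '", p, "' is constant; removed")
        next
      }
      cat_v <- cut(v, breaks = c(-Inf, qs, Inf), right = TRUE,
                   labels = paste0("Q", seq_len(length(qs) + 1)))
      prov <- "quartile-binned numeric"
    } else {
      cat_v <- factor(as.character(v))
      prov <- "categorical"
    }
    tab <- table(cat_v)
    keep <- names(tab)[tab / n >= minFraction]
    cat_v[!cat_v %in% keep] <- NA
    cat_v <- droplevels(cat_v)
    if (nlevels(cat_v) < 2) {
      message("predictor '", p, "' has < 2 usable categories; removed")
      next
    }
    names(cat_v) <- rownames(df)
    attr(cat_v, "provenance") <- prov
    out[[p]] <- cat_v
  }
  if (!length(out)) .stopf("no predictors left after categorization")
  out
}

#' Pairwise Mann-Whitney tests of an alpha-diversity value
#'
#' Two-sided Mann-Whitney U for every unordered category pair: exact null
#' when both sides are small and untied (the \code{\link[stats]{wilcox.test}}
#' convention), otherwise the normal approximation with tie correction
#' (no continuity correction, so identical groups give p = 1). Pairs where
#' a category has fewer than 2 samples are skipped (reflected in the pair
#' count).
#'
#' @param values named numeric vector (e.g. observed richness per sample).
#' @param predictor factor from \code{\link{categorizePredictors}}.
#' @return data.frame: cat1, cat2, p, effect (pooled-SD standardized mean
#'   difference), n1, n2.
#' @export
pairwiseAlphaTests <- function(values, predictor) {
  if (!is.null(names(values)) && !is.null(names(predictor)))
    predictor <- predictor[names(values)]
  levs <- levels(droplevels(predictor))
  rows <- list()
  for (pair in combn(levs, 2, simplify = FALSE)) {
    v1 <- values[!is.na(predictor) & predictor == pair[1]]
    v2 <- values[!is.na(predictor) & predictor == pair[2]]
    if (length(v1) < 2 || length(v2) < 2) next
    p <- suppressWarnings(
      wilcox.test(v1, v2, alternative = "two.sided", correct = FALSE)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      cat1 = pair[1], cat2 = pair[2], p = p,
      effect = effectSizePair(v1, v2), n1 = length(v1), n2 = length(v2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise PERMANOVA tests of beta-diversity
#'
#' \code{\link{permanova}} restricted to each category pair's samples.
#' The per-pair effect size uses each sample's distance to its own group
#' centroid in PCoA space as the univariate value (the procedure needs a
#' univariate summary; this is documented as the package's choice).
#'
#' @param dm distance matrix covering the samples.
#' @param predictor factor from \code{\link{categorizePredictors}}.
#' @param nPermutations permutations per pair.
#' @param seed integer seed.
#' @return data.frame as \code{\link{pairwiseAlphaTests}}.
#' @export
pairwiseBetaTests <- function(dm, predictor, nPermutations = 999,
                              seed = NULL) {
  predictor <- predictor[rownames(dm)]
  levs <- levels(droplevels(predictor))
  rows <- list()
  k <- 0
  for (pair in combn(levs, 2, simplify = FALSE)) {
    k <- k + 1
    sel <- !is.na(predictor) & predictor %in% pair
    if (sum(predictor[sel] == pair[1]) < 2 ||
        sum(predictor[sel] == pair[2]) < 2) next
    sub <- dm[sel, sel]
    g <- droplevels(predictor[sel])
    res <- permanova(sub, g, nPermutations, childSeed(seed, k))
    cd <- centroidDistances(sub, g)
    rows[[length(rows) + 1L]] <- data.frame(
      cat1 = pair[1], cat2 = pair[2], p = res$p_value,
      effect = effectSizePair(cd[g == pair[1]], cd[g == pair[2]]),
      n1 = sum(g == pair[1]), n2 = sum(g == pair[2]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Per-sample distance to its own group centroid in full PCoA space.
centroidDistances <- function(dm, grouping) {
  ord <- pcoaOrdination(dm, nAxes = nrow(dm))
  co <- ord$coordinates
  out <- numeric(nrow(dm))
  for (lev in levels(grouping)) {
    i <- which(grouping == lev)
    ctr <- colMeans(co[i, , drop = FALSE])
    out[i] <- sqrt(rowSums(sweep(co[i, , drop = FALSE], 2, ctr)^2))
  }
  out
}

#' Pool pairwise p values
#'
#' Default is the Simes combination,
#' \eqn{\min_k (q \, p_{(k)} / k)}, which stays valid under the positive
#' dependence that pairwise comparisons sharing a group exhibit — Fisher's
#' chi-square combination (\eqn{-2\sum \ln p} against 2k df) and
#' Stouffer's z assume independence and are anti-conservative there; both
#' are available behind the flag. Zero p values are clamped to the machine
#' minimum with a notice. All methods reduce to the single p value when
#' k = 1.
#'
#' @param p vector of p values (>= 1).
#' @param method \code{"simes"}, \code{"fisher"} or \code{"stouffer"}.
#' @return pooled p value.
#' @export
poolPvalues <- function(p, method = c("simes", "fisher", "stouffer")) {
  method <- match.arg(method)
  stopifnot(length(p) >= 1)
  if (any(p <= 0)) {
    message("p = 0 clamped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  p[p > 1] <- 1
  switch(method,
    simes = min(1, min(length(p) * sort(p) / seq_along(p))),
    fisher = pchisq(-2 * sum(log(p)), df = 2 * length(p),
                    lower.tail = FALSE),
    stouffer = pnorm(sum(stats::qnorm(1 - p)) / sqrt(length(p)),
                     lower.tail = FALSE))
}

#' Pooled-SD standardized mean difference
#'
#' \eqn{|m_1 - m_2| / s_{pooled}} with
#' \eqn{s_{pooled} = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#' A zero pooled SD with unequal means is reported as \code{Inf}.
#'
#' @param values1,values2 numeric vectors (>= 2 each).
#' @return non-negative effect size.
#' @export
effectSizePair <- function(values1, values2) {
  stopifnot(length(values1) >= 2, length(values2) >= 2)
  n1 <- length(values1); n2 <- length(values2)
  sp <- sqrt(((n1 - 1) * var(values1) + (n2 - 1) * var(values2)) /
               (n1 + n2 - 2))
  dm <- abs(mean(values1) - mean(values2))
  if (sp == 0) { if (dm == 0) 0 else Inf } else dm / sp
}

#' Mixed-directional FDR over a set of predictors
#'
#' The four-step procedure: (1) pairwise tests per predictor (supplied);
#' (2) a pooled p value per predictor (\code{\link{poolPvalues}});
#' (3) Benjamini-Hochberg across the m pooled p values, giving the
#' significant set of size R; (4) within significant predictors, retain
#' pairs with raw \eqn{p \le R\alpha/(m q_i)} (\eqn{q_i} = number of
#' pairwise comparisons for predictor i) and report their pooled-SD effect
#' sizes. (The source procedure prints the retention inequality the other
#' way around, which contradicts its own multiplicity logic; the
#' \eqn{\le} reading is used here.)
#'
#' @param predictorTests named list, one data.frame per predictor with
#'   columns \code{cat1}, \code{cat2}, \code{p}, \code{effect} (as
#'   returned by \code{\link{pairwiseAlphaTests}} /
#'   \code{\link{pairwiseBetaTests}}).
#' @param alpha FDR control level (default 0.05).
#' @param poolMethod passed to \code{\link{poolPvalues}}.
#' @return list with \code{predictors} (data.frame: predictor, q, pooled
#'   p, BH-adjusted p, significant), \code{R}, \code{m}, \code{pairs}
#'   (retained pairs with thresholds and effect sizes).
#' @export
runMdfdr <- function(predictorTests, alpha = 0.05,
                     poolMethod = c("simes", "fisher", "stouffer")) {
  poolMethod <- match.arg(poolMethod)
  stopifnot(length(predictorTests) >= 1)
  m <- length(predictorTests)
  pooled <- vapply(predictorTests, function(df) {
    if (is.null(df) || !nrow(df)) return(NA_real_)
    poolPvalues(df$p, poolMethod)
  }, 0)
  ok <- !is.na(pooled)
  bh <- rep(NA_real_, m)
  bh[ok] <- p.adjust(pooled[ok], method = "BH")
  sig <- !is.na(bh) & bh <= alpha
  R <- sum(sig)
  preds <- data.frame(predictor = names(predictorTests),
                      q = vapply(predictorTests,
                                 function(df) if (is.null(df)) 0L else nrow(df),
                                 0L),
                      pooled_p = unname(pooled), bh_p = unname(bh),
                      significant = unname(sig), stringsAsFactors = FALSE)
  pairs <- list()
  if (R > 0) {
    for (pn in names(predictorTests)[sig]) {
      df <- predictorTests[[pn]]
      qi <- nrow(df)
      thr <- R * alpha / (m * qi)
      keep <- df$p <= thr
      if (any(keep)) {
        kept <- df[keep, , drop = FALSE]
        kept$predictor <- pn
        kept$threshold <- thr
        pairs[[pn]] <- kept
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
           else data.frame()
  list(predictors = preds, R = R, m = m, alpha = alpha, pairs = pairs)
}

#' End-to-end mdFDR on alpha diversity
#'
#' Convenience wrapper: categorize predictors, run pairwise Mann-Whitney
#' tests of \code{values}, and apply \code{\link{runMdfdr}}.
#'
#' @param values named per-sample alpha-diversity values.
#' @param metadata a \linkS4class{SampleMetadata}.
#' @param predictors metadata columns to test.
#' @param alpha FDR level.
#' @param minFraction category inclusion fraction.
#' @return as \code{\link{runMdfdr}}.
#' @export
mdfdrAlpha <- function(values, metadata, predictors, alpha = 0.05,
                       minFraction = 0.003) {
  cats <- categorizePredictors(metadata, predictors, minFraction)
  tests <- lapply(cats, function(f) pairwiseAlphaTests(values, f))
  runMdfdr(tests, alpha)
}

#' End-to-end mdFDR on beta diversity
#'
#' As \code{\link{mdfdrAlpha}} but with pairwise PERMANOVA on a distance
#' matrix.
#'
#' @param dm distance matrix.
#' @inheritParams mdfdrAlpha
#' @param nPermutations permutations per pair.
#' @param seed integer seed.
#' @export
mdfdrBeta <- function(dm, metadata, predictors, alpha = 0.05,
                      minFraction = 0.003, nPermutations = 999,
                      seed = NULL) {
  cats <- categorizePredictors(metadata, predictors, minFraction)
  tests <- lapply(seq_along(cats), function(i)
    pairwiseBetaTests(dm, cats[[i]], nPermutations, childSeed(seed, i)))
  names(tests) <- names(cats)
  runMdfdr(tests, alpha)
}
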