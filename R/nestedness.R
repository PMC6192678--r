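# NODF nestedness with null models, analytic hypergeometric moments, SES
# and Wald inference.

#' Prepare a presence-absence matrix
#'
#' Booleans from counts > 0; all-zero rows and columns are dropped and
#' recorded. Sorting by marginal totals is internal to \code{\link{nodf}}
#' (stable, ties keep original order), so the input order is immaterial.
#'
#' @param x an \linkS4class{ObservationTable} (rows = taxa) or a
#'   numeric/logical matrix.
#' @return a \linkS4class{PresenceMatrix}.
#' @export
preparePresence <- function(x) {
  m <- if (methods::is(x, "ObservationTable")) as.matrix(counts(x)) else x
  p <- m > 0
  if (!any(p)) .stopf("all-zero table: no presences")
  dr <- rownames(p)[rowSums(p) == 0]
  dc <- colnames(p)[colSums(p) == 0]
  p <- p[rowSums(p) > 0, colSums(p) > 0, drop = FALSE]
  methods::new("PresenceMatrix", presence = p,
               droppedRows = as.character(dr),
               droppedCols = as.character(dc))
}

nodfAxis <- function(p) {
  # mean over all unordered row pairs of: overlap / smaller marginal when
  # the marginals strictly decrease, else 0 (decreasing-fill condition).
  n <- nrow(p)
  if (n < 2) return(NA_real_)
  fills <- rowSums(p)
  ord <- order(fills, decreasing = TRUE)   # stable: ties keep input order
  p <- p[ord, , drop = FALSE]
  fills <- fills[ord]
  ov <- tcrossprod(p * 1)                  # pairwise overlaps
  # for row j (sorted), the qualifying partners are exactly the first
  # cnt[j] rows (those with strictly greater fill)
  cnt <- vapply(fills, function(f) sum(fills > f), 0L)
  ovc <- apply(ov, 2, cumsum)
  act <- which(cnt > 0)
  tot <- sum(ovc[cbind(cnt[act], act)] / fills[act])
  tot / (n * (n - 1) / 2)
}

#' NODF nestedness statistic
#'
#' For each ordered pair of rows (and, separately, columns) whose marginal
#' totals strictly decrease, the paired term is the shared presences
#' divided by the smaller marginal; equal-marginal pairs contribute 0. The
#' row and column components are means over all same-axis pairs, and the
#' overall statistic is their pair-count-weighted mean. Values are on
#' [0, 1] by default (\code{scale100 = TRUE} gives the literature's 0-100
#' scale). The statistic is invariant to row/column permutations of the
#' input.
#'
#' @param pm a \linkS4class{PresenceMatrix} (or matrix, coerced through
#'   \code{\link{preparePresence}}).
#' @param scale100 report on the 0-100 scale.
#' @return named numeric: \code{rows}, \code{cols}, \code{overall}; an
#'   axis with fewer than two categories is \code{NA} and excluded from
#'   \code{overall}.
#' @export
nodf <- function(pm, scale100 = FALSE) {
  p <- if (methods::is(pm, "PresenceMatrix")) pm@presence
       else preparePresence(pm)@presence
  rowsC <- nodfAxis(p)
  colsC <- nodfAxis(t(p))
  nr <- nrow(p); nc <- ncol(p)
  wr <- nr * (nr - 1) / 2; wc <- nc * (nc - 1) / 2
  w <- c(wr, wc)[!is.na(c(rowsC, colsC))]
  v <- c(rowsC, colsC)[!is.na(c(rowsC, colsC))]
  overall <- if (length(v)) sum(w * v) / sum(w) else NA_real_
  out <- c(rows = rowsC, cols = colsC, overall = overall)
  if (scale100) out * 100 else out
}

#' Null-model shuffle of a presence matrix
#'
#' \code{fixed_rows_equiprobable_cols}: each row's presences are
#' reassigned uniformly among columns (row sums preserved).
#' \code{equiprobable_rows_fixed_cols}: each column's presences are
#' reassigned uniformly among rows (column sums preserved).
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param model null model name.
#' @param seed integer seed.
#' @return a \linkS4class{PresenceMatrix} with shuffled presences.
#' @export
nullShuffle <- function(pm,
                        model = c("equiprobable_rows_fixed_cols",
                                  "fixed_rows_equiprobable_cols"),
                        seed = NULL) {
  model <- match.arg(model)
  p <- pm@presence
  out <- withSeed(seed, .shuffleOnce(p, model))
  methods::new("PresenceMatrix", presence = out,
               droppedRows = character(0), droppedCols = character(0))
}

.shuffleOnce <- function(p, model) {
  q <- matrix(FALSE, nrow(p), ncol(p), dimnames = dimnames(p))
  if (model == "fixed_rows_equiprobable_cols") {
    for (i in seq_len(nrow(p)))
      q[i, sample.int(ncol(p), sum(p[i, ]))] <- TRUE
  } else {
    for (j in seq_len(ncol(p)))
      q[sample.int(nrow(p), sum(p[, j])), j] <- TRUE
  }
  q
}

#' Analytic null moments of a NODF component
#'
#' Under the equiprobable-rows/fixed-columns model the columns are
#' independent and each column's presences are a uniform draw without
#' replacement among the \eqn{R} rows, so the overlap of a column pair
#' with fills \eqn{k_i > k_j} is \eqn{Hypergeometric(R, k_i, k_j)}: the
#' paired term has mean \eqn{k_i/R} and variance \eqn{Var(X)/k_j^2}. The
#' statistic's mean is the average of paired means. For the variance, the
#' overlap covariance of any two column pairs sharing a column vanishes
#' exactly under this null (the shared-column cross moments factorise), so
#' summing the paired variances is exact, not an approximation; the same
#' holds for the row component under the fixed-rows model by symmetry.
#'
#' The non-matching axis (rows under fixed columns, and vice versa) has no
#' hypergeometric form; \code{\link{nodfTest}} falls back to empirical
#' moments for it.
#'
#' @param pm a \linkS4class{PresenceMatrix}.
#' @param model null model name (as \code{\link{nullShuffle}}).
#' @return list with \code{mean}, \code{variance}, and \code{axis} (the
#'   component the moments apply to: \code{"cols"} for fixed columns,
#'   \code{"rows"} for fixed rows).
#' @export
nodfNullMoments <- function(pm,
                            model = c("equiprobable_rows_fixed_cols",
                                      "fixed_rows_equiprobable_cols")) {
  model <- match.arg(model)
  p <- pm@presence
  if (model == "equiprobable_rows_fixed_cols") {
    R <- nrow(p); fills <- colSums(p); axis <- "cols"
  } else {
    R <- ncol(p); fills <- rowSums(p); axis <- "rows"
  }
  n <- length(fills)
  if (n < 2) return(list(mean = NA_real_, variance = NA_real_, axis = axis))
  fills <- sort(unname(fills), decreasing = TRUE)
  mu_sum <- 0; var_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ki <- fills[i]; kj <- fills[j]
      if (ki > kj) {
        mu_sum <- mu_sum + ki / R
        v <- kj * (ki / R) * (1 - ki / R) * (R - kj) / (R - 1)
        var_sum <- var_sum + v / kj^2
      }
    }
  }
  npair <- n * (n - 1) / 2
  list(mean = mu_sum / npair, variance = var_sum / npair^2, axis = axis)
}

#' NODF nestedness test
#'
#' Computes the observed NODF and its null distribution under the chosen
#' null model. Analytic inference uses the hypergeometric moments
#' (\code{\link{nodfNullMoments}}) for the model's matching axis component,
#' with \eqn{SES = (obs - mean)/\sqrt{var}} and a two-sided Wald p value;
#' empirical inference draws \code{nNull} shuffles and reports the
#' one-sided (toward nestedness) \eqn{p = (1 + \#\{null \ge obs\})/(1 +
#' n_{null})}. When the requested statistic has no analytic form
#' (\code{overall}, or the non-matching axis), moments come from the
#' empirical null with a notice in \code{momentsSource}.
#'
#' @param pm a \linkS4class{PresenceMatrix} (or matrix).
#' @param model null model name; the survey convention reports
#'   equiprobable rows / fixed columns, as it is consistent with
#'   rarefaction.
#' @param nNull empirical null draws (>= 99 when empirical inference is
#'   requested).
#' @param seed integer seed.
#' @param mode \code{"analytic"}, \code{"empirical"} or \code{"both"}.
#' @param statistic which component to test; \code{"auto"} picks the
#'   model's matching axis (columns under fixed columns).
#' @return a \linkS4class{NodfResult}.
#' @export
nodfTest <- function(pm,
                     model = c("equiprobable_rows_fixed_cols",
                               "fixed_rows_equiprobable_cols"),
                     nNull = 999, seed = NULL,
                     mode = c("both", "analytic", "empirical"),
                     statistic = c("auto", "rows", "cols", "overall")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (!methods::is(pm, "PresenceMatrix")) pm <- preparePresence(pm)
  if (statistic == "auto")
    statistic <- if (model == "equiprobable_rows_fixed_cols") "cols" else "rows"
  obs_all <- nodf(pm)
  obs <- obs_all[[statistic]]
  analytic_ok <- statistic %in% c("rows", "cols") &&
    ((model == "equiprobable_rows_fixed_cols" && statistic == "cols") ||
     (model == "fixed_rows_equiprobable_cols" && statistic == "rows"))
  needEmp <- mode %in% c("empirical", "both") || !analytic_ok
  nullSample <- numeric(0)
  if (needEmp) {
    if (nNull < 99) .stopf("nNull must be >= 99 for empirical inference")
    nullSample <- withSeed(seed, vapply(seq_len(nNull), function(i) {
      q <- .shuffleOnce(pm@presence, model)
      nodf(methods::new("PresenceMatrix", presence = q,
                        droppedRows = character(0),
                        droppedCols = character(0)))[[statistic]]
    }, 0))
  }
  if (analytic_ok && mode != "empirical") {
    mm <- nodfNullMoments(pm, model)
    nullMean <- mm$mean; nullVar <- mm$variance
    momentsSource <- "analytic"
  } else {
    nullMean <- mean(nullSample); nullVar <- var(nullSample)
    momentsSource <- "empirical"
  }
  ses <- if (isTRUE(nullVar > 0)) (obs - nullMean) / sqrt(nullVar)
         else if (obs == nullMean) 0 else Inf * sign(obs - nullMean)
  pA <- if (momentsSource == "analytic" || mode != "analytic") {
    if (is.finite(ses)) 2 * pnorm(-abs(ses)) else 1 / (1 + max(nNull, 999))
  } else NA_real_
  pE <- if (length(nullSample))
    (1 + sum(nullSample >= obs)) / (1 + length(nullSample))
  else NA_real_
  methods::new("NodfResult", nodf = obs_all, statistic = statistic,
               nullModel = model, nullMean = nullMean,
               nullVariance = nullVar, ses = ses,
               pAnalytic = if (mode == "empirical") NA_real_ else pA,
               pEmpirical = pE, nullSample = nullSample,
               momentsSource = momentsSource)
}

#' Nestedness across taxonomic levels
#'
#' Collapses the table at each requested level, prepares the presence
#' matrix and runs \code{\link{nodfTest}}; optionally within each
#' level-2 environment partition (samples restricted by \code{empo_2}).
#' Levels with fewer than 2 taxa are skipped with a notice.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param taxonomy taxonomy data.frame.
#' @param levels character vector from \code{"phylum"} ... \code{"genus"},
#'   \code{"tag"}.
#' @param metadata a \linkS4class{SampleMetadata} (needed when
#'   \code{partition}).
#' @param partition if \code{TRUE}, additionally run within each
#'   \code{empo_2} category.
#' @param ... passed to \code{\link{nodfTest}}.
#' @return data.frame with one row per (level, partition): NODF
#'   components, null moments, SES and p values.
#' @export
nestednessByLevel <- function(x, taxonomy,
                              levels = c("phylum", "class", "order",
                                         "family", "genus", "tag"),
                              metadata = NULL, partition = FALSE, ...) {
  parts <- list(all = sampleIds(x))
  if (partition) {
    if (is.null(metadata)) .stopf("partition requires metadata")
    e2 <- as.character(as.data.frame(metadata)[sampleIds(x), "empo_2"])
    for (lev in sort(unique(e2[!is.na(e2)])))
      parts[[lev]] <- sampleIds(x)[!is.na(e2) & e2 == lev]
  }
  rows <- list()
  for (pname in names(parts)) {
    samp <- parts[[pname]]
    if (length(samp) < 2) { message("partition '", pname, "': no samples"); next }
    xs <- x[, samp]
    for (lev in levels) {
      coll <- collapseByTaxonomy(xs, taxonomy, lev)
      if (nrow(coll) < 2) {
        message("level '", lev, "': fewer than 2 taxa, skipped")
        next
      }
      res <- nodfTest(preparePresence(coll), ...)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, partition = pname, n_taxa = nrow(coll),
        n_samples = length(samp),
        nodf_rows = res@nodf[["rows"]], nodf_cols = res@nodf[["cols"]],
        nodf_overall = res@nodf[["overall"]],
        statistic = res@statistic, null_mean = res@nullMean,
        null_variance = res@nullVariance, ses = res@ses,
        p_analytic = res@pAnalytic, p_empirical = res@pEmpirical,
        moments = res@momentsSource, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
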