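# Filtering, rarefaction and subsetting rules applied before every
# downstream analysis stage.

#' Drop low-count features
#'
#' Removes tag sequences whose grand total over all samples falls below
#' \code{minTotal}. The survey's convention keeps only tag sequences with at
#' least 25 reads total.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param minTotal minimum grand total (default 25).
#' @return filtered \linkS4class{ObservationTable}; surviving counts
#'   unchanged.
#' @export
filterFeaturesMinTotal <- function(x, minTotal = 25) {
  stopifnot(minTotal >= 1)
  x[featureTotals(x) >= minTotal, ]
}

#' Drop shallow samples
#'
#' Removes samples whose total observation count falls below
#' \code{minDepth}. Quality-control filtering uses 1,000 observations;
#' analysis subsets use 5,000.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param minDepth minimum per-sample total (default 1000).
#' @return filtered \linkS4class{ObservationTable}.
#' @export
qcFilterSamples <- function(x, minDepth = 1000) {
  stopifnot(minDepth >= 1)
  x[, sampleTotals(x) >= minDepth]
}

#' Rarefy to even depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth} observations (QIIME convention). Samples with fewer than
#' \code{depth} observations are dropped, never padded.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param depth target depth (default 5000).
#' @param seed integer seed; identical seeds give identical tables.
#' @return rarefied \linkS4class{ObservationTable}; every retained sample
#'   total equals \code{depth} and no count exceeds its input count.
#' @export
rarefy <- function(x, depth = 5000, seed = NULL) {
  if (depth <= 0) .stopf("depth must be positive")
  tot <- sampleTotals(x)
  x <- x[, tot >= depth]
  m <- as.matrix(counts(x))
  withSeed(seed, {
    for (j in seq_len(ncol(m))) {
      cj <- m[, j]
      if (sum(cj) == depth) next
      reads <- rep.int(seq_along(cj), cj)
      take <- sample(reads, depth, replace = FALSE)
      m[, j] <- tabulate(take, nbins = length(cj))
    }
  })
  ObservationTable(m)
}

#' Environment- and study-balanced sample subset
#'
#' Selects \code{n} samples with as-equal-as-possible representation across
#' level-3 environments (\code{empo_3}) and, within each environment, across
#' studies (\code{study_id}). Allocation is round-robin in lexicographic
#' category order, so remainders go to the earliest categories and the
#' max/min per-category allocation differs by at most 1 whenever capacity
#' allows; exhausted categories hand their surplus to the rest. Within a
#' study, samples are drawn uniformly without replacement under \code{seed}.
#'
#' @param metadata a \linkS4class{SampleMetadata}.
#' @param n number of samples requested.
#' @param seed integer seed.
#' @param eligible optional character vector restricting the candidate
#'   sample ids (e.g. samples passing a depth threshold).
#' @return character vector of selected sample ids.
#' @export
balancedSubset <- function(metadata, n, seed = NULL, eligible = NULL) {
  stopifnot(n >= 1)
  df <- as.data.frame(metadata)
  ids <- rownames(df)
  if (!is.null(eligible)) {
    keep <- ids %in% eligible
    df <- df[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (!nrow(df)) .stopf("no eligible samples")
  env <- as.character(df$empo_3)
  study <- as.character(df$study_id)
  if (n > length(ids)) {
    .warnf("requested %d samples but only %d available; returning all", n,
           length(ids))
    return(ids)
  }
  # per-study shuffled queues, built in lexicographic (env, study) order
  queues <- withSeed(seed, {
    q <- list()
    for (e in sort(unique(env))) {
      q[[e]] <- list()
      in_e <- env == e
      for (s in sort(unique(study[in_e]))) {
        pool <- ids[in_e & study == s]
        q[[e]][[s]] <- if (length(pool) > 1) sample(pool) else pool
      }
    }
    q
  })
  envs <- names(queues)
  study_ptr <- setNames(rep(1L, length(envs)), envs)  # round-robin cursor
  selected <- character(0)
  repeat {
    progressed <- FALSE
    for (e in envs) {
      if (length(selected) >= n) break
      studies <- names(queues[[e]])
      if (!length(studies)) next
      # advance this environment's study cursor to the next non-empty study
      taken <- FALSE
      for (k in seq_along(studies)) {
        s_i <- ((study_ptr[[e]] - 1L + k - 1L) %% length(studies)) + 1L
        s <- studies[s_i]
        if (length(queues[[e]][[s]])) {
          selected <- c(selected, queues[[e]][[s]][1])
          queues[[e]][[s]] <- queues[[e]][[s]][-1]
          study_ptr[[e]] <- (s_i %% length(studies)) + 1L
          taken <- TRUE
          progressed <- TRUE
          break
        }
      }
    }
    if (length(selected) >= n || !progressed) break
  }
  selected
}

#' Collapse features by taxonomy
#'
#' Sums counts over features sharing the full lineage prefix down to
#' \code{level}. Features unassigned at that level are pooled under an
#' explicit \code{"unassigned"} row, so the table grand total is conserved.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param taxonomy taxonomy data.frame (row names = feature ids).
#' @param level one of \code{"kingdom"} ... \code{"genus"}, or \code{"tag"}
#'   (identity).
#' @return collapsed \linkS4class{ObservationTable}; row names are
#'   \code{"; "}-joined lineage prefixes.
#' @export
collapseByTaxonomy <- function(x, taxonomy, level) {
  if (identical(level, "tag")) return(x)
  if (!level %in% taxonomyRanks) .stopf("unknown rank '%s'", level)
  k <- match(level, taxonomyRanks)
  fid <- featureIds(x)
  miss <- setdiff(fid, rownames(taxonomy))
  lin <- matrix("unassigned", length(fid), k)
  present <- fid %in% rownames(taxonomy)
  lin[present, ] <- as.matrix(taxonomy[fid[present], seq_len(k), drop = FALSE])
  label <- apply(lin, 1, paste, collapse = "; ")
  label[lin[, k] == "unassigned"] <- "unassigned"
  fac <- factor(label)
  ind <- Matrix::fac2sparse(fac)        # levels x features indicator
  m <- ind %*% counts(x)
  dimnames(m) <- list(levels(fac), sampleIds(x))
  ObservationTable(m)
}
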