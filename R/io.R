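# Readers and writers for the flat-file interchange formats: classic
# BIOM-style TSV observation tables, QIIME-style mapping files, taxonomy
# tables, newick trees, and square distance-matrix TSVs.

#' Read an observation table
#'
#' Reads a samples-by-tag-sequences count table. The primary on-disk format
#' is the classic BIOM TSV dialect: optional leading \code{#} comment lines,
#' then a header line starting with \code{#OTU ID} followed by sample
#' identifiers, then one row per feature. HDF5/JSON BIOM files are supported
#' through \pkg{biomformat} when that package is installed.
#'
#' @param path file path.
#' @param format \code{"classic_tsv"} (default) or \code{"biom"}.
#' @return an \linkS4class{ObservationTable}; counts round-trip through
#'   \code{\link{writeObservationTable}} exactly.
#' @export
readObservationTable <- function(path, format = c("classic_tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      .stopf("format 'biom' requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(ObservationTable(m))
  }
  lines <- readLines(path)
  if (!length(lines)) .stopf("empty file: %s", path)
  hdr_i <- which(!startsWith(lines, "#") |
                 startsWith(lines, "#OTU ID"))[1]
  if (is.na(hdr_i)) .stopf("no header line found in %s", path)
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    .stopf("line %d: duplicate sample identifier '%s'", hdr_i,
           samples[duplicated(samples)][1])
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  feats <- character(length(body))
  mat <- matrix(0, length(body), length(samples))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != length(header))
      .stopf("line %d: expected %d fields, found %d", hdr_i + i,
             length(header), length(parts))
    feats[i] <- parts[1]
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v))
      .stopf("line %d (feature '%s'): non-numeric count", hdr_i + i, parts[1])
    if (any(v < 0))
      .stopf("line %d (feature '%s'): negative count", hdr_i + i, parts[1])
    if (any(v != round(v)))
      .stopf("line %d (feature '%s'): non-integer count", hdr_i + i, parts[1])
    mat[i, ] <- v
  }
  if (anyDuplicated(feats))
    .stopf("duplicate feature identifier '%s'", feats[duplicated(feats)][1])
  dimnames(mat) <- list(feats, samples)
  ObservationTable(mat)
}

#' Write an observation table as classic BIOM TSV
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeObservationTable <- function(x, path) {
  m <- as.matrix(counts(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Build a SampleMetadata object from a data.frame
#'
#' Validates EMPO consistency (level 2 must be Saline/Non-saline under
#' Free-living and Animal/Plant under Host-associated) and covariate ranges
#' (pH in [0, 14], latitude in [-90, 90]); violations are recorded in
#' \code{\link{validationIssues}} and the samples retained.
#'
#' @param df data.frame with sample identifiers as row names (or in a
#'   \code{sample_id} column).
#' @return a \linkS4class{SampleMetadata}.
#' @export
SampleMetadata <- function(df) {
  if ("sample_id" %in% names(df) &&
      (is.null(rownames(df)) || identical(rownames(df), as.character(seq_len(nrow(df)))))) {
    rownames(df) <- df$sample_id
  }
  if (anyDuplicated(rownames(df)))
    .stopf("duplicate sample identifier '%s'",
           rownames(df)[duplicated(rownames(df))][1])
  issues <- data.frame(sample_id = character(), field = character(),
                       problem = character(), stringsAsFactors = FALSE)
  addIssue <- function(ids, field, problem) {
    if (length(ids))
      issues <<- rbind(issues, data.frame(sample_id = ids, field = field,
                                          problem = problem,
                                          stringsAsFactors = FALSE))
  }
  if (all(c("empo_1", "empo_2") %in% names(df))) {
    e1 <- as.character(df$empo_1); e2 <- as.character(df$empo_2)
    bad_fl <- !is.na(e1) & e1 == "Free-living" &
      !is.na(e2) & !e2 %in% c("Saline", "Non-saline")
    bad_ha <- !is.na(e1) & e1 == "Host-associated" &
      !is.na(e2) & !e2 %in% c("Animal", "Plant")
    rev_fl <- !is.na(e2) & e2 %in% c("Saline", "Non-saline") &
      !is.na(e1) & e1 != "Free-living"
    rev_ha <- !is.na(e2) & e2 %in% c("Animal", "Plant") &
      !is.na(e1) & e1 != "Host-associated"
    addIssue(rownames(df)[bad_fl | bad_ha | rev_fl | rev_ha], "empo_2",
             "empo_2 inconsistent with empo_1")
  }
  if ("ph" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$ph))
    addIssue(rownames(df)[!is.na(v) & (v < 0 | v > 14)], "ph",
             "pH outside [0, 14]")
  }
  if ("latitude_deg" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$latitude_deg))
    addIssue(rownames(df)[!is.na(v) & abs(v) > 90], "latitude_deg",
             "latitude outside [-90, 90]")
  }
  methods::new("SampleMetadata", S4Vectors::DataFrame(df, row.names = rownames(df)),
               issues = issues)
}

#' Read a QIIME-style mapping file
#'
#' Tab-separated, first column the sample identifier (conventionally
#' \code{#SampleID}). Missing-value tokens (\code{""}, \code{NA}, \code{na},
#' \code{not applicable}, \code{Unknown}) become \code{NA}; columns whose
#' remaining values all parse as numbers are converted to numeric.
#'
#' @param path file path.
#' @return a \linkS4class{SampleMetadata}; EMPO/range violations are
#'   reported via \code{\link{validationIssues}}, not dropped.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "",
                   stringsAsFactors = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  ids <- df[[1]]
  if (anyDuplicated(ids))
    .stopf("duplicate sample identifier '%s'", ids[duplicated(ids)][1])
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  for (j in seq_along(df)) {
    v <- df[[j]]
    v[v %in% .na_tokens] <- NA
    num <- suppressWarnings(as.numeric(v))
    nonNA <- !is.na(v)
    if (any(nonNA) && !anyNA(num[nonNA])) v <- num
    df[[j]] <- v
  }
  SampleMetadata(df)
}

#' Write sample metadata as a QIIME-style mapping file
#' @param x a \linkS4class{SampleMetadata}.
#' @param path output path.
#' @export
writeSampleMetadata <- function(x, path) {
  df <- as.data.frame(x)
  out <- cbind(`#SampleID` = rownames(df), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

taxonomyRanks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Accepts either a TSV with one column per rank
#' (\code{kingdom} ... \code{genus}) or a two-column TSV whose second column
#' is a semicolon-separated lineage. Missing ranks become
#' \code{"unassigned"}. Lineage prefix consistency (same genus implies same
#' family, and so on up) is checked; violations are reported as an
#' attribute \code{"issues"} and kept.
#'
#' @param path file path; first column is the feature identifier.
#' @return data.frame, row names = feature ids, columns = ranks.
#' @export
readTaxonomyMap <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "")
  names(df)[1] <- sub("^#", "", names(df)[1])
  ids <- df[[1]]
  if (anyDuplicated(ids))
    .stopf("duplicate feature identifier '%s'", ids[duplicated(ids)][1])
  if (ncol(df) == 2 && !names(df)[2] %in% taxonomyRanks) {
    parts <- strsplit(df[[2]], ";", fixed = TRUE)
    mat <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep("unassigned", 6))[1:6]
    }, character(6)))
  } else {
    mat <- matrix("unassigned", nrow(df), 6,
                  dimnames = list(NULL, taxonomyRanks))
    for (r in intersect(taxonomyRanks, names(df))) mat[, r] <- df[[r]]
  }
  mat[is.na(mat) | mat %in% .na_tokens] <- "unassigned"
  tax <- as.data.frame(mat, stringsAsFactors = FALSE)
  colnames(tax) <- taxonomyRanks
  rownames(tax) <- ids
  attr(tax, "issues") <- checkLineageConsistency(tax)
  tax
}

#' Check lineage prefix consistency of a taxonomy table
#'
#' Two features sharing a (assigned) label at some rank must share the whole
#' lineage above it.
#'
#' @param tax taxonomy data.frame as from \code{\link{readTaxonomyMap}}.
#' @return data.frame of violations (rank, label) — zero rows when clean.
#' @export
checkLineageConsistency <- function(tax) {
  bad <- data.frame(rank = character(), label = character(),
                    stringsAsFactors = FALSE)
  for (r in 2:length(taxonomyRanks)) {
    lab <- tax[[r]]
    keep <- lab != "unassigned"
    if (!any(keep)) next
    prefix <- do.call(paste, c(tax[keep, 1:(r - 1), drop = FALSE], sep = ";"))
    n_prefix <- tapply(prefix, lab[keep], function(p) length(unique(p)))
    viol <- names(n_prefix)[n_prefix > 1]
    if (length(viol))
      bad <- rbind(bad, data.frame(rank = taxonomyRanks[r], label = viol,
                                   stringsAsFactors = FALSE))
  }
  bad
}

#' Write a taxonomy table
#' @param tax taxonomy data.frame.
#' @param path output path.
#' @export
writeTaxonomyMap <- function(tax, path) {
  out <- cbind(`feature_id` = rownames(tax), tax)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree
#'
#' Thin validating wrapper around \code{\link[ape]{read.tree}}: requires a
#' rooted tree with unique tip labels; missing branch lengths are set to 0
#' with a warning.
#'
#' @param text newick string, or \code{NULL} to read from \code{path}.
#' @param path file path (used when \code{text} is \code{NULL}).
#' @return an \code{\link[ape]{ape}} \code{phylo} object.
#' @export
readTree <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text)
        else ape::read.tree(file = path)
  if (is.null(tr)) .stopf("could not parse newick input")
  if (anyDuplicated(tr$tip.label))
    .stopf("duplicate tip label '%s'",
           tr$tip.label[duplicated(tr$tip.label)][1])
  if (is.null(tr$edge.length)) {
    .warnf("tree has no branch lengths; treating all as 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    .warnf("missing branch lengths treated as 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (!ape::is.rooted(tr)) .stopf("tree must be rooted")
  tr
}

#' Total branch length of a tree
#' @param tree a \code{phylo}.
#' @export
totalBranchLength <- function(tree) sum(tree$edge.length)

#' Read / write a square distance matrix TSV
#'
#' Square matrix with matching row and column sample identifiers; validated
#' to be symmetric, finite, non-negative, zero-diagonal.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readDistanceMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  m <- as.matrix(df)
  validateDistanceMatrix(m)
  m
}

#' @rdname readDistanceMatrix
#' @param m distance matrix.
#' @export
writeDistanceMatrix <- function(m, path) {
  validateDistanceMatrix(m)
  out <- cbind(sample_id = rownames(m), as.data.frame(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readDistanceMatrix
#' @export
validateDistanceMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) .stopf("not a square matrix")
  if (!identical(rownames(m), colnames(m)))
    .stopf("row and column identifiers differ")
  if (any(!is.finite(m))) .stopf("non-finite distances")
  if (any(m < 0)) .stopf("negative distances")
  if (max(abs(m - t(m))) > 1e-8) .stopf("matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) .stopf("non-zero diagonal")
  invisible(TRUE)
}
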