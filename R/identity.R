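#' Pairwise identity between two aligned rows
#'
#' Identity is `100 * matches / comparable_columns`. Columns gapped in both
#' rows are excluded; under the default `gaps = "mismatch"` policy a gap
#' paired with a residue counts as a mismatch (BioEdit-style), under
#' `gaps = "exclude"` such columns are dropped from the comparison.
#' Ambiguity codes count as a mismatch unless the two symbols are
#' identical.
#'
#' @param aln A [SeqAlignment-class].
#' @param a,b Row identifiers (or indices).
#' @param gaps Gap policy, `"mismatch"` (default) or `"exclude"`.
#' @return Identity percentage in \[0, 100\]; an error if no column is
#'   comparable.
#' @export
pairwiseIdentity <- function(aln, a, b, gaps = c("mismatch", "exclude")) {
  gaps <- match.arg(gaps)
  mat <- alnMatrix(aln)
  x <- mat[a, ]; y <- mat[b, ]
  .identityVec(x, y, gaps)
}

.identityVec <- function(x, y, gaps) {
  both_gap <- x == .GAP & y == .GAP
  comparable <- !both_gap
  if (gaps == "exclude")
    comparable <- comparable & x != .GAP & y != .GAP
  n <- sum(comparable)
  if (n == 0)
    stop("no comparable columns between the two rows")
  100 * sum(x == y & comparable) / n
}

#' Full pairwise identity matrix
#'
#' @param aln A [SeqAlignment-class].
#' @param gaps Gap policy, see [pairwiseIdentity()].
#' @return Symmetric numeric matrix of identity percentages with a
#'   100-valued diagonal, labelled by accession.
#' @export
identityMatrix <- function(aln, gaps = c("mismatch", "exclude")) {
  gaps <- match.arg(gaps)
  mat <- alnMatrix(aln)
  n <- nrow(mat)
  ids <- rownames(mat)
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    xi <- mat[i, ]
    for (j in (i + 1):n) {
      v <- .identityVec(xi, mat[j, ], gaps)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Intra- and inter-group identity ranges and variability
#'
#' For every group (intra) and group pair (inter) at the requested metadata
#' level, reports the minimum and maximum pairwise identity over all cross
#' pairs - self pairs excluded for intra-group summaries - and the
#' variability percentage `100 - min_identity`. Singleton groups have no
#' intra-group pairs; they are kept with `NA` values and flagged.
#'
#' @param mat Identity matrix from [identityMatrix()].
#' @param st A [SampleTable-class] covering all matrix labels.
#' @param level `"species"`, `"family"` or `"cultivar"`.
#' @param include_references Keep records flagged `is_reference`?
#' @return `data.frame` with `group_a`, `group_b` (equal for intra),
#'   `min_identity`, `max_identity`, `variability`, `n_pairs`, `flagged`.
#' @export
groupSummary <- function(mat, st, level = "species",
                         include_references = TRUE) {
  meta <- sampleMeta(st)
  meta <- meta[match(rownames(mat), meta$accession), , drop = FALSE]
  if (anyNA(meta$accession))
    stop("matrix label(s) missing from the sample table")
  if (!include_references) {
    keep <- !meta$is_reference
    meta <- meta[keep, , drop = FALSE]
    mat <- mat[meta$accession, meta$accession, drop = FALSE]
  }
  groups <- split(meta$accession, meta[[level]])
  gnames <- names(groups)
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in i:length(groups)) {
      if (i == j) {
        ids <- groups[[i]]
        if (length(ids) < 2) {
          rows[[length(rows) + 1L]] <- data.frame(
            group_a = gnames[i], group_b = gnames[i],
            min_identity = NA_real_, max_identity = NA_real_,
            variability = NA_real_, n_pairs = 0L, flagged = TRUE,
            stringsAsFactors = FALSE)
          next
        }
        sub <- mat[ids, ids, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(mat[groups[[i]], groups[[j]], drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gnames[i], group_b = gnames[j],
        min_identity = min(vals), max_identity = max(vals),
        variability = 100 - min(vals), n_pairs = length(vals),
        flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an identity matrix as TSV (labels in first row and column)
#'
#' @param mat Identity matrix.
#' @param path Output path.
#' @param digits Decimals to print (1 matches the conventional reporting
#'   precision).
#' @return `path`, invisibly.
#' @export
writeIdentityMatrix <- function(mat, path, digits = 1) {
  out <- format(round(mat, digits), nsmall = digits, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
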