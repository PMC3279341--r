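# Clustal consensus residue groups: a column is 'conservative' when all its
# residues fall in one strong group, 'semi-conservative' for a weak group.
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")
.SYM_IDENTICAL <- "*"
.SYM_STRONG <- ":"
.SYM_WEAK <- "."
.SYM_NONE <- "•"

#' Shannon entropy of one alignment column
#'
#' \eqn{H = -\sum_s p_s \log_2 p_s} over the unambiguous non-gap symbols of
#' the column, with \eqn{p_s} their frequencies among those symbols. Gaps
#' and ambiguity codes carry no information about residue variability and
#' are excluded (Wu-Kabat convention).
#'
#' @param counts Named integer vector of symbol counts for one column
#'   (gap `-` and ambiguity codes may be present; they are ignored).
#' @param alphabet `"nucleotide"` or `"amino-acid"` (decides which symbols
#'   are ambiguous).
#' @return Entropy in bits; `NA` when no unambiguous residue is present.
#' @export
columnEntropy <- function(counts, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  counts <- .effectiveCounts(counts, alphabet)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  -sum(p * log2(p))
}

.effectiveCounts <- function(counts, alphabet) {
  drop <- c(.GAP, .ambiguousSymbols(alphabet))
  counts <- counts[!(names(counts) %in% drop)]
  counts[counts > 0]
}

#' Wu-Kabat variability index of one alignment column
#'
#' `viv = k / f_max`: the number of distinct residues at the position
#' divided by the frequency of the most common one (count of the modal
#' residue over the number of unambiguous non-gap symbols). A fully
#' conserved column has `viv = 1` at any depth; ties for the modal residue
#' do not change `f_max`.
#'
#' @inheritParams columnEntropy
#' @return The variability index; `NA` when no unambiguous residue present.
#' @export
columnViv <- function(counts, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  counts <- .effectiveCounts(counts, alphabet)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  k <- length(counts)
  f_max <- max(counts) / n
  k / f_max
}

.columnSymbol <- function(residues) {
  # residues: the column's symbols including gaps/ambiguity
  if (any(residues == .GAP)) return(.SYM_NONE)
  u <- unique(residues)
  if (length(u) == 1) return(.SYM_IDENTICAL)
  inGroup <- function(groups) {
    any(vapply(groups, function(g)
      all(u %in% strsplit(g, "")[[1]]), logical(1)))
  }
  if (inGroup(.STRONG_GROUPS)) return(.SYM_STRONG)
  if (inGroup(.WEAK_GROUPS)) return(.SYM_WEAK)
  .SYM_NONE
}

#' Clustal-style consensus symbols for a protein alignment
#'
#' `*` identical column, `:` all residues in one strong group, `.` all in
#' one weak group, bullet otherwise; any gap in the column forces the
#' non-conservative symbol.
#'
#' @param aln Amino-acid [SeqAlignment-class].
#' @return Character vector of per-column symbols.
#' @export
conservationSymbols <- function(aln) {
  stopifnot(alnAlphabet(aln) == "amino-acid")
  apply(alnMatrix(aln), 2, .columnSymbol)
}

#' Per-column profiles of an alignment
#'
#' Computes, for every column at positive anchored position, the symbol
#' counts, the effective depth (unambiguous non-gap symbols), Shannon
#' entropy in bits, the Wu-Kabat variability index, and - for protein
#' alignments - the Clustal consensus symbol. Columns that are more than
#' half gaps are retained but flagged `low_confidence`; columns with no
#' effective symbols get `NA` statistics and are excluded from plots and
#' polymorphism calls.
#'
#' @param aln A [SeqAlignment-class].
#' @param keep_upstream Keep columns left of the anchor (reported with
#'   non-positive positions)? Default drops them, matching position reports
#'   numbered from the start codon.
#' @return `data.frame` with columns `position`, `n_effective`, `n_gap`,
#'   `entropy_bits`, `viv`, `symbol` (NA for nucleotide alignments),
#'   `low_confidence`, plus attribute `counts` (list of per-column count
#'   tables).
#' @export
columnProfiles <- function(aln, keep_upstream = FALSE) {
  mat <- alnMatrix(aln)
  pos <- alnPositions(aln)
  keep <- if (keep_upstream) seq_along(pos) else which(pos >= 1L)
  alphabet <- alnAlphabet(aln)
  is_prot <- alphabet == "amino-acid"
  counts_list <- vector("list", length(keep))
  n_rows <- nrow(mat)
  out <- data.frame(position = pos[keep], n_effective = NA_integer_,
                    n_gap = NA_integer_, entropy_bits = NA_real_,
                    viv = NA_real_, symbol = NA_character_,
                    low_confidence = FALSE, stringsAsFactors = FALSE)
  for (idx in seq_along(keep)) {
    col <- mat[, keep[idx]]
    counts <- table(col)
    counts_list[[idx]] <- counts
    eff <- .effectiveCounts(counts, alphabet)
    n_gap <- sum(col == .GAP)
    out$n_effective[idx] <- sum(eff)
    out$n_gap[idx] <- n_gap
    out$entropy_bits[idx] <- columnEntropy(counts, alphabet)
    out$viv[idx] <- columnViv(counts, alphabet)
    if (is_prot) out$symbol[idx] <- .columnSymbol(col)
    out$low_confidence[idx] <- n_gap > n_rows / 2
  }
  attr(out, "counts") <- counts_list
  out
}

#' Call polymorphic positions (viv strictly above threshold)
#'
#' The comparison is strictly greater (`viv > 3`, not `>=`), so a position
#' at exactly the threshold is not called.
#'
#' @param profiles Output of [columnProfiles()] for one group's alignment.
#' @param threshold Variability index threshold (default 3).
#' @param group Optional label stored as an attribute.
#' @return `data.frame` with `position` and `viv` (ascending positions);
#'   attribute `threshold` and `group`.
#' @export
callPolymorphic <- function(profiles, threshold = 3, group = NA_character_) {
  keep <- !is.na(profiles$viv) & profiles$viv > threshold
  out <- profiles[keep, c("position", "viv")]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "group") <- group
  out
}

#' Per-species polymorphism report
#'
#' Splits the alignment by a metadata level, profiles each group's columns
#' and calls positions with `viv` above the threshold - the wide summary
#' mirrors a per-species polymorphic-position table.
#'
#' @param aln A [SeqAlignment-class] (protein for viv-based calls).
#' @param st A [SampleTable-class] covering the alignment rows.
#' @param level Grouping level: `"species"`, `"family"` or `"cultivar"`.
#' @param threshold viv threshold (strict).
#' @param include_references Keep records flagged `is_reference`?
#' @return Named list of [callPolymorphic()] data frames, one per group.
#' @export
polymorphismReport <- function(aln, st, level = "species", threshold = 3,
                               include_references = TRUE) {
  checkAlignmentSamples(aln, st)
  meta <- sampleMeta(st)
  meta <- meta[match(names(aln), meta$accession), , drop = FALSE]
  if (!include_references) meta <- meta[!meta$is_reference, , drop = FALSE]
  groups <- split(meta$accession, meta[[level]])
  lapply(groups, function(ids) {
    prof <- columnProfiles(subsetAlignment(aln, ids))
    callPolymorphic(prof, threshold = threshold)
  })
}

#' Substitution report over the kinase-interaction motif (KIM) window
#'
#' The profilin KIM domain spans anchored positions 78-98
#' (`IQGEAGAVIRGKKGSGGITIK` in the reference). Every residue of every row
#' that differs from the reference within the window is reported as a
#' position plus substitution; rows whose window is interrupted by a
#' deletion are flagged, not failed.
#'
#' @param aln Anchored amino-acid [SeqAlignment-class] covering the window.
#' @param reference Reference residues of the window.
#' @param ref_start Anchored position of the window's first residue.
#' @return List with `substitutions` (`row_id`, `position`, `ref_aa`,
#'   `observed_aa`) and `flagged_rows` (rows with a gap in the window).
#' @export
kimReport <- function(aln, reference = "IQGEAGAVIRGKKGSGGITIK",
                      ref_start = 78L) {
  stopifnot(alnAlphabet(aln) == "amino-acid")
  ref <- strsplit(reference, "")[[1]]
  want <- ref_start + seq_along(ref) - 1L
  cols <- match(want, alnPositions(aln))
  if (anyNA(cols))
    stop("alignment does not cover anchored positions ",
         min(want), "-", max(want))
  mat <- alnMatrix(aln)[, cols, drop = FALSE]
  flagged <- rownames(mat)[apply(mat == .GAP, 1, any)]
  out <- list()
  for (r in rownames(mat)) {
    diff <- which(mat[r, ] != ref & mat[r, ] != .GAP)
    if (length(diff))
      out[[length(out) + 1L]] <- data.frame(
        row_id = r, position = want[diff], ref_aa = ref[diff],
        observed_aa = mat[r, diff], stringsAsFactors = FALSE)
  }
  subs <- if (length(out)) do.call(rbind, out) else
    data.frame(row_id = character(), position = integer(),
               ref_aa = character(), observed_aa = character(),
               stringsAsFactors = FALSE)
  rownames(subs) <- NULL
  list(substitutions = subs, flagged_rows = flagged)
}

#' Write per-column profiles as TSV
#'
#' @param profiles Output of [columnProfiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
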