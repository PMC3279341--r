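.STOPS <- c("TAA", "TAG", "TGA")

# single-codon translation; ambiguity codes resolve to a residue only when
# every expansion agrees, otherwise X
.translateCodon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (!grepl("[^ACGT]", codon))
    return(unname(gc[codon]))
  expand <- strsplit(codon, "")[[1]]
  opts <- lapply(expand, function(b) if (b %in% .NT_SYMBOLS) b else .NT_SYMBOLS)
  combos <- do.call(paste0, expand.grid(opts, stringsAsFactors = FALSE))
  aa <- unique(unname(gc[combos]))
  if (length(aa) == 1) aa else "X"
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param seq Nucleotide string, length divisible by 3. Codons containing
#'   ambiguity codes translate to the unique residue when all expansions
#'   agree, otherwise to `X`.
#' @return Amino-acid string; a trailing stop codon is stripped. An internal
#'   stop is an error naming the codon position.
#' @export
translateCds <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0 || n %% 3 != 0)
    stop("sequence length ", n, " is not a positive multiple of 3")
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  aa <- vapply(codons, .translateCodon, character(1), USE.NAMES = FALSE)
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa)))
    stop("internal stop codon at codon position ", stops[stops < length(aa)][1])
  if (length(aa) && aa[length(aa)] == "*")
    aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Find open reading frames on the forward strand
#'
#' Scans all three forward frames for ATG..stop spans (these are
#' mRNA-derived cDNA clones, so the reverse strand is not searched).
#' Every ATG with a downstream in-frame stop is reported, including nested
#' starts; selection among them is left to [selectProfilinOrf()].
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length (aa, excluding the stop) to report.
#' @return `data.frame` with columns `start`, `end` (1-based nt positions of
#'   the A of ATG and the last base of the stop codon), `frame` (0/1/2) and
#'   `protein`, sorted longest protein first, ties broken by leftmost start.
#' @export
findOrfs <- function(seq, min_aa = 1) {
  stopifnot(min_aa >= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  res <- list()
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  starts <- starts[starts > 0]
  for (s in starts) {
    i <- s + 3
    while (i + 2 <= n) {
      codon <- paste(chars[i:(i + 2)], collapse = "")
      if (codon %in% .STOPS) {
        aa_len <- (i - s) / 3
        if (aa_len >= min_aa) {
          res[[length(res) + 1]] <- data.frame(
            start = s, end = i + 2, frame = (s - 1) %% 3,
            protein = translateCds(substr(seq, s, i + 2)),
            stringsAsFactors = FALSE)
        }
        break
      }
      i <- i + 3
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(-nchar(out$protein), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the profilin ORF among ORF calls
#'
#' Profilin products run 125-140 aa; among the calls whose protein length
#' falls in that window, the longest is chosen, ties broken by leftmost
#' start. The chosen ORF's ATG is the coordinate anchor for position
#' reports.
#'
#' @param orfs `data.frame` from [findOrfs()].
#' @param window Allowed protein length range in aa.
#' @return Single-row `data.frame` (the chosen ORF).
#' @export
selectProfilinOrf <- function(orfs, window = c(125, 140)) {
  stopifnot(nrow(orfs) > 0)
  len <- nchar(orfs$protein)
  cand <- orfs[len >= window[1] & len <= window[2], , drop = FALSE]
  if (!nrow(cand))
    stop("no ORF with protein length in [", window[1], ", ", window[2], "] aa")
  cand <- cand[order(-nchar(cand$protein), cand$start), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Annotate deletions (gap runs) in an alignment
#'
#' Reports every maximal run of `-` per row, with its anchored start
#' position, length and whether it is in frame (length divisible by 3).
#' Annotation is purely alignment-based; no realignment is attempted.
#'
#' @param aln Nucleotide [SeqAlignment-class].
#' @param reference_id Optional reference row; its own gap runs (insertions
#'   in other rows) are skipped for the remaining rows' reports and the row
#'   itself is excluded.
#' @return `data.frame` with `row_id`, `start_col`, `position` (anchored),
#'   `length`, `in_frame`.
#' @export
annotateDeletions <- function(aln, reference_id = NULL) {
  mat <- alnMatrix(aln)
  rows <- rownames(mat)
  keep_cols <- rep(TRUE, ncol(mat))
  if (!is.null(reference_id)) {
    stopifnot(reference_id %in% rows)
    keep_cols <- mat[reference_id, ] != .GAP
    rows <- setdiff(rows, reference_id)
  }
  pos <- alnPositions(aln)
  out <- list()
  for (r in rows) {
    isgap <- mat[r, ] == .GAP & keep_cols
    rl <- rle(isgap)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    g <- which(rl$values)
    for (k in g) {
      out[[length(out) + 1]] <- data.frame(
        row_id = r, start_col = starts[k], position = pos[starts[k]],
        length = rl$lengths[k], in_frame = rl$lengths[k] %% 3 == 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(row_id = character(), start_col = integer(),
                      position = integer(), length = integer(),
                      in_frame = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sequence ORF report
#'
#' Convenience wrapper running [findOrfs()] + [selectProfilinOrf()] over a
#' sample table, the shape of the pipeline's ORF stage output.
#'
#' @param st A [SampleTable-class] of nucleotide sequences.
#' @param min_aa Passed to [findOrfs()].
#' @return `data.frame` with `accession`, `orf_start`, `orf_end`,
#'   `protein_length`, `protein`.
#' @export
orfTable <- function(st, min_aa = 30) {
  seqs <- as.character(sampleSeqs(st))
  rows <- lapply(names(seqs), function(id) {
    orf <- selectProfilinOrf(findOrfs(seqs[[id]], min_aa = min_aa))
    data.frame(accession = id, orf_start = orf$start, orf_end = orf$end,
               protein_length = nchar(orf$protein), protein = orf$protein,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
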