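#' @import methods
#' @importClassesFrom Biostrings XStringSet
#' @importFrom stats sd var aggregate setNames
#' @importFrom utils read.delim write.table head
NULL

.NT_SYMBOLS <- c("A", "C", "G", "T")
.NT_AMBIG <- "N"
.AA_SYMBOLS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_AMBIG <- c("X", "B", "Z", "J", "U", "O", "*")
.GAP <- "-"

.alphabetSymbols <- function(alphabet, gapped = FALSE) {
  sym <- switch(alphabet,
                nucleotide  = c(.NT_SYMBOLS, .NT_AMBIG),
                `amino-acid` = c(.AA_SYMBOLS, .AA_AMBIG),
                stop("unknown alphabet: ", alphabet))
  if (gapped) sym <- c(sym, .GAP)
  sym
}

.ambiguousSymbols <- function(alphabet) {
  switch(alphabet, nucleotide = .NT_AMBIG, `amino-acid` = .AA_AMBIG)
}

#' SampleTable: sequences bound to their grouping metadata
#'
#' Couples a set of coding (or protein) sequences with the sample table that
#' assigns each accession to a family, species, cultivar and clone. The
#' grouping hierarchy is family > species > cultivar > clone; cultivar and
#' clone labels may be empty for species without named cultivars. Reference
#' entries (previously deposited database sequences) are distinguished by the
#' logical `is_reference` column so every statistic can be run with or
#' without them.
#'
#' @slot seqs An [Biostrings::XStringSet] of sequences named by accession.
#' @slot meta A `data.frame` with columns `accession`, `family`, `species`,
#'   `cultivar`, `clone`, `is_reference`, one row per sequence.
#' @exportClass SampleTable
setClass("SampleTable",
         representation(seqs = "XStringSet", meta = "data.frame"))

setValidity("SampleTable", function(object) {
  m <- object@meta
  need <- c("accession", "family", "species", "cultivar", "clone",
            "is_reference")
  if (!all(need %in% names(m)))
    return(paste("metadata must contain columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (anyDuplicated(m$accession))
    return(paste("duplicated accession(s):",
                 paste(unique(m$accession[duplicated(m$accession)]),
                       collapse = ", ")))
  ids <- names(object@seqs)
  if (is.null(ids) && length(object@seqs) > 0)
    return("sequences must be named by accession")
  missing_meta <- setdiff(ids, m$accession)
  if (length(missing_meta))
    return(paste("accession(s) present in sequences but absent from table:",
                 paste(missing_meta, collapse = ", ")))
  if (any(!nzchar(m$species)) || any(!nzchar(m$family)))
    return("every record must resolve to a non-empty species and family")
  TRUE
})

#' Construct a SampleTable
#'
#' @param seqs Named [Biostrings::XStringSet] (or named character vector,
#'   which is converted), names are accessions.
#' @param meta Metadata `data.frame`; missing `cultivar`/`clone`/
#'   `is_reference` columns are filled with defaults.
#' @return A [SampleTable-class] object.
#' @export
SampleTable <- function(seqs, meta) {
  if (is.character(seqs))
    seqs <- Biostrings::BStringSet(seqs)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$cultivar)) meta$cultivar <- ""
  if (is.null(meta$clone)) meta$clone <- ""
  if (is.null(meta$is_reference)) meta$is_reference <- FALSE
  meta$cultivar[is.na(meta$cultivar)] <- ""
  meta$clone[is.na(meta$clone)] <- ""
  # keep metadata in sequence order where possible
  if (length(seqs) && all(names(seqs) %in% meta$accession))
    meta <- meta[match(names(seqs), meta$accession), , drop = FALSE]
  rownames(meta) <- NULL
  new("SampleTable", seqs = seqs, meta = meta)
}

#' @describeIn SampleTable number of records
#' @param x,object A `SampleTable`.
#' @export
setMethod("length", "SampleTable", function(x) length(x@seqs))

#' @describeIn SampleTable accession identifiers
#' @export
setMethod("names", "SampleTable", function(x) names(x@seqs))

#' Accessors for SampleTable
#'
#' `sampleSeqs()` returns the sequence set, `sampleMeta()` the metadata
#' table, and `accessions()` the accession identifiers.
#' @param x A [SampleTable-class].
#' @return The corresponding slot content.
#' @export
sampleSeqs <- function(x) x@seqs

#' @rdname sampleSeqs
#' @export
sampleMeta <- function(x) x@meta

#' @rdname sampleSeqs
#' @export
accessions <- function(x) names(x@seqs)

#' Subset a SampleTable by accession or predicate on metadata
#'
#' @param x A [SampleTable-class].
#' @param keep Character vector of accessions or logical vector along records.
#' @return A new `SampleTable` restricted to `keep`.
#' @export
subsetSamples <- function(x, keep) {
  if (is.logical(keep)) keep <- accessions(x)[keep]
  stopifnot(all(keep %in% accessions(x)))
  SampleTable(x@seqs[keep], x@meta[match(keep, x@meta$accession), ,
                                   drop = FALSE])
}

setMethod("show", "SampleTable", function(object) {
  m <- object@meta
  cat("SampleTable with", length(object), "records\n")
  if (nrow(m)) {
    cat("  families:", paste(unique(m$family), collapse = ", "), "\n")
    sp <- table(m$species)
    cat("  species: ",
        paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n",
        sep = "")
    cat("  reference entries:", sum(m$is_reference), "\n")
  }
})

#' SeqAlignment: a gapped sequence matrix with anchored coordinates
#'
#' Stores a multiple alignment as a character matrix (rows are sequences,
#' columns are alignment positions) together with its alphabet and an anchor
#' column. Position numbering is 1-based from the anchor: reported position
#' `p` of column `j` is `j - anchor + 1`, so columns left of the anchor get
#' non-positive indices and are excluded from position reports. For profilin
#' coding sequences the anchor is the A of the start codon of the profilin
#' ORF (the "ORF2" start in the source alignments).
#'
#' @slot mat Character matrix with `rownames` = accessions; the only gap
#'   character accepted is `-`.
#' @slot alphabet `"nucleotide"` or `"amino-acid"`.
#' @slot anchor Integer column index of position 1.
#' @exportClass SeqAlignment
setClass("SeqAlignment",
         representation(mat = "matrix", alphabet = "character",
                        anchor = "integer"))

setValidity("SeqAlignment", function(object) {
  if (!object@alphabet %in% c("nucleotide", "amino-acid"))
    return("alphabet must be 'nucleotide' or 'amino-acid'")
  m <- object@mat
  if (nrow(m) && is.null(rownames(m)))
    return("alignment rows must be named by accession")
  if (anyDuplicated(rownames(m)))
    return("duplicated row identifiers")
  ok <- .alphabetSymbols(object@alphabet, gapped = TRUE)
  bad <- setdiff(unique(as.vector(m)), ok)
  if (length(bad))
    return(paste("illegal symbol(s) for", object@alphabet, "alignment:",
                 paste(bad, collapse = " ")))
  if (ncol(m) > 0 &&
      (object@anchor < 1L || object@anchor > ncol(m)))
    return("anchor must lie within [1, width]")
  TRUE
})

#' Construct a SeqAlignment
#'
#' @param seqs Named character vector of equal-length gapped sequences, a
#'   named [Biostrings::XStringSet], or a character matrix.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param anchor Integer column of position 1 (default 1).
#' @return A [SeqAlignment-class].
#' @export
SeqAlignment <- function(seqs, alphabet = c("nucleotide", "amino-acid"),
                         anchor = 1L) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (!is.character(seqs)) seqs <- as.character(seqs)
    if (length(unique(nchar(seqs))) > 1)
      stop("alignment rows differ in length: ",
           paste(range(nchar(seqs)), collapse = " vs "))
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  new("SeqAlignment", mat = mat, alphabet = alphabet,
      anchor = as.integer(anchor))
}

#' Accessors for SeqAlignment
#'
#' @param x A [SeqAlignment-class].
#' @return `alnMatrix()` the character matrix; `alnWidth()` the number of
#'   columns; `alnAlphabet()` the alphabet; `anchorOffset()` the anchor
#'   column; `alnPositions()` the anchored 1-based position of every column;
#'   `alnStrings()` the rows pasted back to strings.
#' @export
alnMatrix <- function(x) x@mat

#' @rdname alnMatrix
#' @export
alnWidth <- function(x) ncol(x@mat)

#' @rdname alnMatrix
#' @export
alnAlphabet <- function(x) x@alphabet

#' @rdname alnMatrix
#' @export
anchorOffset <- function(x) x@anchor

#' @rdname alnMatrix
#' @export
alnPositions <- function(x) seq_len(ncol(x@mat)) - x@anchor + 1L

#' @rdname alnMatrix
#' @export
alnStrings <- function(x) {
  setNames(apply(x@mat, 1, paste, collapse = ""), rownames(x@mat))
}

#' @describeIn SeqAlignment number of rows
#' @param x,object A `SeqAlignment`.
#' @export
setMethod("length", "SeqAlignment", function(x) nrow(x@mat))

#' @describeIn SeqAlignment row identifiers
#' @export
setMethod("names", "SeqAlignment", function(x) rownames(x@mat))

setMethod("show", "SeqAlignment", function(object) {
  cat("SeqAlignment (", object@alphabet, "): ", nrow(object@mat),
      " rows x ", ncol(object@mat), " columns, anchor at column ",
      object@anchor, "\n", sep = "")
})

#' Subset alignment rows
#'
#' @param x A [SeqAlignment-class].
#' @param ids Accessions (or logical along rows) to keep.
#' @return A `SeqAlignment` with the selected rows, same anchor.
#' @export
subsetAlignment <- function(x, ids) {
  if (is.logical(ids)) ids <- rownames(x@mat)[ids]
  stopifnot(all(ids %in% rownames(x@mat)))
  new("SeqAlignment", mat = x@mat[ids, , drop = FALSE],
      alphabet = x@alphabet, anchor = x@anchor)
}
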