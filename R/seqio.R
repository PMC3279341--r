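#' Read a FASTA file with strict alphabet checking
#'
#' Sequences are uppercased on input. Gap characters (`-`) are legal only
#' when `aligned = TRUE`; the dot gap dialect is always rejected. Illegal
#' symbols are reported with the record id and the 1-based offset of the
#' first offending character, duplicated ids with the id.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` (A/C/G/T/N) or `"amino-acid"` (20 residues
#'   plus ambiguity codes).
#' @param aligned Logical; declare the file as an alignment (equal lengths
#'   enforced, gaps permitted).
#' @return A named [Biostrings::XStringSet] (`DNAStringSet` or
#'   `AAStringSet`); for aligned input the gapped set.
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "amino-acid"),
                      aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  ok <- .alphabetSymbols(alphabet, gapped = aligned)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad)) {
      if (chars[bad[1]] == ".")
        stop("'.' found in record '", ids[i], "' at offset ", bad[1],
             "; only '-' is accepted as gap")
      stop("illegal symbol '", chars[bad[1]], "' in record '", ids[i],
           "' at offset ", bad[1])
    }
    if (!length(chars))
      stop("empty sequence in record '", ids[i], "'")
  }
  if (aligned && length(seqs) > 1 && length(unique(nchar(seqs))) > 1)
    stop("file declared aligned but records have unequal lengths: ",
         paste(range(nchar(seqs)), collapse = " vs "))
  if (alphabet == "nucleotide" && !aligned)
    Biostrings::DNAStringSet(seqs)
  else if (alphabet == "amino-acid" && !aligned)
    Biostrings::AAStringSet(seqs)
  else
    Biostrings::BStringSet(seqs)
}

#' Write sequences as canonical FASTA
#'
#' 60-column wrap, LF line endings, no description text: `writeFasta()`
#' followed by [readFasta()] reproduces ids, order and residues exactly, and
#' re-writing reproduces the file byte for byte.
#'
#' @param seqs Named character vector or [Biostrings::XStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is.character(seqs)) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    if (!endsWith(body, "\n")) body <- paste0(body, "\n")
    writeLines(c(paste0(">", names(seqs)[i]), sub("\n$", "", body)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read the sample metadata table and join it to sequences
#'
#' The TSV must carry columns `accession`, `family`, `species`, `cultivar`
#' and `clone` (the latter two may be empty, e.g. for species without named
#' cultivars); an optional logical `is_reference` column marks previously
#' deposited database entries. The join key is the accession,
#' case-sensitively. Any sequence whose accession is missing from the table
#' is an error; table rows without a sequence are dropped with a warning.
#'
#' @param path Path to the TSV metadata file (header required).
#' @param seqs Optional named sequence set to join against.
#' @return If `seqs` is supplied, a [SampleTable-class]; otherwise the
#'   metadata `data.frame`.
#' @export
readMetadata <- function(path, seqs = NULL) {
  stopifnot(file.exists(path))
  meta <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = NULL)
  if (nrow(meta) == 0)
    warning("empty metadata table: ", path)
  need <- c("accession", "family", "species", "cultivar", "clone")
  if (!all(need %in% names(meta)))
    stop("metadata is missing column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  meta$is_reference <- if ("is_reference" %in% names(meta))
    meta$is_reference %in% c("TRUE", "true", "1", "yes")
  else rep(FALSE, nrow(meta))
  if (is.null(seqs))
    return(meta)
  ids <- names(seqs)
  absent <- setdiff(ids, meta$accession)
  if (length(absent))
    stop("accession(s) present in FASTA but absent from metadata: ",
         paste(absent, collapse = ", "))
  unmatched <- setdiff(meta$accession, ids)
  if (length(unmatched))
    warning("metadata row(s) without a sequence dropped: ",
            paste(unmatched, collapse = ", "))
  SampleTable(seqs, meta[meta$accession %in% ids, , drop = FALSE])
}

#' Write a sample metadata table
#'
#' @param meta A metadata `data.frame` or [SampleTable-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(meta, path) {
  if (is(meta, "SampleTable")) meta <- sampleMeta(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Clustal dialect: "CLUSTAL" header line, then interleaved blocks of
# "name  chunk" lines, optionally followed by a consensus line (starts with
# whitespace) and trailing residue counts. Parsed here directly: the
# interleaved layout is accumulated per name, block by block.
.readClustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1]))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  lines <- lines[-1]
  keep <- nzchar(lines) & !grepl("^\\s", lines)
  lines <- lines[keep]
  out <- list()
  order_seen <- character(0)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2)
      stop("malformed Clustal line: '", ln, "'")
    nm <- parts[1]
    chunk <- parts[2]
    if (!nm %in% order_seen) order_seen <- c(order_seen, nm)
    out[[nm]] <- paste0(if (is.null(out[[nm]])) "" else out[[nm]], chunk)
  }
  seqs <- toupper(unlist(out[order_seen]))
  if (length(unique(nchar(seqs))) > 1)
    stop("Clustal rows have unequal lengths after assembly")
  seqs
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' Only `-` is accepted as the gap character; a `.` anywhere in a sequence
#' is an error, so Clustal dialects that use dots for identity or gaps are
#' rejected rather than silently misread. The anchor defaults to column 1
#' until [setAnchor()] is called.
#'
#' @param path Alignment file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param format `"fasta"` or `"clustal"`; default guessed from the first
#'   line (`>` means FASTA).
#' @return A [SeqAlignment-class] with `anchor = 1`.
#' @export
readAlignment <- function(path, alphabet = c("nucleotide", "amino-acid"),
                          format = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  if (is.null(format)) {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  seqs <- if (format == "fasta") {
    as.character(readFasta(path, alphabet, aligned = TRUE))
  } else {
    s <- .readClustal(path)
    if (any(grepl(".", s, fixed = TRUE)))
      stop("'.' found in alignment; only '-' is accepted as gap")
    ok <- .alphabetSymbols(alphabet, gapped = TRUE)
    bad <- setdiff(unique(unlist(strsplit(s, ""))), ok)
    if (length(bad))
      stop("illegal symbol(s) for ", alphabet, " alignment: ",
           paste(bad, collapse = " "))
    s
  }
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("'.' found in alignment; only '-' is accepted as gap")
  SeqAlignment(seqs, alphabet = alphabet, anchor = 1L)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A [SeqAlignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  writeFasta(alnStrings(aln), path)
}

#' Anchor alignment coordinates at a motif of a reference row
#'
#' Sets position 1 of the alignment to the column holding the first symbol
#' of `motif` in the ungapped reference row (for coding alignments the `ATG`
#' of the selected ORF; for proteins the initiator `M`). Gaps in the
#' reference row are skipped when mapping the motif back to columns.
#'
#' @param aln A [SeqAlignment-class].
#' @param reference_id Row to anchor on.
#' @param motif Ungapped motif; default `"ATG"` for nucleotide alignments,
#'   `"M"` for amino-acid alignments.
#' @return The alignment with its anchor updated.
#' @export
setAnchor <- function(aln, reference_id, motif = NULL) {
  stopifnot(is(aln, "SeqAlignment"))
  if (!reference_id %in% names(aln))
    stop("reference id not in alignment: ", reference_id)
  if (is.null(motif))
    motif <- if (alnAlphabet(aln) == "nucleotide") "ATG" else "M"
  row <- aln@mat[reference_id, ]
  resid_cols <- which(row != .GAP)
  ungapped <- paste(row[resid_cols], collapse = "")
  hit <- regexpr(motif, ungapped, fixed = TRUE)
  if (hit < 0)
    stop("motif '", motif, "' not found in ungapped reference row '",
         reference_id, "'")
  new("SeqAlignment", mat = aln@mat, alphabet = aln@alphabet,
      anchor = as.integer(resid_cols[hit]))
}

#' Check that every alignment row has a metadata record
#'
#' Run before any grouped analysis: verifies that each alignment row maps to
#' exactly one record of the sample table.
#'
#' @param aln A [SeqAlignment-class].
#' @param st A [SampleTable-class].
#' @return Invisibly `TRUE`; error otherwise.
#' @export
checkAlignmentSamples <- function(aln, st) {
  absent <- setdiff(names(aln), accessions(st))
  if (length(absent))
    stop("alignment row(s) without metadata: ",
         paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Translate a codon-aligned nucleotide alignment to proteins
#'
#' Requires the alignment width to be a multiple of 3 downstream of the
#' anchor and gaps to come in whole codons (the shape emitted by
#' [truthAlignment()] and by codon-aware aligners). Columns left of the
#' anchor are dropped; the resulting amino-acid alignment is anchored at the
#' initiator methionine (position 1). A trailing stop codon is trimmed.
#'
#' @param aln Nucleotide [SeqAlignment-class], anchored at the start codon.
#' @return Amino-acid [SeqAlignment-class].
#' @export
alnTranslate <- function(aln) {
  stopifnot(alnAlphabet(aln) == "nucleotide")
  mat <- aln@mat[, aln@anchor:ncol(aln@mat), drop = FALSE]
  w <- ncol(mat) - ncol(mat) %% 3L
  mat <- mat[, seq_len(w), drop = FALSE]
  n_codons <- w %/% 3L
  prot <- vapply(seq_len(nrow(mat)), function(i) {
    codons <- vapply(seq_len(n_codons), function(j)
      paste(mat[i, (3 * j - 2):(3 * j)], collapse = ""), character(1))
    aa <- vapply(codons, function(cd) {
      if (cd == "---") return("-")
      if (grepl("-", cd, fixed = TRUE))
        stop("gap not codon-aligned in row '", rownames(mat)[i], "'")
      .translateCodon(cd)
    }, character(1))
    paste(aa, collapse = "")
  }, character(1))
  names(prot) <- rownames(mat)
  # trim a trailing stop shared by all rows
  prot <- sub("\\*$", "-", prot)
  if (all(substring(prot, nchar(prot)) == "-") &&
      all(!grepl("*", prot, fixed = TRUE)))
    prot <- substring(prot, 1, nchar(prot) - 1)
  if (any(grepl("*", prot, fixed = TRUE)))
    stop("internal stop codon after translation of aligned rows: ",
         paste(names(prot)[grepl("*", prot, fixed = TRUE)], collapse = ", "))
  SeqAlignment(prot, alphabet = "amino-acid", anchor = 1L)
}
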