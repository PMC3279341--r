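# ---------------------------------------------------------------------------
# PROSITE-syntax pattern engine.
#
# Supported syntax: elements separated by '-'; an element is a residue
# letter, 'x' (any), '[SET]' or '{NEGATED SET}', optionally repeated with
# '(n)' or '(n,m)'; '<' anchors the match to the N-terminus, '>' to the
# C-terminus; an optional trailing '.' closes the pattern. Variable-length
# repetitions are expanded shortest-first when scanning.
# ---------------------------------------------------------------------------

#' Parse a PROSITE-syntax pattern
#'
#' @param text Pattern string, e.g. `"N-{P}-[ST]-{P}"`.
#' @param id,name Optional identifier and human-readable name.
#' @return A `PrositePattern` object (list with `elements`, `nterm`,
#'   `cterm`, `id`, `name`); printing it reproduces the canonical form.
#' @export
parsePrositePattern <- function(text, id = NA_character_,
                                name = NA_character_) {
  raw <- text
  text <- sub("\\.$", "", trimws(text))
  nterm <- startsWith(text, "<")
  if (nterm) text <- substring(text, 2)
  cterm <- endsWith(text, ">")
  if (cterm) text <- substring(text, 1, nchar(text) - 1)
  if (!nzchar(text))
    stop("empty pattern: '", raw, "'")
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  offset <- if (nterm) 1L else 0L
  elements <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    el <- parts[i]
    if (!nzchar(el))
      stop("syntax error in '", raw, "': empty element at offset ",
           offset + 1)
    rep_min <- 1L; rep_max <- 1L
    rep_m <- regexpr("\\((\\d+)(,(\\d+))?\\)$", el)
    if (rep_m > 0) {
      rep_txt <- substring(el, rep_m + 1, nchar(el) - 1)
      nums <- as.integer(strsplit(rep_txt, ",", fixed = TRUE)[[1]])
      rep_min <- nums[1]
      rep_max <- if (length(nums) == 2) nums[2] else nums[1]
      if (is.na(rep_min) || is.na(rep_max) || rep_min > rep_max ||
          rep_min < 0)
        stop("syntax error in '", raw, "': bad repetition '", rep_txt,
             "' at offset ", offset + rep_m)
      el <- substring(el, 1, rep_m - 1)
    }
    base <- NULL
    if (el == "x") {
      base <- list(type = "any", chars = "")
    } else if (grepl("^\\[[A-Z]+\\]$", el)) {
      base <- list(type = "set",
                   chars = substring(el, 2, nchar(el) - 1))
    } else if (grepl("^\\{[A-Z]+\\}$", el)) {
      base <- list(type = "negset",
                   chars = substring(el, 2, nchar(el) - 1))
    } else if (grepl("^[A-Z]$", el)) {
      base <- list(type = "residue", chars = el)
    } else {
      stop("syntax error in '", raw, "': cannot parse element '", el,
           "' at offset ", offset + 1)
    }
    base$min <- rep_min
    base$max <- rep_max
    elements[[i]] <- base
    offset <- offset + nchar(parts[i]) + 1L
  }
  structure(list(id = id, name = name, elements = elements,
                 nterm = nterm, cterm = cterm),
            class = "PrositePattern")
}

#' @export
format.PrositePattern <- function(x, ...) {
  el_txt <- vapply(x$elements, function(e) {
    base <- switch(e$type, any = "x", residue = e$chars,
                   set = paste0("[", e$chars, "]"),
                   negset = paste0("{", e$chars, "}"))
    if (e$min == 1 && e$max == 1) base
    else if (e$min == e$max) paste0(base, "(", e$min, ")")
    else paste0(base, "(", e$min, ",", e$max, ")")
  }, character(1))
  paste0(if (x$nterm) "<" else "", paste(el_txt, collapse = "-"),
         if (x$cterm) ">" else "", ".")
}

#' @export
print.PrositePattern <- function(x, ...) {
  cat("PrositePattern", if (!is.na(x$id)) x$id else "", format(x), "\n")
  invisible(x)
}

# lazy-quantifier PCRE equivalent; matching anchored at a start position
# then yields the shortest-first expansion of variable elements
.prositeRegex <- function(pat) {
  el_re <- vapply(pat$elements, function(e) {
    base <- switch(e$type, any = ".", residue = e$chars,
                   set = paste0("[", e$chars, "]"),
                   negset = paste0("[^", e$chars, "]"))
    if (e$min == 1 && e$max == 1) base
    else if (e$min == e$max) paste0(base, "{", e$min, "}")
    else paste0(base, "{", e$min, ",", e$max, "}?")
  }, character(1))
  paste0("^", paste(el_re, collapse = ""), if (pat$cterm) "$" else "")
}

#' Scan a protein with a PROSITE pattern
#'
#' Every start position is tried, so overlapping hits are reported
#' (ScanProsite behaviour); at each start the shortest expansion of
#' variable-length elements is taken. Set `non_overlapping = TRUE` to skip
#' starts inside the previous hit.
#'
#' @param protein Amino-acid string (anchored: position 1 is the
#'   initiator).
#' @param pattern A `PrositePattern` or pattern string.
#' @param non_overlapping Suppress hits starting inside an earlier hit?
#' @return `data.frame` with `start`, `end` (1-based inclusive), `matched`.
#' @export
scanProsite <- function(protein, pattern, non_overlapping = FALSE) {
  if (is.character(pattern)) pattern <- parsePrositePattern(pattern)
  protein <- toupper(protein)
  L <- nchar(protein)
  re <- .prositeRegex(pattern)
  starts <- if (pattern$nterm) 1L else seq_len(L)
  out <- list()
  last_end <- 0L
  for (s in starts) {
    if (s > L) break
    if (non_overlapping && s <= last_end) next
    m <- regexpr(re, substring(protein, s), perl = TRUE)
    if (m > 0) {
      len <- attr(m, "match.length")
      if (len > 0) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + len - 1L,
          matched = substring(protein, s, s + len - 1L),
          stringsAsFactors = FALSE)
        last_end <- s + len - 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The packaged post-translational modification motif panel
#'
#' Reads `inst/extdata/motif_panel.tsv`: the classical PROSITE patterns for
#' N-glycosylation, protein kinase C and casein kinase II phosphorylation,
#' tyrosine kinase phosphorylation, N-myristoylation, amidation and the
#' microbody C-terminal targeting signal.
#'
#' @return `data.frame` with columns `id`, `name`, `pattern`.
#' @export
defaultMotifPanel <- function() {
  path <- system.file("extdata", "motif_panel.tsv", package = "profvar",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Scan a set of proteins against a motif panel
#'
#' @param proteins Named character vector of anchored protein sequences.
#' @param panel `data.frame` with `id`, `name`, `pattern` columns (default
#'   [defaultMotifPanel()]).
#' @param non_overlapping Passed to [scanProsite()].
#' @return `data.frame` with `accession`, `id`, `name`, `start`, `end`,
#'   `matched`.
#' @export
motifPanel <- function(proteins, panel = defaultMotifPanel(),
                       non_overlapping = FALSE) {
  stopifnot(!is.null(names(proteins)))
  compiled <- lapply(seq_len(nrow(panel)), function(i)
    parsePrositePattern(panel$pattern[i], id = panel$id[i],
                        name = panel$name[i]))
  out <- list()
  for (acc in names(proteins)) {
    for (p in compiled) {
      hits <- scanProsite(proteins[[acc]], p,
                          non_overlapping = non_overlapping)
      if (nrow(hits))
        out[[length(out) + 1L]] <- cbind(
          data.frame(accession = acc, id = p$id, name = p$name,
                     stringsAsFactors = FALSE), hits)
    }
  }
  if (!length(out))
    return(data.frame(accession = character(), id = character(),
                      name = character(), start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Which motif hits are gained or lost between variants
#'
#' For every (pattern, start) pair seen in any protein, counts in how many
#' proteins it occurs: positions present in all proteins are 'universal',
#' the rest are the polymorphic motif complement.
#'
#' @param hits Output of [motifPanel()].
#' @param n_proteins Total number of proteins scanned.
#' @return `data.frame` with `id`, `start`, `n_present`, `universal`.
#' @export
motifVariability <- function(hits, n_proteins) {
  if (!nrow(hits))
    return(data.frame(id = character(), start = integer(),
                      n_present = integer(), universal = logical(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$id, hits$start)
  agg <- aggregate(list(n_present = hits$accession),
                   by = list(id = hits$id, start = hits$start),
                   FUN = function(a) length(unique(a)))
  agg$universal <- agg$n_present == n_proteins
  agg[order(agg$id, agg$start), ]
}

.PHOSPHO_CLASSES <- list(
  S = c("PS00005", "PS00006"),   # PKC + CK2 with Ser at the hit start
  T = c("PS00005", "PS00006"),   # same classes, Thr at the hit start
  Y = "PS00007")                 # Tyr kinase, Tyr at the hit end

#' Candidate phosphosite inventory
#'
#' Counts serine, threonine and tyrosine residues predicted as
#' phosphorylation sites by the PKC / CK2 / tyrosine-kinase pattern
#' classes, deduplicated per residue position (a residue hit by both PKC
#' and CK2 counts once). Raw S/T/Y tallies are included so both readings of
#' a per-residue summary are available.
#'
#' @param proteins Named character vector of anchored protein sequences.
#' @param panel Motif panel containing the phospho patterns.
#' @return `data.frame` with per-protein `n_ser`, `n_thr`, `n_tyr`
#'   (predicted sites) and `total_S`, `total_T`, `total_Y` (raw residue
#'   counts); attribute `"sites"` holds the per-position site table.
#' @export
phosphoInventory <- function(proteins, panel = defaultMotifPanel()) {
  hits <- motifPanel(proteins, panel)
  sites <- list()
  rows <- lapply(names(proteins), function(acc) {
    h <- hits[hits$accession == acc, , drop = FALSE]
    chars <- strsplit(toupper(proteins[[acc]]), "")[[1]]
    pos_res <- function(residue) {
      cls <- .PHOSPHO_CLASSES[[residue]]
      hh <- h[h$id %in% cls, , drop = FALSE]
      at <- if (residue == "Y") hh$end else hh$start
      at <- at[chars[at] == residue]
      unique(at)
    }
    for (res in c("S", "T", "Y")) {
      p <- pos_res(res)
      if (length(p))
        sites[[length(sites) + 1L]] <<- data.frame(
          accession = acc, residue = res, position = p,
          stringsAsFactors = FALSE)
    }
    data.frame(accession = acc,
               n_ser = length(pos_res("S")), n_thr = length(pos_res("T")),
               n_tyr = length(pos_res("Y")),
               total_S = sum(chars == "S"), total_T = sum(chars == "T"),
               total_Y = sum(chars == "Y"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sites") <- if (length(sites)) do.call(rbind, sites) else
    data.frame(accession = character(), residue = character(),
               position = integer(), stringsAsFactors = FALSE)
  out
}
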