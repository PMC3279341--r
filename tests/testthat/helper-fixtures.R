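# Shared fixtures and independent oracles used across the suite.

# small, fast family: 3 species, few clones, no deletions unless asked
smallSimConfig <- function(seed = 1, n_species = 3, clones = 5,
                           divergence = 0.08, background = 0.01,
                           hotspot_rate = 0.3,
                           hotspots = c(5L, 20L, 40L),
                           deletions = TRUE) {
  species <- .defaultSpeciesTableN(n_species, clones, divergence)
  del <- if (deletions)
    data.frame(length = c(3L, 9L, 12L), prob = c(0.1, 0.2, 0.1),
               win_start = 10L, win_end = 60L)
  else
    data.frame(length = 9L, prob = 0, win_start = 10L, win_end = 60L)
  simConfig(species = species, hotspot_codons = hotspots,
            background_sub_rate = background, cultivar_sub_rate = 0.002,
            hotspot_sub_rate = hotspot_rate, deletion_spec = del,
            seed = seed)
}

.defaultSpeciesTableN <- function(n, clones, divergence) {
  data.frame(species = paste0("sp", seq_len(n)),
             family = paste0("fam", rep(seq_len(ceiling(n / 2)),
                                        each = 2)[seq_len(n)]),
             divergence = divergence, n_cultivars = 1L,
             clones_min = as.integer(clones), clones_max = as.integer(clones),
             stringsAsFactors = FALSE)
}

randomProtein <- function(n, alphabet = c("A","R","N","D","C","E","Q","G",
                                          "H","I","L","K","M","F","P","S",
                                          "T","W","Y","V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randomCds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# --- naive backtracking PROSITE matcher (independent oracle) ---------------
# returns the length of the shortest match of `pat` starting at `start`,
# or NA; element-wise recursion trying repetition counts smallest first
naiveProsite <- function(pat, s, start) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  elAccepts <- function(e, ch) {
    switch(e$type,
           any = TRUE,
           residue = ch == e$chars,
           set = ch %in% strsplit(e$chars, "")[[1]],
           negset = !(ch %in% strsplit(e$chars, "")[[1]]))
  }
  rec <- function(ei, pos) {
    if (ei > length(pat$elements)) {
      if (pat$cterm && pos != n + 1) return(NA_integer_)
      return(pos - start)
    }
    e <- pat$elements[[ei]]
    for (cnt in e$min:e$max) {
      if (pos + cnt - 1 > n) break
      ok <- cnt == 0 ||
        all(vapply(chars[pos:(pos + cnt - 1)], function(ch)
          elAccepts(e, ch), logical(1)))
      if (ok) {
        res <- rec(ei + 1, pos + cnt)
        if (!is.na(res)) return(res)
      }
    }
    NA_integer_
  }
  if (pat$nterm && start != 1) return(NA_integer_)
  rec(1, start)
}

naiveScan <- function(s, pattern_text) {
  pat <- parsePrositePattern(pattern_text)
  starts <- if (pat$nterm) 1L else seq_len(nchar(s))
  out <- lapply(starts, function(st) {
    len <- naiveProsite(pat, s, st)
    if (!is.na(len) && len > 0)
      data.frame(start = st, end = st + len - 1L,
                 matched = substr(s, st, st + len - 1L),
                 stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# random PROSITE pattern over a tiny alphabet, <= 8 elements
randomPattern <- function(max_el = 8, alphabet = c("A", "B", "C", "D")) {
  k <- sample(2:max_el, 1)
  els <- vapply(seq_len(k), function(i) {
    base <- switch(sample(4, 1),
                   "x",
                   sample(alphabet, 1),
                   paste0("[", paste(sample(alphabet, sample(2:3, 1)),
                                     collapse = ""), "]"),
                   paste0("{", sample(alphabet, 1), "}"))
    if (runif(1) < 0.3) {
      a <- sample(0:2, 1); b <- a + sample(0:2, 1)
      base <- if (a == b) paste0(base, "(", a, ")")
      else paste0(base, "(", a, ",", b, ")")
    }
    base
  }, character(1))
  paste(els, collapse = "-")
}
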