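# ---------------------------------------------------------------------------
# Synthetic profilin-family generator.
#
# The packaged reference is a SYNTHETIC profilin-like protein, designed (not
# downloaded) to carry the hallmarks the analyses look for: 134 aa, the
# kinase-interaction motif IQGEAGAVIRGKKGSGGITIK at positions 78-98, cysteines
# at 13/106/118, N-myristoylation motifs at 30/33/67, the amidation motif
# RGKK at 87-90, and PKC/CK2/Tyr-kinase phosphosite candidates (S41, T96,
# T126, Y125). Back-translation uses one fixed codon per residue so the
# 405 nt CDS is deterministic.
# ---------------------------------------------------------------------------

.profilinRefProtein <- paste0(
  "MSWQTYVDEH", "LMCEIEGHHL", "ASAAILGHD", "GQDGSV", "WAQSSSFPEF",
  "KPEEITGIMK", "DFEEPGHLAP", "TGLHLGGIKY", "MV",
  "IQGEAGAVIRGKKGSGGITIK",
  "KTGQALV", "C", "NMYVERLGDYL", "C", "KAEEGAYTIEDQLRSY")

.codonPref <- c(A = "GCT", R = "AGG", N = "AAC", D = "GAT", C = "TGC",
                E = "GAG", Q = "CAG", G = "GGT", H = "CAC", I = "ATC",
                L = "CTT", K = "AAG", M = "ATG", F = "TTC", P = "CCT",
                S = "TCC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

#' Packaged reference profilin-like coding sequence
#'
#' A synthetic 405 nt CDS (134 aa product plus stop) used as the root of all
#' simulations; see the package vignette for the design constraints it
#' satisfies.
#'
#' @return Nucleotide string of length 405 ending in a stop codon.
#' @export
referenceCDS <- function() {
  aa <- strsplit(.profilinRefProtein, "")[[1]]
  paste0(paste(.codonPref[aa], collapse = ""), "TAA")
}

.defaultSpeciesTable <- function() {
  data.frame(
    species = c("Olea europaea", "Betula pendula", "Corylus avellana",
                "Phleum pratense", "Zea mays"),
    family = c("Oleaceae", "Betulaceae", "Betulaceae", "Poaceae", "Poaceae"),
    divergence = c(0.11, 0.11, 0.11, 0.11, 0.11),
    n_cultivars = c(24L, 1L, 1L, 1L, 1L),
    clones_min = c(1L, 4L, 10L, 8L, 7L),
    clones_max = c(7L, 4L, 10L, 8L, 7L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for a profilin-like CDS family
#'
#' The defaults emulate the structure of the pollen profilin data set the
#' package targets: five species (one of them, the olive stand-in, with 24
#' cultivars and several clones each), per-site substitution polymorphism
#' with designated hotspot codons in the 5' half, and in-frame deletions of
#' 3/9/12 nt (whole codons) restricted to a 5'-half window, 9 nt being the
#' most likely. Species-level divergence is applied on a star topology with
#' one internal branch per species before cultivar- and clone-level noise.
#'
#' @param reference_cds Root coding sequence (default [referenceCDS()]).
#' @param species `data.frame` with columns `species`, `family`,
#'   `divergence` (per-site substitution probability on the species branch),
#'   `n_cultivars`, `clones_min`, `clones_max`.
#' @param hotspot_codons Codon (amino-acid) positions with elevated
#'   clone-level substitution rate.
#' @param background_sub_rate Clone-level per-site substitution probability
#'   outside hotspots.
#' @param cultivar_sub_rate Per-site probability on the cultivar branch.
#' @param hotspot_sub_rate Clone-level per-site probability inside hotspot
#'   codons.
#' @param deletion_spec `data.frame` with columns `length` (nt, multiples of
#'   3), `prob` (per-sequence probability), `win_start`, `win_end` (codon
#'   window in the 5' half). At most one deletion per sequence.
#' @param seed Integer seed; part of the public contract - identical seeds
#'   give byte-identical output.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(reference_cds = referenceCDS(),
                      species = .defaultSpeciesTable(),
                      hotspot_codons = c(5L, 18L, 20L, 24L, 25L, 29L, 34L,
                                         41L, 48L, 52L),
                      background_sub_rate = 0.004,
                      cultivar_sub_rate = 0.003,
                      hotspot_sub_rate = 0.25,
                      deletion_spec = data.frame(
                        length = c(3L, 9L, 12L),
                        prob = c(0.10, 0.22, 0.08),
                        win_start = 10L, win_end = 60L),
                      seed = 1L) {
  reference_cds <- toupper(reference_cds)
  n <- nchar(reference_cds)
  stopifnot(n %% 3 == 0, !grepl("[^ACGT]", reference_cds))
  n_codons <- n %/% 3L
  rates <- c(background_sub_rate, cultivar_sub_rate, hotspot_sub_rate,
             species$divergence, deletion_spec$prob)
  if (any(rates < 0 | rates > 1))
    stop("all rates and probabilities must lie in [0, 1]")
  if (sum(deletion_spec$prob) > 1)
    stop("deletion probabilities sum to more than 1")
  if (any(deletion_spec$length %% 3 != 0))
    stop("deletion lengths must be multiples of 3 (in frame)")
  if (any(hotspot_codons < 1 | hotspot_codons > n_codons - 1))
    stop("hotspot codons must lie within the CDS (excluding the stop)")
  win_len <- deletion_spec$win_end - deletion_spec$win_start + 1L
  if (any(win_len < deletion_spec$length %/% 3L))
    stop("deletion window shorter than deletion length")
  if (any(deletion_spec$win_end >= n_codons))
    stop("deletion window must not reach the stop codon")
  structure(list(reference_cds = reference_cds, species = species,
                 hotspot_codons = as.integer(hotspot_codons),
                 background_sub_rate = background_sub_rate,
                 cultivar_sub_rate = cultivar_sub_rate,
                 hotspot_sub_rate = hotspot_sub_rate,
                 deletion_spec = deletion_spec, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Read a simulation configuration from a JSON file
#'
#' @param path JSON file holding any subset of [simConfig()]'s arguments.
#' @return A `SimConfig`.
#' @export
readSimConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simConfig))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$species)) cfg$species <- as.data.frame(cfg$species)
  if (!is.null(cfg$deletion_spec))
    cfg$deletion_spec <- as.data.frame(cfg$deletion_spec)
  do.call(simConfig, cfg)
}

# mutate positions of a reference-coordinate base vector at per-site rates,
# avoiding the creation of internal stop codons (rejection sampling of the
# affected codon). `alive` marks non-deleted positions.
.mutateSites <- function(vec, rates, alive = rep(TRUE, length(vec))) {
  n <- length(vec)
  hit <- which(stats::runif(n) < rates & alive)
  if (!length(hit)) return(vec)
  old <- vec
  for (i in hit)
    vec[i] <- sample(setdiff(.NT_SYMBOLS, vec[i]), 1L)
  n_codons <- n %/% 3L
  affected <- unique((hit - 1L) %/% 3L + 1L)
  affected <- affected[affected < n_codons]    # terminal codon may be a stop
  for (cd in affected) {
    io <- (3L * cd - 2L):(3L * cd)
    tries <- 0L
    while (paste(vec[io], collapse = "") %in% .STOPS && tries < 25L) {
      mut <- intersect(io, hit)
      for (i in mut) vec[i] <- sample(setdiff(.NT_SYMBOLS, old[i]), 1L)
      tries <- tries + 1L
    }
    if (paste(vec[io], collapse = "") %in% .STOPS)
      vec[io] <- old[io]
  }
  vec
}

# sample() treats a length-1 vector as 1:x; avoid that trap
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.drawDeletion <- function(spec) {
  u <- stats::runif(1)
  edge <- cumsum(spec$prob)
  k <- which(u < edge)[1]
  if (is.na(k)) return(NULL)
  len_codons <- spec$length[k] %/% 3L
  start_codon <- .sample1(spec$win_start[k]:(spec$win_end[k] - len_codons + 1L))
  list(start = 3L * (start_codon - 1L) + 1L, length = spec$length[k])
}

#' Simulate a profilin-like CDS family with known ground truth
#'
#' Every emitted coding sequence translates without internal stop codons
#' (codon-aligned deletions plus stop-avoiding substitution sampling), and
#' identical seeds give identical output. Substitutions are uniform over the
#' three non-source bases. Deletions are applied before clone-level point
#' substitutions and at most one occurs per sequence.
#'
#' @param cfg A [simConfig()].
#' @return List with elements `samples` (a [SampleTable-class]), and `truth`
#'   - a list holding `substitutions` (accession, position, from, to - in
#'   reference coordinates, relative to the reference CDS), `deletions`
#'   (accession, start, length), `rates` (clone-level per-site rate vector),
#'   `species` (the species table used) and `config`.
#' @export
simulateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  ref <- strsplit(cfg$reference_cds, "")[[1]]
  n <- length(ref)
  clone_rates <- rep(cfg$background_sub_rate, n)
  hot_sites <- as.vector(vapply(cfg$hotspot_codons,
                                function(cd) (3L * cd - 2L):(3L * cd),
                                integer(3)))
  clone_rates[hot_sites] <- cfg$hotspot_sub_rate
  fixed_sites <- c(1L:3L, (n - 2L):n)  # start and stop codons never mutate
  clone_rates[fixed_sites] <- 0
  flat <- function(r) { v <- rep(r, n); v[fixed_sites] <- 0; v }

  seqs <- character(0); meta <- list(); subs <- list(); dels <- list()
  counter <- 0L
  for (si in seq_len(nrow(cfg$species))) {
    sp <- cfg$species[si, ]
    code <- toupper(substr(gsub("[^A-Za-z]", "", sp$species), 1, 3))
    anc_sp <- .mutateSites(ref, flat(sp$divergence))
    for (ci in seq_len(sp$n_cultivars)) {
      anc_cv <- .mutateSites(anc_sp, flat(cfg$cultivar_sub_rate))
      cultivar <- if (sp$n_cultivars > 1) sprintf("cv%02d", ci) else ""
      n_clones <- .sample1(sp$clones_min:sp$clones_max)
      for (k in seq_len(n_clones)) {
        counter <- counter + 1L
        acc <- sprintf("SIM%s%04d", code, counter)
        alive <- rep(TRUE, n)
        del <- .drawDeletion(cfg$deletion_spec)
        if (!is.null(del)) {
          alive[del$start:(del$start + del$length - 1L)] <- FALSE
          dels[[length(dels) + 1L]] <- data.frame(
            accession = acc, start = del$start, length = del$length,
            stringsAsFactors = FALSE)
        }
        vec <- .mutateSites(anc_cv, clone_rates, alive)
        diffs <- which(vec != ref & alive)
        if (length(diffs))
          subs[[length(subs) + 1L]] <- data.frame(
            accession = acc, position = diffs, from = ref[diffs],
            to = vec[diffs], stringsAsFactors = FALSE)
        seqs[acc] <- paste(vec[alive], collapse = "")
        meta[[counter]] <- data.frame(
          accession = acc, family = sp$family, species = sp$species,
          cultivar = cultivar, clone = as.character(k),
          is_reference = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  # post-condition: every emitted CDS translates cleanly
  for (acc in names(seqs)) translateCds(seqs[[acc]])
  empty_subs <- data.frame(accession = character(), position = integer(),
                           from = character(), to = character(),
                           stringsAsFactors = FALSE)
  empty_dels <- data.frame(accession = character(), start = integer(),
                           length = integer(), stringsAsFactors = FALSE)
  truth <- list(
    substitutions = if (length(subs)) do.call(rbind, subs) else empty_subs,
    deletions = if (length(dels)) do.call(rbind, dels) else empty_dels,
    rates = clone_rates, species = cfg$species, config = cfg)
  list(samples = SampleTable(Biostrings::DNAStringSet(seqs), meta),
       truth = truth)
}

#' Replay a truth table on the reference
#'
#' Rebuilds every emitted sequence from the reference CDS plus the recorded
#' substitutions and deletions; by construction this must reproduce
#' `simulateFamily()`'s output exactly, which the test suite asserts.
#'
#' @param truth The `truth` element of [simulateFamily()]'s return value.
#' @return Named character vector of sequences.
#' @export
replayTruth <- function(truth) {
  ref <- strsplit(truth$config$reference_cds, "")[[1]]
  meta_acc <- unique(c(truth$substitutions$accession,
                       truth$deletions$accession))
  rebuild <- function(acc) {
    vec <- ref
    s <- truth$substitutions[truth$substitutions$accession == acc, ]
    vec[s$position] <- s$to
    alive <- rep(TRUE, length(vec))
    d <- truth$deletions[truth$deletions$accession == acc, ]
    if (nrow(d))
      for (j in seq_len(nrow(d)))
        alive[d$start[j]:(d$start[j] + d$length[j] - 1L)] <- FALSE
    paste(vec[alive], collapse = "")
  }
  setNames(vapply(meta_acc, rebuild, character(1)), meta_acc)
}

#' Emit the true gapped alignment of a simulated family
#'
#' Places every sequence in reference coordinates with `-` at deleted
#' positions, bypassing any external aligner: the width equals the
#' reference length and the anchor is column 1 (the A of the start codon).
#'
#' @param sim Return value of [simulateFamily()].
#' @return Nucleotide [SeqAlignment-class].
#' @export
truthAlignment <- function(sim) {
  truth <- sim$truth
  ref <- strsplit(truth$config$reference_cds, "")[[1]]
  accs <- accessions(sim$samples)
  rows <- vapply(accs, function(acc) {
    vec <- ref
    s <- truth$substitutions[truth$substitutions$accession == acc, ]
    vec[s$position] <- s$to
    d <- truth$deletions[truth$deletions$accession == acc, ]
    if (nrow(d))
      for (j in seq_len(nrow(d)))
        vec[d$start[j]:(d$start[j] + d$length[j] - 1L)] <- .GAP
    paste(vec, collapse = "")
  }, character(1))
  SeqAlignment(rows, alphabet = "nucleotide", anchor = 1L)
}

#' Write a simulated family to disk
#'
#' Emits the FASTA, the metadata TSV, the two truth TSVs and the
#' configuration (seed included) as JSON, the file set the rest of the
#' pipeline consumes.
#'
#' @param sim Return value of [simulateFamily()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(sampleSeqs(sim$samples), file.path(dir, "family.fasta"))
  writeMetadata(sim$samples, file.path(dir, "metadata.tsv"))
  write.table(sim$truth$substitutions, file.path(dir, "truth_substitutions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$deletions, file.path(dir, "truth_deletions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$truth$config)
  cfg$species <- as.list(cfg$species)
  cfg$deletion_spec <- as.list(cfg$deletion_spec)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
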