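#' Pipeline configuration
#'
#' Collects the inputs and knobs of [runPipeline()]. Either file paths
#' (`fasta`, `metadata`, optional `alignment`) or in-memory objects
#' (`samples`, `aln`) may be supplied; objects win when both are present.
#'
#' @param fasta,metadata,alignment Input file paths (FASTA, TSV, aligned
#'   FASTA/Clustal).
#' @param samples Optional [SampleTable-class].
#' @param aln Optional nucleotide [SeqAlignment-class].
#' @param anchor_ref Row id used to anchor coordinates at its profilin ORF
#'   start; default the first alignment row.
#' @param viv_threshold Polymorphism threshold (strict `>`).
#' @param gap_policy Identity gap policy, `"mismatch"` or `"exclude"`.
#' @param bootstrap_reps Bootstrap replicates for the protein tree.
#' @param seed Integer seed for the bootstrap.
#' @param level Grouping level for summaries.
#' @param include_references Keep `is_reference` records in statistics?
#' @param out_dir Output directory.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(fasta = NULL, metadata = NULL, alignment = NULL,
                           samples = NULL, aln = NULL, anchor_ref = NULL,
                           viv_threshold = 3, gap_policy = "mismatch",
                           bootstrap_reps = 100, seed = 1L,
                           level = "species", include_references = TRUE,
                           out_dir = tempfile("profvar_run")) {
  stopifnot(viv_threshold > 0, bootstrap_reps >= 1)
  for (p in c(fasta, metadata, alignment))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  if (is.null(samples) && (is.null(fasta) || is.null(metadata)))
    stop("either 'samples' or both 'fasta' and 'metadata' are required")
  if (is.null(aln) && is.null(alignment))
    stop("an alignment is required ('aln' object or 'alignment' path); ",
         "alignment construction is delegated to an external aligner")
  structure(list(fasta = fasta, metadata = metadata, alignment = alignment,
                 samples = samples, aln = aln, anchor_ref = anchor_ref,
                 viv_threshold = viv_threshold, gap_policy = gap_policy,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), level = level,
                 include_references = include_references,
                 out_dir = out_dir),
            class = "PipelineConfig")
}

.anchorAtOrf <- function(aln, ref_id) {
  row <- alnMatrix(aln)[ref_id, ]
  resid_cols <- which(row != .GAP)
  ungapped <- paste(row[resid_cols], collapse = "")
  orf <- selectProfilinOrf(findOrfs(ungapped, min_aa = 30))
  new("SeqAlignment", mat = alnMatrix(aln), alphabet = alnAlphabet(aln),
      anchor = as.integer(resid_cols[orf$start]))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

#' Run the full polymorphism pipeline
#'
#' Orchestrates, in order: input loading, coordinate anchoring at the
#' profilin ORF, ORF/translation and deletion annotation, per-column
#' variability profiles (nucleotide entropy and amino-acid Wu-Kabat index)
#' with per-group polymorphic-position calls, nucleotide and amino-acid
#' identity matrices with group divergence summaries, physicochemical
#' profiles, the motif panel and phosphosite inventory, the KIM-window
#' substitution report, a bootstrapped NJ protein tree, and the
#' between-group statistics. Each stage writes a TSV (or Newick) into
#' `out_dir` and logs its row/column counts; a machine-readable
#' `summary.json` records totals, the seed and a configuration hash.
#' Identical configurations and seeds give byte-identical output bundles.
#'
#' @param config A [pipelineConfig()].
#' @param quiet Suppress per-stage log messages?
#' @return Invisibly, a list with the summary and the paths written.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- function(...) if (!quiet) message("[profvar] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  st <- .stage("load", {
    if (!is.null(config$samples)) config$samples
    else readMetadata(config$metadata,
                      readFasta(config$fasta, "nucleotide"))
  })
  aln <- .stage("alignment", {
    a <- if (!is.null(config$aln)) config$aln
    else readAlignment(config$alignment, "nucleotide")
    checkAlignmentSamples(a, st)
    a
  })
  log("loaded ", length(st), " records; alignment ", length(aln), " x ",
      alnWidth(aln))

  ref_id <- if (is.null(config$anchor_ref)) names(aln)[1] else
    config$anchor_ref
  aln <- .stage("anchor", .anchorAtOrf(aln, ref_id))
  log("anchored at column ", anchorOffset(aln), " (ORF start of ", ref_id, ")")

  orf <- .stage("orf", orfTable(st))
  paths["orf"] <- .tsv(orf[, c("accession", "orf_start", "orf_end",
                               "protein_length")],
                       file.path(config$out_dir, "orf.tsv"))
  dels <- .stage("deletions", annotateDeletions(aln))
  paths["deletions"] <- .tsv(dels, file.path(config$out_dir, "deletions.tsv"))
  log(nrow(orf), " ORFs, ", nrow(dels), " deletion runs")

  paln <- .stage("translate_alignment", alnTranslate(aln))

  prof_nt <- .stage("profiles_nt", columnProfiles(aln))
  prof_aa <- .stage("profiles_aa", columnProfiles(paln))
  paths["profiles_nucleotide"] <-
    .tsv(prof_nt, file.path(config$out_dir, "profiles_nucleotide.tsv"))
  paths["profiles_protein"] <-
    .tsv(prof_aa, file.path(config$out_dir, "profiles_protein.tsv"))

  poly <- .stage("polymorphic", {
    rep <- polymorphismReport(paln, st, level = config$level,
                              threshold = config$viv_threshold,
                              include_references = config$include_references)
    stacked <- do.call(rbind, lapply(names(rep), function(g)
      if (nrow(rep[[g]]))
        cbind(data.frame(group = g, stringsAsFactors = FALSE), rep[[g]])
      else NULL))
    if (is.null(stacked))
      stacked <- data.frame(group = character(), position = integer(),
                            viv = numeric(), stringsAsFactors = FALSE)
    stacked
  })
  paths["polymorphic"] <- .tsv(poly,
                               file.path(config$out_dir, "polymorphic.tsv"))
  log(nrow(poly), " polymorphic (group, position) calls at viv > ",
      config$viv_threshold)

  idm_nt <- .stage("identity_nt", identityMatrix(aln, config$gap_policy))
  idm_aa <- .stage("identity_aa", identityMatrix(paln, config$gap_policy))
  paths["identity_nucleotide"] <- file.path(config$out_dir,
                                            "identity_nucleotide.tsv")
  writeIdentityMatrix(idm_nt, paths["identity_nucleotide"])
  paths["identity_aminoacid"] <- file.path(config$out_dir,
                                           "identity_aminoacid.tsv")
  writeIdentityMatrix(idm_aa, paths["identity_aminoacid"])
  gs_nt <- .stage("groups_nt",
                  groupSummary(idm_nt, st, config$level,
                               config$include_references))
  gs_aa <- .stage("groups_aa",
                  groupSummary(idm_aa, st, config$level,
                               config$include_references))
  paths["groups_nucleotide"] <-
    .tsv(gs_nt, file.path(config$out_dir, "groups_nucleotide.tsv"))
  paths["groups_aminoacid"] <-
    .tsv(gs_aa, file.path(config$out_dir, "groups_aminoacid.tsv"))

  proteins <- setNames(orf$protein, orf$accession)
  phys <- .stage("physchem", physchemTable(proteins, summary = TRUE))
  paths["physchem"] <- .tsv(phys, file.path(config$out_dir, "physchem.tsv"))

  motifs <- .stage("motifs", motifPanel(proteins))
  paths["motifs"] <- .tsv(motifs, file.path(config$out_dir, "motifs.tsv"))
  phospho <- .stage("phospho", phosphoInventory(proteins))
  paths["phospho"] <- .tsv(phospho, file.path(config$out_dir, "phospho.tsv"))
  log(nrow(motifs), " motif hits across ", length(proteins), " proteins")

  kim <- .stage("kim", tryCatch(kimReport(paln), error = function(e) NULL))
  if (!is.null(kim))
    paths["kim"] <- .tsv(kim$substitutions,
                         file.path(config$out_dir, "kim.tsv"))

  tree <- .stage("phylogeny",
                 bootstrapTree(paln, n_reps = config$bootstrap_reps,
                               seed = config$seed,
                               gaps = config$gap_policy))
  paths["tree"] <- file.path(config$out_dir, "tree.nwk")
  writeNewick(tree, paths["tree"])
  paths["supports"] <- .tsv(supportTable(tree),
                            file.path(config$out_dir, "supports.tsv"))

  stats_out <- .stage("stats", {
    res <- list()
    for (alpha_level in c("nucleotide", "aminoacid")) {
      a <- if (alpha_level == "nucleotide") aln else paln
      smp <- variabilitySamples(a, st, level = config$level,
                                include_references =
                                  config$include_references)
      smp <- smp[lengths(smp) >= 2]
      if (length(smp) >= 2)
        res[[alpha_level]] <- compareGroups(smp)
    }
    res
  })
  for (alpha_level in names(stats_out))
    paths[paste0("stats_", alpha_level)] <-
      .tsv(stats_out[[alpha_level]]$games_howell,
           file.path(config$out_dir, paste0("stats_", alpha_level, ".tsv")))

  cfg_export <- config[setdiff(names(config),
                               c("samples", "aln", "out_dir"))]
  cfg_json <- jsonlite::toJSON(cfg_export, auto_unbox = TRUE, digits = NA,
                               null = "null")
  hash_file <- tempfile()
  writeLines(cfg_json, hash_file)
  cfg_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  summary <- list(
    package_version = as.character(utils::packageVersion("profvar")),
    seed = config$seed, config_hash = cfg_hash,
    n_sequences = length(st), n_columns = alnWidth(aln),
    n_protein_columns = alnWidth(paln),
    n_polymorphic_calls = nrow(poly),
    n_deletion_runs = nrow(dels),
    n_motif_hits = nrow(motifs),
    clamped_branch_deficit = attr(tree, "clamped"),
    anova = lapply(stats_out, function(x)
      list(F = x$anova$F, p = x$anova$p)),
    levene = lapply(stats_out, function(x)
      list(W = x$levene$W, p = x$levene$p)))
  paths["summary"] <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log("summary written to ", paths["summary"])
  invisible(list(summary = summary, paths = paths, tree = tree,
                 stats = stats_out))
}
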