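#' Distance matrix from an identity matrix
#'
#' Uncorrected p-distance: `d = 1 - identity / 100`. No evolutionary
#' correction (Jukes-Cantor etc.) is applied, consistent with the
#' identity-only divergence summaries.
#'
#' @param mat Identity matrix from [identityMatrix()].
#' @return A [stats::dist] object.
#' @export
distanceFromIdentity <- function(mat) {
  stopifnot(is.matrix(mat), isSymmetric(unname(mat)))
  stats::as.dist((100 - mat) / 100)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classical NJ agglomeration via [ape::nj()]. Negative branch lengths -
#' an artefact of non-additive distances - are clamped to zero and the
#' total clamped deficit is recorded in the `"clamped"` attribute.
#'
#' @param d A [stats::dist] or symmetric distance matrix with at least 3
#'   taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 3)
    stop("neighbor-joining requires at least 3 taxa")
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  deficit <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- deficit
  tree
}

# nj on a character alignment matrix, used for bootstrap replicates
.njFromMatrix <- function(mat, gaps = "mismatch") {
  aln <- new("SeqAlignment", mat = mat, alphabet = "amino-acid",
             anchor = 1L)
  njTree(distanceFromIdentity(identityMatrix(aln, gaps = gaps)))
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' identity-distance NJ tree for each replicate and reports, for every
#' internal edge of the original tree, the percentage of replicates whose
#' tree contains the same bipartition. Seeded and reproducible.
#'
#' @param aln A [SeqAlignment-class] with at least 3 rows.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param gaps Gap policy for the identity computation.
#' @return The NJ tree of the full alignment with supports (percent) in
#'   `node.label`; attribute `"degenerate"` is `TRUE` when all pairwise
#'   distances are zero (star-like tree, supports not meaningful).
#' @export
bootstrapTree <- function(aln, n_reps = 1000, seed = 1L,
                          gaps = c("mismatch", "exclude")) {
  gaps <- match.arg(gaps)
  stopifnot(length(aln) >= 3, n_reps >= 1)
  mat <- alnMatrix(aln)
  # validity of SeqAlignment already checked; alphabet generalised here
  d <- distanceFromIdentity(identityMatrix(aln, gaps = gaps))
  tree <- njTree(d)
  degenerate <- all(d == 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  alphabet <- alnAlphabet(aln)
  fun <- function(x) {
    a <- new("SeqAlignment", mat = x, alphabet = alphabet, anchor = 1L)
    njTree(distanceFromIdentity(identityMatrix(a, gaps = gaps)))
  }
  counts <- ape::boot.phylo(tree, mat, fun, B = n_reps, quiet = TRUE)
  support <- round(100 * counts / n_reps, 1)
  if (degenerate) support[] <- 100
  tree$node.label <- as.character(support)
  attr(tree, "degenerate") <- degenerate
  attr(tree, "n_reps") <- n_reps
  tree
}

# smallest tip label below each node, for deterministic child ordering
.minTipBelow <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  res <- character(ntip + nnode)
  res[seq_len(ntip)] <- tree$tip.label
  edges <- tree$edge
  # postorder guarantees children are resolved before their parent edge
  for (e in ape::postorder(tree)) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    if (res[parent] == "" || res[child] < res[parent])
      res[parent] <- res[child]
  }
  res
}

#' Deterministic Newick serialization
#'
#' Branch lengths with 6 decimals, bootstrap supports as internal node
#' labels, children of every node ordered by their smallest descendant tip
#' label so the same tree always serializes to the same bytes.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional file to write to (LF-terminated single line).
#' @return The Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  lens <- tree$edge.length
  labels <- .minTipBelow(tree)
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  fmt <- function(node, edge_idx) {
    body <- if (node <= ntip) {
      tree$tip.label[node]
    } else {
      ch <- kids[[as.character(node)]]
      ch <- ch[order(labels[edges[ch, 2]])]
      inner <- vapply(ch, function(e) fmt(edges[e, 2], e), character(1))
      lab <- if (!is.null(tree$node.label))
        tree$node.label[node - ntip] else ""
      if (is.na(lab)) lab <- ""
      paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (!is.null(edge_idx) && !is.null(lens))
      paste0(body, ":", sprintf("%.6f", lens[edge_idx]))
    else body
  }
  root <- ntip + 1L
  out <- paste0(fmt(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(out, path, sep = "\n")
    return(invisible(out))
  }
  out
}

#' Fraction of groups forming monophyletic clades
#'
#' @param tree An [ape::phylo] tree with accession tip labels.
#' @param st A [SampleTable-class].
#' @param level Grouping level (default species).
#' @return Named logical vector (group is a clade), with attribute
#'   `"fraction"`.
#' @export
cladeRecovery <- function(tree, st, level = "species") {
  meta <- sampleMeta(st)
  meta <- meta[meta$accession %in% tree$tip.label, , drop = FALSE]
  groups <- split(meta$accession, meta[[level]])
  groups <- groups[vapply(groups, length, integer(1)) >= 1]
  res <- vapply(groups, function(tips)
    ape::is.monophyletic(tree, tips), logical(1))
  attr(res, "fraction") <- mean(res)
  res
}

#' Bipartition support table
#'
#' @param tree Tree from [bootstrapTree()].
#' @return `data.frame` with one row per internal node: `node`, `support`,
#'   `tips` (semicolon-joined smaller side of the bipartition).
#' @export
supportTable <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  rows <- lapply(seq_along(parts), function(i) {
    tips <- sort(labs[parts[[i]]])
    data.frame(node = ntip + i,
               support = if (!is.null(tree$node.label))
                 tree$node.label[i] else NA_character_,
               tips = paste(tips, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
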