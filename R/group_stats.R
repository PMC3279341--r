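#' Per-group variability samples from an alignment
#'
#' The observation unit for the between-species comparisons is a
#' per-position variability value: the Wu-Kabat index on amino-acid
#' columns, Shannon entropy on nucleotide columns. Each species (or other
#' grouping level) contributes one sample holding its alignment's
#' per-position values; positions with no effective symbols are dropped.
#'
#' @param aln A [SeqAlignment-class].
#' @param st A [SampleTable-class].
#' @param level Grouping level, default `"species"`.
#' @param statistic `"viv"` or `"entropy"`; default picks viv for
#'   amino-acid alignments and entropy for nucleotide ones.
#' @param include_references Keep records flagged `is_reference`?
#' @return Named list of numeric vectors, one per group.
#' @export
variabilitySamples <- function(aln, st, level = "species", statistic = NULL,
                               include_references = TRUE) {
  if (is.null(statistic))
    statistic <- if (alnAlphabet(aln) == "amino-acid") "viv" else "entropy"
  stopifnot(statistic %in% c("viv", "entropy"))
  checkAlignmentSamples(aln, st)
  meta <- sampleMeta(st)
  meta <- meta[match(names(aln), meta$accession), , drop = FALSE]
  if (!include_references) meta <- meta[!meta$is_reference, , drop = FALSE]
  groups <- split(meta$accession, meta[[level]])
  lapply(groups, function(ids) {
    prof <- columnProfiles(subsetAlignment(aln, ids))
    v <- if (statistic == "viv") prof$viv else prof$entropy_bits
    v[!is.na(v)]
  })
}

.checkSamples <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("every group needs at least 2 observations")
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  samples
}

#' One-way ANOVA F test across groups
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' statistic against the Fisher-Snedecor distribution). In the degenerate
#' case of zero variance everywhere with equal means the convention
#' `F = 0`, `p = 1` is returned with `flagged = TRUE`.
#'
#' @param samples Named list of numeric vectors (one per group).
#' @return List with `F`, `df_between`, `df_within`, `p`, `flagged`.
#' @export
anovaF <- function(samples) {
  samples <- .checkSamples(samples)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), lengths(samples)))
  k <- length(samples); n <- length(values)
  if (all(vapply(samples, function(v) var(v) == 0, logical(1)))) {
    means <- vapply(samples, mean, numeric(1))
    if (max(means) == min(means))
      return(list(F = 0, df_between = k - 1, df_within = n - k, p = 1,
                  flagged = TRUE))
    return(list(F = Inf, df_between = k - 1, df_within = n - k, p = 0,
                flagged = TRUE))
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]), p = unname(fit$p.value),
       flagged = FALSE)
}

#' Levene test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from each group's center
#' (mean by default; the median variant is the Brown-Forsythe flavour).
#'
#' @param samples Named list of numeric vectors.
#' @param center `"mean"` or `"median"`.
#' @return List with `W`, `df_between`, `df_within`, `p`, `flagged`.
#' @export
leveneW <- function(samples, center = c("mean", "median")) {
  center <- match.arg(center)
  samples <- .checkSamples(samples)
  cfun <- if (center == "mean") mean else stats::median
  devs <- lapply(samples, function(v) abs(v - cfun(v)))
  res <- anovaF(devs)
  list(W = res$F, df_between = res$df_between, df_within = res$df_within,
       p = res$p, flagged = res$flagged)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (3 <= n <= 5000); a constant
#' sample is rejected with an informative error.
#'
#' @param values Numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiroWilkTest <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (max(values) == min(values))
    stop("sample is constant; normality test degenerate")
  fit <- stats::shapiro.test(values)
  list(W = unname(fit$statistic), p = unname(fit$p.value))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' For each pair of groups i, j:
#' \deqn{t = |\bar x_i - \bar x_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}}
#' with Welch-Satterthwaite degrees of freedom and the p-value from the
#' studentized range distribution with \eqn{q = t\sqrt 2} and `k` = number
#' of groups. Variances are never pooled, so unequal variances and sample
#' sizes are handled by construction. A pair of groups both with zero
#' variance gets its degrees of freedom floored at 1 and is flagged.
#'
#' @param samples Named list of numeric vectors (one per group).
#' @param alpha Significance level for the `significant` flag.
#' @return `data.frame` with `group_a`, `group_b`, `mean_difference`, `se`,
#'   `t`, `welch_df`, `q_statistic`, `p_value`, `significant`, `flagged`.
#' @export
gamesHowell <- function(samples, alpha = 0.05) {
  samples <- .checkSamples(samples)
  k <- length(samples)
  gn <- names(samples)
  means <- vapply(samples, mean, numeric(1))
  vars <- vapply(samples, var, numeric(1))
  ns <- lengths(samples)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      vi <- vars[i] / ns[i]; vj <- vars[j] / ns[j]
      se <- sqrt(vi + vj)
      diff <- means[i] - means[j]
      flagged <- FALSE
      if (se == 0) {
        # both groups constant: no sampling variance to test against
        flagged <- TRUE
        tstat <- if (diff == 0) 0 else Inf
        df <- 1
      } else {
        tstat <- abs(diff) / se
        df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
        if (!is.finite(df) || df < 1) { df <- 1; flagged <- TRUE }
      }
      q <- tstat * sqrt(2)
      p <- if (is.infinite(tstat)) 0 else
        stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gn[i], group_b = gn[j], mean_difference = diff,
        se = se, t = tstat, welch_df = df, q_statistic = q, p_value = p,
        significant = p < alpha, flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full between-group statistical comparison of variability
#'
#' Runs the omnibus F test, the Levene variance-homogeneity test, per-group
#' Shapiro-Wilk normality tests, and the Games-Howell pairwise
#' comparisons - the analysis battery applied to per-position variability
#' distributions.
#'
#' @param samples Named list of numeric vectors.
#' @param alpha Significance level.
#' @return List with elements `anova`, `levene`, `shapiro` (per-group
#'   data.frame), `games_howell`.
#' @export
compareGroups <- function(samples, alpha = 0.05) {
  samples <- .checkSamples(samples)
  sw <- lapply(names(samples), function(g) {
    res <- tryCatch(shapiroWilkTest(samples[[g]]),
                    error = function(e) list(W = NA_real_, p = NA_real_))
    data.frame(group = g, W = res$W, p = res$p, stringsAsFactors = FALSE)
  })
  list(anova = anovaF(samples), levene = leveneW(samples),
       shapiro = do.call(rbind, sw),
       games_howell = gamesHowell(samples, alpha = alpha))
}
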