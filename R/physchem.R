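# ---------------------------------------------------------------------------
# ProtParam-style physicochemical calculators.
#
# Residue constants: Expasy average residue masses; Kyte-Doolittle (1982)
# hydropathy; Bjellqvist pKa set for the isoelectric point (N-terminal pKa
# depends on the first residue, C-terminal on the last); Gill-von Hippel
# (1989) molar extinction coefficients; Ikai (1980) aliphatic index; the
# Guruprasad, Reddy & Pandit (1990) 400-entry dipeptide instability weights
# are shipped as inst/extdata/diwv_guruprasad.tsv.
# ---------------------------------------------------------------------------

.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER <- 18.01524

.KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.PK_POS <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.PK_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.PK_NTERM_BY_RES <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                      V = 7.44, E = 7.7)
.PK_CTERM_BY_RES <- c(D = 4.55, E = 4.75)

.diwv_cache <- new.env(parent = emptyenv())

.diwv <- function() {
  if (is.null(.diwv_cache$tab)) {
    path <- system.file("extdata", "diwv_guruprasad.tsv", package = "profvar",
                        mustWork = TRUE)
    d <- read.delim(path, stringsAsFactors = FALSE)
    tab <- matrix(0, 20, 20, dimnames = list(.AA_SYMBOLS, .AA_SYMBOLS))
    tab[cbind(d$first, d$second)] <- d$weight
    .diwv_cache$tab <- tab
  }
  .diwv_cache$tab
}

.checkProtein <- function(protein, min_len = 1) {
  protein <- toupper(protein)
  if (nchar(protein) < min_len)
    stop("protein must have at least ", min_len, " residue(s)")
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(chars), .AA_SYMBOLS)
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = " "))
  chars
}

#' Molecular weight of a protein (average isotopic masses)
#'
#' Sum of average residue masses plus one water (18.01524 Da).
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @return Mass in Da.
#' @export
molecularWeight <- function(protein) {
  chars <- .checkProtein(protein)
  sum(.AA_MASS[chars]) + .WATER
}

.netCharge <- function(chars, pH) {
  n <- length(chars)
  counts <- table(factor(chars, levels = .AA_SYMBOLS))
  pk_n <- unname(.PK_NTERM_BY_RES[chars[1]])
  if (is.na(pk_n)) pk_n <- .PK_POS[["Nterm"]]
  pk_c <- unname(.PK_CTERM_BY_RES[chars[n]])
  if (is.na(pk_c)) pk_c <- .PK_NEG[["Cterm"]]
  pos <- function(pk, count) {
    cr <- 10^(pk - pH)
    count * cr / (cr + 1)
  }
  neg <- function(pk, count) {
    cr <- 10^(pH - pk)
    count * cr / (cr + 1)
  }
  q <- pos(pk_n, 1) + pos(.PK_POS[["K"]], counts[["K"]]) +
    pos(.PK_POS[["R"]], counts[["R"]]) + pos(.PK_POS[["H"]], counts[["H"]])
  q - (neg(pk_c, 1) + neg(.PK_NEG[["D"]], counts[["D"]]) +
       neg(.PK_NEG[["E"]], counts[["E"]]) + neg(.PK_NEG[["C"]], counts[["C"]]) +
       neg(.PK_NEG[["Y"]], counts[["Y"]]))
}

#' Isoelectric point by bisection of the Henderson-Hasselbalch net charge
#'
#' The net charge `Q(pH)` sums the protonated fractions of the N-terminus,
#' Lys, Arg and His against the deprotonated fractions of the C-terminus,
#' Asp, Glu, Cys and Tyr with the Bjellqvist pKa set. `Q` is monotone
#' decreasing in pH, so bisection on \[0, 14\] to `|Q| < 1e-4` always
#' converges to the unique root.
#'
#' @param protein Amino-acid string.
#' @param tol Charge tolerance at the root.
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(protein, tol = 1e-4) {
  chars <- .checkProtein(protein)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .netCharge(chars, mid)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Net charge of a protein at a given pH
#'
#' @param protein Amino-acid string.
#' @param pH pH value.
#' @return Net charge (elementary charges).
#' @export
netCharge <- function(protein, pH) {
  .netCharge(.checkProtein(protein), pH)
}

#' Molar extinction coefficients at 280 nm (Gill-von Hippel)
#'
#' Reduced form: `5500 * nW + 1490 * nY`; oxidized form adds 125 per
#' cystine bridge, i.e. `floor(nC / 2)` pairs.
#'
#' @param protein Amino-acid string.
#' @return Named numeric vector `c(reduced =, oxidized =)` in 1/(M cm).
#' @export
extinction280 <- function(protein) {
  chars <- .checkProtein(protein)
  nW <- sum(chars == "W"); nY <- sum(chars == "Y"); nC <- sum(chars == "C")
  reduced <- 5500 * nW + 1490 * nY
  c(reduced = reduced, oxidized = reduced + 125 * (nC %/% 2))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values
#' indicate an overall hydrophilic protein.
#'
#' @param protein Amino-acid string.
#' @return GRAVY value.
#' @export
gravyIndex <- function(protein) {
  chars <- .checkProtein(protein)
  mean(.KD_HYDROPATHY[chars])
}

#' Aliphatic index (Ikai)
#'
#' `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with `X` the mole percent
#' of each residue.
#'
#' @param protein Amino-acid string.
#' @return Aliphatic index.
#' @export
aliphaticIndex <- function(protein) {
  chars <- .checkProtein(protein)
  x <- 100 * c(A = mean(chars == "A"), V = mean(chars == "V"),
               I = mean(chars == "I"), L = mean(chars == "L"))
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Instability index (Guruprasad)
#'
#' `II = (10 / L) * sum(DIWV(res_i, res_{i+1}))` over consecutive residue
#' pairs, with the published 400-entry dipeptide weight table. Values below
#' 40 classify the protein as stable.
#'
#' @param protein Amino-acid string of length >= 2.
#' @return Instability index.
#' @export
instabilityIndex <- function(protein) {
  chars <- .checkProtein(protein, min_len = 2)
  tab <- .diwv()
  L <- length(chars)
  w <- tab[cbind(chars[-L], chars[-1])]
  10 / L * sum(w)
}

#' Full physicochemical profile of one protein
#'
#' @param protein Amino-acid string.
#' @return One-row `data.frame`: `length`, `mw`, `pi`, `ext_reduced`,
#'   `ext_oxidized`, `gravy`, `aliphatic_index`, `instability_index`,
#'   `stable` (instability below 40).
#' @export
physchemProfile <- function(protein) {
  ext <- extinction280(protein)
  ii <- instabilityIndex(protein)
  data.frame(length = nchar(protein), mw = molecularWeight(protein),
             pi = isoelectricPoint(protein),
             ext_reduced = unname(ext["reduced"]),
             ext_oxidized = unname(ext["oxidized"]),
             gravy = gravyIndex(protein),
             aliphatic_index = aliphaticIndex(protein),
             instability_index = ii, stable = ii < 40)
}

#' Physicochemical table for a set of proteins
#'
#' One row per protein, mirroring a ProtParam summary table; a final
#' `mean` / `sd` pair of rows can be appended for reporting.
#'
#' @param proteins Named character vector of amino-acid strings.
#' @param summary Append mean and standard deviation rows?
#' @return `data.frame` with an `accession` column plus the profile columns.
#' @export
physchemTable <- function(proteins, summary = FALSE) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id)
    cbind(data.frame(accession = id, stringsAsFactors = FALSE),
          physchemProfile(proteins[[id]])))
  out <- do.call(rbind, rows)
  if (summary) {
    num <- vapply(out, is.numeric, logical(1))
    m <- out[1, ]; s <- out[1, ]
    m$accession <- "mean"; s$accession <- "sd"
    for (col in names(out)[num]) {
      m[[col]] <- mean(out[[col]])
      s[[col]] <- sd(out[[col]])
    }
    m$stable <- NA; s$stable <- NA
    out <- rbind(out, m, s)
  }
  rownames(out) <- NULL
  out
}
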