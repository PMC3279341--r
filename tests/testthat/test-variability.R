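test_that("column entropy matches closed forms", {
  expect_equal(columnEntropy(c(A = 10)), 0)
  expect_equal(columnEntropy(c(A = 2, C = 2)), 1)
  expect_equal(columnEntropy(c(A = 3, C = 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  # gaps and ambiguity codes carry no signal
  expect_equal(columnEntropy(c(A = 3, C = 1, N = 5, `-` = 7)),
               columnEntropy(c(A = 3, C = 1)))
  expect_true(is.na(columnEntropy(c(`-` = 4, N = 1))))
})

test_that("the Wu-Kabat index follows k over f_max", {
  expect_equal(columnViv(c(A = 17)), 1)
  expect_equal(columnViv(c(L = 400), alphabet = "amino-acid"), 1)
  expect_equal(columnViv(c(A = 3, C = 1)), 2 / 0.75)
  # ties for the most frequent residue leave f_max unchanged
  expect_equal(columnViv(c(A = 2, C = 2, G = 1)), 3 / (2 / 5))
  expect_equal(columnViv(c(A = 3, C = 1, `-` = 10, N = 2)), 2 / 0.75)
})

test_that("viv equals k for uniform columns and is permutation invariant", {
  # brute force over all count vectors with n <= 8, k <= 4
  for (k in 1:4) {
    combos <- expand.grid(rep(list(1:8), k))
    combos <- combos[rowSums(combos) <= 8, , drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      counts <- as.numeric(combos[r, ])
      names(counts) <- c("A", "C", "G", "T")[seq_len(k)]
      v <- columnViv(counts)
      oracle <- length(counts) / (max(counts) / sum(counts))
      expect_equal(v, oracle)
      # equal frequencies: f_max = 1/k, so the index peaks at k^2
      if (length(unique(counts)) == 1) expect_equal(v, k^2)
      perm <- counts[sample(seq_along(counts))]
      expect_equal(columnViv(perm), v)
    }
  }
})

test_that("entropy is bounded by log2(k) with equality iff uniform", {
  for (k in 2:4) {
    combos <- expand.grid(rep(list(1:6), k))
    for (r in seq_len(min(nrow(combos), 400))) {
      counts <- as.numeric(combos[r, ])
      names(counts) <- c("A", "C", "G", "T")[seq_len(k)]
      h <- columnEntropy(counts)
      expect_lte(h, log2(k) + 1e-12)
      if (length(unique(counts)) == 1)
        expect_equal(h, log2(k))
      else if (h >= log2(k) - 1e-12)
        fail("entropy attained the bound on a non-uniform column")
    }
  }
})

test_that("consensus symbols follow the Clustal residue groups", {
  sym <- function(col) {
    aln <- SeqAlignment(setNames(col, paste0("r", seq_along(col))),
                        "amino-acid")
    conservationSymbols(aln)
  }
  expect_equal(sym(c("L", "L", "L")), "*")
  expect_equal(sym(c("I", "L", "V")), ":")   # MILV strong group
  expect_equal(sym(c("S", "A", "G")), ".")   # SAG weak group
  expect_equal(sym(c("D", "K")), ".")   # SNDEQK weak group
  expect_equal(sym(c("D", "W")), "•")   # no shared group
  expect_equal(sym(c("L", "-", "L")), "•")  # gap forces non-conservative
})

test_that("polymorphic calling uses a strict threshold", {
  prof <- data.frame(position = 1:3, viv = c(1, 3, 3.2))
  called <- callPolymorphic(prof, threshold = 3)
  expect_equal(called$position, 3)   # viv exactly 3 excluded
  empty <- callPolymorphic(data.frame(position = 1:5, viv = rep(1, 5)))
  expect_equal(nrow(empty), 0)
})

test_that("column profiles flag gap-heavy and empty columns", {
  aln <- SeqAlignment(c(a = "A-K", b = "A-K", c = "C--"), "amino-acid")
  prof <- columnProfiles(aln)
  expect_equal(prof$n_effective, c(3, 0, 2))
  expect_true(is.na(prof$viv[2]))
  expect_true(prof$low_confidence[2])
  expect_equal(prof$viv[1], 2 / (2 / 3))
})

test_that("hotspot positions are recovered as polymorphic across seeds", {
  hot <- c(5L, 20L, 40L, 60L, 85L)
  hits <- 0; total <- 0
  for (seed in 1:20) {
    cfg <- simConfig(
      species = data.frame(species = "one", family = "f", divergence = 0,
                           n_cultivars = 1L, clones_min = 30L,
                           clones_max = 30L),
      hotspot_codons = hot, background_sub_rate = 0.002,
      cultivar_sub_rate = 0, hotspot_sub_rate = 0.3,
      deletion_spec = data.frame(length = 9L, prob = 0, win_start = 10L,
                                 win_end = 60L),
      seed = seed)
    sim <- simulateFamily(cfg)
    prof <- columnProfiles(alnTranslate(truthAlignment(sim)))
    called <- callPolymorphic(prof)$position
    hits <- hits + sum(hot %in% called)
    total <- total + length(hot)
  }
  expect_gte(hits / total, 0.9)
})

test_that("the KIM window report catalogues substitutions and deletions", {
  ref <- translateCds(referenceCDS())
  v1 <- ref
  substr(v1, 79, 79) <- "A"     # Q -> A at 79
  substr(v1, 92, 92) <- "T"     # S -> T at 92
  v2 <- paste0(substr(ref, 1, 80), "---", substr(ref, 84, nchar(ref)))
  aln <- SeqAlignment(c(ref = ref, var = v1, del = v2), "amino-acid")
  rep <- kimReport(aln)
  expect_equal(rep$flagged_rows, "del")
  subs <- rep$substitutions[rep$substitutions$row_id == "var", ]
  expect_equal(subs$position, c(79, 92))
  expect_equal(subs$ref_aa, c("Q", "S"))
  expect_equal(subs$observed_aa, c("A", "T"))
  expect_equal(nrow(rep$substitutions[rep$substitutions$row_id == "ref", ]), 0)
})

test_that("planted KIM substitutions are recovered on simulated proteins", {
  sim <- simulateFamily(smallSimConfig(seed = 19, deletions = FALSE,
                                       hotspots = c(79L, 84L, 92L)))
  paln <- alnTranslate(truthAlignment(sim))
  rep <- kimReport(paln)
  ref_prot <- strsplit(translateCds(referenceCDS()), "")[[1]]
  mat <- alnMatrix(paln)
  for (i in seq_len(nrow(rep$substitutions))) {
    r <- rep$substitutions[i, ]
    expect_identical(unname(mat[r$row_id, r$position]), r$observed_aa)
    expect_identical(ref_prot[r$position], r$ref_aa)
  }
  # completeness: every within-window difference from the reference is listed
  want <- 78:98
  n_diff <- sum(t(mat[, want]) != ref_prot[want] & t(mat[, want]) != "-")
  expect_equal(nrow(rep$substitutions), n_diff)
})
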