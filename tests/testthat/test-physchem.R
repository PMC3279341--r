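# Frozen reference values computed with an independent implementation of the
# same published formulas (Expasy average masses, Bjellqvist pKa set,
# Kyte-Doolittle hydropathy, Guruprasad DIWV weights).
.frozen <- list(
  p1 = list(seq = "MSWQTYVDEHLMCEIEGHHL", mw = 2458.7461, pi = 4.7734,
            gravy = -0.43, ii = 51.785),
  p2 = list(seq = "ACDEFGHIKLMNPQRSTVWY", mw = 2395.7134, pi = 6.7846,
            gravy = -0.49, ii = 84.74),
  p3 = list(seq = "MKKLLVVAAIIFFGGSSTTYYWWCCPPHHRRDDEE", mw = 4157.7519,
            pi = 6.7008, gravy = -0.2142857, ii = 53.5657143),
  kim = list(seq = "IQGEAGAVIRGKKGSGGITIK", mw = 2040.3673, pi = 10.2897,
             gravy = -0.0619048, ii = -12.4476190))

test_that("molecular weight sums average residue masses plus one water", {
  expect_equal(molecularWeight("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_error(molecularWeight(""), "at least 1")
  expect_error(molecularWeight("AXA"), "non-standard")
  for (f in .frozen)
    expect_equal(molecularWeight(f$seq), f$mw, tolerance = 2e-5)
  # additivity under concatenation
  set.seed(5)
  for (i in 1:10) {
    a <- randomProtein(sample(3:40, 1)); b <- randomProtein(sample(3:40, 1))
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 18.01524,
                 tolerance = 1e-9)
  }
})

test_that("the isoelectric point is the root of the net charge", {
  expect_gt(isoelectricPoint("KKKKKKKK"), 10)
  expect_lt(isoelectricPoint("DDEEDDEE"), 4.6)
  for (f in .frozen)
    expect_equal(isoelectricPoint(f$seq), f$pi, tolerance = 0.01)
  set.seed(9)
  for (i in 1:20) {
    p <- randomProtein(sample(10:100, 1))
    pi <- isoelectricPoint(p)
    expect_lt(abs(netCharge(p, pi)), 1e-3)
    expect_gt(netCharge(p, pi - 1), 0)
    expect_lt(netCharge(p, pi + 1), 0)
  }
})

test_that("extinction coefficients follow Gill-von Hippel", {
  expect_equal(unname(extinction280("ACDE")), c(0, 0))
  expect_equal(unname(extinction280("WYCC")), c(6990, 6990 + 125))
  # the packaged profilin-like protein has 3 Cys: one cystine pair
  ref <- translateCds(referenceCDS())
  e <- extinction280(ref)
  expect_equal(unname(e["oxidized"] - e["reduced"]), 125)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravyIndex("A"), 1.8)
  expect_equal(gravyIndex("R"), -4.5)
  for (f in .frozen)
    expect_equal(gravyIndex(f$seq), f$gravy, tolerance = 1e-6)
})

test_that("the aliphatic index uses Ikai's mole-percent weights", {
  expect_equal(aliphaticIndex("AAAA"), 100)
  expect_equal(aliphaticIndex("V"), 290)
  expect_equal(aliphaticIndex("I"), 390)
  expect_equal(aliphaticIndex("AV"), 50 + 2.9 * 50)
})

test_that("the instability index applies the DIWV dipeptide weights", {
  expect_equal(instabilityIndex("AA"), 5 * 1.0)
  expect_equal(instabilityIndex("AC"), 5 * 44.94)
  expect_error(instabilityIndex("A"), "at least 2")
  for (f in .frozen)
    expect_equal(instabilityIndex(f$seq), f$ii, tolerance = 1e-6)
})

test_that("all six calculators agree with a direct re-derivation", {
  # independent in-test recomputation from the published constant tables
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  diwv <- read.delim(system.file("extdata", "diwv_guruprasad.tsv",
                                 package = "profvar"))
  set.seed(77)
  for (i in 1:50) {
    p <- randomProtein(sample(5:150, 1))
    ch <- strsplit(p, "")[[1]]
    expect_equal(molecularWeight(p), sum(masses[ch]) + 18.01524,
                 tolerance = 1e-9)
    expect_equal(gravyIndex(p), mean(kd[ch]), tolerance = 1e-12)
    x <- 100 * table(factor(ch, levels = names(masses))) / length(ch)
    expect_equal(aliphaticIndex(p),
                 unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"])),
                 tolerance = 1e-9)
    w <- mapply(function(a, b)
      diwv$weight[diwv$first == a & diwv$second == b],
      ch[-length(ch)], ch[-1])
    expect_equal(instabilityIndex(p), 10 / length(ch) * sum(w),
                 tolerance = 1e-9)
    nW <- sum(ch == "W"); nY <- sum(ch == "Y"); nC <- sum(ch == "C")
    expect_equal(unname(extinction280(p)),
                 c(5500 * nW + 1490 * nY,
                   5500 * nW + 1490 * nY + 125 * floor(nC / 2)))
  }
})

test_that("profile rows assemble correctly with the stability flag", {
  prof <- physchemProfile("IQGEAGAVIRGKKGSGGITIK")
  expect_true(prof$stable)   # negative instability index
  expect_equal(prof$length, 21)
  tab <- physchemTable(c(a = "MSWQTYVDEH", b = "IQGEAGAVIRGKKGSGGITIK"),
                       summary = TRUE)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$mw[3], mean(tab$mw[1:2]))
})
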