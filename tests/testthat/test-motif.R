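test_that("PROSITE parsing handles sets, negations, repeats and anchors", {
  p <- parsePrositePattern("N-{P}-[ST]-{P}")
  expect_length(p$elements, 4)
  expect_equal(p$elements[[1]]$type, "residue")
  expect_equal(p$elements[[3]]$chars, "ST")

  m <- parsePrositePattern("G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}")
  expect_length(m$elements, 5)
  expect_equal(m$elements[[3]]$min, 2)
  expect_equal(m$elements[[3]]$max, 2)

  v <- parsePrositePattern("[RK]-x(2,3)-[DE]")
  expect_equal(v$elements[[2]]$min, 2)
  expect_equal(v$elements[[2]]$max, 3)

  a <- parsePrositePattern("<M-x(4)-K>.")
  expect_true(a$nterm); expect_true(a$cterm)

  # canonical form round-trips
  for (txt in c("N-{P}-[ST]-{P}.", "<M-x(2,4)-[AC]>.", "x-G-[RK]-[RK]."))
    expect_equal(format(parsePrositePattern(txt)), txt)

  expect_error(parsePrositePattern("N--P"), "offset")
  expect_error(parsePrositePattern("N-[st]"), "cannot parse")
  expect_error(parsePrositePattern("A-x(3,2)"), "repetition")
})

test_that("variable repetitions match exactly the declared lengths", {
  # x(2,4) between anchors accepts only lengths 2-4, enumerated on {A,B}
  pat <- "<A-x(2,4)-B>."
  for (len in 0:6) {
    grid <- expand.grid(rep(list(c("A", "B")), len),
                        stringsAsFactors = FALSE)
    mids <- if (len == 0) "" else apply(grid, 1, paste, collapse = "")
    for (mid in unique(mids)) {
      s <- paste0("A", mid, "B")
      hit <- scanProsite(s, pat)
      expect_equal(nrow(hit) == 1, len >= 2 && len <= 4, info = s)
    }
  }
})

test_that("the compiled matcher agrees with a naive backtracking oracle", {
  set.seed(123)
  for (i in 1:120) {
    pat <- randomPattern()
    s <- paste(sample(c("A", "B", "C", "D"), sample(1:30, 1),
                      replace = TRUE), collapse = "")
    got <- scanProsite(s, pat)
    want <- naiveScan(s, pat)
    expect_equal(got$start, want$start, info = paste(pat, s))
    expect_equal(got$matched, want$matched, info = paste(pat, s))
  }
})

test_that("scanning reports overlapping hits at anchored positions", {
  expect_equal(nrow(scanProsite("", "N-{P}-[ST]-{P}")), 0)
  hits <- scanProsite("ASASAS", "[ST]-x-[ST]")
  expect_equal(hits$start, c(2, 4))   # overlapping starts both reported
  nov <- scanProsite("ASASAS", "[ST]-x-[ST]", non_overlapping = TRUE)
  expect_equal(nov$start, 2)

  # position completeness: removing a hit's first residue removes the hit
  s <- "KAEEGAYTIEDQLRSY"
  p <- "[RK]-x(2,3)-[DE]-x(2,3)-Y"
  h <- scanProsite(s, p)
  expect_gt(nrow(h), 0)
  for (i in seq_len(nrow(h))) {
    mut <- s
    substr(mut, h$start[i], h$start[i]) <- "G"
    expect_false(h$start[i] %in% scanProsite(mut, p)$start)
  }
})

test_that("planted motifs are recovered at their offsets in random proteins", {
  set.seed(11)
  bg <- setdiff(c("A","R","D","C","E","Q","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V"), c("N"))
  for (i in 1:100) {
    prot <- paste(sample(bg, 60, replace = TRUE), collapse = "")
    at <- sample(1:(60 - 3), 1)
    substr(prot, at, at + 3) <- "NGTM"
    hits <- scanProsite(prot, "N-{P}-[ST]-{P}")
    expect_true(at %in% hits$start)
  }
})

test_that("the packaged panel reproduces the designed reference motifs", {
  prot <- translateCds(referenceCDS())
  hits <- motifPanel(setNames(prot, "ref"))
  amid <- hits[hits$id == "PS00009", ]
  expect_equal(c(amid$start, amid$end), c(87, 90))
  expect_equal(amid$matched, "RGKK")
  myr <- hits[hits$id == "PS00008", ]
  expect_true(nrow(myr) >= 1 && nrow(myr) <= 4)
  expect_setequal(myr$start, c(30, 33, 67))
  # no glycosylation motif in the reference protein itself
  expect_equal(nrow(hits[hits$id == "PS00001", ]), 0)
  # a Blanqueta-style variant gains the N-glycosylation site at 51
  v <- prot
  substr(v, 51, 54) <- "NGTM"
  vh <- motifPanel(setNames(v, "v"))
  expect_equal(vh[vh$id == "PS00001", ]$start, 51)

  noG <- gsub("G", "A", prot)
  expect_equal(nrow(scanProsite(noG, "G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}")), 0)
})

test_that("phosphosite inventory counts deduplicated S/T/Y candidates", {
  none <- phosphoInventory(c(p = "GGAAGGVVLL"))
  expect_equal(unlist(none[, c("n_ser", "n_thr", "n_tyr")],
                      use.names = FALSE), c(0, 0, 0))

  prot <- translateCds(referenceCDS())
  inv <- phosphoInventory(setNames(prot, "ref"))
  sites <- attr(inv, "sites")
  expect_true(41 %in% sites$position[sites$residue == "S"])
  # toggling the serine removes exactly the sites at that position
  v <- prot
  substr(v, 41, 41) <- "A"
  inv2 <- phosphoInventory(setNames(v, "v"))
  lost <- sum(sites$residue == "S" & sites$position == 41)
  expect_equal(inv2$n_ser, inv$n_ser - lost)
  # counts stay in the ranges reported for pollen profilin panels
  expect_true(inv$n_ser >= 0 && inv$n_ser <= 2)
  expect_true(inv$n_thr >= 1 && inv$n_thr <= 4)
  expect_true(inv$n_tyr >= 1 && inv$n_tyr <= 3)
})

test_that("motif variability separates universal from polymorphic hits", {
  prot <- translateCds(referenceCDS())
  v <- prot
  substr(v, 41, 41) <- "A"
  hits <- motifPanel(c(a = prot, b = v))
  mv <- motifVariability(hits, 2)
  amid <- mv[mv$id == "PS00009" & mv$start == 87, ]
  expect_true(amid$universal)
  expect_true(any(!mv$universal))
})
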