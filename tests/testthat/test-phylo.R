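test_that("three taxa solve the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  expect_equal(ape::Ntip(tr), 3)
  cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-10)
  # closed form: x_a = (d_ab + d_ac - d_bc) / 2
  xa <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(xa, (0.3 + 0.5 - 0.4) / 2)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- true$edge.length + 0.05  # keep internal edges positive
    d <- ape::cophenetic.phylo(true)
    got <- njTree(d)
    expect_equal(ape::dist.topo(ape::unroot(true), got), 0,
                 ignore_attr = TRUE)
    cd <- ape::cophenetic.phylo(got)[rownames(d), colnames(d)]
    expect_equal(cd, d, tolerance = 1e-8)
  }
})

test_that("negative branch lengths are clamped and logged", {
  # a non-additive matrix that forces a negative NJ branch
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 2,
                9, 10, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 0.1; d["b", "a"] <- 0.1
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped") >= 0)
})

test_that("species clades are recovered from a simulated family", {
  sim <- simulateFamily(smallSimConfig(seed = 37, n_species = 5, clones = 4))
  paln <- alnTranslate(truthAlignment(sim))
  tr <- njTree(distanceFromIdentity(identityMatrix(paln)))
  rec <- cladeRecovery(tr, sim$samples)
  expect_equal(attr(rec, "fraction"), 1)
})

test_that("bootstrap supports are seeded, reproducible and sensible", {
  sim <- simulateFamily(smallSimConfig(seed = 43, n_species = 2, clones = 4,
                                       deletions = FALSE))
  paln <- alnTranslate(truthAlignment(sim))
  t1 <- bootstrapTree(paln, n_reps = 100, seed = 5)
  t2 <- bootstrapTree(paln, n_reps = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  t3 <- bootstrapTree(paln, n_reps = 100, seed = 6)
  expect_identical(writeNewick(t1), writeNewick(t1))
  # the two species are far apart: their bipartition is near-certain
  meta <- sampleMeta(sim$samples)
  tipsA <- meta$accession[meta$species == "sp1"]
  parts <- supportTable(t1)
  side <- vapply(strsplit(parts$tips, ";"), function(tp)
    setequal(tp, tipsA) ||
      setequal(tp, setdiff(meta$accession, tipsA)), logical(1))
  expect_true(any(side))
  expect_gte(as.numeric(parts$support[side][1]), 95)
})

test_that("bootstrap supports are stable under row permutation", {
  # tied resampled distances leave NJ joins to the documented
  # lowest-index rule, so replicate topologies can flip on permutation;
  # supports of the data tree's bipartitions must still agree closely and
  # fully supported splits exactly
  set.seed(48)
  sim <- simulateFamily(smallSimConfig(seed = 47, n_species = 3, clones = 3,
                                       deletions = FALSE,
                                       background = 0.04))
  paln <- alnTranslate(truthAlignment(sim))
  t1 <- bootstrapTree(paln, n_reps = 50, seed = 9)
  perm <- subsetAlignment(paln, sample(names(paln)))
  t2 <- bootstrapTree(perm, n_reps = 50, seed = 9)
  s1 <- supportTable(t1); s2 <- supportTable(t2)
  m <- merge(s1, s2, by = "tips")
  m$sx <- suppressWarnings(as.numeric(m$support.x))
  m$sy <- suppressWarnings(as.numeric(m$support.y))
  m <- m[!is.na(m$sx) & !is.na(m$sy), ]
  expect_gt(nrow(m), 0)
  expect_true(all(abs(m$sx - m$sy) <= 10))
  full1 <- s1$tips[suppressWarnings(as.numeric(s1$support)) %in% 100]
  full2 <- s2$tips[suppressWarnings(as.numeric(s2$support)) %in% 100]
  expect_identical(sort(full1), sort(full2))
})

test_that("identical sequences give a degenerate flagged tree", {
  aln <- SeqAlignment(setNames(rep("MKKLLVVAAIIFFGG", 4), paste0("r", 1:4)),
                      "amino-acid")
  tr <- bootstrapTree(aln, n_reps = 10, seed = 1)
  expect_true(attr(tr, "degenerate"))
  expect_true(all(as.numeric(tr$node.label) == 100))
})

test_that("Newick output is canonical and round-trips", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  tr <- njTree(d)
  nw <- writeNewick(tr)
  expect_match(nw, "^\\(")
  back <- ape::read.tree(text = nw)
  expect_equal(sort(back$tip.label), c("a", "b", "c"))
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)

  set.seed(53)
  for (i in 1:10) {
    t0 <- ape::rtree(20)
    nw1 <- writeNewick(t0)
    expect_identical(nw1, writeNewick(t0))
    back <- ape::read.tree(text = nw1)
    expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(t0)), 0,
                 ignore_attr = TRUE)
    # branch lengths preserved at 6 decimals
    cb <- ape::cophenetic.phylo(back)[t0$tip.label, t0$tip.label]
    ct <- ape::cophenetic.phylo(t0)
    expect_equal(cb, ct, tolerance = 1e-4)
  }

  f <- withr::local_tempfile()
  writeNewick(tr, f)
  expect_identical(readLines(f), nw)
})
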