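test_that("inner cube filter keeps the center and drops corners", {
  fr <- boundDimerFrame(box = 4)  # dimer near the box center
  expect_setequal(innerCubeIds(fr, 0.85), c(1, 2))
  ## a molecule hugging a corner is excluded for any fraction < 1
  pos <- array(0, c(1, 3, 4))
  pos[1, , ] <- .rigidSitesForTest() + c(0.05, 0.05, 0.05)
  corner <- waterFrame(pos, box = 4)
  expect_length(innerCubeIds(corner, 0.85), 0)
  expect_equal(innerCubeIds(corner, 1), 1L)
})

test_that("interference cylinder is finite and capped at the endpoints", {
  a <- c(0, 0, 0); b <- c(1, 0, 0)
  ## on-axis midpoint: blocked at any radius
  expect_true(cylinderBlocked(a, b, c(0.5, 0, 0), rc = 0.01))
  ## outside the radius
  expect_false(cylinderBlocked(a, b, c(0.5, 0.40, 0), rc = 0.3159))
  expect_true(cylinderBlocked(a, b, c(0.5, 0.30, 0), rc = 0.3159))
  ## on the axis line but beyond an endpoint: finite cylinder, not blocked
  expect_false(cylinderBlocked(a, b, c(1.5, 0, 0), rc = 0.3159))
  expect_false(cylinderBlocked(a, b, c(-0.2, 0, 0), rc = 0.3159))
  ## endpoints themselves project at t = 0 and t = 1 (strict interior)
  expect_false(cylinderBlocked(a, b, a, rc = 0.3159))
  expect_error(cylinderBlocked(a, a, c(0.5, 0, 0), rc = 0.1), "degenerate")
})

test_that("candidate pairs equal all-pairs enumeration on random frames", {
  fr <- randomTestFrame(200, box = 3.2, seed = 21)
  for (cutoff in c(0.4, 0.8)) {
    got <- candidatePairs(fr, cutoff = cutoff)
    want <- allPairsCandidates(fr, fr@ids, cutoff)
    expect_equal(unname(got), unname(want))
  }
  ## the cell-list branch (n > 400) agrees with the dense branch
  frBig <- generateWaterFrame(600, box = 4.4, temperature = 673, seed = 22,
                              minSep = 0.24)
  got <- candidatePairs(frBig, cutoff = 0.5)
  sub <- candidatePairs(frBig, ids = frBig@ids[1:300], cutoff = 0.5)
  wantSub <- allPairsCandidates(frBig, frBig@ids[1:300], 0.5)
  expect_equal(unname(sub), unname(wantSub))
  d2 <- {
    cm <- com(frBig)
    rowSums((cm[got[, 1], ] - cm[got[, 2], ])^2)
  }
  expect_true(all(d2 <= 0.5^2 + 1e-12))
})

test_that("simple candidate geometries behave as expected", {
  fr <- boundDimerFrame(dOO = 0.3)
  expect_equal(nrow(candidatePairs(fr, cutoff = 0.8)), 1)
  expect_equal(nrow(candidatePairs(fr, cutoff = 0.1)), 0)
})

test_that("a bound dimer yields exactly one edge under the calibrated criterion", {
  fr <- boundDimerFrame(dOO = 0.28)
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  net <- buildNetwork(fr, p)
  expect_equal(nrow(net@edges), 1)
  expect_lt(net@edges$total[1], 0)
  expect_setequal(interactingNodes(net), c(1, 2))
})

test_that("a third molecule on the pair axis removes the edge", {
  fr <- boundDimerFrame(dOO = 0.56, box = 6)
  p <- criterionParameters(lambda = 0, temperature = 673, pairCutoff = 1.0)
  ## insert a blocker at the midpoint of the COM-COM segment
  cm <- com(fr)
  mid <- (cm[1, ] + cm[2, ]) / 2
  pos <- array(0, c(3, 3, 4))
  pos[1:2, , ] <- fr@pos
  pos[3, , ] <- .rigidSitesForTest() + mid
  fr3 <- waterFrame(pos, box = 6)
  net <- buildNetwork(fr3, p)
  expect_false(any(net@edges$i == 1 & net@edges$j == 2))
  ## without the blocker (and lambda = 0) the pair is connected
  net2 <- buildNetwork(boundDimerFrame(dOO = 0.56, box = 6), p)
  expect_equal(nrow(net2@edges), 1)
})

test_that("removing third molecules can only add edges", {
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  fr <- randomTestFrame(60, box = 2.2, seed = 31)
  net <- buildNetwork(fr, p)
  key <- function(n) paste(n@edges$i, n@edges$j)
  ## drop a handful of molecules that are not endpoints of current edges
  involved <- unique(c(net@edges$i, net@edges$j))
  removable <- setdiff(fr@ids, involved)[1:5]
  keep <- !(fr@ids %in% removable)
  fr2 <- waterFrame(fr@pos[keep, , , drop = FALSE], fr@vel[keep, , , drop = FALSE],
                    box = fr@box, ids = fr@ids[keep], wrap = FALSE)
  net2 <- buildNetwork(fr2, p)
  expect_true(all(key(net) %in% key(net2)))
})

test_that("enlarging the candidate cutoff never changes the edge set", {
  p8 <- criterionParameters(lambda = 0.655, temperature = 673,
                            pairCutoff = 0.8)
  p12 <- criterionParameters(lambda = 0.655, temperature = 673,
                             pairCutoff = 1.2)
  for (seed in c(41, 42)) {
    fr <- randomTestFrame(50, box = 2.2, seed = seed)
    e8 <- buildNetwork(fr, p8)@edges
    e12 <- buildNetwork(fr, p12)@edges
    expect_equal(e8[order(e8$i, e8$j), ], e12[order(e12$i, e12$j), ],
                 ignore_attr = TRUE)
  }
})

test_that("the network is invariant under molecule relabeling", {
  fr <- randomTestFrame(40, box = 2.0, seed = 51)
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  net <- buildNetwork(fr, p)
  ## permute storage order and give new ids 101..140 following the permutation
  set.seed(1)
  perm <- sample(40)
  newIds <- integer(40)
  newIds[perm] <- 100L + seq_len(40)  # id of molecule perm[k] becomes 100+k
  fr2 <- waterFrame(fr@pos[perm, , , drop = FALSE],
                    fr@vel[perm, , , drop = FALSE],
                    box = fr@box, ids = newIds[perm], wrap = FALSE)
  net2 <- buildNetwork(fr2, p)
  mapEdge <- function(e, map) {
    a <- map[e$i]; b <- map[e$j]
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  map <- stats::setNames(newIds, fr@ids)
  expect_equal(mapEdge(net@edges, map),
               sort(paste(pmin(net2@edges$i, net2@edges$j),
                          pmax(net2@edges$i, net2@edges$j))))
})

test_that("rc = 0 disables blocking except for exactly on-axis third bodies", {
  fr <- randomTestFrame(50, box = 2.2, seed = 61)
  p0 <- criterionParameters(lambda = 0.655, temperature = 673, rc = 0)
  net0 <- buildNetwork(fr, p0)
  ## reproduce by skipping the cylinder filter entirely (random COMs are
  ## never exactly collinear)
  nodes <- innerCubeIds(fr, 0.85)
  prs <- candidatePairs(fr, nodes, 0.8)
  en <- pairEnergies(fr, prs)
  en$total <- criterionTotal(en$Vcoul, en$VLJ, en$Ekin, p0)
  en <- en[en$total < 0, ]
  expect_equal(nrow(net0@edges), nrow(en))
  expect_equal(net0@edges$total, en$total)
})

test_that("empty frames build empty networks", {
  fr <- waterFrame(array(0, c(0, 3, 4)), box = 3)
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  net <- buildNetwork(fr, p)
  expect_length(net@nodes, 0)
  expect_equal(nrow(net@edges), 0)
})

test_that("edge tables are written with 6-decimal energies", {
  fr <- boundDimerFrame(dOO = 0.28)
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  net <- buildNetwork(fr, p)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeTable(net, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab),
               c("i", "j", "V_coul", "V_LJ", "E_kin_pair", "criterion_total"))
  expect_equal(tab$V_coul, round(net@edges$Vcoul, 6))
})
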