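test_that("distribution error aligns on the union of sizes", {
  expect_equal(distributionError(c(`1` = 0.5, `2` = 0.5),
                                 c(`1` = 0.5, `2` = 0.5)),
               c(mae = 0, rmse = 0))
  err <- distributionError(c(`1` = 0.5, `2` = 0.5), c(`1` = 0.6, `2` = 0.4))
  expect_equal(unname(err), c(0.1, 0.1))
  ## disjoint supports align with zeros
  err <- distributionError(c(`1` = 1), c(`2` = 1))
  expect_equal(err[["mae"]], 1)
  ## symmetry
  a <- c(`1` = 0.7, `3` = 0.3); b <- c(`1` = 0.5, `2` = 0.5)
  expect_equal(distributionError(a, b), distributionError(b, a))
  expect_error(distributionError(numeric(), a), "non-empty")
})

test_that("curve agreement reproduces closed-form residual metrics", {
  x <- seq(0, 2 * pi, length.out = 50)
  obs <- sin(x) + 1
  m <- curveAgreement(obs, obs)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0)
  ## constant offset: mae = rmse = 0.1, R^2 from the closed form
  m <- curveAgreement(obs, obs + 0.1)
  expect_equal(m$mae, 0.1, tolerance = 1e-12)
  expect_equal(m$rmse, 0.1, tolerance = 1e-12)
  ssTot <- sum((obs - mean(obs))^2)
  expect_equal(m$r_squared, 1 - 0.01 * length(obs) / ssTot, tolerance = 1e-12)
  ## predicting the mean gives R^2 = 0
  m <- curveAgreement(obs, rep(mean(obs), length(obs)))
  expect_equal(m$r_squared, 0, tolerance = 1e-12)
  expect_error(curveAgreement(rep(1, 5), rep(1, 5)), "constant")
})

test_that("lambda calibration recovers the generating lambda with zero error", {
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  frames <- list(
    generateWaterFrame(120, box = 2.2, temperature = 673, seed = 301,
                       minSep = 0.24),
    generateWaterFrame(120, box = 2.2, temperature = 673, seed = 302,
                       minSep = 0.24))
  grid <- seq(0.2, 0.8, by = 0.1)
  for (lambda0 in c(0.3, 0.5, 0.7)) {
    pp <- criterionParameters(lambda = lambda0, temperature = 673)
    ref <- local({
      counts <- integer()
      for (fr in frames) {
        d <- componentSizeDistribution(buildNetwork(fr, pp))
        for (ix in seq_along(d@sizes)) {
          s <- as.character(d@sizes[ix])
          counts[s] <- (if (s %in% names(counts)) counts[[s]] else 0L) +
            d@counts[ix]
        }
      }
      counts / sum(counts)
    })
    cal <- calibrateLambda(frames, ref, grid = grid, params = p)
    expect_equal(cal@lambdaStar, lambda0)
    expect_equal(cal@maeStar, 0)
  }
})

test_that("a graded dimer sweep pins the calibrated lambda uniquely", {
  ## O-O spacings sweeping 0.27-0.75 nm give pair energies covering the
  ## threshold range densely, so the MAE minimum is unique on the grid
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  sweep <- plantedClusterFrame(c(`2` = 80),
                               spacing = seq(0.27, 0.75, length.out = 80),
                               seed = 901)
  for (lambda0 in c(0.3, 0.65)) {
    pp <- criterionParameters(lambda = lambda0, temperature = 673)
    ref <- fractions(componentSizeDistribution(buildNetwork(sweep$frame, pp)))
    cal <- calibrateLambda(list(sweep$frame), ref,
                           grid = seq(0.1, 0.9, by = 0.05), params = p)
    expect_equal(cal@lambdaStar, lambda0)
    expect_equal(cal@maeStar, 0)
    expect_equal(sum(cal@mae == 0), 1)  # unique zero
  }
})

test_that("pooled edge counts are non-increasing along an increasing lambda grid", {
  fr <- randomTestFrame(80, box = 2.4, seed = 401)
  base <- criterionParameters(lambda = 0, temperature = 673)
  grid <- seq(0, 1.2, by = 0.2)
  edges <- vapply(grid, function(l) {
    p <- criterionParameters(lambda = l, temperature = 673)
    nrow(buildNetwork(fr, p)@edges)
  }, numeric(1))
  expect_true(all(diff(edges) <= 0))
})

test_that("a single-point grid returns that lambda trivially", {
  fr <- randomTestFrame(40, box = 2.0, seed = 402)
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  cal <- calibrateLambda(list(fr), c(`1` = 1), grid = 0.655, params = p)
  expect_equal(cal@lambdaStar, 0.655)
})

test_that("frame flattening yields 12 columns per molecule", {
  fr <- randomTestFrame(7, box = 2, seed = 403)
  expect_length(flattenFrame(fr), 7 * 12)
  ## the layout scales to the production system size
  expect_equal(8544 * 12, 102528)
})

test_that("representative-frame selection finds the cloud center", {
  base <- generateWaterFrame(30, box = 2.2, temperature = 673, seed = 501,
                             minSep = 0.24)
  jitterFrame <- function(fr, sd, seed) {
    set.seed(seed)
    fr@pos <- fr@pos + array(rnorm(length(fr@pos), sd = sd), dim(fr@pos))
    fr
  }
  frames <- c(lapply(1:10, function(k) jitterFrame(base, 0.01, k)),
              list(jitterFrame(base, 1.0, 99)))  # far outlier last
  for (n in c(1, 3, 10)) {
    sel <- selectRepresentativeFrames(frames, n = n)
    expect_false(11 %in% sel)
    expect_length(sel, n)
  }
  ## identical frames: degenerate cloud, first n indices
  same <- replicate(5, base, simplify = FALSE)
  expect_equal(selectRepresentativeFrames(same, 3), 1:3)
  ## n = number of frames returns everything
  expect_setequal(selectRepresentativeFrames(frames, 11), 1:11)
  expect_warning(selectRepresentativeFrames(frames[1:2], 5), "exceeds")
})

test_that("frame selection is invariant under a rigid translation of all frames", {
  frames <- lapply(1:6, function(k)
    generateWaterFrame(20, box = 2.4, temperature = 673, seed = 600 + k,
                       minSep = 0.24))
  shift <- function(fr, v) {
    fr@pos <- fr@pos + rep(v, each = dim(fr@pos)[1])
    fr
  }
  moved <- lapply(frames, shift, v = c(0.3, -0.2, 0.1))
  expect_equal(selectRepresentativeFrames(frames, 3),
               selectRepresentativeFrames(moved, 3))
})

test_that("component descriptors summarize edge lengths and energies", {
  p <- criterionParameters(lambda = 0.655, temperature = 673)
  pl <- plantedClusterFrame(c(`2` = 1, `3` = 1), spacing = 0.28, seed = 71)
  net <- buildNetwork(pl$frame, p)
  desc <- componentDescriptors(net, pl$frame)
  expect_equal(nrow(desc), 2)
  expect_setequal(desc$size, c(2, 3))
  d2 <- desc[desc$size == 2, ]
  expect_equal(d2$sumLength, 0.28, tolerance = 1e-9)
  expect_equal(d2$sdLength, 0)  # single-edge component
  expect_equal(d2$sdEnergy, 0)
  d3 <- desc[desc$size == 3, ]
  expect_equal(d3$sumLength, 2 * 0.28, tolerance = 1e-9)
  expect_equal(d3$topology, "linear")
})

test_that("representative components match a no-PCA nearest-centroid oracle", {
  set.seed(81)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    desc <- data.frame(id = sample(1000, n), size = 3,
                       topology = "linear",
                       sumLength = runif(n, 0.5, 0.9),
                       sdLength = runif(n, 0, 0.05),
                       meanEnergy = runif(n, -30, -15),
                       sdEnergy = runif(n, 0, 4))
    got <- selectRepresentativeComponent(desc)
    M <- scale(as.matrix(desc[, c("sumLength", "sdLength",
                                  "meanEnergy", "sdEnergy")]))
    d <- sqrt(rowSums(M^2))
    want <- desc$id[order(d, desc$id)][1]
    expect_equal(got, want)
  }
  ## single candidate is its own representative
  expect_equal(selectRepresentativeComponent(data.frame(
    id = 5, size = 2, topology = "linear", sumLength = 0.28,
    sdLength = 0, meanEnergy = -20, sdEnergy = 0)), 5)
})
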