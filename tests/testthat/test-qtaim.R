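test_that("potential energy density satisfies V = -G - K", {
  expect_equal(potentialEnergyDensity(1.0, 0.5), -1.5)
  expect_equal(potentialEnergyDensity(0, 0), 0)
  set.seed(9)
  G <- runif(20, 0, 2); K <- rnorm(20)
  expect_equal(potentialEnergyDensity(G, K) + G + K, rep(0, 20))
  expect_error(potentialEnergyDensity(-0.1, 0), "non-negative")
})

test_that("BCP tables derive the missing member of {K, V} and validate triples", {
  df <- bcpTable(data.frame(rho = 0.01, laplacian = 0.05, G = 1.0, K = 0.5))
  expect_equal(df$V, -1.5)
  expect_equal(df$H, -0.5)
  df <- bcpTable(data.frame(rho = 0.01, laplacian = 0.05, G = 1.0, V = -1.5))
  expect_equal(df$K, 0.5)
  expect_error(
    bcpTable(data.frame(rho = 0.01, laplacian = 0.05, G = 1.0, K = 0.5,
                        V = -1.4)),
    "inconsistent")
  expect_error(
    bcpTable(data.frame(rho = 0.01, laplacian = 0.05, G = -1, K = 0.5)),
    "G must be")
})

test_that("BCP tables round-trip through CSV", {
  tab <- syntheticBcpTable(25, c(noncovalent = 0.6, partially_covalent = 0.3,
                                 covalent = 0.1), seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  writeBcpTable(tab[, c("rho", "laplacian", "G", "K", "V")], path)
  back <- readBcpTable(path)
  expect_equal(back$rho, tab$rho)
  expect_equal(back$V, tab$V)
  expect_equal(back$label, tab$label)
  ## tab-separated input is auto-detected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[, c("rho", "laplacian", "G", "K")], path2,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- readBcpTable(path2)
  expect_equal(back2$V, tab$V)
})

test_that("the sign rules classify the three interaction regimes", {
  got <- classifyBcp(laplacian = 0.08, G = 0.01, V = -0.008)   # H = +0.002
  expect_equal(got$label, "noncovalent")
  got <- classifyBcp(laplacian = 0.10, G = 0.02, V = -0.025)   # H = -0.005
  expect_equal(got$label, "partially_covalent")
  got <- classifyBcp(laplacian = -0.5, G = 0.05, V = -0.30)    # H = -0.25
  expect_equal(got$label, "covalent")
  ## inconsistent region flagged, not raised
  got <- classifyBcp(laplacian = -0.5, G = 0.05, V = -0.03)    # H = +0.02
  expect_true(got$inconsistent)
  expect_true(is.na(got$label))
  ## zero laplacian falls back to the -G/V ratio
  got <- classifyBcp(laplacian = 0, G = 0.03, V = -0.02)       # ratio 1.5
  expect_equal(got$label, "noncovalent")
  got <- classifyBcp(laplacian = 0, G = 0.03, V = -0.04)       # ratio 0.75
  expect_equal(got$label, "partially_covalent")
  got <- classifyBcp(laplacian = 0, G = 0.03, V = -0.08)       # ratio 0.375
  expect_equal(got$label, "covalent")
})

test_that("classification is invariant under positive rescaling of (G, K, V)", {
  tab <- syntheticBcpTable(60, c(noncovalent = 0.5, partially_covalent = 0.3,
                                 covalent = 0.2), seed = 11)
  for (c_ in c(0.1, 3, 1000)) {
    got <- classifyBcp(tab$laplacian, c_ * tab$G, c_ * tab$V)
    expect_equal(got$label, tab$label)
  }
})

test_that("sign rule and ratio rule agree when the Laplacian is positive", {
  ## for V < 0: ratio > 1  <=>  H = G + V > 0
  set.seed(12)
  G <- runif(200, 0.001, 0.2)
  H <- runif(200, -0.1, 0.1)
  keep <- abs(H) > 1e-6 & H < G  # V = H - G < 0, H bounded away from 0
  G <- G[keep]; H <- H[keep]
  V <- H - G
  lap <- runif(length(G), 0.01, 0.5)
  signRule <- classifyBcp(lap, G, V)$label
  ratio <- -G / V
  ## with V < 0, ratio > 1 is algebraically equivalent to H > 0, so the
  ## two rules agree on the noncovalent boundary
  expect_equal(signRule == "noncovalent", ratio > 1)
  expect_equal(ratio > 1, H > 0)
})

test_that("class summaries give percentages per group that sum to 100", {
  labels <- c(rep("noncovalent", 179), rep("partially_covalent", 21))
  s <- summarizeClasses(labels)
  expect_equal(s$percent[s$label == "partially_covalent"], 10.5)
  expect_equal(sum(s$percent), 100)
  groups <- rep(c("3:Linear", "4:Linear"), each = 100)
  s2 <- summarizeClasses(labels[sample(200)], groups)
  for (g in unique(groups)) {
    expect_equal(sum(s2$percent[s2$group == g]), 100)
  }
  expect_error(summarizeClasses(character()), "no records")
})

test_that("ground-truth labels are recovered on synthetic BCP mixtures", {
  tab <- syntheticBcpTable(200, c(noncovalent = 0.9, partially_covalent = 0.1,
                                  covalent = 0), seed = 13)
  expect_equal(tab$label, tab$trueLabel)
  expect_false(any(tab$inconsistent))
  s <- summarizeClasses(tab$label)
  expect_equal(s$percent[s$label == "partially_covalent"], 10)
  ## generated records always pass the consistency checks
  expect_silent(bcpTable(tab[, c("rho", "laplacian", "G", "K", "V")]))
  expect_equal(nrow(syntheticBcpTable(0)), 0)
})

test_that("group comparison detects real shifts and not identical groups", {
  set.seed(14)
  same <- list(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(3, 4, 1, 2))
  expect_gt(compareGroups(same)$p.value, 0.9)
  shifted <- list(rnorm(20, 0), rnorm(20, 10))
  expect_lt(compareGroups(shifted)$p.value, 0.05)
  expect_lt(compareGroups(shifted, method = "anova")$p.value, 0.05)
  expect_error(compareGroups(list(rnorm(5))), "2 groups")
  expect_error(compareGroups(list(rnorm(5), 1)), "at least 2 observations")
  expect_warning(p1 <- compareGroups(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(p1$p.value, 1)
})
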