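test_that("relative abundance normalises samples to 1", {
  expect_equal(relativeAbundance(matrix(c(2, 2), 1)), matrix(c(0.5, 0.5), 1))
  expect_equal(as.numeric(relativeAbundance(matrix(c(1, 2, 7), 1))),
               c(0.1, 0.2, 0.7))
  expect_equal(as.numeric(relativeAbundance(matrix(5, 1))), 1)
  ae <- simulateCommunity(nDonors = 2, nGenera = 4, depth = 100, seed = 1)
  expect_true(all(abs(colSums(relativeAbundance(ae)) - 1) < 1e-12))
})

test_that("enrichment factor matches the closed form and its conventions", {
  expect_equal(enrichmentFactor(0.3, 0.3), 0)
  expect_equal(enrichmentFactor(0.5, 0), 1)
  expect_equal(enrichmentFactor(0, 0.5), -1)
  expect_equal(enrichmentFactor(0, 0), 0) # 0/0 convention
  expect_equal(enrichmentFactor(0.02, 0.04), -1 / 3)
  expect_error(enrichmentFactor(-0.1, 0.2), "non-negative")
})

test_that("enrichment factor is antisymmetric and monotone in the treated abundance", {
  set.seed(3)
  a <- runif(100)
  b <- runif(100)
  expect_equal(enrichmentFactor(a, b), -enrichmentFactor(b, a))
  b0 <- 0.2
  efs <- enrichmentFactor(sort(runif(50)), b0)
  expect_true(all(diff(efs) >= 0))
  expect_true(all(abs(enrichmentFactor(a, b)) <= 1))
})

test_that("EF tables pair each donor's treated sample with its matched control", {
  cnt <- matrix(rep(c(10L, 30L, 60L), 4), nrow = 3) # treated == control
  ae <- pairedAbundance(cnt, nDonors = 2)
  efs <- efTable(ae, "AG", 6)
  expect_true(all(efs$ef == 0))
  expect_equal(nrow(efs), 3 * 2)
  # a missing donor pair is reported by donor
  meta <- data.frame(donor = c("D1", "D1", "D2"),
                     treatment = c("AG", "NA", "AG"), timepoint = 6)
  ae2 <- AbundanceExperiment(matrix(1L, 2, 3), meta)
  expect_error(efTable(ae2, "AG", 6), "D2")
})

test_that("EF cancels across donors with opposite responses", {
  # one genus: donor 1 treated 3x control, donor 2 treated 1/3 of control
  cnt <- matrix(c(30L, 70L, 10L, 90L, 10L, 90L, 30L, 70L), nrow = 2)
  ae <- pairedAbundance(cnt, nDonors = 2)
  efs <- efTable(ae, "AG", 6)
  g1 <- efs$ef[efs$genus == rownames(ae)[1]]
  expect_equal(g1[1], -g1[2])
  expect_equal(mean(g1), 0)
})

test_that("planted genera get the largest mean EF", {
  ae <- simulateCommunity(nDonors = 6, nGenera = 10, depth = 20000,
                          enrichedGenera = 4, effectMultiplier = 4,
                          timepoints = 6, seed = 2)
  efs <- efTable(ae, "AG", 6)
  means <- tapply(efs$ef, efs$genus, mean)
  expect_identical(unname(which.max(means)), 4L)
})

test_that("enrichment calls combine the z statistic, BH adjustment and the EF sign", {
  null <- data.frame(genus = rep(c("g1", "g2"), each = 3),
                     donor = rep(c("a", "b", "c"), 2), ef = 0)
  calls <- callEnrichment(null)
  expect_false(any(calls$enriched))
  expect_true(all(calls$p == 1))
  # unanimous strong effect: SD floor keeps z finite and extreme
  strong <- data.frame(genus = "g1", donor = letters[1:10], ef = 0.9)
  res <- callEnrichment(strong)
  expect_true(is.finite(res$z) && res$z > 1e6)
  expect_true(res$enriched)
  # consistent depletion is significant but never called enriched
  depleted <- data.frame(genus = "g1", donor = letters[1:5],
                         ef = c(-0.5, -0.6, -0.4, -0.55, -0.45))
  expect_false(callEnrichment(depleted)$enriched)
  expect_error(callEnrichment(data.frame(genus = "g", donor = "a", ef = 1)),
               "2 donors")
})

test_that("Benjamini-Hochberg matches the hand-computed step-up and is monotone", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(30)
  adj <- benjaminiHochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
})

test_that("Bray-Curtis matches the formula and vegan", {
  expect_equal(brayCurtis(c(1, 2), c(1, 2)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 1)
  expect_equal(brayCurtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(8)
  x <- matrix(runif(40), 5)
  d <- as.matrix(brayCurtisMatrix(x))
  expect_equal(d[2, 4], brayCurtis(x[2, ], x[4, ]), tolerance = 1e-12)
})

test_that("permanova agrees with vegan::adonis2 on sums of squares, R2 and F", {
  set.seed(42)
  x <- matrix(rgamma(12 * 5, 2), 12)
  x <- x / rowSums(x)
  meta <- data.frame(donor = rep(c("a", "b", "c"), each = 4),
                     treatment = rep(c("T", "C"), 6))
  d <- brayCurtisMatrix(x)
  mine <- permanova(d, meta, c("donor", "treatment"), nPerm = 99, seed = 1)
  ref <- as.data.frame(vegan::adonis2(d ~ donor + treatment, data = meta,
                                      permutations = 99, by = "terms"))
  expect_equal(mine$sum_sq, ref$SumOfSqs, tolerance = 1e-10)
  expect_equal(mine$r2, ref$R2, tolerance = 1e-10)
  expect_equal(mine$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(sum(mine$r2[1:3]), 1, tolerance = 1e-9)
  expect_gte(min(mine$p, na.rm = TRUE), 1 / 100)
})

test_that("permanova validates its inputs", {
  d <- dist(matrix(rnorm(12), 6))
  meta <- data.frame(g = rep("x", 6))
  expect_error(permanova(d, meta, "g", nPerm = 99), "single level")
  meta2 <- data.frame(g = rep(c("x", "y"), 3))
  expect_error(permanova(d, meta2, "g", nPerm = 9), ">= 99")
  expect_error(permanova(matrix(1:9, 3), meta2[1:3, , drop = FALSE], "g",
                         nPerm = 99), "symmetric")
})

test_that("PCoA recovers collinear spacing, degenerate and Euclidean geometries", {
  # three collinear points at 0, 1, 2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  ord <- pcoaOrdination(d)
  expect_equal(ncol(ord$points), 1)
  x <- sort(ord$points[, 1])
  expect_equal(diff(x), c(1, 1), tolerance = 1e-9)
  # identical samples: no positive axes
  expect_equal(ncol(pcoaOrdination(matrix(0, 4, 4))$points), 0)
  # round trip for a Euclidean-embeddable matrix
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- dist(pts)
  rec <- pcoaOrdination(d2)$points[, 1:2]
  expect_equal(as.numeric(dist(rec)), as.numeric(d2), tolerance = 1e-6)
})
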