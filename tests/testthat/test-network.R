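test_that("Pearson matrix has unit diagonal and exact linear relations", {
  d <- data.frame(x = c(1, 2, 3, 4, 5))
  d$y <- 2 * d$x + 3
  d$z <- c(2, 1, 4, 3, 5)
  pm <- pearsonMatrix(d)
  expect_equal(diag(pm$r), c(x = 1, y = 1, z = 1))
  expect_equal(pm$r["x", "y"], 1, tolerance = 1e-12)
  expect_lt(pm$p["x", "z"], 1)
})

test_that("independent traits have small null correlations at panel size", {
  set.seed(61)
  d <- as.data.frame(matrix(rnorm(276 * 10), 276, 10))
  pm <- pearsonMatrix(d)
  off <- abs(pm$r[upper.tri(pm$r)])
  expect_gte(mean(off < 0.2), 0.95)
})

test_that("PCA matches the two-variable closed form and reconstructs exactly", {
  X <- exactCorrData(100, matrix(c(1, 0.8, 0.8, 1), 2), seed = 62)
  pca <- pcaTraits(X)
  expect_equal(pca$explained_variance_pct[1], 90, tolerance = 1e-8)
  expect_equal(unname(pca$contributions_pct[, 1]), c(50, 50),
               tolerance = 1e-8)
  expect_equal(sum(pca$explained_variance_pct), 100, tolerance = 1e-8)
  expect_equal(colSums(pca$contributions_pct),
               setNames(c(100, 100), c("PC1", "PC2")), tolerance = 1e-8)
  # orthogonal rotation of scores reproduces the standardized data
  Z <- scale(as.matrix(X))
  rec <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(rec - Z)), 1e-10)
})

test_that("constant columns are rejected under scaling by name", {
  d <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_error(pcaTraits(d), "b")
})

test_that("partial correlations match closed forms and the regression oracle", {
  # all pairwise r = 0.5: every partial correlation is 0.25/0.75 = 1/3
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  X3 <- exactCorrData(60, R3, seed = 63)
  net <- ggmNetwork(X3, trait_cols = names(X3))
  off <- net$pcor[upper.tri(net$pcor)]
  expect_equal(off, rep(1 / 3, 3), tolerance = 1e-8)

  # explaining away: x,y independent but both feed z
  set.seed(64)
  x <- rnorm(400); y <- rnorm(400); z <- x + y + rnorm(400, sd = 0.5)
  netz <- ggmNetwork(data.frame(x = x, y = y, z = z),
                     trait_cols = c("x", "y", "z"))
  expect_lt(netz$pcor["x", "y"], 0)

  # two variables: partial correlation equals Pearson r
  d2 <- data.frame(a = rnorm(50))
  d2$b <- d2$a + rnorm(50)
  net2 <- ggmNetwork(d2, trait_cols = c("a", "b"))
  expect_equal(net2$pcor["a", "b"], cor(d2$a, d2$b), tolerance = 1e-10)

  # recursive regression-residual definition on a 5-variable instance
  set.seed(65)
  X5 <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  X5$V2 <- X5$V1 + 0.5 * X5$V3 + rnorm(200, sd = 0.7)
  net5 <- ggmNetwork(X5, trait_cols = names(X5))
  for (pair in list(c(1, 2), c(2, 3), c(4, 5))) {
    others <- setdiff(1:5, pair)
    rx <- residuals(lm(X5[[pair[1]]] ~ as.matrix(X5[others])))
    ry <- residuals(lm(X5[[pair[2]]] ~ as.matrix(X5[others])))
    expect_equal(net5$pcor[pair[1], pair[2]], cor(rx, ry),
                 tolerance = 1e-8)
  }
})

test_that("centrality matches hand-computed graphs", {
  mkNet <- function(adj, val = 0.5) {
    pc <- adj * val
    diag(pc) <- 1
    structure(list(pcor = pc, traits = rownames(pc), jitter = 0),
              class = "ggm_network")
  }
  # path A-B-C
  adj <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  adj["A", "B"] <- adj["B", "A"] <- adj["B", "C"] <- adj["C", "B"] <- 1
  cen <- networkCentrality(mkNet(adj), cutoff = 0.15)$centrality
  expect_equal(cen$betweenness, c(0, 1, 0))
  expect_equal(cen$outdegree, c(1L, 2L, 1L))
  # complete graph on 4 nodes
  adj4 <- matrix(1, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2)); diag(adj4) <- 0
  cen4 <- networkCentrality(mkNet(adj4), cutoff = 0.15)$centrality
  expect_true(all(cen4$betweenness == 0))
  expect_true(all(cen4$outdegree == 3L))
  # star with 5 leaves: hub betweenness = choose(5, 2)
  nm <- c("hub", paste0("L", 1:5))
  adjs <- matrix(0, 6, 6, dimnames = list(nm, nm))
  adjs["hub", -1] <- adjs[-1, "hub"] <- 1
  cens <- networkCentrality(mkNet(adjs), cutoff = 0.15)$centrality
  expect_equal(cens$outdegree[cens$trait == "hub"], 5L)
  expect_equal(cens$betweenness[cens$trait == "hub"], 10)
})

test_that("raising the cutoff never increases outdegree", {
  set.seed(66)
  X <- as.data.frame(matrix(rnorm(80 * 6), 80, 6))
  X$V2 <- X$V1 + rnorm(80, sd = 0.8)
  net <- ggmNetwork(X, trait_cols = names(X))
  prev <- rep(Inf, 6)
  for (cut in c(0.05, 0.15, 0.3, 0.6)) {
    deg <- networkCentrality(net, cut)$centrality$outdegree
    expect_true(all(deg <= prev))
    prev <- deg
  }
})
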