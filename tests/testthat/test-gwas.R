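test_that("marker QC applies strict missingness and MAF rules", {
  dosage <- rbind(
    m1 = c(rep(NA, 6), 0, 1, 2, 0),        # 60% missing -> dropped
    m2 = c(rep(NA, 5), 0, 1, 2, 0, 1),     # exactly 50% missing -> kept
    m3 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),  # MAF 0.05 exactly -> kept
    m4 = rep(0, 10),                       # monomorphic -> dropped
    m5 = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0))
  geno <- makeGenotypeData(t(dosage), data.frame(
    marker_id = rownames(dosage), chromosome = "chr1",
    position_bp = seq(100, 500, by = 100)))
  f <- filterMarkers(geno)
  expect_setequal(rownames(f), c("m2", "m3", "m5"))
  qc <- S4Vectors::metadata(f)$filter
  expect_equal(qc$n_missing_dropped, 1L)
  expect_equal(qc$n_maf_dropped, 1L)
  # idempotent
  f2 <- filterMarkers(f)
  expect_identical(dosages(f2), dosages(f))
  expect_error(filterMarkers(geno, min_maf = 0.49), "all markers")
})

test_that("the centered kinship matrix has its algebraic properties", {
  geno <- smallPanel$geno
  K <- smallPanel$K
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # mean diagonal equals mean per-marker dosage variance (1/n convention)
  d <- t(dosages(geno))                  # markers x genotypes
  na <- which(is.na(d), arr.ind = TRUE)
  d[na] <- rowMeans(d, na.rm = TRUE)[na[, 1]]
  W <- sweep(t(d), 2, rowMeans(d))       # centered genotypes x markers
  vars <- apply(W, 2, function(x) mean(x^2))
  expect_equal(mean(diag(K)), mean(vars), tolerance = 1e-10)
  # duplicated genotype rows produce identical kinship rows
  dd <- dosages(geno)[c(1, 1, 2:10), ]
  rownames(dd) <- sprintf("G%02d", 1:11)
  K2 <- relatednessMatrix(makeGenotypeData(dd, markerMap(geno)))
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)
})

test_that("with identity kinship the scan equals plain regression Wald tests", {
  geno <- smallPanel$geno
  n <- ncol(geno)
  set.seed(51)
  y <- setNames(rnorm(n), colnames(geno))
  KI <- diag(n); dimnames(KI) <- list(colnames(geno), colnames(geno))
  res <- lmmScan(y, geno, K = KI)
  W <- dosages(geno)
  for (j in c(3, 57, 101)) {
    x <- W[names(y), j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    cf <- summary(lm(y ~ x))$coefficients
    p_lm <- pchisq((cf[2, 1] / cf[2, 2])^2, 1, lower.tail = FALSE)
    expect_equal(res$p_value[j], p_lm, tolerance = 1e-6)
  }
})

test_that("exact per-marker REML agrees closely with the null-reuse scan", {
  geno <- smallPanel$geno
  set.seed(52)
  u <- drop(t(chol(smallPanel$K + diag(1e-6, ncol(geno)))) %*%
              rnorm(ncol(geno)))
  y <- setNames(u + rnorm(ncol(geno)), colnames(geno))
  r1 <- lmmScan(y, geno, K = smallPanel$K, per_marker = "null")
  r2 <- lmmScan(y, geno, K = smallPanel$K, per_marker = "exact")
  expect_gt(cor(r1$minus_log10_p, r2$minus_log10_p,
                use = "complete.obs"), 0.999)
  expect_lt(max(abs(r1$minus_log10_p - r2$minus_log10_p), na.rm = TRUE),
            0.25)
})

test_that("the multivariate scan reduces exactly to the univariate at d = 1", {
  geno <- smallPanel$geno
  set.seed(53)
  y <- setNames(rnorm(ncol(geno)), colnames(geno))
  uni <- lmmScan(y, geno, K = smallPanel$K)
  mv <- mvLmmScan(matrix(y, ncol = 1, dimnames = list(names(y), "t")),
                  geno, K = smallPanel$K)
  expect_equal(mv$p_value, uni$p_value, tolerance = 1e-6)
})

test_that("Wald statistics are invariant to trait order", {
  geno <- smallPanel$geno
  st <- simulateTraits(geno, sigma_g2 = 1, sigma_e2 = 2, n_traits = 3,
                       genetic_corr = diag(3) * 0.5 + 0.5, seed = 54)
  gm <- genotypeMeans(st$plants)
  Y <- as.matrix(gm[c("trait_01", "trait_02", "trait_03")])
  rownames(Y) <- gm$genotype_id
  a <- mvLmmScan(Y, geno, K = smallPanel$K)
  b <- mvLmmScan(Y[, c(3, 1, 2)], geno, K = smallPanel$K)
  expect_equal(a$stat, b$stat, tolerance = 1e-3)
})

test_that("duplicated traits in a set trigger the singularity warning", {
  geno <- smallPanel$geno
  set.seed(55)
  y <- rnorm(ncol(geno))
  Y <- cbind(t1 = y, t2 = y)
  rownames(Y) <- colnames(geno)
  w <- capture_warnings(mvLmmScan(Y, geno, K = smallPanel$K))
  expect_true(any(grepl("singular|duplicate", w)))
})

test_that("a pleiotropic QTL is more detectable jointly than singly", {
  # antagonistic effects on a positively correlated trait pair: the
  # setting where joint modelling is known to add power over the best
  # single-trait scan
  wins <- vapply(1:9, function(s) {
    g <- simulateGenotypes(SimulationConfig(n_genotypes = 150,
                                            n_markers = 60,
                                            missing_rate = 0,
                                            seed = 500 + s))
    W <- dosages(g)
    mk <- which.max(mafs(g))
    x <- W[, mk]
    set.seed(600 + s)
    b <- 0.3
    R <- matrix(c(1, 0.7, 0.3, 0.7, 1, 0.3, 0.3, 0.3, 1), 3)
    E <- matrix(rnorm(150 * 3), 150) %*% chol(R)
    Y <- cbind(t1 = x * b + E[, 1],
               t2 = -x * b + E[, 2],
               t3 = E[, 3])
    rownames(Y) <- rownames(W)
    K <- relatednessMatrix(g)
    mv <- suppressWarnings(mvLmmScan(Y, g, K = K))
    best_uni <- max(vapply(1:3, function(k) {
      suppressWarnings(
        lmmScan(setNames(Y[, k], rownames(Y)), g,
                K = K)$minus_log10_p[mk])
    }, numeric(1)))
    mv$minus_log10_p[mk] > best_uni
  }, logical(1))
  expect_gte(sum(wins), 5)
})

test_that("PC-GWAS labels scans and matches the degenerate single-trait case", {
  geno <- smallPanel$geno
  st <- simulateTraits(geno, sigma_g2 = 1, sigma_e2 = 2, n_traits = 12,
                       seed = 56)
  gm <- genotypeMeans(st$plants)
  pca <- pcaTraits(gm)
  res <- pcGwas(pca, geno, K = smallPanel$K, n_pcs = 10)
  expect_setequal(unique(res$trait), paste0("PC", 1:10))
  expect_true(all(res$model == "pc"))
  # degenerate "PCA" whose scores are a single trait
  fake <- pca
  fake$scores <- matrix(gm$trait_01, ncol = 1,
                        dimnames = list(gm$genotype_id, "PC1"))
  r_pc <- pcGwas(fake, geno, K = smallPanel$K, n_pcs = 1)
  r_tr <- lmmScan(setNames(gm$trait_01, gm$genotype_id), geno,
                  K = smallPanel$K)
  expect_equal(r_pc$p_value, r_tr$p_value, tolerance = 1e-10)
})

test_that("significance flags honour the inclusive raw threshold and BH", {
  res <- data.frame(marker_id = sprintf("m%d", 1:1000),
                    trait = "t", model = "univariate",
                    p_value = NA_real_, minus_log10_p = NA_real_)
  set.seed(57)
  res$p_value <- runif(1000)
  res$p_value[1] <- 10^-3.5
  res$minus_log10_p <- -log10(res$p_value)
  out <- declareSignificant(res)
  expect_true(out$raw_pass[1])                      # inclusive >=
  expect_lte(sum(out$fdr_pass), 2)                  # uniform null: ~none
  res$p_value[2] <- 1e-8
  res$minus_log10_p <- -log10(res$p_value)
  out2 <- declareSignificant(res)
  expect_true(out2$raw_pass[2] && out2$fdr_pass[2])
})

test_that("candidate windows use inclusive 250 kb boundaries per chromosome", {
  mk <- data.frame(marker_id = "mk1", chromosome = "chr1",
                   position_bp = 1000000)
  ann <- data.frame(
    gene_id = c("span", "edge", "far", "wrongchr"),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    start = c(999000, 700000, 600000, 999000),
    end = c(1001000, 750000, 749999, 1001000))
  hits <- candidateWindows(mk, ann)
  expect_setequal(hits$gene_id, c("span", "edge"))
  expect_equal(hits$distance_bp[hits$gene_id == "span"], 0L)
  # gene ending exactly window_bp before the marker is still a hit
  expect_equal(hits$distance_bp[hits$gene_id == "edge"],
               1000000L - 750000L - 1L)
  expect_equal(nrow(candidateWindows(mk[0, ], ann)), 0L)
})
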