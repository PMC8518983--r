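# shared small fixtures, built in code at load time

# small unstructured panel reused across GWAS tests
smallPanel <- local({
  geno <- simulateGenotypes(SimulationConfig(
    n_genotypes = 80, n_markers = 200, n_chromosomes = 3,
    missing_rate = 0.02, seed = 11))
  geno <- filterMarkers(geno)
  list(geno = geno, K = relatednessMatrix(geno))
})

# transform data so its sample correlation matrix is exactly `target`
exactCorrData <- function(n, target, seed = 1) {
  set.seed(seed)
  p <- nrow(target)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S <- cov(Z)
  X <- Z %*% solve(chol(S)) %*% chol(target)
  colnames(X) <- paste0("v", seq_len(p))
  as.data.frame(X)
}

# balanced RCBD ANOVA moment estimator: the independent oracle for REML
anovaSigmaG2 <- function(plants, trait = "value") {
  f <- as.formula(paste(trait, "~ factor(block_id) + factor(genotype_id)"))
  a <- anova(lm(f, plants))
  r <- length(unique(plants$block_id))
  msg <- a["factor(genotype_id)", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(sigma_g2 = max((msg - mse) / r, 0), sigma_e2 = mse)
}

# plain per-marker linear-regression Wald chi-squares (uncorrected scan)
plainScanChisq <- function(y, geno) {
  W <- dosages(geno)
  W[is.na(W)] <- 0
  r <- suppressWarnings(cor(y[rownames(W)], W))
  n <- length(y)
  drop((r * sqrt((n - 2) / (1 - r^2)))^2)
}
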