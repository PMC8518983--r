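# --- EMMA-style univariate linear mixed model machinery -------------------
#
# Model: y = X b + u + e, u ~ N(0, sigma_g2 K), e ~ N(0, sigma_e2 I).
# After the eigendecomposition K = U D U', rotating by U' gives independent
# observations with variances sigma_e2 (lambda d_i + 1), lambda =
# sigma_g2/sigma_e2. The REML profile over lambda is maximized by Brent
# search over log10(lambda) in [-5, 5].

# REML log-likelihood (up to a constant) for rotated data at a given lambda
.remlLoglik <- function(log10_lambda, yt, Xt, d) {
  lambda <- 10^log10_lambda
  w <- 1 / (lambda * d + 1)
  n <- length(yt); p <- ncol(Xt)
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  rss <- sum(yt^2 * w) - sum(beta * XtWy)
  if (rss <= 0) return(-Inf)
  -0.5 * ((n - p) * log(rss) + sum(log(lambda * d + 1)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

# null-model REML fit: returns rotation, lambda, variance components
.nullReml <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  opt <- optimize(.remlLoglik, interval = c(-5, 5), yt = yt, Xt = Xt,
                  d = d, maximum = TRUE, tol = 1e-8)
  lambda <- 10^opt$maximum
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  rss <- sum(yt^2 * w) - sum(beta * XtWy)
  sigma_e2 <- rss / (n - ncol(Xt))
  list(U = U, d = d, yt = yt, Xt = Xt, lambda = lambda,
       sigma_e2 = sigma_e2, sigma_g2 = lambda * sigma_e2,
       loglik = opt$objective)
}

#' Univariate mixed-model association scan
#'
#' Tests each marker for association with a genotype-mean phenotype under
#' y = mu + x beta + u + e, u ~ N(0, sigma_g2 K), by a Wald chi-square test
#' on beta. The kinship eigendecomposition is computed once; by default the
#' variance ratio lambda is estimated by REML under the no-marker null and
#' reused for every marker, with the residual scale re-estimated per marker
#' from the weighted residual sum of squares. \code{per_marker = "exact"}
#' re-optimizes lambda for every marker instead.
#'
#' @param y named numeric vector of genotype means (names = genotype ids)
#' @param geno a QC-filtered \linkS4class{GenotypeData}
#' @param K kinship matrix; computed with \code{\link{relatednessMatrix}}
#'   when NULL
#' @param covariates optional numeric matrix of fixed covariates (rows
#'   aligned with \code{y} after name matching)
#' @param per_marker \code{"null"} (reuse the null-model lambda) or
#'   \code{"exact"} (re-estimate lambda per marker)
#' @param trait label recorded in the result
#' @param model model tag recorded in the result
#' @return data.frame (one row per marker): marker_id, chromosome,
#'   position_bp, maf, beta, se, stat, p_value, minus_log10_p, trait, model
#' @export
lmmScan <- function(y, geno, K = NULL, covariates = NULL,
                    per_marker = c("null", "exact"), trait = "trait",
                    model = "univariate") {
  per_marker <- match.arg(per_marker)
  stopifnot(is(geno, "GenotypeData"), !is.null(names(y)))
  ids <- intersect(colnames(geno), names(y)[!is.na(y)])
  if (length(ids) < 10) stop("fewer than 10 genotypes with phenotype")
  geno <- geno[, ids]
  y <- y[ids]
  if (is.null(K)) K <- relatednessMatrix(geno)
  K <- K[ids, ids]
  W <- t(.imputeDosage(SummarizedExperiment::assay(geno, "dosage")))
  X0 <- matrix(1, length(y), 1)
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  null <- .nullReml(y, K, X0)
  Wt <- crossprod(null$U, W)            # rotated markers
  p0 <- ncol(X0)
  n <- length(y)
  m <- ncol(W)
  beta <- se <- stat <- rep(NA_real_, m)
  if (per_marker == "null") {
    w <- 1 / (null$lambda * null$d + 1)
    Xt <- null$Xt; yt <- null$yt
    XtWX0 <- crossprod(Xt, Xt * w)
    XtWy0 <- crossprod(Xt, yt * w)
    yWy <- sum(yt^2 * w)
    for (j in seq_len(m)) {
      x <- Wt[, j]
      xw <- x * w
      xx <- sum(x * xw)
      Xx <- crossprod(Xt, xw)
      xy <- sum(yt * xw)
      A <- rbind(cbind(XtWX0, Xx), c(Xx, xx))
      b <- c(XtWy0, xy)
      bh <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(bh)) next                       # monomorphic/collinear
      rss <- yWy - sum(bh * b)
      s2 <- rss / (n - p0 - 1)
      v <- tryCatch(solve(A)[p0 + 1, p0 + 1] * s2,
                    error = function(e) NA_real_)
      if (!is.finite(v) || v <= 0) next
      beta[j] <- bh[p0 + 1]
      se[j] <- sqrt(v)
      stat[j] <- beta[j]^2 / v
    }
  } else {
    for (j in seq_len(m)) {
      Xt <- cbind(null$Xt, Wt[, j])
      if (qr(Xt)$rank < ncol(Xt)) next
      opt <- optimize(.remlLoglik, interval = c(-5, 5), yt = null$yt,
                      Xt = Xt, d = null$d, maximum = TRUE, tol = 1e-8)
      w <- 1 / (10^opt$maximum * null$d + 1)
      A <- crossprod(Xt, Xt * w)
      b <- crossprod(Xt, null$yt * w)
      bh <- solve(A, b)
      rss <- sum(null$yt^2 * w) - sum(bh * b)
      s2 <- rss / (n - ncol(Xt))
      v <- solve(A)[ncol(Xt), ncol(Xt)] * s2
      beta[j] <- bh[ncol(Xt)]
      se[j] <- sqrt(v)
      stat[j] <- beta[j]^2 / v
    }
  }
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  map <- markerMap(geno)
  res <- data.frame(
    marker_id = map$marker_id, chromosome = map$chromosome,
    position_bp = map$position_bp, maf = unname(mafs(geno)),
    beta = beta, se = se, stat = stat, p_value = pv,
    minus_log10_p = -log10(pv), trait = trait, model = model,
    stringsAsFactors = FALSE
  )
  attr(res, "null_fit") <- null[c("lambda", "sigma_g2", "sigma_e2",
                                  "loglik")]
  res
}

#' Genomic inflation factor
#'
#' lambda_GC = median(chi-square statistics) / qchisq(0.5, df), the standard
#' diagnostic for residual stratification in an association scan: values
#' near 1 indicate calibrated tests.
#'
#' @param results an association result data.frame with a \code{stat} (or
#'   \code{p_value}) column
#' @param df degrees of freedom of the test statistics
#' @return the inflation factor
#' @export
genomicInflation <- function(results, df = 1) {
  stat <- results$stat
  if (is.null(stat)) stat <- qchisq(results$p_value, df, lower.tail = FALSE)
  median(stat, na.rm = TRUE) / qchisq(0.5, df)
}
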