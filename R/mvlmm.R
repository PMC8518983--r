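# --- multivariate (multi-trait) mixed model -------------------------------
#
# Model: vec(Y) ~ N(vec(1 mu'), Vg x K + Ve x I) with d traits. After
# rotating rows by the kinship eigenvectors, row i is independent with
# covariance Sigma_i = d_i Vg + Ve. For any fixed (Vg, Ve) the whole family
# {Sigma_i} is simultaneously diagonalized by T = P' Le^-1, where Ve =
# Le Le' and Le^-1 Vg Le^-T = P Lambda P': in the T-transformed trait space
# the d coordinates decouple into independent weighted regressions with
# weights 1/(d_i lambda_j + 1). REML in (Vg, Ve) is maximized over their
# Cholesky factors (log-diagonal), so estimates are PSD by construction.

.cholFromTheta <- function(theta, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

.thetaFromChol <- function(L) {
  L <- t(chol(L + diag(1e-8 * mean(diag(L)), nrow(L))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# simultaneous diagonalization of {d_i Vg + Ve}
.mvTransform <- function(Vg, Ve) {
  Le <- t(chol(Ve))
  Le_inv <- backsolve(t(Le), diag(nrow(Ve)))  # Le^-T; transpose for Le^-1
  Le_inv <- t(Le_inv)
  M <- Le_inv %*% Vg %*% t(Le_inv)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(T = t(eg$vectors) %*% Le_inv, lambda = pmax(eg$values, 0),
       logdet_ve = 2 * sum(log(diag(Le))))
}

# REML log-likelihood (intercept-only fixed effects), up to a constant.
# ct is the rotated intercept column U'1, whose entries are not constant.
.mvRemlLoglik <- function(theta, Yt, dvals, ct) {
  d <- ncol(Yt)
  k <- d * (d + 1) / 2
  Lg <- .cholFromTheta(theta[seq_len(k)], d)
  Le <- .cholFromTheta(theta[k + seq_len(k)], d)
  Vg <- tcrossprod(Lg); Ve <- tcrossprod(Le) + diag(1e-10, d)
  tr <- tryCatch(.mvTransform(Vg, Ve), error = function(e) NULL)
  if (is.null(tr)) return(-Inf)
  Yw <- Yt %*% t(tr$T)                       # n x d, decoupled coordinates
  A <- outer(dvals, tr$lambda) + 1           # n x d variance factors
  Wm <- 1 / A
  S <- colSums(ct^2 * Wm)
  mu <- colSums(ct * Yw * Wm) / S
  R <- Yw - ct %o% mu
  quad <- sum(R^2 * Wm)
  ll <- -0.5 * ((nrow(Yt) - 1) * tr$logdet_ve + sum(log(A)) + quad +
                  sum(log(S)))
  if (!is.finite(ll)) -Inf else ll
}

# null-model REML for the multivariate model; d = 1 delegates to the
# univariate Brent profile so the reduction is exact
.mvNullReml <- function(Y, K) {
  d <- ncol(Y)
  eig <- eigen(K, symmetric = TRUE)
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors
  Yt <- crossprod(U, Y)
  ct <- drop(crossprod(U, rep(1, nrow(Y))))
  if (d == 1L) {
    uni <- .nullReml(drop(Y), K)
    Vg <- matrix(uni$sigma_g2, 1, 1)
    Ve <- matrix(uni$sigma_e2, 1, 1)
    ll <- uni$loglik
  } else {
    C <- cov(Y)
    start <- c(.thetaFromChol(C / 2), .thetaFromChol(C / 2))
    opt <- optim(start, .mvRemlLoglik, Yt = Yt, dvals = dvals, ct = ct,
                 method = "BFGS",
                 control = list(fnscale = -1, maxit = 1000,
                                reltol = 1e-14))
    k <- d * (d + 1) / 2
    Vg <- tcrossprod(.cholFromTheta(opt$par[seq_len(k)], d))
    Ve <- tcrossprod(.cholFromTheta(opt$par[k + seq_len(k)], d))
    ll <- opt$value
  }
  kap <- kappa(Ve, exact = TRUE)
  if (kap > 1e8)
    warning("residual covariance estimate is near-singular ",
            "(condition number ", format(kap, digits = 3),
            "); consider dropping duplicated traits")
  tr <- .mvTransform(Vg, Ve + diag(1e-10 * mean(diag(Ve)), d))
  list(U = U, d = dvals, Yt = Yt, ct = ct, Vg = Vg, Ve = Ve,
       transform = tr, loglik = ll)
}

#' Multivariate (multi-trait) mixed-model association scan
#'
#' Tests each marker for association with a set of 2-6 genotype-mean traits
#' jointly, under the multivariate mixed model with genetic covariance
#' Vg (x) K and residual covariance Ve (x) I. Vg and Ve are estimated once
#' by REML under the no-marker null (on the kinship eigen-rotation,
#' parameterized by Cholesky factors so both stay positive semi-definite)
#' and reused across markers; each marker's d-vector of effects is then
#' tested by a Wald chi-square with d degrees of freedom, with the residual
#' scale re-estimated per marker so that d = 1 reduces exactly to
#' \code{\link{lmmScan}}.
#'
#' @param Y numeric matrix of genotype means, genotypes x traits, with
#'   rownames = genotype ids and colnames = trait names
#' @param geno a QC-filtered \linkS4class{GenotypeData}
#' @param K kinship matrix; computed when NULL
#' @param trait_set label recorded in the result (defaults to the joined
#'   trait names)
#' @return data.frame as \code{\link{lmmScan}} but with \code{stat} a Wald
#'   chi-square on d degrees of freedom and per-trait effects in columns
#'   \code{beta.<trait>}
#' @export
mvLmmScan <- function(Y, geno, K = NULL, trait_set = NULL) {
  stopifnot(is.matrix(Y), !is.null(rownames(Y)))
  d <- ncol(Y)
  if (d < 1 || d > 6) stop("between 1 and 6 traits are supported")
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("t%d", seq_len(d))
  if (is.null(trait_set)) trait_set <- paste(colnames(Y), collapse = "+")
  ok <- rowSums(is.na(Y)) == 0
  ids <- intersect(colnames(geno), rownames(Y)[ok])
  if (length(ids) < 10) stop("fewer than 10 complete-case genotypes")
  geno <- geno[, ids]
  Y <- Y[ids, , drop = FALSE]
  if (d > 1) {
    cc <- cor(Y)
    if (any(abs(cc[upper.tri(cc)]) > 0.9999))
      warning("near-duplicate traits in the set; ",
              "the residual covariance will be singular")
  }
  if (is.null(K)) K <- relatednessMatrix(geno)
  K <- K[ids, ids]
  null <- .mvNullReml(Y, K)
  Tm <- null$transform$T
  lam <- null$transform$lambda
  Yw <- null$Yt %*% t(Tm)
  W <- t(.imputeDosage(SummarizedExperiment::assay(geno, "dosage")))
  Wt <- crossprod(null$U, W)
  n <- nrow(Yw); m <- ncol(W)
  Amat <- outer(null$d, lam) + 1
  Wm <- 1 / Amat
  stat <- rep(NA_real_, m)
  betas <- matrix(NA_real_, m, d, dimnames = list(NULL, colnames(Y)))
  ct <- null$ct
  Suu <- colSums(ct^2 * Wm)
  Suy <- colSums(ct * Yw * Wm)
  for (j in seq_len(m)) {
    x <- Wt[, j]
    # per-coordinate weighted regression of Yw[, jj] on (U'1, x)
    Sux <- colSums(ct * x * Wm)
    Sxx <- colSums(x^2 * Wm)
    Sxy <- colSums(x * Yw * Wm)
    det_j <- Suu * Sxx - Sux^2
    if (any(det_j <= 0)) next
    b1 <- (Suu * Sxy - Sux * Suy) / det_j          # slope per coordinate
    b0 <- (Suy - Sux * b1) / Suu
    res2 <- colSums(Wm * (Yw - ct %o% b0 - x %o% b1)^2)
    s2 <- sum(res2) / (n * d - 2 * d)
    vb <- Suu / det_j * s2                         # var of each slope
    stat[j] <- sum(b1^2 / vb)
    # back-transform effects to the original trait scale: beta = T^-1 b1
    betas[j, ] <- drop(solve(Tm, b1))
  }
  pv <- pchisq(stat, df = d, lower.tail = FALSE)
  map <- markerMap(geno)
  res <- data.frame(
    marker_id = map$marker_id, chromosome = map$chromosome,
    position_bp = map$position_bp, maf = unname(mafs(geno)),
    stat = stat, p_value = pv, minus_log10_p = -log10(pv),
    trait = trait_set, model = "multivariate", stringsAsFactors = FALSE
  )
  colnames(betas) <- paste0("beta.", colnames(Y))
  res <- cbind(res, betas)
  attr(res, "null_fit") <- null[c("Vg", "Ve", "loglik")]
  res
}
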