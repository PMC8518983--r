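#' Pairwise Pearson correlations with significance
#'
#' Pearson r for every trait pair on pairwise-complete observations, with a
#' two-sided t-test p-value per pair.
#'
#' @param traits genotype-level trait table (or any numeric data.frame)
#' @param trait_cols columns to correlate (default: all numeric except
#'   identifiers)
#' @return list with matrices \code{r} and \code{p} (diagonal r = 1, p = NA)
#' @export
pearsonMatrix <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))],
                          c("block_id", "n_reps"))
  X <- as.matrix(traits[trait_cols])
  stopifnot(nrow(X) >= 3)
  r <- cor(X, use = "pairwise.complete.obs")
  nmat <- crossprod(!is.na(X))
  tstat <- r * sqrt((nmat - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = pmax(nmat - 2, 1), lower.tail = FALSE)
  diag(p) <- NA
  list(r = r, p = p)
}

#' Principal component analysis of the trait space
#'
#' Centers (and by default unit-scales, since the traits carry
#' incommensurate units) the trait columns and decomposes via singular
#' values. Variable contributions to each component are the squared unit
#' loadings in percent.
#'
#' @param traits genotype-level trait table; rows must be complete cases
#'   for the chosen columns (incomplete rows are dropped)
#' @param trait_cols columns to include
#' @param scale. unit-scale the columns (default TRUE)
#' @return list with \code{scores} (genotypes x PCs, rownames = genotype
#'   ids when available), \code{loadings} (traits x PCs, unit
#'   eigenvectors), \code{explained_variance_pct} and
#'   \code{contributions_pct} (traits x PCs, each column sums to 100)
#' @export
pcaTraits <- function(traits, trait_cols = NULL, scale. = TRUE) {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))],
                          c("block_id", "n_reps"))
  stopifnot(length(trait_cols) >= 2)
  X <- as.matrix(traits[trait_cols])
  if (!is.null(traits$genotype_id)) rownames(X) <- traits$genotype_id
  X <- X[complete.cases(X), , drop = FALSE]
  if (scale.) {
    sds <- apply(X, 2L, sd)
    if (any(sds == 0))
      stop("constant trait under scaling: ",
           paste(colnames(X)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  list(
    scores = pc$x,
    loadings = pc$rotation,
    explained_variance_pct = 100 * ev / sum(ev),
    contributions_pct = 100 * sweep(pc$rotation^2, 2L,
                                    colSums(pc$rotation^2), "/")
  )
}

#' Gaussian graphical model of the trait space
#'
#' Partial correlations between all trait pairs conditional on every other
#' trait, from the inverse of the Pearson correlation matrix:
#' pcor_ij = -P_ij / sqrt(P_ii P_jj). A near-singular correlation matrix is
#' ridge-jittered (with a message) before inversion.
#'
#' @param traits genotype-level trait table
#' @param trait_cols trait subset for the network. The default excludes the
#'   volume, surface-area and lateral:axial length-ratio traits, which are
#'   near-collinear with the retained length traits and would make the
#'   correlation matrix singular.
#' @param max_jitter largest ridge added to the correlation diagonal before
#'   giving up
#' @return object of class \code{ggm_network}: \code{pcor} (traits x
#'   traits, unit diagonal), the trait names, and the jitter used
#' @export
ggmNetwork <- function(traits, trait_cols = NULL, max_jitter = 1e-2) {
  if (is.null(trait_cols)) {
    excluded <- c("TRV", "ARV", "LRV", "TSA", "ASA", "LSA", "L_A_L",
                  "L_A_V", "TRR_pred")
    avail <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                     c("block_id", "n_reps"))
    trait_cols <- setdiff(avail, excluded)
  }
  X <- as.matrix(traits[trait_cols])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X))
    stop("need more observations than traits for a GGM")
  R <- cor(X)
  jitter <- 0
  P <- tryCatch(solve(R), error = function(e) NULL)
  while (is.null(P) || !all(is.finite(P))) {
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
    if (jitter > max_jitter) {
      ev <- eigen(R, symmetric = TRUE)
      v <- abs(ev$vectors[, which.min(ev$values)])
      stop("correlation matrix singular; near-collinear traits: ",
           paste(trait_cols[v > 0.3], collapse = ", "))
    }
    P <- tryCatch(solve(R + diag(jitter, nrow(R))),
                  error = function(e) NULL)
  }
  if (jitter > 0)
    message("correlation matrix ridge-jittered by ", jitter)
  Dm <- 1 / sqrt(diag(P))
  pcor <- -P * (Dm %o% Dm)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- list(trait_cols, trait_cols)
  structure(list(pcor = pcor, traits = trait_cols, jitter = jitter),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat("Gaussian graphical model over", length(x$traits), "traits\n")
  off <- x$pcor[upper.tri(x$pcor)]
  cat(sprintf("  |pcor| range: %.3f-%.3f\n", min(abs(off)), max(abs(off))))
  invisible(x)
}

#' Centrality of traits in the thresholded partial-correlation network
#'
#' Keeps edges with |partial correlation| at or above the cutoff and
#' computes, on the resulting unweighted graph, each node's outdegree
#' (number of retained connections) and Brandes betweenness centrality
#' (number of shortest paths between other node pairs passing through the
#' node, with fractional counting over tied shortest paths).
#'
#' @param network a \code{ggm_network}
#' @param cutoff minimum |partial correlation| for an edge (default 0.15)
#' @return list with \code{edges} (trait_a, trait_b, pcor) and
#'   \code{centrality} (trait, outdegree, betweenness)
#' @export
networkCentrality <- function(network, cutoff = 0.15) {
  stopifnot(inherits(network, "ggm_network"))
  pc <- network$pcor
  adj <- abs(pc) >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(
    trait_a = rownames(pc)[ij[, 1L]],
    trait_b = colnames(pc)[ij[, 2L]],
    pcor = pc[ij], stringsAsFactors = FALSE
  )
  list(
    edges = edges,
    centrality = data.frame(
      trait = network$traits,
      outdegree = as.integer(igraph::degree(g)),
      betweenness = igraph::betweenness(g, directed = FALSE),
      stringsAsFactors = FALSE, row.names = NULL
    )
  )
}
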