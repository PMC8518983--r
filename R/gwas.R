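#' Association scans on principal-component scores
#'
#' Runs the univariate mixed-model scan on each of the first
#' \code{n_pcs} principal-component scores of the genotype-mean trait
#' table, labelling the results PC1..PCn.
#'
#' @param pca a \code{\link{pcaTraits}} result (scores must have genotype
#'   ids as rownames)
#' @param geno a QC-filtered \linkS4class{GenotypeData}
#' @param K kinship matrix; computed when NULL
#' @param n_pcs number of leading components to scan (default 10)
#' @return one combined data.frame of \code{\link{lmmScan}} results with
#'   \code{trait} = PC label and \code{model} = "pc"
#' @export
pcGwas <- function(pca, geno, K = NULL, n_pcs = 10) {
  scores <- pca$scores
  n_pcs <- min(n_pcs, ncol(scores))
  if (is.null(K)) K <- relatednessMatrix(geno)
  out <- lapply(seq_len(n_pcs), function(k) {
    y <- setNames(scores[, k], rownames(scores))
    lmmScan(y, geno, K = K, trait = colnames(scores)[k], model = "pc")
  })
  do.call(rbind, out)
}

#' Flag significant associations
#'
#' Adds two significance flags per marker: \code{raw_pass} when
#' -log10(p) meets the raw threshold (inclusive), and \code{fdr_pass} under
#' Benjamini-Hochberg control at rate \code{fdr_q}, applied within each
#' trait/model scan.
#'
#' @param results association results (possibly several scans row-bound)
#' @param logp_threshold raw -log10(p) threshold (default 3.5)
#' @param fdr_q Benjamini-Hochberg false discovery rate (default 0.05)
#' @return \code{results} with columns \code{p_adj}, \code{raw_pass},
#'   \code{fdr_pass} appended
#' @export
declareSignificant <- function(results, logp_threshold = 3.5,
                               fdr_q = 0.05) {
  stopifnot(nrow(results) > 0)
  grp <- paste(results$trait, results$model)
  p_adj <- rep(NA_real_, nrow(results))
  for (g in unique(grp)) {
    ix <- grp == g
    p_adj[ix] <- p.adjust(results$p_value[ix], method = "BH")
  }
  results$p_adj <- p_adj
  results$raw_pass <- !is.na(results$minus_log10_p) &
    results$minus_log10_p >= logp_threshold
  results$fdr_pass <- !is.na(p_adj) & p_adj <= fdr_q
  results
}

#' Candidate genes within a window around significant markers
#'
#' For each marker, reports the genes whose annotated span overlaps the
#' interval [position - window_bp, position + window_bp] (inclusive
#' boundaries, clipped at zero) on the same chromosome, with the genomic
#' distance between gene and marker.
#'
#' @param markers data.frame with marker_id, chromosome, position_bp (e.g.
#'   the \code{raw_pass} rows of \code{\link{declareSignificant}} output)
#' @param annotation data.frame with gene_id, chromosome, start, end
#'   (1-based inclusive coordinates)
#' @param window_bp half-width of the search window (default 250000)
#' @return data.frame with marker_id, gene_id, chromosome, gene_start,
#'   gene_end, distance_bp (0 when the gene spans the marker)
#' @export
candidateWindows <- function(markers, annotation, window_bp = 250000) {
  stopifnot(all(c("marker_id", "chromosome", "position_bp")
                %in% names(markers)),
            all(c("gene_id", "chromosome", "start", "end")
                %in% names(annotation)))
  if (!nrow(markers))
    return(data.frame(marker_id = character(), gene_id = character(),
                      chromosome = character(), gene_start = integer(),
                      gene_end = integer(), distance_bp = integer()))
  mk <- GenomicRanges::GRanges(
    markers$chromosome,
    IRanges::IRanges(start = pmax(markers$position_bp - window_bp, 0),
                     end = markers$position_bp + window_bp))
  pt <- GenomicRanges::GRanges(
    markers$chromosome,
    IRanges::IRanges(start = markers$position_bp, width = 1L))
  gn <- GenomicRanges::GRanges(
    annotation$chromosome,
    IRanges::IRanges(start = annotation$start, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(mk, gn)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(pt[qi], gn[si])
  out <- data.frame(
    marker_id = markers$marker_id[qi],
    gene_id = annotation$gene_id[si],
    chromosome = annotation$chromosome[si],
    gene_start = annotation$start[si],
    gene_end = annotation$end[si],
    distance_bp = as.integer(dist),
    stringsAsFactors = FALSE
  )
  out[order(out$marker_id, out$distance_bp), , drop = FALSE]
}
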