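#' VanRaden genomic relationship matrix
#'
#' Computes K = Zc Zc' / (2 * sum(p * (1 - p))) where Zc is the dosage matrix
#' centered by twice the allele frequency of each marker (frequencies computed
#' on the chosen subset). K is symmetric positive semidefinite but generally
#' singular when markers are fewer than individuals; downstream mixed-model
#' code therefore works through the ridge matrix H or an eigendecomposition
#' rather than inverting K.
#'
#' @param panel a genotype_panel, or a plain dosage matrix.
#' @param subset row indices over which to compute frequencies and K;
#'   default all rows.
#' @param max_dosage homozygote dosage of the counted allele (2 for diploid
#'   codings, including the 0/2 inbred coding).
#' @return n x n numeric matrix with sample ids as dimnames.
#' @export
vanraden_kinship <- function(panel, subset = NULL, max_dosage = 2) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosages else as.matrix(panel)
  if (is.null(subset)) subset <- seq_len(nrow(X))
  if (length(subset) == 0) stop("empty subset", call. = FALSE)
  X <- X[subset, , drop = FALSE]
  p <- colMeans(X) / max_dosage
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic in the subset; kinship is degenerate",
         call. = FALSE)
  Zc <- sweep(X, 2, max_dosage * p)
  K <- tcrossprod(Zc) / denom
  (K + t(K)) / 2
}
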