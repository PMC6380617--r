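#' Simulation configuration
#'
#' Parameters of the synthetic structured-panel generator. Defaults emulate a
#' moderately structured inbred-line diversity panel: two clusters whose
#' allele frequencies diverge under the Balding-Nichols model, 0/2 dosage
#' coding, local LD blocks, a sparse additive QTL architecture and a
#' mid-range heritability.
#'
#' @param n_samples number of individuals (default 200).
#' @param n_markers number of markers (default 500).
#' @param n_clusters number of subpopulations (default 2).
#' @param fst cluster divergence in (0, 1) (default 0.15).
#' @param inbred logical; TRUE gives doubled-haploid 0/2 dosages (default),
#'   FALSE gives 0/1/2 binomial dosages.
#' @param ld_block local LD block length in markers; 1 disables LD
#'   (default 5).
#' @param n_qtl number of causal markers (default 10).
#' @param h2 target heritability in (0, 1] or 0 for a null trait
#'   (default 0.5).
#' @param seed integer RNG seed.
#' @param cluster_sizes optional vector summing to n_samples; default splits
#'   evenly with the remainder on the first cluster.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 200, n_markers = 500, n_clusters = 2,
                       fst = 0.15, inbred = TRUE, ld_block = 5, n_qtl = 10,
                       h2 = 0.5, seed = 1, cluster_sizes = NULL) {
  stopifnot(n_samples >= 2, n_markers >= 1, n_clusters >= 1,
            fst > 0, fst < 1, ld_block >= 1, n_qtl >= 0,
            n_qtl <= n_markers, h2 >= 0, h2 <= 1)
  if (is.null(cluster_sizes)) {
    base <- n_samples %/% n_clusters
    cluster_sizes <- rep(base, n_clusters)
    cluster_sizes[1] <- cluster_sizes[1] + n_samples - sum(cluster_sizes)
  }
  if (sum(cluster_sizes) != n_samples)
    stop("cluster_sizes must sum to n_samples", call. = FALSE)
  structure(list(n_samples = n_samples, n_markers = n_markers,
                 n_clusters = n_clusters, fst = fst, inbred = inbred,
                 ld_block = ld_block, n_qtl = n_qtl, h2 = h2,
                 seed = as.integer(seed), cluster_sizes = cluster_sizes),
            class = "sim_config")
}

#' Simulate a structured genotype panel
#'
#' Ancestral allele frequencies are drawn Uniform(0.1, 0.9); each cluster's
#' frequencies follow the Balding-Nichols model, Beta(p(1-F)/F, (1-p)(1-F)/F)
#' around the ancestral p with divergence F = \code{fst}. Dosages are
#' Binomial(2, p_c) per sample, or 2 x Bernoulli(p_c) for inbred
#' (doubled-haploid) panels. Local LD is induced by Markov copying: within
#' each block of \code{ld_block} consecutive markers, a sample's dosage at a
#' marker is copied from its dosage at the previous marker with probability
#' 0.7. Each cluster draws its own phase orientation per marker (probability
#' 1/2 of copying the flipped dosage, 2 - x), so local LD diverges between
#' clusters in sign as well as magnitude — marker-effect estimates trained in
#' one cluster then transfer poorly to the other, the hallmark of structured
#' diversity panels. The generator is fully deterministic given the config
#' seed, and the config is attached to the panel for provenance.
#'
#' @param config a \code{sim_config}.
#' @return a \code{genotype_panel} with attributes \code{cluster} (integer
#'   cluster id per sample) and \code{sim_config}.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_samples; M <- config$n_markers
  cl <- rep(seq_len(config$n_clusters), config$cluster_sizes)
  p_anc <- stats::runif(M, 0.1, 0.9)
  F <- config$fst
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  dos <- matrix(0, n, M)
  for (k in seq_len(config$n_clusters)) {
    rows <- which(cl == k)
    p_k <- stats::rbeta(M, a, b)
    p_k <- pmin(pmax(p_k, 1e-4), 1 - 1e-4)
    if (config$inbred) {
      dos[rows, ] <- 2 * matrix(
        stats::rbinom(length(rows) * M, 1, rep(p_k, each = length(rows))),
        length(rows), M)
    } else {
      dos[rows, ] <- matrix(
        stats::rbinom(length(rows) * M, 2, rep(p_k, each = length(rows))),
        length(rows), M)
    }
  }
  max_dos <- if (config$inbred) 2 else 2
  if (config$ld_block > 1) {
    for (j in seq_len(M)[-1]) {
      if ((j - 1) %% config$ld_block != 0) {  # j not at a block start
        for (k in seq_len(config$n_clusters)) {
          rows <- which(cl == k)
          flip <- stats::runif(1) < 0.5   # cluster-specific LD phase
          copy <- stats::runif(length(rows)) < 0.7
          src <- dos[rows, j - 1]
          dos[rows[copy], j] <- if (flip) max_dos - src[copy] else src[copy]
        }
      }
    }
  }
  panel <- genotype_panel(dos,
                          sample_ids = sprintf("S%03d", seq_len(n)),
                          marker_ids = sprintf("M%04d", seq_len(M)))
  attr(panel, "cluster") <- cl
  attr(panel, "sim_config") <- config
  panel
}

#' Simulate a sparse-QTL phenotype on a panel
#'
#' QTL markers are sampled without replacement among polymorphic markers, QTL
#' effects are standard normal, and the residual variance is set so that the
#' sample variance ratio Var(Q theta) / (Var(Q theta) + sigma_e^2) equals
#' \code{h2}. With \code{h2 = 0} the effects are zeroed and the phenotype is
#' pure noise of variance 1. An optional cluster mean shift creates
#' structure-confounded traits. If all sampled QTLs are monomorphic the draw
#' is retried (at most 10 times).
#'
#' @param panel a \code{genotype_panel} (with a \code{cluster} attribute if
#'   \code{cluster_effect} is used).
#' @param n_qtl number of causal markers.
#' @param h2 target heritability in [0, 1].
#' @param seed integer RNG seed.
#' @param cluster_effect optional scalar mean shift added per unit of
#'   (cluster id - 1); confounds structure with the trait.
#' @return list with \code{phenotype} (named numeric vector) and \code{truth},
#'   a \code{sim_truth} list: \code{qtl_indices}, \code{theta_true},
#'   \code{genetic_values}, \code{sigma2_e}, \code{realized_h2}.
#' @export
simulate_phenotype <- function(panel, n_qtl, h2, seed = 1,
                               cluster_effect = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), n_qtl <= ncol(panel$dosages),
            h2 >= 0, h2 <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- panel$dosages
  n <- nrow(X)
  poly <- which(apply(X, 2, stats::var) > 0)
  if (length(poly) < n_qtl)
    stop("not enough polymorphic markers for the requested QTL count",
         call. = FALSE)
  for (attempt in seq_len(10)) {
    qtl <- sort(sample(poly, n_qtl))
    theta <- stats::rnorm(n_qtl)
    g <- if (n_qtl > 0) drop(X[, qtl, drop = FALSE] %*% theta) else rep(0, n)
    vg <- stats::var(g)
    if (n_qtl == 0 || vg > 0) break
    warning("all sampled QTLs monomorphic; resampling", call. = FALSE)
    if (attempt == 10)
      stop("degenerate genetic variance after 10 attempts", call. = FALSE)
  }
  if (h2 == 0) {
    theta <- theta * 0
    g <- g * 0
    vg <- 0
    sigma2_e <- 1
  } else if (h2 == 1) {
    sigma2_e <- 0
  } else {
    sigma2_e <- vg * (1 - h2) / h2
  }
  e <- if (sigma2_e > 0) stats::rnorm(n, 0, sqrt(sigma2_e)) else rep(0, n)
  y <- g + e
  if (!is.null(cluster_effect)) {
    cl <- attr(panel, "cluster")
    if (is.null(cl)) stop("panel has no cluster attribute", call. = FALSE)
    y <- y + cluster_effect * (cl - 1)
  }
  names(y) <- panel$sample_ids
  list(phenotype = y,
       truth = structure(list(qtl_indices = qtl, theta_true = theta,
                              genetic_values = g, sigma2_e = sigma2_e,
                              realized_h2 = if (stats::var(y) > 0)
                                vg / stats::var(y) else 0),
                         class = "sim_truth"))
}
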