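#' Dirichlet hyperparameters for a SNP matrix
#'
#' The symmetric Dirichlet hyperparameter at locus `j` is `1 / N_A(j)`, where
#' `N_A(j)` is the number of distinct observed alleles at that locus, so the
#' prior pseudo-counts at every locus sum to one.  The same hyperparameter is
#' used for every allele and every cluster.
#'
#' @param snp An `hb_snp` object.
#' @return A list of class `hb_hyper` with element `alpha`, one value per
#'   retained locus.
#' @export
snp_hyperparameters <- function(snp) {
  structure(list(alpha = 1 / snp$n_alleles), class = "hb_hyper")
}

#' Log marginal likelihood of one cluster at one locus
#'
#' The collapsed Dirichlet-multinomial factor for a single cluster and locus:
#' with allele counts \eqn{n_l} and a symmetric hyperparameter \eqn{\alpha},
#' \deqn{\log\frac{\Gamma(\sum_l \alpha)}{\Gamma(\sum_l \alpha + \sum_l n_l)}
#'       \prod_l \frac{\Gamma(\alpha + n_l)}{\Gamma(\alpha)}}
#' evaluated entirely in log space via `lgamma`.  Empty clusters score 0
#' (every ratio collapses), and more homogeneous counts score higher than
#' split counts at the same total, which is the model's clustering signal.
#'
#' @param counts Non-negative integer vector of per-allele counts at the
#'   locus (length = number of alleles).
#' @param alpha Positive scalar Dirichlet hyperparameter applied to every
#'   allele.
#' @return Log probability (finite for all valid inputs).
#' @examples
#' cluster_locus_log_ml(c(1, 1), 0.5)   # log(0.125)
#' cluster_locus_log_ml(c(2, 0), 0.5)   # log(0.375)
#' @export
cluster_locus_log_ml <- function(counts, alpha) {
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_hb("hb_bad_argument", "`counts` must be non-negative integers")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop_hb("hb_bad_argument", "`alpha` must be a positive scalar")
  a0 <- length(counts) * alpha
  lgamma(a0) - lgamma(a0 + sum(counts)) +
    sum(lgamma(alpha + counts) - lgamma(alpha))
}

# Vectorised per-cluster log marginal likelihood from an M x A count matrix.
# Slots beyond a locus's allele number hold zero counts and contribute
# exactly zero, so the sum can run over the full rectangle.
cluster_lml_mat <- function(cm, alpha, a0) {
  if (length(cm) == 0L) return(0)
  tot <- rowSums(cm)
  sum(lgamma(a0) - lgamma(a0 + tot)) +
    sum(lgamma(alpha + cm) - lgamma(alpha))
}

# Per-cluster x locus x allele counts for a compacted label vector.
# Missing cells contribute nothing.
allele_count_array <- function(snp, labels, K) {
  M <- ncol(snp$codes)
  A <- max(c(1L, snp$n_alleles))
  counts <- array(0, dim = c(K, M, A))
  if (M > 0L) {
    for (a in seq_len(A)) {
      ia <- !is.na(snp$codes) & snp$codes == a
      storage.mode(ia) <- "double"
      counts[, , a] <- rowsum(ia, labels)
    }
  }
  counts
}

compact_labels <- function(labels) {
  match(labels, unique(labels))
}

#' Log marginal likelihood of a partition
#'
#' Sum over clusters and loci of [cluster_locus_log_ml()]: the probability of
#' the observed allele counts with each cluster's allele frequencies
#' integrated out under the Dirichlet prior.  The value is additive over
#' clusters and invariant to relabelling the clusters.
#'
#' @param snp An `hb_snp` object.
#' @param labels Cluster assignment, one positive integer per sequence.
#' @param hyp Hyperparameters, by default [snp_hyperparameters()] of `snp`.
#' @return Log probability of the data given the partition.
#' @export
partition_log_ml <- function(snp, labels, hyp = snp_hyperparameters(snp)) {
  if (length(labels) != nrow(snp$codes))
    stop_hb("hb_dimension_mismatch",
            sprintf("`labels` has length %d but the matrix has %d sequences",
                    length(labels), nrow(snp$codes)))
  labels <- compact_labels(labels)
  K <- max(labels)
  M <- ncol(snp$codes)
  if (M == 0L) return(0)
  counts <- allele_count_array(snp, labels, K)
  a0 <- snp$n_alleles * hyp$alpha
  total <- 0
  for (i in seq_len(K)) {
    cm <- counts[i, , , drop = FALSE]
    dim(cm) <- c(M, dim(counts)[3])
    total <- total + cluster_lml_mat(cm, hyp$alpha, a0)
  }
  total
}

#' Unnormalised log posterior of a partition
#'
#' Adds the partition prior to [partition_log_ml()].  The prior on the number
#' of clusters `K` is discretised uniform on `1..k_max`, taken flat over the
#' partitions within each `K`, which makes the prior a constant
#' `-log(k_max)` over every admissible partition: posterior comparisons
#' reduce to marginal-likelihood comparisons.  The normalising constant over
#' all partitions is never computed.
#'
#' @inheritParams partition_log_ml
#' @param k_max Maximum admissible number of clusters (prior support).
#' @return Unnormalised log posterior.
#' @export
log_posterior <- function(snp, labels, hyp = snp_hyperparameters(snp),
                          k_max = max(compact_labels(labels))) {
  if (k_max < 1)
    stop_hb("hb_bad_argument", "`k_max` must be at least 1")
  K <- max(compact_labels(labels))
  if (K > k_max)
    stop_hb("hb_bad_argument",
            sprintf("partition has %d clusters, more than k_max = %d",
                    K, k_max))
  partition_log_ml(snp, labels, hyp) - log(k_max)
}
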