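#' Simulate an alignment with planted cluster structure
#'
#' Generates haploid sequences under the clustering model's own generative
#' assumptions: each cluster has per-locus allele frequencies drawn from a
#' symmetric Dirichlet, and sequences draw their alleles independently per
#' locus from their cluster's multinomial.  Loci come in two kinds:
#' *divergent* loci get an independent frequency draw per cluster, *shared*
#' loci use a single draw for everyone, so `divergence` dials the separation
#' from trivial to impossible.
#'
#' A nested specification (`n_per_cluster` a list of vectors) plants
#' two-level structure: one macro cluster per list element, one sub-cluster
#' per vector entry.  Divergent loci are then divided between the scales --
#' a fraction `sub_fraction` of them take an independent draw per
#' sub-cluster, the rest take one draw per macro cluster shared by its
#' sub-clusters.  The default `sub_fraction` is small, mirroring clonal
#' microbial populations where deep lineages are separated by many fixed
#' differences and recent sub-lineages by comparatively few.
#'
#' @param n_per_cluster Integer vector of cluster sizes, or a list of such
#'   vectors for two-level (macro / sub) structure.
#' @param n_loci Number of loci (default 200).
#' @param concentration Symmetric Dirichlet concentration per allele for the
#'   frequency draws (default 0.05; small values give near-fixed alleles, as
#'   in clonal SNP data).
#' @param divergence Fraction of loci whose frequencies differ between
#'   clusters (default 0.5).
#' @param sub_fraction For nested specifications, the fraction of the
#'   divergent loci that differentiate sub-clusters rather than macro
#'   clusters (default 0.06).
#' @param missing_rate Per-cell probability of replacing the allele with `n`
#'   (missing completely at random; default 0).
#' @param seed Integer seed; the output, including FASTA bytes, is
#'   deterministic given the seed.
#' @param fasta_path Optional path; when given, the alignment is written as
#'   FASTA.
#' @param labels_path Optional path; when given, the true labels are written
#'   as TSV.
#' @param prefix Identifier prefix for the simulated sequences.
#' @return A list of class `hb_sim`: `ids`; `sequences` (character matrix,
#'   post-missingness); `labels` (data frame with `id`, `level1` and, for
#'   nested specifications, `level2`); `freqs` (clusters x loci x 4 array of
#'   the drawn frequencies of the leaf clusters); and the paths written (or
#'   `NULL`).
#' @examples
#' sim <- simulate_alignment(c(10, 10), n_loci = 50, seed = 1)
#' table(sim$labels$level1)
#' @export
simulate_alignment <- function(n_per_cluster, n_loci = 200L,
                               concentration = 0.05, divergence = 0.5,
                               sub_fraction = 0.06, missing_rate = 0,
                               seed = 1L, fasta_path = NULL,
                               labels_path = NULL, prefix = "isolate") {
  nested <- is.list(n_per_cluster)
  sizes <- if (nested) unlist(n_per_cluster) else n_per_cluster
  if (length(sizes) < 1L || any(sizes < 1) || any(sizes != round(sizes)))
    stop_hb("hb_bad_argument", "cluster sizes must be positive integers")
  if (n_loci < 1)
    stop_hb("hb_bad_argument", "`n_loci` must be positive")
  if (concentration <= 0)
    stop_hb("hb_bad_argument", "`concentration` must be positive")
  if (divergence < 0 || divergence > 1 || missing_rate < 0 ||
      missing_rate > 1 || sub_fraction < 0 || sub_fraction > 1)
    stop_hb("hb_bad_argument",
            "`divergence`, `sub_fraction` and `missing_rate` must be in [0, 1]")

  n_leaf <- length(sizes)
  macro_of_leaf <- if (nested)
    rep(seq_along(n_per_cluster), lengths(n_per_cluster))
  else
    seq_len(n_leaf)
  n <- sum(sizes)
  leaf_of_seq <- rep(seq_len(n_leaf), sizes)

  set.seed(derive_seed(seed, 0L, 0L))
  n_div <- round(divergence * n_loci)
  n_sub <- if (nested) round(sub_fraction * n_div) else 0L
  n_macro <- n_div - n_sub
  kind <- rep("shared", n_loci)
  ord <- sample.int(n_loci)
  if (n_macro > 0L) kind[ord[seq_len(n_macro)]] <- "macro"
  if (n_sub > 0L) kind[ord[n_macro + seq_len(n_sub)]] <- "sub"

  rdirichlet1 <- function(a) {
    g <- rgamma(4L, shape = a)
    while (sum(g) == 0) g <- rgamma(4L, shape = a)
    g / sum(g)
  }
  # A divergent locus must actually differ between the groups it separates:
  # each group gets its own dominant allele (distinct while four alleles
  # last) and its Dirichlet draw is rotated so the largest frequency lands
  # on it.  Marginally each group's frequencies are still a symmetric
  # Dirichlet draw up to allele relabelling.
  divergent_draws <- function(k) {
    focal <- rep_len(sample.int(4L), k)
    out <- matrix(NA_real_, k, 4L)
    for (i in seq_len(k)) {
      f <- rdirichlet1(concentration)
      swap <- which.max(f)
      f[c(swap, focal[i])] <- f[c(focal[i], swap)]
      out[i, ] <- f
    }
    out
  }
  freqs <- array(NA_real_, dim = c(n_leaf, n_loci, 4L))
  for (j in seq_len(n_loci)) {
    if (kind[j] == "shared") {
      f <- rdirichlet1(concentration)
      for (l in seq_len(n_leaf)) freqs[l, j, ] <- f
    } else if (kind[j] == "macro") {
      dd <- divergent_draws(max(macro_of_leaf))
      for (l in seq_len(n_leaf)) freqs[l, j, ] <- dd[macro_of_leaf[l], ]
    } else {
      # sub-divergent: sub-clusters within each macro cluster get distinct
      # dominant alleles; draws are independent across macro clusters too.
      for (m in seq_len(max(macro_of_leaf))) {
        leaves <- which(macro_of_leaf == m)
        dd <- divergent_draws(length(leaves))
        for (i in seq_along(leaves)) freqs[leaves[i], j, ] <- dd[i, ]
      }
    }
  }

  codes <- matrix(0L, n, n_loci)
  for (l in seq_len(n_leaf)) {
    rows <- which(leaf_of_seq == l)
    for (j in seq_len(n_loci))
      codes[rows, j] <- sample.int(4L, length(rows), replace = TRUE,
                                   prob = freqs[l, j, ])
  }
  chars <- matrix(HB_ALLELES[codes], n, n_loci)
  if (missing_rate > 0) {
    mask <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    chars[mask] <- "n"
  }

  ids <- sprintf("%s_%04d", prefix, seq_len(n))
  labels <- data.frame(id = ids, level1 = macro_of_leaf[leaf_of_seq])
  if (nested) labels$level2 <- leaf_of_seq

  if (!is.null(fasta_path)) {
    dna <- chars
    rownames(dna) <- ids
    ape::write.FASTA(ape::as.DNAbin(dna), file = fasta_path)
  }
  if (!is.null(labels_path))
    write.table(labels, file = labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

  structure(list(ids = ids, sequences = chars, labels = labels,
                 freqs = freqs, fasta_path = fasta_path,
                 labels_path = labels_path), class = "hb_sim")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement from the pair-counting contingency table:
#' 1 for identical clusterings up to label names, about 0 for independent
#' ones.  Symmetric in its arguments and invariant to permuting label names.
#'
#' @param labels_a,labels_b Two labelings of the same items (any atomic
#'   type, equal length).
#' @return A score in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_hb("hb_length_mismatch",
            "the two labelings must have equal length")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
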