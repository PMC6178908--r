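#' Hierarchical Bayesian clustering of a SNP matrix
#'
#' Level 1 clusters the full matrix with [greedy_search()].  Each subsequent
#' level re-runs the search inside every cluster of the level above: the
#' cluster's sequences are extracted, the locus filter is re-applied within
#' the subset (sites that became invariant are dropped, singleton alleles
#' recoded missing, allele inventories and hyperparameters recomputed), and
#' the search is run with `k_max = min(n_pops, cluster size)`.  A cluster is
#' left unsplit when it has fewer than 4 members, when no polymorphic locus
#' survives within it, or when the searched optimum is the single-cluster
#' partition -- the model's own integrated likelihood then prefers no split,
#' so no ad-hoc threshold is involved.  Global labels at each level are
#' assigned by ascending parent label, then sub-cluster index, which makes
#' every level a nested refinement of the level above.
#'
#' Subset searches use seeds derived deterministically from `seed` and the
#' (level, parent cluster) pair, so results are independent of traversal
#' order and of `workers`.
#'
#' @param snp An `hb_snp` object from [encode_snp_matrix()].
#' @param max_depth Number of nested clustering levels (>= 1; default 2).
#' @param n_pops Maximum number of clusters per search (default 20); also
#'   the support of the uniform prior on the number of clusters.  Should
#'   exceed the number of clusters expected in the data.
#' @param seed Integer seed governing all stochastic choices (default 42).
#' @param n_restarts Independent restarts per search (default 3).
#' @param workers Number of worker processes for restarts and sibling
#'   clusters (default 1); the output never depends on it.
#' @param quiet Suppress per-level progress messages (default `TRUE`).
#' @return An object of class `hb_hier`: a list with `ids`; `assignments`
#'   (integer matrix, sequences x levels); `partition` (data frame with
#'   columns `Isolate`, `level 1`, ..., one row per input sequence);
#'   `lml_log` (data frame with one row per level and searched cluster:
#'   `level`, `cluster` -- the parent being subdivided, 0 for the whole
#'   data set -- and `log_ml`, the final log marginal likelihood of that
#'   search on its re-filtered subset matrix); and `params` echoing the
#'   call for provenance.
#' @examples
#' sim <- simulate_alignment(list(c(5, 5), c(5, 5)), n_loci = 60, seed = 7)
#' aln <- new_alignment(sim$ids, sim$sequences)
#' res <- hierbaps(encode_snp_matrix(aln), max_depth = 2, n_pops = 5)
#' head(res$partition)
#' @export
hierbaps <- function(snp, max_depth = 2L, n_pops = 20L, seed = 42L,
                     n_restarts = 3L, workers = 1L, quiet = TRUE) {
  if (!inherits(snp, "hb_snp"))
    stop_hb("hb_bad_argument", "`snp` must be an hb_snp object")
  if (!is.numeric(max_depth) || max_depth < 1)
    stop_hb("hb_bad_argument", "`max_depth` must be at least 1")
  if (!is.numeric(n_pops) || n_pops < 2)
    stop_hb("hb_bad_argument", "`n_pops` must be at least 2")
  n <- nrow(snp$codes)
  assignments <- matrix(NA_integer_, n, max_depth)
  if (!quiet) message(sprintf("level 1: clustering %d sequences", n))
  top <- greedy_search(snp, min(n_pops, n), seed = seed,
                       n_restarts = n_restarts, workers = workers)
  assignments[, 1L] <- top$labels
  lml <- data.frame(level = 1L, cluster = 0L, log_ml = top$log_ml)

  if (max_depth > 1L) for (d in seq.int(2L, max_depth)) {
    parents <- seq_len(max(assignments[, d - 1L]))
    if (!quiet) message(sprintf("level %d: subdividing %d clusters",
                                d, length(parents)))
    split_one <- function(p) {
      members <- which(assignments[, d - 1L] == p)
      sub <- subset_snp_matrix(snp, members)
      if (length(members) < 4L || ncol(sub$codes) == 0L)
        return(list(sub_labels = rep(1L, length(members)),
                    log_ml = partition_log_ml(sub, rep(1L, length(members)))))
      gs <- greedy_search(sub, min(n_pops, length(members)),
                          seed = derive_seed(seed, d, p),
                          n_restarts = n_restarts, workers = 1L)
      list(sub_labels = gs$labels, log_ml = gs$log_ml)
    }
    results <- if (workers > 1L)
      parallel::mclapply(parents, split_one, mc.cores = as.integer(workers))
    else
      lapply(parents, split_one)
    next_label <- 0L
    for (p in parents) {
      members <- which(assignments[, d - 1L] == p)
      subl <- results[[p]]$sub_labels
      assignments[members, d] <- next_label + subl
      next_label <- next_label + max(subl)
      lml <- rbind(lml, data.frame(level = d, cluster = p,
                                   log_ml = results[[p]]$log_ml))
    }
  }

  colnames(assignments) <- paste("level", seq_len(max_depth))
  partition <- data.frame(Isolate = snp$ids, assignments,
                          check.names = FALSE)
  structure(list(
    ids = snp$ids,
    assignments = assignments,
    partition = partition,
    lml_log = lml,
    params = list(n_pops = as.integer(n_pops),
                  max_depth = as.integer(max_depth),
                  seed = as.integer(seed),
                  n_restarts = as.integer(n_restarts),
                  keep_singletons = isTRUE(snp$keep_singletons),
                  workers = as.integer(workers))
  ), class = "hb_hier")
}

#' @export
print.hb_hier <- function(x, ...) {
  k <- apply(x$assignments, 2L, max)
  cat(sprintf("Hierarchical clustering of %d sequences, depth %d\n",
              length(x$ids), ncol(x$assignments)))
  cat(sprintf("  clusters per level: %s\n", paste(k, collapse = ", ")))
  invisible(x)
}
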