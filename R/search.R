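#' Complete-linkage initial partition
#'
#' Builds the starting partition for the greedy search: pairwise SNP
#' (Hamming) distances over shared observed loci, agglomerated with complete
#' linkage, and the tree cut into `min(k_init, number of distinct sequences)`
#' clusters.  Labels are compacted in order of first appearance.
#'
#' @param snp An `hb_snp` object.
#' @param k_init Requested number of initial clusters (`1 <= k_init`).
#' @return Integer label vector of length `nrow(snp$codes)`.
#' @export
initialize_partition <- function(snp, k_init) {
  if (!is.numeric(k_init) || length(k_init) != 1L || k_init < 1)
    stop_hb("hb_bad_argument", "`k_init` must be a positive integer")
  n <- nrow(snp$codes)
  keys <- apply(snp$codes, 1L, paste, collapse = ",")
  n_distinct <- length(unique(keys))
  k_use <- min(as.integer(k_init), n_distinct, n)
  if (k_use == 1L) return(rep(1L, n))
  hc <- hclust(as.dist(snp_hamming(snp)), method = "complete")
  compact_labels(cutree(hc, k = k_use))
}

#' Greedy sweep: reassign individual sequences
#'
#' Visits the sequences in a random order; each sequence is moved to the
#' cluster (including, when `K < k_max`, a new singleton cluster) with the
#' best strictly positive log-ML delta, applied immediately.  Full passes
#' repeat until one makes no move.  Ties go to the lowest cluster index.  The
#' cached log marginal likelihood never decreases.
#'
#' @param state An `hb_state`.
#' @return The improved `hb_state`.
#' @export
sweep_reassign_individuals <- function(state) {
  n <- length(state$labels)
  repeat {
    moved <- FALSE
    for (s in sample.int(n)) {
      from <- state$labels[s]
      cand <- seq_len(state$K)[-from]
      if (state$K < state$k_max && state$sizes[from] > 1L)
        cand <- c(cand, state$K + 1L)
      if (!length(cand)) next
      d_from <- delta_remove_seq(state, s, from)
      deltas <- d_from + vapply(cand, function(t) delta_add_seq(state, s, t),
                                numeric(1))
      b <- which.max(deltas)
      if (deltas[b] > HB_TOL) {
        state <- apply_move(state, s, cand[b])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  state
}

#' Greedy sweep: merge cluster pairs
#'
#' Scores every pair of clusters by its exact merge delta and applies the
#' best merge while it is a strict improvement; the labels are compacted
#' after each merge.  Ties go to the lexicographically smallest pair.
#'
#' @param state An `hb_state`.
#' @return The improved `hb_state`.
#' @export
sweep_merge_clusters <- function(state) {
  repeat {
    if (state$K < 2L) break
    best <- NULL
    best_d <- HB_TOL
    for (i in seq_len(state$K - 1L)) {
      for (j in seq.int(i + 1L, state$K)) {
        dm <- delta_merge(state, i, j)
        if (dm$delta > best_d) {
          best <- list(i = i, j = j, merged_lml = dm$merged_lml)
          best_d <- dm$delta
        }
      }
    }
    if (is.null(best)) break
    state <- apply_merge(state, best$i, best$j, best$merged_lml)
  }
  state
}

# Member sets under each internal node of a complete-linkage tree of the
# given sequences, excluding the root (the whole set).  Candidate subgroups
# for relocation; singletons are handled by the reassignment sweep.
subtree_groups <- function(snp, members) {
  m <- length(members)
  if (m < 4L) return(list())
  d <- snp_hamming(subset_snp_matrix_rows(snp, members))
  hc <- hclust(as.dist(d), method = "complete")
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- c(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L]))
  }
  lapply(sets[-length(sets)], function(ix) members[ix])
}

# Row subset of the codes without re-filtering loci: used only for distance
# computations inside the search, where the locus inventory must stay fixed.
subset_snp_matrix_rows <- function(snp, rows) {
  out <- snp
  out$codes <- snp$codes[rows, , drop = FALSE]
  out$ids <- snp$ids[rows]
  out
}

#' Greedy sweep: relocate complete-linkage subgroups
#'
#' For each cluster with at least four members, builds a complete-linkage
#' subtree of its members and treats the member set under each internal node
#' (except the root) as a candidate subgroup.  Every subgroup is scored for
#' relocation to every other cluster, or to a new cluster when `K < k_max`;
#' the single best strictly-improving relocation is applied, and the scan
#' repeats until no improvement remains.  This is the move family that lets
#' the search split a cluster that hides two subpopulations.
#'
#' @param state An `hb_state`.
#' @return The improved `hb_state`.
#' @export
sweep_split_relocate <- function(state) {
  repeat {
    best <- NULL
    best_d <- HB_TOL
    for (cl in seq_len(state$K)) {
      if (state$sizes[cl] < 4L) next
      members <- which(state$labels == cl)
      for (grp in subtree_groups(state$snp, members)) {
        gcm <- group_count_mat(state$snp, grp)
        targets <- seq_len(state$K)[-cl]
        if (state$K < state$k_max) targets <- c(targets, state$K + 1L)
        for (t in targets) {
          dg <- delta_group_move(state, gcm, cl, t)
          if (dg$delta > best_d) {
            best <- list(grp = grp, to = t, dg = dg)
            best_d <- dg$delta
          }
        }
      }
    }
    if (is.null(best)) break
    state <- apply_group_move(state, best$grp, best$to, best$dg)
  }
  state
}

#' Greedy stochastic search for the maximum a posteriori partition
#'
#' Runs `n_restarts` independent greedy searches and returns the best final
#' partition.  Restart `r` seeds the random number generator with
#' `seed + r`; restart 0 starts from the complete-linkage partition at
#' `k_max`, later restarts from randomly perturbed versions of it.  Each
#' search cycles the three sweep families (individual reassignment, pairwise
#' merge, subgroup relocation) until a full cycle yields no improvement.
#' Acceptance is strictly greedy, so the cached log marginal likelihood is
#' non-decreasing across every applied move; the randomness only shapes the
#' search path.  Identical inputs, seed and `n_restarts` give identical
#' results regardless of `workers`.
#'
#' @param snp An `hb_snp` object.
#' @param k_max Maximum number of clusters (the prior support).
#' @param seed Integer seed governing all stochastic choices.
#' @param n_restarts Number of independent restarts (default 3).
#' @param workers Restarts run under [parallel::mclapply()] when
#'   `workers > 1`; results are reduced in restart order, so the output does
#'   not depend on the worker count.
#' @param trace Record the cached log-ML after every sweep of the winning
#'   restart (returned as element `trace`).
#' @return A list of class `hb_search`: `labels` (compacted in order of first
#'   appearance), `k`, `log_ml` (equal to `partition_log_ml` of `labels`),
#'   `restart` (index of the winning restart) and optionally `trace`.
#' @export
greedy_search <- function(snp, k_max, seed = 42L, n_restarts = 3L,
                          workers = 1L, trace = FALSE) {
  if (!is.numeric(k_max) || k_max < 1)
    stop_hb("hb_bad_argument", "`k_max` must be at least 1")
  n <- nrow(snp$codes)
  k_max <- as.integer(min(k_max, n))
  if (k_max == 1L || ncol(snp$codes) == 0L) {
    labels <- rep(1L, n)
    return(structure(list(labels = labels, k = 1L,
                          log_ml = partition_log_ml(snp, labels),
                          restart = 0L,
                          trace = numeric(0)), class = "hb_search"))
  }
  run_one <- function(r) {
    set.seed(derive_seed(seed + r, 0L, 0L))
    labels <- initialize_partition(snp, k_max)
    if (r > 0L) {
      flip <- runif(n) < 0.25
      labels[flip] <- sample.int(k_max, sum(flip), replace = TRUE)
      labels <- compact_labels(labels)
    }
    state <- new_search_state(snp, labels, k_max)
    tr <- state$log_ml
    repeat {
      before <- state$log_ml
      state <- sweep_reassign_individuals(state)
      tr <- c(tr, state$log_ml)
      state <- sweep_merge_clusters(state)
      tr <- c(tr, state$log_ml)
      state <- sweep_split_relocate(state)
      tr <- c(tr, state$log_ml)
      if (state$log_ml - before <= HB_TOL) break
    }
    list(labels = state$labels, log_ml = state$log_ml, trace = tr)
  }
  runs <- if (workers > 1L)
    parallel::mclapply(seq_len(n_restarts) - 1L, run_one,
                       mc.cores = as.integer(workers))
  else
    lapply(seq_len(n_restarts) - 1L, run_one)
  scores <- vapply(runs, `[[`, numeric(1), "log_ml")
  best <- which.max(scores)
  labels <- compact_labels(runs[[best]]$labels)
  structure(list(labels = labels, k = max(labels),
                 log_ml = runs[[best]]$log_ml,
                 restart = best - 1L,
                 trace = if (trace) runs[[best]]$trace else numeric(0)),
            class = "hb_search")
}

#' @export
print.hb_search <- function(x, ...) {
  cat(sprintf("Greedy MAP search: %d clusters, log ML %.4f (restart %d)\n",
              x$k, x$log_ml, x$restart))
  invisible(x)
}
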