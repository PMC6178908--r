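#' Create a search state
#'
#' Bundles a partition with its cached allele-count table and cached log
#' marginal likelihood so that candidate moves can be scored incrementally,
#' touching only the clusters a move affects.
#'
#' @param snp An `hb_snp` object.
#' @param labels Initial cluster assignment (any positive integers; compacted
#'   to `1..K` in order of first appearance).
#' @param k_max Maximum number of clusters the search may use.
#' @return An object of class `hb_state` with elements `snp`, `labels`, `K`,
#'   `k_max`, `counts` (K x loci x alleles), `tot` (K x loci observed
#'   totals), `sizes`, `cluster_lml` (per-cluster log marginal likelihood)
#'   and `log_ml` (their sum).
#' @export
new_search_state <- function(snp, labels, k_max = max(compact_labels(labels))) {
  n <- nrow(snp$codes)
  if (length(labels) != n)
    stop_hb("hb_dimension_mismatch", "one label per sequence required")
  labels <- compact_labels(labels)
  K <- max(labels)
  if (k_max < K)
    stop_hb("hb_bad_argument", "`k_max` smaller than the number of clusters")
  M <- ncol(snp$codes)
  counts <- allele_count_array(snp, labels, K)
  obs <- !is.na(snp$codes)
  storage.mode(obs) <- "double"
  tot <- rowsum(obs, labels)
  dimnames(tot) <- NULL
  alpha <- 1 / snp$n_alleles
  a0 <- snp$n_alleles * alpha
  cluster_lml <- vapply(seq_len(K), function(i)
    cluster_lml_mat(state_count_mat(counts, i, M), alpha, a0), numeric(1))
  seq_obs <- lapply(seq_len(n), function(s) {
    j <- which(!is.na(snp$codes[s, ]))
    list(j = j, a = snp$codes[s, j])
  })
  structure(list(
    snp = snp, labels = labels, K = K, k_max = as.integer(k_max),
    counts = counts, tot = tot, sizes = tabulate(labels, K),
    alpha = alpha, a0 = a0, seq_obs = seq_obs,
    cluster_lml = cluster_lml, log_ml = sum(cluster_lml)
  ), class = "hb_state")
}

# Extract cluster i's M x A count matrix without dropping dimensions.
state_count_mat <- function(counts, i, M) {
  cm <- counts[i, , , drop = FALSE]
  dim(cm) <- c(M, dim(counts)[3])
  cm
}

# Change in cluster `from`'s log-ML when sequence s leaves it.  Uses
# lgamma(x + 1) - lgamma(x) = log(x), so only the observed loci of s enter.
delta_remove_seq <- function(state, s, from) {
  ob <- state$seq_obs[[s]]
  if (!length(ob$j)) return(0)
  cf <- state$counts[cbind(from, ob$j, ob$a)]
  tf <- state$tot[from, ob$j]
  -sum(log(state$alpha[ob$j] + cf - 1) - log(state$a0[ob$j] + tf - 1))
}

# Change in cluster `to`'s log-ML when sequence s joins it; `to` may be
# K + 1, an empty cluster.
delta_add_seq <- function(state, s, to) {
  ob <- state$seq_obs[[s]]
  if (!length(ob$j)) return(0)
  if (to > state$K) {
    ct <- 0
    tt <- 0
  } else {
    ct <- state$counts[cbind(to, ob$j, ob$a)]
    tt <- state$tot[to, ob$j]
  }
  sum(log(state$alpha[ob$j] + ct) - log(state$a0[ob$j] + tt))
}

#' Exact log-ML change of moving one sequence between clusters
#'
#' Scores the move of `seq_index` from `from_cluster` to `to_cluster`
#' (possibly `K + 1`, a new cluster, when `K < k_max`) by touching only the
#' two affected clusters' terms.  Applying the move and recomputing the
#' partition log marginal likelihood from scratch agrees with the cached
#' update to tight numerical tolerance.
#'
#' @param state An `hb_state`.
#' @param seq_index Index of the sequence to move.
#' @param from_cluster Its current cluster (checked).
#' @param to_cluster Destination cluster; `state$K + 1` opens a new cluster.
#' @return The log-ML difference, with attribute `empties_from` set to `TRUE`
#'   when the move would leave `from_cluster` empty, so the caller knows the
#'   labels must be compacted after applying it.
#' @export
delta_log_ml_move <- function(state, seq_index, from_cluster, to_cluster) {
  if (state$labels[seq_index] != from_cluster)
    stop_hb("hb_invalid_move",
            sprintf("sequence %d is not in cluster %d", seq_index,
                    from_cluster))
  if (to_cluster == from_cluster)
    stop_hb("hb_invalid_move", "`to_cluster` must differ from `from_cluster`")
  if (to_cluster > state$K + 1L ||
      (to_cluster == state$K + 1L && state$K >= state$k_max))
    stop_hb("hb_invalid_move",
            "`to_cluster` must be an existing cluster or K + 1 with K < k_max")
  d <- delta_remove_seq(state, seq_index, from_cluster) +
    delta_add_seq(state, seq_index, to_cluster)
  attr(d, "empties_from") <- state$sizes[from_cluster] == 1L
  d
}

# Drop an emptied cluster row and close the gap in the labels, preserving
# the relative order of the surviving clusters.
drop_cluster <- function(state, i) {
  state$counts <- state$counts[-i, , , drop = FALSE]
  state$tot <- state$tot[-i, , drop = FALSE]
  state$sizes <- state$sizes[-i]
  state$cluster_lml <- state$cluster_lml[-i]
  state$labels[state$labels > i] <- state$labels[state$labels > i] - 1L
  state$K <- state$K - 1L
  state
}

# Append an empty cluster row.
grow_cluster <- function(state) {
  M <- ncol(state$snp$codes)
  A <- dim(state$counts)[3]
  counts <- array(0, dim = c(state$K + 1L, M, A))
  counts[seq_len(state$K), , ] <- state$counts
  state$counts <- counts
  state$tot <- rbind(state$tot, 0)
  state$sizes <- c(state$sizes, 0L)
  state$cluster_lml <- c(state$cluster_lml, 0)
  state$K <- state$K + 1L
  state
}

#' Apply a single-sequence move to a search state
#'
#' Moves `seq_index` into `to_cluster` (possibly `K + 1`), updating the
#' cached counts and per-cluster log marginal likelihoods incrementally.  A
#' cluster emptied by the move is removed and the labels are compacted.
#'
#' @inheritParams delta_log_ml_move
#' @return The updated `hb_state`.
#' @export
apply_move <- function(state, seq_index, to_cluster) {
  from <- state$labels[seq_index]
  d_from <- delta_remove_seq(state, seq_index, from)
  if (to_cluster > state$K) state <- grow_cluster(state)
  d_to <- delta_add_seq(state, seq_index, to_cluster)
  ob <- state$seq_obs[[seq_index]]
  if (length(ob$j)) {
    idx_f <- cbind(from, ob$j, ob$a)
    idx_t <- cbind(to_cluster, ob$j, ob$a)
    state$counts[idx_f] <- state$counts[idx_f] - 1
    state$counts[idx_t] <- state$counts[idx_t] + 1
    state$tot[from, ob$j] <- state$tot[from, ob$j] - 1
    state$tot[to_cluster, ob$j] <- state$tot[to_cluster, ob$j] + 1
  }
  state$sizes[from] <- state$sizes[from] - 1L
  state$sizes[to_cluster] <- state$sizes[to_cluster] + 1L
  state$labels[seq_index] <- to_cluster
  state$cluster_lml[from] <- state$cluster_lml[from] + d_from
  state$cluster_lml[to_cluster] <- state$cluster_lml[to_cluster] + d_to
  state$log_ml <- state$log_ml + d_from + d_to
  if (state$sizes[from] == 0L) state <- drop_cluster(state, from)
  state
}

# Log-ML change of merging clusters i and j (exact, via additivity).
delta_merge <- function(state, i, j) {
  M <- ncol(state$snp$codes)
  merged <- state_count_mat(state$counts, i, M) +
    state_count_mat(state$counts, j, M)
  lml <- cluster_lml_mat(merged, state$alpha, state$a0)
  list(delta = lml - state$cluster_lml[i] - state$cluster_lml[j],
       merged_lml = lml)
}

apply_merge <- function(state, i, j, merged_lml) {
  stopifnot(i < j)
  state$counts[i, , ] <- state$counts[i, , ] + state$counts[j, , ]
  state$tot[i, ] <- state$tot[i, ] + state$tot[j, ]
  state$sizes[i] <- state$sizes[i] + state$sizes[j]
  state$log_ml <- state$log_ml - state$cluster_lml[i] -
    state$cluster_lml[j] + merged_lml
  state$cluster_lml[i] <- merged_lml
  state$labels[state$labels == j] <- i
  state$sizes[j] <- 0L
  drop_cluster(state, j)
}

# M x A count matrix of an arbitrary set of sequences.
group_count_mat <- function(snp, members) {
  M <- ncol(snp$codes)
  A <- max(c(1L, snp$n_alleles))
  cm <- matrix(0, M, A)
  sub <- snp$codes[members, , drop = FALSE]
  for (a in seq_len(A))
    cm[, a] <- colSums(!is.na(sub) & sub == a)
  cm
}

# Log-ML change of relocating a whole subgroup from cluster `from` to
# cluster `to` (or to a new cluster when to == K + 1).
delta_group_move <- function(state, gcm, from, to) {
  M <- ncol(state$snp$codes)
  from_new <- cluster_lml_mat(state_count_mat(state$counts, from, M) - gcm,
                              state$alpha, state$a0)
  to_new <- if (to > state$K)
    cluster_lml_mat(gcm, state$alpha, state$a0)
  else
    cluster_lml_mat(state_count_mat(state$counts, to, M) + gcm,
                    state$alpha, state$a0)
  to_old <- if (to > state$K) 0 else state$cluster_lml[to]
  list(delta = (from_new - state$cluster_lml[from]) + (to_new - to_old),
       from_new = from_new, to_new = to_new)
}

apply_group_move <- function(state, members, to, dg) {
  from <- state$labels[members[1L]]
  if (to > state$K) state <- grow_cluster(state)
  gcm <- group_count_mat(state$snp, members)
  gtot <- rowSums(gcm)
  state$counts[from, , ] <- state$counts[from, , ] - gcm
  state$counts[to, , ] <- state$counts[to, , ] + gcm
  state$tot[from, ] <- state$tot[from, ] - gtot
  state$tot[to, ] <- state$tot[to, ] + gtot
  state$sizes[from] <- state$sizes[from] - length(members)
  state$sizes[to] <- state$sizes[to] + length(members)
  state$labels[members] <- to
  # cluster_lml[to] is still the pre-move value here (zero for a cluster
  # just opened by grow_cluster), so the two differences are exact.
  state$log_ml <- state$log_ml +
    (dg$from_new - state$cluster_lml[from]) +
    (dg$to_new - state$cluster_lml[to])
  state$cluster_lml[from] <- dg$from_new
  state$cluster_lml[to] <- dg$to_new
  if (state$sizes[from] == 0L) state <- drop_cluster(state, from)
  state
}
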