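# Shared fixtures and independent oracles for the test suite.

# Sequential-predictive evaluation of the collapsed Dirichlet-multinomial
# factor: the probability of observing the counts one draw at a time,
# p(next = l) = (alpha + seen_l) / (A * alpha + seen_total).  Independent of
# the closed-form log-gamma route used by the package.
oracle_locus_lml <- function(counts, alpha) {
  draws <- rep(seq_along(counts), counts)
  seen <- numeric(length(counts))
  lp <- 0
  for (o in draws) {
    lp <- lp + log((alpha + seen[o]) / (length(counts) * alpha + sum(seen)))
    seen[o] <- seen[o] + 1
  }
  lp
}

# Naive partition score: counts accumulated by explicit loops, scored locus
# by locus with the sequential-predictive oracle.
oracle_partition_lml <- function(snp, labels) {
  labels <- match(labels, unique(labels))
  total <- 0
  for (i in sort(unique(labels))) {
    rows <- which(labels == i)
    for (j in seq_len(ncol(snp$codes))) {
      cnt <- integer(snp$n_alleles[j])
      for (s in rows) {
        a <- snp$codes[s, j]
        if (!is.na(a)) cnt[a] <- cnt[a] + 1L
      }
      total <- total + oracle_locus_lml(cnt, 1 / snp$n_alleles[j])
    }
  }
  total
}

# All set partitions of n items with at most k_max blocks, as restricted
# growth strings.
all_partitions <- function(n, k_max = n) {
  out <- list()
  rec <- function(pref, m) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (v in seq_len(min(m + 1L, k_max)))
      rec(c(pref, v), max(m, v))
  }
  rec(1L, 1L)
  out
}

# Exhaustive MAP over all partitions with K <= k_max, scored with the
# package's own likelihood (the enumeration, not the formula, is the oracle
# here).
oracle_map <- function(snp, k_max) {
  parts <- all_partitions(nrow(snp$codes), k_max)
  scores <- vapply(parts, function(p) partition_log_ml(snp, p), numeric(1))
  list(labels = parts[[which.max(scores)]], log_ml = max(scores))
}

# Write sequences to a temporary FASTA file.
write_temp_fasta <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                             width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(mapply(function(id, s) {
    body <- if (is.null(width)) s
    else {
      st <- seq(1L, nchar(s), by = width)
      substring(s, st, pmin(st + width - 1L, nchar(s)))
    }
    c(paste0(">", id), body)
  }, ids, seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# Alignment built directly from whole-sequence strings.
make_aln <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  new_alignment(ids, do.call(rbind, strsplit(seqs, "")))
}

# Random small SNP instance: n sequences over M binary-or-more loci with a
# little missingness, pushed through the real encoder with the singleton
# filter off so every polymorphic column survives.
make_random_snp <- function(n, M, seed, miss = 0.05) {
  set.seed(seed)
  repeat {
    chars <- matrix(sample(c("a", "c", "g", "t"), n * M, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1)), n, M)
    chars[matrix(runif(n * M) < miss, n, M)] <- "n"
    ok <- tryCatch(
      encode_snp_matrix(make_aln(apply(chars, 1, paste, collapse = "")),
                        keep_singletons = TRUE),
      hb_no_polymorphic_loci = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}
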