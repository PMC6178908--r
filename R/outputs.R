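#' Write the per-level partition table to CSV
#'
#' One row per input sequence, in input order, with header
#' `Isolate,level 1,...,level max_depth` and no row names, so the file can
#' be joined directly onto tree or metadata tables downstream.
#'
#' @param result An `hb_hier` object from [hierbaps()].
#' @param path Output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_partition_csv <- function(result, path) {
  if (!inherits(result, "hb_hier"))
    stop_hb("hb_bad_argument", "`result` must be an hb_hier object")
  write.csv(result$partition, file = path, row.names = FALSE)
  invisible(result$partition)
}

#' Save the per-search log marginal likelihoods
#'
#' Plain-text log: a header echoing the run parameters, then one line per
#' level and searched cluster with the final log marginal likelihood in full
#' precision scientific notation.  Cluster 0 denotes the search over the
#' whole data set (level 1); at deeper levels the cluster column names the
#' parent cluster that was subdivided.
#'
#' @param result An `hb_hier` object.
#' @param path Output file path.
#' @return Invisibly, `result$lml_log`.
#' @export
save_lml_logs <- function(result, path) {
  if (!inherits(result, "hb_hier"))
    stop_hb("hb_bad_argument", "`result` must be an hb_hier object")
  p <- result$params
  header <- c(
    "# log marginal likelihoods per level and searched cluster",
    sprintf("# n_pops=%d max_depth=%d seed=%d n_restarts=%d keep_singletons=%s",
            p$n_pops, p$max_depth, p$seed, p$n_restarts,
            p$keep_singletons))
  body <- sprintf("level %d\tcluster %d\tlog_ml %.17e",
                  result$lml_log$level, result$lml_log$cluster,
                  result$lml_log$log_ml)
  writeLines(c(header, body), path)
  invisible(result$lml_log)
}

#' Map phylogeny tips to clusters for tree annotation
#'
#' Reads a Newick tree whose tip labels match the isolate identifiers of a
#' clustering result and writes a two-column TSV (`tip`, `cluster`) giving
#' each tip's cluster at the requested level, in tree tip order -- the
#' format tree viewers take for tip colouring.
#'
#' @param result An `hb_hier` object.
#' @param newick_path Path to a Newick tree file (quoted labels supported).
#' @param level Clustering level to export (default 1).
#' @param path Optional output TSV path; when `NULL` the table is only
#'   returned.
#' @return The annotation data frame, invisibly when `path` is given.
#' @export
tree_annotation_table <- function(result, newick_path, level = 1L,
                                  path = NULL) {
  if (!inherits(result, "hb_hier"))
    stop_hb("hb_bad_argument", "`result` must be an hb_hier object")
  if (level < 1L || level > ncol(result$assignments))
    stop_hb("hb_bad_argument",
            sprintf("`level` must be between 1 and %d",
                    ncol(result$assignments)))
  tree <- ape::read.tree(newick_path)
  tips <- tree$tip.label
  extra <- setdiff(tips, result$ids)
  absent <- setdiff(result$ids, tips)
  if (length(extra) || length(absent))
    stop_hb("hb_tip_mismatch", paste0(
      "tree tips and isolates do not match.",
      if (length(extra)) paste0(" In tree only: ",
                                paste(extra, collapse = ", "), "."),
      if (length(absent)) paste0(" In alignment only: ",
                                 paste(absent, collapse = ", "), ".")))
  df <- data.frame(tip = tips,
                   cluster = result$assignments[match(tips, result$ids),
                                                level])
  if (!is.null(path)) {
    write.table(df, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Run the full clustering pipeline
#'
#' Load a FASTA alignment, encode and filter it, run the hierarchical
#' clustering, and write the partition CSV and log-ML log (plus a tip
#' annotation TSV when a Newick tree is supplied).  Output files are fully
#' determined by the input bytes and the parameters; the worker count never
#' changes them.  Progress goes to standard error; results go to files only.
#'
#' @param input Path to the input FASTA alignment.
#' @param out_prefix Prefix for the output files
#'   (`<prefix>_partition.csv`, `<prefix>_logml.txt`,
#'   `<prefix>_level<level>_annotation.tsv`).
#' @param max_depth,n_pops,seed,n_restarts,workers,quiet Passed to
#'   [hierbaps()]; defaults 2, 20, 42, 3, 1, `FALSE`.
#' @param keep_singletons Passed to [encode_snp_matrix()] (default `FALSE`).
#' @param tree Optional Newick tree path for [tree_annotation_table()].
#' @param level Level exported in the annotation table (default 1).
#' @return Invisibly, the `hb_hier` result.
#' @export
run_pipeline <- function(input, out_prefix, max_depth = 2L, n_pops = 20L,
                         seed = 42L, n_restarts = 3L,
                         keep_singletons = FALSE, workers = 1L,
                         tree = NULL, level = 1L, quiet = FALSE) {
  aln <- load_fasta(input)
  if (!quiet)
    message(sprintf("loaded %d sequences x %d columns",
                    nrow(aln$residues), ncol(aln$residues)))
  snp <- encode_snp_matrix(aln, keep_singletons = keep_singletons)
  if (!quiet)
    message(sprintf("retained %d polymorphic loci", ncol(snp$codes)))
  res <- hierbaps(snp, max_depth = max_depth, n_pops = n_pops, seed = seed,
                  n_restarts = n_restarts, workers = workers, quiet = quiet)
  write_partition_csv(res, paste0(out_prefix, "_partition.csv"))
  save_lml_logs(res, paste0(out_prefix, "_logml.txt"))
  if (!is.null(tree))
    tree_annotation_table(res, tree, level = level,
                          path = sprintf("%s_level%d_annotation.tsv",
                                         out_prefix, level))
  if (!quiet) message("done")
  invisible(res)
}
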