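#' @keywords internal
"_PACKAGE"

read_label_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Infer the trait emergence order and write the report
#'
#' File-level front end for [build_order()]: reads a rooted species tree
#' and a trait matrix, reconciles them, infers the order and writes
#' `order.json` / `pair_relations.csv` under `out_dir`.
#'
#' @param tree_file Newick file with the rooted species tree.
#' @param traits_file TSV trait matrix (see [read_trait_matrix()]).
#' @param out_dir Output directory.
#' @param prune Prune tree/matrix to their common species set?
#' @param skip_absent Skip all-absent traits instead of erroring?
#' @return The `trait_order` object, invisibly.
#' @export
run_infer_order <- function(tree_file, traits_file, out_dir,
                            prune = FALSE, skip_absent = FALSE) {
  tree <- read_trees(tree_file)[[1]]
  tm <- read_trait_matrix(traits_file)
  rec <- reconcile(tm, tree, prune = prune)
  ord <- build_order(rec$tree, rec$matrix, skip_absent = skip_absent)
  write_order_report(ord, out_dir)
  invisible(ord)
}

#' Compute homoplasy indices and write the report
#'
#' File-level front end for [trait_indices()]: writes `indices.csv` and
#' `indices_summary.json` under `out_dir`.
#'
#' @inheritParams run_infer_order
#' @return The `parsimony_indices` object, invisibly.
#' @export
run_indices <- function(tree_file, traits_file, out_dir, prune = FALSE) {
  tree <- read_trees(tree_file)[[1]]
  tm <- read_trait_matrix(traits_file)
  rec <- reconcile(tm, tree, prune = prune)
  idx <- trait_indices(rec$tree, rec$matrix)
  write_indices(idx, out_dir)
  invisible(idx)
}

#' Gene-tree concordance analysis, end to end
#'
#' Reads gene trees, roots each on the outgroup (trees whose outgroup is
#' not a single partition are dropped and counted), strips the outgroup
#' leaves, and computes [concordance()] against the species-tree order.
#' With `exclude_taxa` a second, pruned rerun is written alongside the
#' main one (files prefixed `concordance_excl`).
#'
#' @inheritParams run_infer_order
#' @param gene_trees_file Newick file (one tree per line) or directory.
#' @param outgroup_file Text file with one outgroup label per line.
#' @param exclude_taxa Optional species labels for a taxon-exclusion rerun.
#' @param lenient Lenient scoring (see [concordance()])?
#' @return The main `trait_concordance` object, invisibly.
#' @export
run_concordance <- function(tree_file, gene_trees_file, traits_file,
                            outgroup_file, out_dir, exclude_taxa = NULL,
                            lenient = FALSE, prune = FALSE) {
  tree <- read_trees(tree_file)[[1]]
  tm <- read_trait_matrix(traits_file)
  outgroup <- read_label_file(outgroup_file)
  gts <- read_trees(gene_trees_file)
  if (length(gts) == 0L) stop("no gene trees found")
  rec <- reconcile(tm, tree, prune = prune)
  ord <- build_order(rec$tree, rec$matrix)

  rooted <- list()
  n_unrootable <- 0L
  for (id in names(gts)) {
    gt <- gts[[id]]
    og <- intersect(outgroup, gt$tip.label)
    ok <- length(og) > 0L &&
      tryCatch(outgroup_partition_ok(gt, og), error = function(e) FALSE)
    if (!ok) {
      n_unrootable <- n_unrootable + 1L
      next
    }
    rooted[[id]] <- drop_outgroup(root_on_outgroup(gt, og), og)
  }
  conc <- concordance(rooted, rec$matrix, ord, lenient = lenient,
                      prune_unknown = TRUE)
  write_concordance(conc, out_dir)
  jsonlite::write_json(list(n_input = length(gts),
                            n_unrootable = n_unrootable,
                            n_used = length(rooted)),
                       file.path(out_dir, "gene_tree_rooting.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(exclude_taxa) && length(exclude_taxa) > 0L) {
    conc2 <- concordance(rooted, rec$matrix, ord, exclude_taxa = exclude_taxa,
                         lenient = lenient, prune_unknown = TRUE)
    write_concordance(conc2, out_dir, prefix = "concordance_excl")
  }
  invisible(conc)
}

#' Root-support census, end to end
#'
#' File-level front end for [census()]: writes `census.json` and
#' `census_per_tree.csv` under `out_dir`.
#'
#' @inheritParams run_concordance
#' @param groups_file TSV group map (see [read_group_map()]).
#' @param min_per_group Minimum leaves per group (default 2).
#' @param metadata_file Optional TSV (tree id, numeric value) for
#'   per-category medians.
#' @return The `root_census` object, invisibly.
#' @export
run_root_census <- function(gene_trees_file, groups_file, outgroup_file,
                            out_dir, min_per_group = 2L, metadata_file = NULL) {
  gts <- read_trees(gene_trees_file)
  if (length(gts) == 0L) stop("no gene trees found")
  gm <- read_group_map(groups_file)
  outgroup <- read_label_file(outgroup_file)
  md <- NULL
  if (!is.null(metadata_file)) {
    df <- utils::read.delim(metadata_file, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    md <- setNames(as.numeric(df[[2]]), trimws(df[[1]]))
  }
  cs <- census(gts, gm, outgroup, min_per_group = min_per_group, metadata = md)
  write_census(cs, out_dir)
  invisible(cs)
}

#' Simulate a dataset, file-level front end
#'
#' @param out_dir Output directory for the dataset files.
#' @param ... Passed to [sim_config()].
#' @return The [generate_dataset()] result, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  generate_dataset(sim_config(...), out_dir)
}
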