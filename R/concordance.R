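#' Can a trait pair be evaluated in a gene tree?
#'
#' A pair is evaluable in a gene tree when at least two of the tree's
#' leaves bear each of the two traits; with fewer bearers an origin node in
#' the gene tree is a leaf or undefined and carries no order information.
#' Missing trait states count as absences here, consistent with
#' [presence_set()].
#'
#' @param gene_tree A rooted `phylo` object whose leaves are species of `tm`.
#' @param tm A [trait_matrix()].
#' @param trait_a,trait_b Trait names.
#' @return Logical scalar.
#' @export
pair_evaluable <- function(gene_tree, tm, trait_a, trait_b) {
  tips <- gene_tree$tip.label
  length(intersect(presence_set(tm, trait_a), tips)) >= 2L &&
    length(intersect(presence_set(tm, trait_b), tips)) >= 2L
}

#' Order relation of a trait pair within a gene tree
#'
#' Applies the same origin rule as on the species tree — each trait's
#' origin is the MRCA of its bearers among the gene tree's leaves — then
#' compares the two origins with [compare_pair()].
#'
#' @inheritParams pair_evaluable
#' @return One of `"simultaneous"`, `"first_earlier"`, `"second_earlier"`,
#'   `"non_nested"`.
#' @export
gene_pair_relation <- function(gene_tree, tm, trait_a, trait_b) {
  if (!pair_evaluable(gene_tree, tm, trait_a, trait_b)) {
    stop("pair (", trait_a, ", ", trait_b, ") not evaluable in this gene tree")
  }
  a <- assign_origin(gene_tree, tm, trait_a)
  b <- assign_origin(gene_tree, tm, trait_b)
  compare_pair(gene_tree, a, b)
}

#' Gene-tree concordance with the species-tree trait order
#'
#' For every trait pair ordered on the species tree, counts the rooted gene
#' trees in which the same origin rule yields the identical relation, and
#' reports the agreement proportion over the evaluable trees. Agreement is
#' exact by default: a gene tree saying `"simultaneous"` where the species
#' tree says `"first_earlier"` is a disagreement, as is `"non_nested"`. In
#' lenient mode gene trees whose relation is `"non_nested"` are removed
#' from the pair's denominator instead of counting against it.
#'
#' Gene trees are expected to be rooted already (see [root_on_outgroup()]);
#' this function never roots. `exclude_taxa` are pruned from every gene
#' tree before evaluation (the taxon-exclusion sensitivity rerun), and
#' evaluability is re-checked after pruning.
#'
#' @param gene_trees List of rooted `phylo` objects.
#' @param tm A [trait_matrix()].
#' @param species_order A `trait_order` from [build_order()].
#' @param exclude_taxa Species labels to prune from every gene tree.
#' @param lenient Drop non-nested gene-tree relations from denominators?
#' @param prune_unknown Drop gene-tree leaves absent from the trait matrix
#'   instead of erroring.
#' @return A `trait_concordance` object: list with `pairs` (long data
#'   frame: trait_a, trait_b, species_relation, n_evaluable, n_agree,
#'   proportion), `n_gene_trees`, `lenient`.
#' @export
concordance <- function(gene_trees, tm, species_order,
                        exclude_taxa = character(0), lenient = FALSE,
                        prune_unknown = FALSE) {
  stopifnot(inherits(species_order, "trait_order"))
  traits <- names(species_order$origins)
  prepped <- lapply(gene_trees, function(gt) {
    unknown <- setdiff(gt$tip.label, rownames(tm))
    if (length(unknown) > 0L) {
      if (!prune_unknown) {
        stop("gene tree leaves absent from trait matrix: ",
             paste(utils::head(unknown, 5), collapse = ", "),
             if (length(unknown) > 5) " ...")
      }
      gt <- ape::drop.tip(gt, unknown)
    }
    dropme <- intersect(exclude_taxa, gt$tip.label)
    if (length(dropme) > 0L) {
      if (length(setdiff(gt$tip.label, dropme)) < 2L) return(NULL)
      gt <- ape::drop.tip(gt, dropme)
    }
    if (is.null(gt) || ape::Ntip(gt) < 2L) return(NULL)
    # precompute per-trait bearer counts and origin nodes once per tree
    bearers <- lapply(setNames(traits, traits),
                      function(tr) intersect(presence_set(tm, tr), gt$tip.label))
    nb <- vapply(bearers, length, integer(1))
    origins <- rep(NA_integer_, length(traits))
    names(origins) <- traits
    for (tr in traits[nb >= 1L]) origins[tr] <- mrca_node(gt, bearers[[tr]])
    anc <- ancestor_paths(gt, origins[!is.na(origins)])
    list(nb = nb, origins = origins, anc = anc)
  })
  prepped <- prepped[!vapply(prepped, is.null, logical(1))]

  idx <- which(upper.tri(matrix(0, length(traits), length(traits))), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ta <- traits[i]; tb <- traits[j]
    sp_rel <- species_order$relations[ta, tb]
    n_eval <- 0L; n_agree <- 0L
    for (pp in prepped) {
      if (pp$nb[ta] < 2L || pp$nb[tb] < 2L) next
      a <- pp$origins[ta]; b <- pp$origins[tb]
      g_rel <-
        if (a == b) "simultaneous"
        else if (a %in% pp$anc[[as.character(b)]]) "first_earlier"
        else if (b %in% pp$anc[[as.character(a)]]) "second_earlier"
        else "non_nested"
      if (lenient && g_rel == "non_nested" && sp_rel != "non_nested") next
      n_eval <- n_eval + 1L
      if (g_rel == sp_rel) n_agree <- n_agree + 1L
    }
    data.frame(trait_a = ta, trait_b = tb, species_relation = sp_rel,
               n_evaluable = n_eval, n_agree = n_agree,
               proportion = if (n_eval == 0L) NA_real_ else n_agree / n_eval,
               stringsAsFactors = FALSE)
  })
  structure(list(
    pairs = do.call(rbind, rows),
    n_gene_trees = length(gene_trees),
    lenient = lenient
  ), class = "trait_concordance")
}

#' Concordance results as a square matrix
#'
#' Upper triangle holds agreement proportions, lower triangle the number of
#' evaluable gene trees per pair.
#'
#' @param x A `trait_concordance` object.
#' @return A numeric matrix (traits x traits).
#' @export
concordance_matrix <- function(x) {
  # preserve the original pair ordering, not alphabetical
  traits <- unique(c(x$pairs$trait_a, x$pairs$trait_b))
  m <- matrix(NA_real_, length(traits), length(traits),
              dimnames = list(traits, traits))
  for (r in seq_len(nrow(x$pairs))) {
    i <- match(x$pairs$trait_a[r], traits)
    j <- match(x$pairs$trait_b[r], traits)
    m[min(i, j), max(i, j)] <- x$pairs$proportion[r]
    m[max(i, j), min(i, j)] <- x$pairs$n_evaluable[r]
  }
  m
}

#' @export
print.trait_concordance <- function(x, ...) {
  p <- x$pairs$proportion
  cat("Gene-tree concordance over ", nrow(x$pairs), " trait pairs, ",
      x$n_gene_trees, " gene trees (", if (x$lenient) "lenient" else "strict",
      ")\n  defined pairs: ", sum(!is.na(p)),
      "; mean agreement = ", format(mean(p, na.rm = TRUE), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Export concordance results to CSV and JSON
#'
#' Writes `concordance_long.csv` (heat-map-ready long format),
#' `concordance_matrix.csv` (upper = proportion, lower = n evaluable) and
#' `concordance.json` under `out_dir`.
#'
#' @param x A `trait_concordance` object.
#' @param out_dir Output directory.
#' @param prefix Optional file-name prefix (used by exclusion reruns).
#' @return Invisibly, the paths written.
#' @export
write_concordance <- function(x, out_dir, prefix = "concordance") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long_path <- file.path(out_dir, paste0(prefix, "_long.csv"))
  mat_path <- file.path(out_dir, paste0(prefix, "_matrix.csv"))
  json_path <- file.path(out_dir, paste0(prefix, ".json"))
  utils::write.csv(x$pairs, long_path, row.names = FALSE)
  utils::write.csv(concordance_matrix(x), mat_path)
  jsonlite::write_json(list(
    n_gene_trees = x$n_gene_trees, lenient = x$lenient,
    mean_proportion = mean(x$pairs$proportion, na.rm = TRUE),
    n_pairs = nrow(x$pairs),
    n_undefined = sum(is.na(x$pairs$proportion)),
    pairs = x$pairs
  ), json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(long_path, mat_path, json_path))
}
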