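#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults mirror the shape of the cyanobacterial study system the
#' pipeline was built for: 199 ingroup species, 21 binary traits, 553 gene
#' trees, 6 outgroup taxa, and three ingroup groups (the clade on one side
#' of the root; a mid-size clade of roughly 16% of the species; the rest).
#' Noise parameters the study does not determine are fixed at moderate
#' values: per-edge trait loss probability 0.05, per-gene taxon retention
#' 0.8, 2 NNI perturbations per gene tree, no lateral trait transfer and no
#' missing data unless requested.
#'
#' One master seed drives everything; per-component substreams are derived
#' from it so that, e.g., changing `n_gene_trees` leaves the trait matrix
#' untouched.
#'
#' @param n_species Ingroup species count (>= 4).
#' @param n_traits Number of binary traits.
#' @param loss_prob Per-edge probability of an irreversible trait loss
#'   below the origin, in `[0, 1]`.
#' @param n_gene_trees Number of gene trees to simulate.
#' @param retention Per-species retention probability per gene tree, in
#'   `(0, 1]`.
#' @param n_nni Number of random NNI moves applied to each gene tree.
#' @param lgt_prob Per-trait probability of one extra gain grafted onto a
#'   non-descendant clade (controlled homoplasy), in `[0, 1]`.
#' @param missing_prob Per-cell probability of masking a state as
#'   unobserved, in `[0, 1)`.
#' @param n_outgroup Number of outgroup taxa appended to gene trees.
#' @param second_group_fraction Target fraction of ingroup species for the
#'   mid-size group, in `(0, 1)`.
#' @param origin_nodes Optional explicit vector of origin node ids (must be
#'   totally ordered by ancestry); default samples a root-to-tip backbone.
#' @param seed Master seed (integer).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 199L, n_traits = 21L, loss_prob = 0.05,
                       n_gene_trees = 553L, retention = 0.8, n_nni = 2L,
                       lgt_prob = 0, missing_prob = 0, n_outgroup = 6L,
                       second_group_fraction = 0.16, origin_nodes = NULL,
                       seed = 1L) {
  stopifnot(n_species >= 4L, n_traits >= 1L, n_gene_trees >= 0L,
            loss_prob >= 0, loss_prob <= 1,
            retention > 0, retention <= 1,
            n_nni >= 0L, lgt_prob >= 0, lgt_prob <= 1,
            missing_prob >= 0, missing_prob < 1,
            n_outgroup >= 1L,
            second_group_fraction > 0, second_group_fraction < 1)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(
    n_species = as.integer(n_species), n_traits = as.integer(n_traits),
    loss_prob = loss_prob, n_gene_trees = as.integer(n_gene_trees),
    retention = retention, n_nni = as.integer(n_nni), lgt_prob = lgt_prob,
    missing_prob = missing_prob, n_outgroup = as.integer(n_outgroup),
    second_group_fraction = second_group_fraction,
    origin_nodes = origin_nodes, seed = seed
  ), class = "sim_config")
}

# deterministic 31-bit substream seed per component
substream_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Rooted binary tree with exponentially distributed waiting times,
#' deterministically labeled `s001`, `s002`, ... in tip-number order.
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A rooted `phylo` object.
#' @export
simulate_species_tree <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2L)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$tip.label <- sprintf("s%03d", seq_len(n_species))
  validate_tree(tr)
}

# internal nodes along the root -> deepest-leaf path (root first, the
# deepest internal node last); ties broken by node number
backbone_nodes <- function(tree) {
  p <- node_parents(tree)
  n <- ape::Ntip(tree)
  depth <- vapply(seq_len(n), function(i) node_depth_edges(tree, i), integer(1))
  leaf <- which.max(depth)
  path <- integer(0)
  nd <- p[leaf]
  while (nd != 0L) {
    path <- c(nd, path)
    nd <- p[nd]
  }
  path
}

#' Simulate binary traits under a single-gain / multiple-loss model
#'
#' Each trait is gained exactly once at an origin node and is then present
#' in every descendant, except where an irreversible loss strikes: every
#' edge strictly below the origin loses the trait (in its whole subtree)
#' independently with probability `loss_prob`. Origins are placed on the
#' nodes of a root-to-tip backbone path, evenly spaced root-first, so the
#' true emergence order is nested and known; when more traits than
#' backbone nodes are requested, several traits share an origin (blocks).
#' With probability `lgt_prob` a trait receives one extra gain on a clade
#' disjoint from its origin clade, creating controlled homoplasy. Traits
#' whose losses wipe out every bearer are resampled (and logged). Cells are
#' masked to missing with probability `missing_prob`, never masking a
#' trait's last observed presence.
#'
#' @param tree A rooted species tree.
#' @param config A [sim_config()].
#' @return A list: `matrix` (a [trait_matrix()]) and `truth` — a ground
#'   truth record with per-trait `origin` node, `origin_tips`, `losses`
#'   (edge child-node ids), `lgt_node`, `n_resamples`, plus the true
#'   `blocks` (root-most first).
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "traits"))
  n <- ape::Ntip(tree)
  p <- node_parents(tree)
  bb <- backbone_nodes(tree)
  if (!is.null(config$origin_nodes)) {
    origins <- as.integer(config$origin_nodes)
    if (length(origins) != config$n_traits) {
      stop("origin_nodes must have length n_traits")
    }
    dist_o <- unique(origins)
    for (i in seq_along(dist_o)) {
      for (j in seq_along(dist_o)) {
        if (i < j && dist_o[i] != dist_o[j] &&
            !is_ancestor(tree, dist_o[i], dist_o[j]) &&
            !is_ancestor(tree, dist_o[j], dist_o[i])) {
          stop("explicit origin nodes are not totally ordered by ancestry")
        }
      }
    }
  } else {
    if (length(bb) == 0L) stop("tree has no internal backbone (too few species)")
    origins <- bb[sort(round(seq(1, length(bb), length.out = config$n_traits)))]
  }
  traits <- sprintf("t%02d", seq_len(config$n_traits))
  m <- matrix(0L, n, config$n_traits,
              dimnames = list(tree$tip.label, traits))
  desc_tips <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  truth_traits <- vector("list", config$n_traits)
  names(truth_traits) <- traits

  draw_trait <- function(origin) {
    # preorder walk below origin; each edge may kill its whole subtree
    lost <- rep(FALSE, n + tree$Nnode)
    loss_edges <- integer(0)
    stack <- origin
    while (length(stack) > 0L) {
      nd <- stack[1]; stack <- stack[-1]
      kids <- kids_of[[as.character(nd)]]
      for (k in kids) {
        if (lost[nd]) {
          lost[k] <- TRUE
        } else if (stats::runif(1) < config$loss_prob) {
          lost[k] <- TRUE
          loss_edges <- c(loss_edges, k) # maximal (visible) loss events only
        }
        if (k > n) stack <- c(stack, k)
      }
    }
    present <- desc_tips[[origin]]
    present <- present[!lost[present]]
    list(present = present, losses = loss_edges)
  }

  for (i in seq_len(config$n_traits)) {
    origin <- origins[i]
    n_res <- 0L
    repeat {
      d <- draw_trait(origin)
      if (length(d$present) > 0L) break
      n_res <- n_res + 1L
      if (n_res > 1000L) stop("could not realize a surviving trait; lower loss_prob")
    }
    lgt_node <- NA_integer_
    if (config$lgt_prob > 0 && stats::runif(1) < config$lgt_prob) {
      ocl <- desc_tips[[origin]]
      cand <- which(vapply(seq_len(n + tree$Nnode), function(nd)
        length(intersect(desc_tips[[nd]], ocl)) == 0L, logical(1)))
      if (length(cand) > 0L) {
        lgt_node <- cand[sample.int(length(cand), 1L)]
        d$present <- union(d$present, desc_tips[[lgt_node]])
      }
    }
    m[d$present, i] <- 1L
    truth_traits[[i]] <- list(origin = origin,
                              origin_tips = sort(tree$tip.label[desc_tips[[origin]]]),
                              losses = d$losses, lgt_node = lgt_node,
                              n_resamples = n_res)
  }

  if (config$missing_prob > 0) {
    for (i in seq_len(config$n_traits)) {
      mask <- stats::runif(n) < config$missing_prob
      # never mask the last observed presence of a trait
      pres <- which(m[, i] == 1L)
      if (all(pres %in% which(mask))) mask[pres[1]] <- FALSE
      m[mask, i] <- NA_integer_
    }
  }

  uniq <- unique(origins)
  depth <- vapply(uniq, function(nd) node_depth_edges(tree, nd), integer(1))
  ord <- order(depth, match(uniq, origins))
  blocks <- lapply(ord, function(j) {
    nd <- uniq[j]
    list(node = nd, depth = depth[j],
         tips = sort(tree$tip.label[desc_tips[[nd]]]),
         traits = traits[origins == nd])
  })
  list(matrix = trait_matrix(m),
       truth = list(traits = truth_traits, blocks = blocks, origins = origins))
}

#' Simulate gene trees as subsampled, NNI-perturbed copies of the species tree
#'
#' Each gene tree keeps every ingroup species independently with
#' probability `retention` (redrawn while fewer than 4 survive), applies
#' `n_nni` random nearest-neighbor interchanges, and finally receives an
#' outgroup clade (labels `og1`, `og2`, ...; each outgroup taxon retained
#' with the same probability, at least one kept) as sister to the whole
#' ingroup, so that downstream outgroup rooting is exercised end to end.
#'
#' @param tree The rooted ingroup species tree.
#' @param config A [sim_config()].
#' @return A list: `trees` (named list of `phylo`) and `log` (data frame:
#'   tree, n_kept, n_outgroup, n_nni, n_redraws).
#' @export
simulate_gene_trees <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genes"))
  n <- ape::Ntip(tree)
  og_all <- sprintf("og%d", seq_len(config$n_outgroup))
  trees <- vector("list", config$n_gene_trees)
  logs <- vector("list", config$n_gene_trees)
  for (i in seq_len(config$n_gene_trees)) {
    n_redraws <- 0L
    repeat {
      keep <- which(stats::runif(n) < config$retention)
      if (length(keep) >= 4L) break
      n_redraws <- n_redraws + 1L
    }
    gt <- ape::keep.tip(tree, tree$tip.label[keep])
    gt$edge.length <- NULL
    gt$node.label <- NULL
    if (config$n_nni > 0L) {
      gt <- phangorn::rNNI(gt, moves = config$n_nni)
    }
    n_og <- sum(stats::runif(config$n_outgroup) < config$retention)
    n_og <- max(1L, n_og)
    og <- og_all[seq_len(n_og)]
    og_str <- if (n_og == 1L) og else paste0("(", paste(og, collapse = ","), ")")
    ing_str <- sub(";$", "", write_newick(gt))
    full <- parse_newick(paste0("(", ing_str, ",", og_str, ");"))
    trees[[i]] <- full
    logs[[i]] <- data.frame(tree = sprintf("gene%04d", i),
                            n_kept = length(keep), n_outgroup = n_og,
                            n_nni = config$n_nni, n_redraws = n_redraws,
                            stringsAsFactors = FALSE)
  }
  names(trees) <- sprintf("gene%04d", seq_len(config$n_gene_trees))
  list(trees = trees, log = do.call(rbind, logs))
}

# three ingroup groups from the realized tree: G1 = smaller root side
# (the basal group by construction), G2 = the clade on the other side whose
# size is closest to second_group_fraction of the ingroup, G3 = the rest
groups_from_tree <- function(tree, second_group_fraction = 0.16) {
  n <- ape::Ntip(tree)
  rn <- root_node(tree)
  kids <- tree$edge[tree$edge[, 1] == rn, 2]
  sides <- lapply(kids, function(k) tips_under(tree, k))
  sizes <- vapply(sides, length, integer(1))
  basal <- sides[[which.min(sizes)]]
  other_side_node <- kids[which.max(sizes)]
  desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  other_tips <- sides[[which.max(sizes)]]
  target <- second_group_fraction * n
  cand <- setdiff(which(vapply(desc, function(d)
    all(tree$tip.label[d] %in% other_tips), logical(1))), other_side_node)
  cand <- cand[vapply(cand, function(nd) length(desc[[nd]]) >= 2L, logical(1))]
  cand <- cand[vapply(cand, function(nd)
    length(desc[[nd]]) < length(other_tips), logical(1))]
  if (length(cand) == 0L) stop("tree too small to carve three groups")
  pick <- cand[which.min(abs(vapply(cand, function(nd)
    length(desc[[nd]]), integer(1)) - target))]
  g2 <- tree$tip.label[desc[[pick]]]
  g3 <- setdiff(other_tips, g2)
  gm <- c(setNames(rep("G1", length(basal)), basal),
          setNames(rep("G2", length(g2)), g2),
          setNames(rep("G3", length(g3)), g3))
  gm[tree$tip.label]
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_species_tree()], [simulate_traits()] and
#' [simulate_gene_trees()] on independent substreams of the master seed,
#' derives a three-group map from the realized tree (the smaller root side
#' is the true basal group, `G1`), and writes:
#' `species_tree.nwk`, `gene_trees.nwk` (one per line), `traits.tsv`,
#' `groups.tsv`, `outgroup.txt`, `ground_truth.json`, `manifest.json`.
#' Re-running with the same config reproduces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: config, file paths and md5 checksums.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulate_species_tree(config$n_species,
                              substream_seed(config$seed, "tree"))
  tm <- simulate_traits(sp, config)
  gt <- simulate_gene_trees(sp, config)
  gm <- groups_from_tree(sp, config$second_group_fraction)
  og <- sprintf("og%d", seq_len(config$n_outgroup))

  paths <- c(
    species_tree = file.path(out_dir, "species_tree.nwk"),
    gene_trees = file.path(out_dir, "gene_trees.nwk"),
    traits = file.path(out_dir, "traits.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    outgroup = file.path(out_dir, "outgroup.txt"),
    ground_truth = file.path(out_dir, "ground_truth.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  writeLines(write_newick(sp), paths["species_tree"])
  write_trees(gt$trees, paths["gene_trees"])
  write_trait_matrix(tm$matrix, paths["traits"])
  utils::write.table(data.frame(species = names(gm), group = unname(gm)),
                     paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(og, paths["outgroup"])
  jsonlite::write_json(list(
    basal_group = "G1",
    origins = lapply(tm$truth$traits, function(x)
      list(origin_tips = x$origin_tips, n_losses = length(x$losses),
           lgt = !is.na(x$lgt_node), n_resamples = x$n_resamples)),
    blocks = lapply(tm$truth$blocks, function(b)
      list(traits = b$traits, depth = b$depth, clade = b$tips)),
    gene_tree_log = gt$log
  ), paths["ground_truth"], auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   files = as.list(paths[names(paths) != "manifest"]),
                   md5 = as.list(tools::md5sum(unname(paths[names(paths) != "manifest"]))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(config = config, paths = paths,
                 species_tree = sp, traits = tm, gene_trees = gt,
                 group_map = gm, outgroup = og))
}
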