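test_that("simulate_species_tree is deterministic with the requested leaf count", {
  t2 <- simulate_species_tree(2, 1)
  expect_equal(ape::Ntip(t2), 2)
  a <- write_newick(simulate_species_tree(64, 5))
  b <- write_newick(simulate_species_tree(64, 5))
  expect_identical(a, b)
  for (n in c(4, 10, 33)) {
    expect_equal(ape::Ntip(simulate_species_tree(n, 3)), n)
  }
})

test_that("sim_config validates its domains", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_species = 3))
  expect_error(sim_config(loss_prob = 1.2))
  expect_error(sim_config(retention = 0))
  expect_error(sim_config(n_nni = -1))
})

test_that("noise-free traits equal their origin clades; losses stay below the origin", {
  sp <- simulate_species_tree(24, 11)
  cfg0 <- sim_config(n_species = 24, n_traits = 6, loss_prob = 0,
                     n_gene_trees = 0, seed = 11)
  sim0 <- simulate_traits(sp, cfg0)
  for (tr in colnames(sim0$matrix)) {
    expect_setequal(presence_set(sim0$matrix, tr),
                    sim0$truth$traits[[tr]]$origin_tips)
    expect_length(sim0$truth$traits[[tr]]$losses, 0)
  }
  # true blocks are nested root-to-tip
  blocks <- sim0$truth$blocks
  for (i in seq_along(blocks)[-1]) {
    expect_true(all(blocks[[i]]$tips %in% blocks[[i - 1]]$tips))
  }
  # with losses on: every loss edge is strictly below the trait's origin
  cfgL <- sim_config(n_species = 24, n_traits = 6, loss_prob = 0.15,
                     n_gene_trees = 0, seed = 11)
  simL <- simulate_traits(sp, cfgL)
  for (tr in colnames(simL$matrix)) {
    info <- simL$truth$traits[[tr]]
    for (edge_child in info$losses) {
      expect_true(edge_child == info$origin ||
                  is_ancestor(sp, info$origin, edge_child))
      expect_true(edge_child != info$origin)
    }
    expect_gte(length(presence_set(simL$matrix, tr)), 1)
  }
})

test_that("a grafted extra gain forces at least two parsimony steps", {
  sp <- simulate_species_tree(24, 13)
  cfg <- sim_config(n_species = 24, n_traits = 8, loss_prob = 0,
                    lgt_prob = 1, n_gene_trees = 0, seed = 13)
  sim <- simulate_traits(sp, cfg)
  grafted <- Filter(function(x) !is.na(x$lgt_node), sim$truth$traits)
  expect_gt(length(grafted), 0)
  for (tr in names(grafted)) {
    st <- setNames(sim$matrix[, tr], rownames(sim$matrix))
    expect_gte(parsimony_steps(sp, st), 2L)
  }
})

test_that("explicit origin nodes must be totally ordered by ancestry", {
  sp <- parse_newick("((A,B),(C,D));")
  cfg <- sim_config(n_species = 4, n_traits = 2, n_gene_trees = 0, seed = 1,
                    origin_nodes = c(mrca_node(sp, c("A", "B")),
                                     mrca_node(sp, c("C", "D"))))
  expect_error(simulate_traits(sp, cfg), "not totally ordered")
  ok <- sim_config(n_species = 4, n_traits = 2, n_gene_trees = 0, seed = 1,
                   origin_nodes = c(5L, mrca_node(sp, c("A", "B"))))
  sim <- simulate_traits(sp, ok)
  expect_equal(unname(sim$truth$origins), c(5L, 6L))
})

test_that("unperturbed full-retention gene trees match the species tree", {
  sp <- simulate_species_tree(16, 19)
  cfg <- sim_config(n_species = 16, n_traits = 2, n_gene_trees = 6,
                    retention = 1, n_nni = 0, seed = 19)
  gt <- simulate_gene_trees(sp, cfg)
  for (g in gt$trees) {
    ing <- ape::keep.tip(g, sp$tip.label)
    expect_equal(phangorn::RF.dist(ape::unroot(ing), ape::unroot(sp)), 0)
  }
})

test_that("subsampled but unperturbed gene trees display only species-tree splits", {
  sp <- simulate_species_tree(20, 23)
  cfg <- sim_config(n_species = 20, n_traits = 2, n_gene_trees = 8,
                    retention = 0.7, n_nni = 0, seed = 23)
  gt <- simulate_gene_trees(sp, cfg)
  for (g in gt$trees) {
    ing_tips <- intersect(g$tip.label, sp$tip.label)
    ing <- ape::keep.tip(g, ing_tips)
    ref <- ape::keep.tip(sp, ing_tips)
    expect_equal(phangorn::RF.dist(ape::unroot(ing), ape::unroot(ref)), 0)
  }
})

test_that("every gene tree carries at least one outgroup leaf, rootable by construction", {
  sp <- simulate_species_tree(16, 29)
  cfg <- sim_config(n_species = 16, n_traits = 2, n_gene_trees = 10,
                    retention = 0.6, n_nni = 4, seed = 29)
  gt <- simulate_gene_trees(sp, cfg)
  for (g in gt$trees) {
    og <- grep("^og", g$tip.label, value = TRUE)
    expect_gte(length(og), 1)
    expect_true(outgroup_partition_ok(g, og))
  }
})

test_that("generate_dataset writes a complete, reproducible, re-parseable bundle", {
  cfg <- sim_config(n_species = 16, n_traits = 5, n_gene_trees = 6,
                    retention = 0.9, n_nni = 1, missing_prob = 0.05, seed = 41)
  d1 <- generate_dataset(cfg, tempfile())
  d2 <- generate_dataset(cfg, tempfile())
  files <- setdiff(names(d1$paths), "manifest")
  for (f in files) {
    expect_identical(unname(tools::md5sum(d1$paths[[f]])),
                     unname(tools::md5sum(d2$paths[[f]])),
                     info = f)
  }
  # all artifacts parse with the package's own readers
  sp <- read_trees(d1$paths[["species_tree"]])[[1]]
  expect_equal(ape::Ntip(sp), 16)
  expect_length(read_trees(d1$paths[["gene_trees"]]), 6)
  tm <- read_trait_matrix(d1$paths[["traits"]])
  expect_equal(dim(tm), c(16L, 5L))
  gm <- read_group_map(d1$paths[["groups"]])
  expect_setequal(names(gm), sp$tip.label)
  expect_setequal(unique(unname(gm)), c("G1", "G2", "G3"))
  expect_length(readLines(d1$paths[["outgroup"]]), cfg$n_outgroup)
  manifest <- jsonlite::read_json(d1$paths[["manifest"]])
  expect_equal(manifest$config$seed, 41)
})

test_that("the trait substream is insulated from the gene-tree settings", {
  c1 <- sim_config(n_species = 16, n_traits = 4, n_gene_trees = 3, seed = 9)
  c2 <- sim_config(n_species = 16, n_traits = 4, n_gene_trees = 30, seed = 9)
  d1 <- generate_dataset(c1, tempfile())
  d2 <- generate_dataset(c2, tempfile())
  expect_identical(unname(tools::md5sum(d1$paths[["traits"]])),
                   unname(tools::md5sum(d2$paths[["traits"]])))
})

test_that("the group map marks the smaller root side as the basal group", {
  cfg <- sim_config(n_species = 30, n_traits = 2, n_gene_trees = 0, seed = 55)
  d <- generate_dataset(cfg, tempfile())
  sp <- d$species_tree
  rn <- ape::Ntip(sp) + 1L
  kids <- sp$edge[sp$edge[, 1] == rn, 2]
  sides <- lapply(kids, function(k) traitorder:::tips_under(sp, k))
  smaller <- sides[[which.min(lengths(sides))]]
  expect_setequal(names(d$group_map)[d$group_map == "G1"], smaller)
})

test_that("origin-order recovery stays high under mild loss", {
  accs <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_species = 32, n_traits = 8, loss_prob = 0.05,
                      n_gene_trees = 0, retention = 0.9, n_nni = 1, seed = seed)
    d <- generate_dataset(cfg, tempfile())
    ord <- build_order(d$species_tree, d$traits$matrix)
    tru <- truth_relations(d$species_tree, d$traits$truth)
    mean(ord$relations[upper.tri(ord$relations)] == tru[upper.tri(tru)])
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})
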