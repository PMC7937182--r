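test_that("parsimony_steps handles the worked micro-examples", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(parsimony_steps(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_equal(parsimony_steps(tr, c(A = 1, B = 0, C = 0, D = 0)), 1L)
  expect_equal(parsimony_steps(tr, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_equal(parsimony_steps(tr, c(A = 1, B = 0, C = 1, D = 0)),
               bf_parsimony(tr, c(A = 1, B = 0, C = 1, D = 0)))
  expect_error(parsimony_steps(tr, c(A = 1, B = 0, C = 1)), "leaf without a state")
  expect_error(parsimony_steps(tr, c(A = NA, B = NA, C = NA, D = NA)[c("A","B","C","D")]),
               "all states missing")
})

test_that("parsimony_steps equals brute-force enumeration on 200 random instances", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(4:8, 1) # binary rooted tree: n - 1 internal nodes, <= 7
    tr <- ape::rtree(n)
    tr$tip.label <- sprintf("L%02d", seq_len(n))
    states <- sample(c(0L, 1L), n, replace = TRUE)
    # sprinkle at most two missing values
    nmiss <- sample(0:2, 1)
    if (nmiss > 0) states[sample(n, nmiss)] <- NA
    if (all(is.na(states))) states[1] <- 1L
    names(states) <- tr$tip.label
    expect_equal(parsimony_steps(tr, states), bf_parsimony(tr, states),
                 info = paste("instance", i))
  }
})

test_that("parsimony_steps agrees with an independent library implementation", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    tr <- ape::rtree(n)
    states <- sample(c(0L, 1L), n, replace = TRUE)
    names(states) <- tr$tip.label
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(parsimony_steps(tr, states),
                 as.integer(phangorn::parsimony(tr, dat, method = "sankoff")))
  }
})

test_that("parsimony_steps is invariant to the root position", {
  set.seed(7)
  tr <- ape::rtree(10)
  tr$tip.label <- sprintf("L%02d", 1:10)
  states <- setNames(sample(c(0L, 1L), 10, replace = TRUE), tr$tip.label)
  ref <- parsimony_steps(tr, states)
  for (tip in tr$tip.label) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(parsimony_steps(rr, states), ref)
  }
  for (node in (ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode)) {
    og <- traitorder:::tips_under(tr, node)
    if (length(og) < ape::Ntip(tr) - 1) {
      rr <- root_on_outgroup(tr, og)
      expect_equal(parsimony_steps(rr, states), ref)
    }
  }
})

test_that("min_steps and max_steps implement the binary-character bounds", {
  expect_equal(min_steps(c(1, 1, 1)), 0L)
  expect_equal(min_steps(c(1, 0, 1)), 1L)
  expect_equal(min_steps(c(NA, NA, 0)), 0L)
  expect_equal(max_steps(c(1, 1, 0, 0)), 2)
  expect_equal(max_steps(c(1, rep(0, 20))), 1)
  expect_equal(max_steps(c(1, 1, 1)), 0)
  expect_equal(max_steps(c(NA, 1, 0, 0)), 1)
})

test_that("trait_indices reproduces CI/RI hand formulas and guards division by zero", {
  tr <- parse_newick("((A,B),(C,D));")
  tm <- tm_from_sets(c("A", "B", "C", "D"),
                     list(synapomorphy = c("A", "B"),
                          homoplasy = c("A", "C"),
                          singleton = "A",
                          invariant = c("A", "B", "C", "D")))
  idx <- trait_indices(tr, tm)
  tab <- idx$table
  rownames(tab) <- tab$trait
  # perfect synapomorphy: one step, no homoplasy
  expect_equal(tab["synapomorphy", c("m", "s", "g")], data.frame(m = 1L, s = 1L, g = 2,
               row.names = "synapomorphy"))
  expect_equal(tab["synapomorphy", "ci"], 1)
  expect_equal(tab["synapomorphy", "ri"], 1)
  # A=1,B=0,C=1,D=0: s=2, CI=0.5, RI=0
  expect_equal(tab["homoplasy", "s"], 2L)
  expect_equal(tab["homoplasy", "ci"], 0.5)
  expect_equal(tab["homoplasy", "ri"], 0)
  # single presence: CI defined (=1), RI undefined (g = m = 1)
  expect_equal(tab["singleton", "ci"], 1)
  expect_true(is.na(tab["singleton", "ri"]))
  # invariant: s = 0, CI undefined
  expect_true(is.na(tab["invariant", "ci"]))
  expect_setequal(idx$ci_excluded, "invariant")
  expect_setequal(idx$ri_excluded, c("singleton", "invariant"))
  # medians computed over the defined values only
  expect_equal(idx$median_ci, median(c(1, 0.5, 1)))
  expect_equal(idx$median_ri, median(c(1, 0)))
})

test_that("m <= s <= g and a one-clade trait scores CI = RI = 1", {
  for (seed in 1:8) {
    tr <- rand_tree(12, seed)
    set.seed(seed)
    sets <- lapply(1:5, function(i) sample(tr$tip.label, sample(2:10, 1)))
    names(sets) <- sprintf("t%d", 1:5)
    # add a clean clade trait
    node <- sample((ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode), 1)
    sets$clade <- traitorder:::tips_under(tr, node)
    tm <- tm_from_sets(tr$tip.label, sets)
    tab <- trait_indices(tr, tm)$table
    expect_true(all(tab$m <= tab$s & tab$s <= tab$g))
    cl <- tab[tab$trait == "clade", ]
    if (cl$g > cl$m) {
      expect_equal(cl$s, 1L)
      expect_equal(cl$ci, 1)
      expect_equal(cl$ri, 1)
    }
  }
})

test_that("single-origin losses bound the parsimony length via the event log", {
  for (seed in 1:10) {
    cfg <- sim_config(n_species = 32, n_traits = 6, loss_prob = 0.1,
                      n_gene_trees = 0, seed = seed)
    sp <- simulate_species_tree(32, seed)
    sim <- simulate_traits(sp, cfg)
    for (tr in colnames(sim$matrix)) {
      st <- setNames(sim$matrix[, tr], rownames(sim$matrix))
      s <- parsimony_steps(sp, st)
      info <- sim$truth$traits[[tr]]
      if (min_steps(st) == 1L) expect_gte(s, 1L)
      expect_lte(s, 1L + length(info$losses))
      if (length(info$losses) == 0L && min_steps(st) == 1L) expect_equal(s, 1L)
    }
  }
})

test_that("indices export to CSV and JSON", {
  tr <- parse_newick("((A,B),(C,D));")
  tm <- tm_from_sets(c("A", "B", "C", "D"), list(t1 = c("A", "B")))
  out <- tempfile()
  write_indices(trait_indices(tr, tm), out)
  tab <- read.csv(file.path(out, "indices.csv"))
  expect_equal(tab$ci, 1)
  js <- jsonlite::read_json(file.path(out, "indices_summary.json"))
  expect_equal(js$median_ri, 1)
})
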