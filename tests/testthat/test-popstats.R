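test_that("gene diversity matches closed forms and is relabeling-invariant", {
  expect_equal(gene_diversity(c(h1 = 10)), 0)
  expect_equal(gene_diversity(rep(1, 7)), 1)
  # counts (2,1,1): (4/3)(1 - 6/16) = 5/6
  expect_equal(gene_diversity(c(2, 1, 1)), 5 / 6, tolerance = 1e-12)
  expect_equal(round(gene_diversity(c(2, 1, 1)), 4), 0.8333)

  expect_error(gene_diversity(c(h1 = 1)), class = "ysnpdb_too_few")

  set.seed(12)
  for (i in 1:10) {
    counts <- rpois(6, 5) + 1
    expect_equal(gene_diversity(counts), gene_diversity(rev(counts)))
    # splitting one class into two nonzero classes increases diversity
    split <- c(counts[-1], counts[1] - 1, 1)
    if (counts[1] >= 2) expect_gt(gene_diversity(split), gene_diversity(counts))
  }
})

test_that("pairwise FST hits its limits and matches the brute-force AMOVA oracle", {
  # identical monomorphic populations
  expect_equal(as.numeric(pairwise_fst(c(h1 = 10), c(h1 = 10))), 0)
  # opposite fixation
  expect_equal(as.numeric(pairwise_fst(c(h1 = 10), c(h2 = 10))), 1)

  fixtures <- list(
    list(a = c(h1 = 8, h2 = 2), b = c(h1 = 2, h2 = 8)),
    list(a = c(h1 = 5, h2 = 5, h3 = 2), b = c(h1 = 1, h2 = 9, h4 = 3)),
    list(a = c(h1 = 3, h2 = 4), b = c(h2 = 6, h3 = 6))
  )
  for (fx in fixtures) {
    got <- as.numeric(pairwise_fst(fx$a, fx$b))
    want <- oracle_amova_fst(fx$a, fx$b)
    expect_equal(got, want, tolerance = 1e-12)
    # symmetry
    expect_equal(as.numeric(pairwise_fst(fx$b, fx$a)), got, tolerance = 1e-12)
    expect_lte(got, 1)
  }

  # negative estimates are reported unless clamped
  a <- c(h1 = 5, h2 = 5)
  b <- c(h1 = 5, h2 = 5)
  raw <- as.numeric(pairwise_fst(a, b))
  expect_lte(raw, 0)
  expect_equal(as.numeric(pairwise_fst(a, b, clamp = TRUE)), max(0, raw))

  expect_error(pairwise_fst(c(h1 = 1), c(h1 = 5)), class = "ysnpdb_too_few")
})

test_that("reduced panel keeps exactly the SNPs meeting both criteria", {
  # 12 branches under one root, one SNP each, with planted typing/frequency
  ids <- sprintf("B%02d", 1:12)
  branches <- c(
    list(list(id = "ROOT", parent = NA_character_, snps = list())),
    lapply(1:12, function(i) list(
      id = ids[i], parent = "ROOT",
      snps = list(list(name = sprintf("T%02d", i), synonyms = character(0),
                       position = NA_integer_))
    ))
  )
  tree <- ysnpdb:::build_tree(branches, version = "planted")

  # two populations of 20; SNP i typed in samples whose index < typed_n[i],
  # derived in PopA samples with index < der_n[i]
  typed_n <- c(40, 40, 40, 40, 40, 40, 40, 30, 30, 40, 40, 20)  # /40 samples
  der_n <- c(5, 1, 20, 0, 0, 10, 3, 20, 1, 2, 2, 20)            # /20 PopA typed max
  samples <- list()
  for (p in c("PopA", "PopB")) {
    for (j in 1:20) {
      idx <- if (p == "PopA") j else 20 + j
      der <- character(0)
      anc <- character(0)
      for (i in 1:12) {
        if (idx > typed_n[i]) next
        if (p == "PopA" && j <= der_n[i]) der <- c(der, sprintf("T%02d", i))
        else anc <- c(anc, sprintf("T%02d", i))
      }
      samples[[length(samples) + 1]] <-
        make_sample(sprintf("%s_%02d", p, j), "R1", derived = der,
                    ancestral = anc, population = p)
    }
  }
  ds <- make_dataset(samples, tree)

  panel <- build_reduced_panel(ds, tree, typed_min = 0.90, freq_min = 0.05)
  # brute-force both criteria per SNP
  expected <- character(0)
  for (i in 1:12) {
    typed_frac <- typed_n[i] / 40
    freq_a <- der_n[i] / min(typed_n[i], 20)
    if (typed_frac >= 0.90 && freq_a >= 0.05) expected <- c(expected, ids[i])
  }
  expect_setequal(panel$branch_ids, expected)
  expect_length(expected, 7)  # planted: exactly 7 qualify

  # monotonicity: tightening either criterion never adds SNPs
  for (tm in c(0.95, 1.0)) {
    expect_true(all(build_reduced_panel(ds, tree, typed_min = tm)$branch_ids
                    %in% panel$branch_ids))
  }
  for (fm in c(0.10, 0.30)) {
    expect_true(all(build_reduced_panel(ds, tree, freq_min = fm)$branch_ids
                    %in% panel$branch_ids))
  }

  expect_error(build_reduced_panel(make_dataset(list(), tree, regions = "R1"), tree),
               class = "ysnpdb_empty_dataset")
})

test_that("collapsed trees re-parent to the nearest kept ancestor", {
  p <- tempfile(fileext = ".json")
  writeLines('{"version":"v","branches":[
    {"id":"A","parent":null,"snps":[]},
    {"id":"B","parent":"A","snps":[{"name":"S1","synonyms":[],"position":null}]},
    {"id":"C","parent":"B","snps":[{"name":"S2","synonyms":[],"position":null}]},
    {"id":"D","parent":"C","snps":[{"name":"S3","synonyms":[],"position":null}]}]}', p)
  tree <- load_tree(p)
  collapsed <- ysnpdb:::collapse_tree(tree, c("B", "D"))  # C dropped
  expect_setequal(names(collapsed$branches), c("A", "B", "D"))
  expect_identical(collapsed$branches[["D"]]$parent, "B")
})

test_that("samples collapse to the deepest derived panel branch", {
  sim <- shared_sim()
  tree <- sim$tree
  ds <- sim$sim$dataset
  panel <- build_reduced_panel(ds, tree)

  # nested derived evidence picks the deeper branch
  nested <- NULL
  for (b in panel$branch_ids) {
    anc <- intersect(ancestors(tree, b), panel$branch_ids)
    if (length(anc) >= 2) {
      nested <- b
      break
    }
  }
  if (!is.null(nested)) {
    snp <- tree$branches[[nested]]$snps[[1]]$name
    parent_panel <- setdiff(intersect(ancestors(tree, nested), panel$branch_ids), nested)
    parent_snp <- tree$branches[[parent_panel[length(parent_panel)]]]$snps[[1]]$name
    s <- make_sample("nest", "Region01", derived = c(snp, parent_snp))
    expect_identical(collapse_assignment(s, panel, tree), nested)
  }

  # no panel-relevant calls -> root
  blank <- make_sample("blank", "Region01")
  expect_identical(collapse_assignment(blank, panel, tree), tree$root)

  # collapsing never deepens an assignment past the sample's true leaf path
  truth <- sim$sim$truth$sample_leaf
  pc <- ysnpdb:::panel_contexts(panel, tree)
  for (sid in sample(names(ds$samples), 50)) {
    got <- ysnpdb:::collapse_assignment_fast(ds$samples[[sid]], pc, tree)
    expect_true(got %in% ancestors(tree, truth[[sid]]))
  }
})

test_that("FST matrices are symmetric, zero-diagonal and element-wise consistent", {
  sim <- shared_sim()
  panel <- build_reduced_panel(sim$sim$dataset, sim$tree)
  m <- fst_matrix(sim$sim$dataset, panel, sim$tree)
  expect_identical(dim(m), c(4L, 4L))
  expect_equal(diag(m), setNames(rep(0, 4), rownames(m)))
  expect_equal(m, t(m))

  counts <- haplogroup_counts(sim$sim$dataset, panel, sim$tree)
  expect_equal(m["Pop01", "Pop02"],
               as.numeric(pairwise_fst(counts[["Pop01"]], counts[["Pop02"]])))

  # two identical populations -> zero off-diagonal
  tree <- fixture_tree()
  twin <- c(
    lapply(1:5, function(i) make_sample(sprintf("a%d", i), "R1", population = "P1",
                                        derived = "M96", ancestral = c("M207", "M3"))),
    lapply(1:5, function(i) make_sample(sprintf("b%d", i), "R1", population = "P2",
                                        derived = "M96", ancestral = c("M207", "M3")))
  )
  ds2 <- make_dataset(twin, tree)
  panel2 <- build_reduced_panel(ds2, tree)
  m2 <- fst_matrix(ds2, panel2, tree)
  expect_equal(m2["P1", "P2"], 0)
})

test_that("classical MDS recovers configurations and explained variance", {
  # three equidistant points: two equal axes
  d3 <- matrix(1, 3, 3) - diag(3)
  mds3 <- classical_mds(d3, k = 2)
  expect_equal(mds3$explained, c(0.5, 0.5), tolerance = 1e-9)

  # collinear configuration: first axis explains everything
  d_line <- as.matrix(dist(c(0, 1, 2)))
  mds_line <- classical_mds(d_line, k = 2)
  expect_equal(mds_line$explained[1], 1, tolerance = 1e-9)

  # Euclidean distances round-trip exactly
  set.seed(17)
  pts <- matrix(rnorm(10), 5, 2)
  d5 <- as.matrix(dist(pts))
  mds5 <- classical_mds(d5, k = 2)
  expect_equal(as.matrix(dist(mds5$points)), d5, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(mds5$explained), 1, tolerance = 1e-9)

  # degenerate all-zero matrix
  mds0 <- classical_mds(matrix(0, 3, 3), k = 2)
  expect_true(all(mds0$points == 0))
  expect_equal(mds0$explained, c(0, 0))

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "ysnpdb_bad_arguments")
})

test_that("population summaries mirror the comparative-table layout", {
  tree <- fixture_tree()
  # PopX: 3x E-V13, 2x R-L51, 1x Q-M3 at full resolution; reduced panel may
  # collapse E-V13 into E depending on criteria, so check a panel we control
  samples <- c(
    lapply(1:3, function(i) make_sample(sprintf("e%d", i), "R1", population = "PopX",
                                        derived = c("M96", "V13"),
                                        ancestral = c("M207", "M3"))),
    lapply(1:2, function(i) make_sample(sprintf("r%d", i), "R1", population = "PopX",
                                        derived = c("M207", "L51"),
                                        ancestral = c("M96", "M3"))),
    list(make_sample("q1", "R1", population = "PopX",
                     derived = "M3", ancestral = c("M96", "M207")))
  )
  ds <- make_dataset(samples, tree)
  panel <- build_reduced_panel(ds, tree, typed_min = 0.9, freq_min = 0.05)
  tab <- pop_summary_table(ds, panel, tree)
  expect_identical(tab$population, "PopX")
  expect_identical(tab$n, 6L)
  expect_identical(tab$full_unique_hgs, 3L)
  expect_equal(tab$full_diversity, gene_diversity(c(3, 2, 1)))
  expect_identical(tab$full_modal_hg, "E-V13 (50%)")
  # reduced resolution can never exceed full resolution
  expect_lte(tab$reduced_unique_hgs, tab$full_unique_hgs)
  expect_lte(tab$reduced_diversity, tab$full_diversity + 1e-12)

  # modal ties are joined with a slash
  tie <- c(
    lapply(1:2, function(i) make_sample(sprintf("t%d", i), "R1", population = "PopT",
                                        derived = c("M96", "V13"), ancestral = "M207")),
    lapply(1:2, function(i) make_sample(sprintf("s%d", i), "R1", population = "PopT",
                                        derived = "M207", ancestral = "M96"))
  )
  ds_tie <- make_dataset(tie, tree)
  panel_tie <- build_reduced_panel(ds_tie, tree)
  tab_tie <- pop_summary_table(ds_tie, panel_tie, tree)
  expect_match(tab_tie$full_modal_hg, "^(E-V13/R|R/E-V13) \\(50%\\)$")

  # multi-population tables are ordered by ascending reduced diversity
  sim <- shared_sim()
  panel_sim <- build_reduced_panel(sim$sim$dataset, sim$tree)
  tab_sim <- pop_summary_table(sim$sim$dataset, panel_sim, sim$tree)
  expect_false(is.unsorted(tab_sim$reduced_diversity))
  expect_true(all(tab_sim$reduced_unique_hgs <= tab_sim$full_unique_hgs))
  expect_true(all(tab_sim$reduced_diversity <= tab_sim$full_diversity + 1e-9))
})

test_that("distance matrices round-trip through CSV and lower-triangle import", {
  m <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- tempfile(fileext = ".csv")
  write_dist_csv(m, p)
  expect_equal(read_dist_csv(p), m)

  tri <- tempfile(fileext = ".txt")
  writeLines(c("3", "A", "B 0.1", "C 0.2 0.3"), tri)
  expect_equal(read_dist_csv(tri), m)
})
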