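# shared fixtures and independent oracles

# 7-branch fixture tree:
#   A0-T
#   +-- E (M96)
#   |   +-- E-V13 (V13)
#   |   +-- E-V22 (V22)
#   +-- R (M207)
#   |   +-- R-L51 (L51 syn M412; equivalent Y410)
#   +-- Q-M3 (M3)
fixture_tree_json <- function(path = tempfile(fileext = ".json")) {
  writeLines('{
  "version": "fixture-1",
  "branches": [
    {"id": "A0-T", "parent": null, "snps": []},
    {"id": "E", "parent": "A0-T",
     "snps": [{"name": "M96", "synonyms": [], "position": null}]},
    {"id": "E-V13", "parent": "E",
     "snps": [{"name": "V13", "synonyms": [], "position": 6818291}]},
    {"id": "E-V22", "parent": "E",
     "snps": [{"name": "V22", "synonyms": [], "position": null}]},
    {"id": "R", "parent": "A0-T",
     "snps": [{"name": "M207", "synonyms": [], "position": null}]},
    {"id": "R-L51", "parent": "R",
     "snps": [{"name": "L51", "synonyms": ["M412"], "position": 8502236},
              {"name": "Y410", "synonyms": [], "position": null}]},
    {"id": "Q-M3", "parent": "A0-T",
     "snps": [{"name": "M3", "synonyms": [], "position": null}]}
  ]
}', path)
  path
}

fixture_tree <- function() load_tree(fixture_tree_json())

# bare sample record for frequency tests
make_sample <- function(id, region, derived = character(0),
                        ancestral = character(0), population = region,
                        subregion = NA, hg = NA) {
  ysnpdb:::new_sample_record(
    sample_id = id, population = population, region_id = region,
    subregion_id = subregion, assigned_haplogroup = hg,
    calls = data.frame(
      snp_name = c(derived, ancestral),
      state = c(rep("derived", length(derived)), rep("ancestral", length(ancestral))),
      stringsAsFactors = FALSE
    ),
    source_ref = "test"
  )
}

make_dataset <- function(samples, tree, regions = NULL, subregions = list()) {
  if (is.null(regions)) {
    regions <- unique(vapply(samples, `[[`, character(1), "region_id"))
  }
  ds <- new_dataset(tree$version, regions, subregions)
  for (s in samples) ds$samples[[s$sample_id]] <- s
  ds
}

# frequency_table shell around hand-made cells (for interpolation tests)
fake_freq_table <- function(cells) {
  if (is.null(cells$country_id)) cells$country_id <- cells$region_id
  if (is.null(cells$display_pct)) cells$display_pct <- NA_real_
  if (is.null(cells$interpolated)) cells$interpolated <- FALSE
  structure(list(query = NULL, mode = "direct", scale = "absolute",
                 level = "country", cells = cells, conflicts = character(0),
                 tree_version = "fixture"),
            class = "frequency_table")
}

# --- independent membership oracle: the counting definition applied literally ---

oracle_membership <- function(sample, branch_id, tree, mode) {
  branch <- tree$branches[[branch_id]]
  class_names <- character(0)
  for (s in branch$snps) class_names <- c(class_names, s$name, s$synonyms)
  class_names <- tolower(trimws(class_names))

  nd <- 0
  na_ <- 0
  if (nrow(sample$calls)) {
    for (i in seq_len(nrow(sample$calls))) {
      nm <- tolower(trimws(sample$calls$snp_name[i]))
      if (nm %in% class_names) {
        if (sample$calls$state[i] == "derived") nd <- nd + 1 else na_ <- na_ + 1
      }
    }
  }
  direct <-
    if (nd > 0 && na_ > 0) {
      if (nd == na_) "conflicting" else if (nd > na_) "derived" else "ancestral"
    } else if (nd > 0) "derived" else if (na_ > 0) "ancestral" else "uninformative"
  if (mode == "direct") return(direct)
  if (direct == "derived") return("derived")

  desc <- descendants(tree, branch_id)
  strict <- setdiff(desc, branch_id)
  extra <- FALSE
  if (nrow(sample$calls)) {
    for (i in seq_len(nrow(sample$calls))) {
      if (sample$calls$state[i] != "derived") next
      hit <- tree$name_index[tolower(trimws(sample$calls$snp_name[i]))]
      if (!is.na(hit) && unname(hit) %in% strict) extra <- TRUE
    }
  }
  if (!extra && !is.na(sample$assigned_haplogroup)) {
    hit <- tree$name_index[tolower(trimws(sample$assigned_haplogroup))]
    if (!is.na(hit) && unname(hit) %in% desc) extra <- TRUE
  }
  if (extra) "derived" else direct
}

# brute-force per-region recount for a (possibly paraphyletic) query
oracle_region_counts <- function(dataset, query, tree, mode) {
  keys <- character(0)
  nd <- integer(0)
  ni <- integer(0)
  for (rec in dataset$samples) {
    st <- oracle_membership(rec, query$main, tree, mode)
    if (st == "conflicting" || st == "uninformative") next
    skip <- FALSE
    for (ex in query$exclusions) {
      if (oracle_membership(rec, ex, tree, mode) == "derived") skip <- TRUE
    }
    if (skip) next
    key <- rec$region_id
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key)
      nd <- c(nd, 0L)
      ni <- c(ni, 0L)
      i <- length(keys)
    }
    ni[i] <- ni[i] + 1L
    if (st == "derived") nd[i] <- nd[i] + 1L
  }
  data.frame(region_id = keys, n_derived = nd, n_informative = ni,
             stringsAsFactors = FALSE)[order(keys), , drop = FALSE]
}

# --- independent AMOVA oracle: literal O(N^2) pairwise 0/1 distances ---

oracle_amova_fst <- function(a, b) {
  haps <- c(rep(names(a), a), rep(names(b), b))
  pop <- c(rep(1L, sum(a)), rep(2L, sum(b)))
  N <- length(haps)
  d <- outer(haps, haps, FUN = function(x, y) as.numeric(x != y))
  ssd_total <- sum(d) / (2 * N)
  ssd_within <- 0
  for (p in 1:2) {
    idx <- which(pop == p)
    ssd_within <- ssd_within + sum(d[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  n1 <- sum(pop == 1)
  n2 <- sum(pop == 2)
  s2w <- ssd_within / (N - 2)
  n_prime <- (N - (n1^2 + n2^2) / N)
  s2a <- (ssd_among - s2w) / n_prime
  if (s2a + s2w == 0) 0 else s2a / (s2a + s2w)
}

# small simulated study shared by several test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tree <- sim_tree(30, seed = 7)
      regions <- sim_regions(4)
      cfg <- sim_config(populations = data.frame(
        name = sprintf("Pop%02d", 1:4),
        region_id = sprintf("Region%02d", 1:4),
        n_samples = 80L, stringsAsFactors = FALSE
      ))
      cache <<- list(tree = tree, regions = regions,
                     sim = sim_dataset(tree, regions, cfg, seed = 7))
    }
    cache
  }
})
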