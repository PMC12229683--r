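#' Simulate a random haplogroup tree
#'
#' Grows a rooted tree by attaching each new branch to a uniformly chosen
#' existing branch. Every non-root branch carries one primary defining SNP
#' plus a Geometric(`equivalent_rate`) number of equivalent SNPs (distinct
#' SNPs defining the same branch); each SNP independently receives one
#' synonym with probability `synonym_rate`. Branch ids follow the field's
#' letter-plus-SNP convention (`A-S002`): depth-1 clades get consecutive
#' letters which their descendants inherit. Deterministic given `seed`.
#'
#' @param n_branches Total number of branches including the root.
#' @param equivalent_rate Expected-extra-equivalents parameter in \code{[0,1)}.
#' @param synonym_rate Per-SNP synonym probability.
#' @param seed Integer seed.
#' @return A `haplogroup_tree` (version tag records the seed).
#' @export
sim_tree <- function(n_branches = 40, equivalent_rate = 0.3,
                     synonym_rate = 0.2, seed = 1) {
  stopifnot(n_branches >= 1, equivalent_rate >= 0, equivalent_rate < 1)
  with_seed(seed, {
    version <- sprintf("sim-%d", seed)
    if (n_branches == 1) {
      return(build_tree(list(list(id = "ROOT", parent = NA_character_, snps = list())),
                        version = version))
    }
    parent_idx <- c(NA_integer_, vapply(2:n_branches, function(i) {
      if (i == 2) 1L else sample.int(i - 1L, 1)
    }, integer(1)))
    # major-clade letter: inherited from the depth-1 ancestor
    letters_pool <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
    clade <- character(n_branches)
    next_letter <- 0L
    ids <- character(n_branches)
    ids[1] <- "ROOT"
    branches <- vector("list", n_branches)
    branches[[1]] <- list(id = "ROOT", parent = NA_character_, snps = list())
    for (i in 2:n_branches) {
      p <- parent_idx[i]
      if (p == 1L) {
        next_letter <- next_letter + 1L
        clade[i] <- letters_pool[next_letter]
      } else {
        clade[i] <- clade[p]
      }
      primary <- sprintf("S%03d", i)
      n_equiv <- min(stats::rgeom(1, prob = 1 - equivalent_rate), 3L)
      snp_names <- c(primary,
                     if (n_equiv > 0) sprintf("%sE%d", primary, seq_len(n_equiv)))
      snps <- lapply(snp_names, function(nm) {
        list(name = nm,
             synonyms = if (stats::runif(1) < synonym_rate) paste0(nm, ".1") else character(0),
             position = NA_integer_)
      })
      ids[i] <- sprintf("%s-%s", clade[i], primary)
      branches[[i]] <- list(id = ids[i], parent = ids[p], snps = snps)
    }
    build_tree(branches, version = version)
  })
}

#' Simulate region geometries along the equator
#'
#' Lays out `n` one-degree squares along a great-circle strip on the
#' equator, with a one-degree gap between consecutive squares (about
#' 111.2 km of arc), so inter-border distances are known in closed form.
#'
#' @param n Number of regions.
#' @param seed Integer seed (kept for interface symmetry; the layout is
#'   deterministic).
#' @return List of `region_geometry` with ids `Region01`, `Region02`, ...
#' @export
sim_regions <- function(n, seed = 1) {
  if (n < 1) {
    ysnpdb_abort("need at least one region", "ysnpdb_bad_arguments")
  }
  lapply(seq_len(n), function(k) {
    lon0 <- 2 * (k - 1)
    ring <- cbind(lat = c(0, 0, 1, 1, 0),
                  lon = c(lon0, lon0 + 1, lon0 + 1, lon0, lon0))
    region_geometry(sprintf("Region%02d", k), list(ring))
  })
}

#' Default simulation configuration
#'
#' Emulates a multi-population repository genotyped with three technology
#' tiers: a whole-genome-scale panel observing every SNP, a targeted panel
#' covering 60% of SNPs, and a minisequencing-scale panel covering 5%, mixed
#' within each population at 17% / 78% / 5% (the shares of WGS, large
#' targeted panel and SNaPshot data in typical mixed-technology Y-SNP
#' repositories). Per-population leaf-haplogroup frequencies are drawn from
#' a symmetric Dirichlet over the tree's leaves.
#'
#' @param populations Data.frame with columns `name`, `region_id`,
#'   `n_samples`; defaults to six populations of 200 samples, one per
#'   simulated region.
#' @param dirichlet_alpha Symmetric Dirichlet concentration over leaves.
#' @param panels Data.frame with columns `name`, `snp_fraction`,
#'   `missing_rate`.
#' @param panel_mix Numeric vector (one weight per panel, summing to 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(populations = NULL, dirichlet_alpha = 1,
                       panels = NULL, panel_mix = c(0.17, 0.78, 0.05)) {
  if (is.null(populations)) {
    populations <- data.frame(
      name = sprintf("Pop%02d", 1:6),
      region_id = sprintf("Region%02d", 1:6),
      n_samples = 200L,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(panels)) {
    panels <- data.frame(
      name = c("wgs", "targeted", "snapshot"),
      snp_fraction = c(1, 0.6, 0.05),
      missing_rate = c(0, 0.05, 0.10),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(panels) == length(panel_mix),
            abs(sum(panel_mix) - 1) < 1e-8,
            all(panels$snp_fraction >= 0 & panels$snp_fraction <= 1),
            all(panels$missing_rate >= 0 & panels$missing_rate < 1),
            dirichlet_alpha > 0)
  structure(list(populations = populations, dirichlet_alpha = dirichlet_alpha,
                 panels = panels, panel_mix = panel_mix),
            class = "sim_config")
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a genotype dataset with known ground truth
#'
#' Each sample draws a true leaf haplogroup from its population's Dirichlet
#' leaf frequencies; its (randomly assigned) genotyping panel determines
#' which SNPs are observed, further thinned by the panel's missing rate. An
#' observed call is derived exactly when the SNP's branch lies on the
#' root-to-leaf path of the sample's true haplogroup — there is no
#' genotyping error model. The assigned haplogroup is the deepest branch
#' with an observed derived call (the root when none is observed).
#'
#' @param tree A `haplogroup_tree` (e.g. from [sim_tree()]).
#' @param regions List of `region_geometry` (e.g. from [sim_regions()]);
#'   every population's `region_id` must be present.
#' @param config A [sim_config()].
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return List with `dataset` (an `hg_dataset`), `truth` (list:
#'   `sample_leaf`, per-sample true leaf; `branch_prob`, branch x population
#'   matrix of true membership probabilities; `leaf_prob`, leaf x population
#'   matrix) and `config`.
#' @export
sim_dataset <- function(tree, regions, config = sim_config(), seed = 1) {
  stopifnot(inherits(tree, "haplogroup_tree"), inherits(config, "sim_config"))
  region_ids <- vapply(regions, `[[`, character(1), "region_id")
  if (!all(config$populations$region_id %in% region_ids)) {
    ysnpdb_abort("config names a region with no geometry", "ysnpdb_bad_arguments")
  }
  branch_ids <- names(tree$branches)
  leaves <- branch_ids[vapply(branch_ids, function(b) {
    is.null(tree$children[[b]]) || !length(tree$children[[b]])
  }, logical(1))]
  all_snps <- unlist(lapply(tree$branches, function(b) {
    vapply(b$snps, `[[`, character(1), "name")
  }), use.names = FALSE)
  snp_branch <- stats::setNames(
    rep(names(tree$branches),
        vapply(tree$branches, function(b) length(b$snps), integer(1))),
    all_snps
  )

  with_seed(seed, {
    # fixed SNP subsets per panel
    panel_snps <- lapply(config$panels$snp_fraction, function(frac) {
      if (frac >= 1) all_snps else
        sample(all_snps, max(1L, round(frac * length(all_snps))))
    })

    pops <- config$populations
    leaf_prob <- matrix(0, length(leaves), nrow(pops),
                        dimnames = list(leaves, pops$name))
    samples <- list()
    sample_leaf <- character(0)
    for (pi in seq_len(nrow(pops))) {
      p_leaf <- rdirichlet1(rep(config$dirichlet_alpha, length(leaves)))
      leaf_prob[, pi] <- p_leaf
      n <- pops$n_samples[pi]
      true_leaves <- sample(leaves, n, replace = TRUE, prob = p_leaf)
      panel_of <- sample.int(nrow(config$panels), n, replace = TRUE,
                             prob = config$panel_mix)
      for (si in seq_len(n)) {
        sid <- sprintf("%s_%04d", pops$name[pi], si)
        path <- ancestors(tree, true_leaves[si])
        observed <- panel_snps[[panel_of[si]]]
        mr <- config$panels$missing_rate[panel_of[si]]
        if (mr > 0) observed <- observed[stats::runif(length(observed)) >= mr]
        state <- ifelse(snp_branch[observed] %in% path, "derived", "ancestral")
        der_branches <- unique(snp_branch[observed[state == "derived"]])
        assigned <- if (length(der_branches)) {
          depths <- match(der_branches, path)  # all lie on the path
          der_branches[which.max(depths)]
        } else tree$root
        samples[[sid]] <- new_sample_record(
          sample_id = sid, population = pops$name[pi],
          region_id = pops$region_id[pi],
          assigned_haplogroup = assigned,
          calls = data.frame(snp_name = unname(observed), state = unname(state),
                             stringsAsFactors = FALSE),
          source_ref = sprintf("synthetic:%s", config$panels$name[panel_of[si]])
        )
        sample_leaf[sid] <- true_leaves[si]
      }
    }

    # true branch membership probability = sum of leaf probabilities under it
    branch_prob <- matrix(0, length(branch_ids), nrow(pops),
                          dimnames = list(branch_ids, pops$name))
    for (b in branch_ids) {
      under <- intersect(descendants(tree, b), leaves)
      branch_prob[b, ] <- colSums(leaf_prob[under, , drop = FALSE])
    }

    ds <- new_dataset(tree_version = tree$version, region_registry = region_ids)
    ds$samples <- samples
    list(dataset = ds,
         truth = list(sample_leaf = sample_leaf, branch_prob = branch_prob,
                      leaf_prob = leaf_prob),
         config = config)
  })
}
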