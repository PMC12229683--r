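#' Build a reduced Y-SNP panel for cross-population comparison
#'
#' When populations are genotyped with technologies of very different
#' resolution (whole-genome sequencing down to a few dozen SNPs), comparing
#' them fairly requires restricting the phylogeny to SNPs observable in
#' essentially all samples. A SNP (evaluated at the level of its branch's
#' equivalence class: a call at any equivalent counts as typed) is kept when
#' it is typed in at least `typed_min` of the pooled samples AND its derived
#' frequency among typed samples reaches `freq_min` in at least one
#' population. The kept branches are re-linked to their nearest kept
#' ancestor to form a valid collapsed tree.
#'
#' @param dataset An `hg_dataset` (non-empty).
#' @param tree A `haplogroup_tree`.
#' @param typed_min Minimum typed fraction over all samples (default 0.90).
#' @param freq_min Minimum derived frequency in at least one population
#'   (default 0.05).
#' @return A `reduced_panel`: list with `snps` (kept primary SNP names),
#'   `branch_ids`, `collapsed_tree` and the criteria used.
#' @export
build_reduced_panel <- function(dataset, tree, typed_min = 0.90, freq_min = 0.05) {
  stopifnot(inherits(dataset, "hg_dataset"), inherits(tree, "haplogroup_tree"))
  n_total <- length(dataset$samples)
  if (n_total == 0) {
    ysnpdb_abort("cannot build a reduced panel from an empty dataset",
                 "ysnpdb_empty_dataset")
  }
  pops <- vapply(dataset$samples, `[[`, character(1), "population")
  branch_ids <- setdiff(names(tree$branches), tree$root)

  kept <- character(0)
  for (b in branch_ids) {
    ctx <- membership_context(tree, b)
    st <- vapply(dataset$samples, function(rec) {
      if (!nrow(rec$calls)) return("untyped")
      in_class <- norm_name(rec$calls$snp_name) %in% ctx$class_set
      if (!any(in_class)) return("untyped")
      if (any(in_class & rec$calls$state == "derived")) "derived" else "ancestral"
    }, character(1))
    typed <- st != "untyped"
    if (sum(typed) / n_total < typed_min) next
    # derived frequency among typed samples, per population
    ok <- FALSE
    for (p in unique(pops)) {
      sel <- typed & pops == p
      if (any(sel) && sum(st[sel] == "derived") / sum(sel) >= freq_min) {
        ok <- TRUE
        break
      }
    }
    if (ok) kept <- c(kept, b)
  }

  collapsed <- collapse_tree(tree, kept)
  snps <- unlist(lapply(kept, function(b) {
    vapply(tree$branches[[b]]$snps, `[[`, character(1), "name")
  }), use.names = FALSE)
  structure(list(snps = snps %||% character(0), branch_ids = kept,
                 collapsed_tree = collapsed,
                 typed_min = typed_min, freq_min = freq_min),
            class = "reduced_panel")
}

# restrict a tree to kept branches (+ root), re-parenting to nearest kept ancestor
collapse_tree <- function(tree, kept) {
  keep <- union(tree$root, kept)
  branches <- lapply(keep, function(b) {
    br <- tree$branches[[b]]
    if (!is.na(br$parent)) {
      path <- ancestors(tree, b)
      up <- rev(path[-length(path)])
      br$parent <- up[match(TRUE, up %in% keep)]
    }
    br
  })
  build_tree(branches, version = paste0(tree$version, "+reduced"))
}

#' @export
print.reduced_panel <- function(x, ...) {
  cat(sprintf("<reduced_panel> %d SNPs on %d branches (typed >= %d%%, freq >= %d%% in >=1 population)\n",
              length(x$snps), length(x$branch_ids),
              round(100 * x$typed_min), round(100 * x$freq_min)))
  invisible(x)
}

#' Collapse a sample's haplogroup assignment onto a reduced panel
#'
#' Returns the deepest panel branch at which the sample is derived under
#' phylogenetic membership; samples with no derived evidence at any panel
#' branch collapse to the root. Samples with conflicting evidence, or with
#' derived evidence at two incomparable branches of equal depth, are flagged
#' with `NA` (and excluded from downstream counts).
#'
#' @param sample A sample record.
#' @param panel A `reduced_panel`.
#' @param tree The full `haplogroup_tree`.
#' @return A branch id of the collapsed tree, or `NA_character_`.
#' @export
collapse_assignment <- function(sample, panel, tree) {
  stopifnot(inherits(panel, "reduced_panel"))
  collapse_assignment_fast(sample, panel_contexts(panel, tree), tree)
}

# contexts + depths for every panel branch, computed once per panel
panel_contexts <- function(panel, tree) {
  ctxs <- lapply(panel$branch_ids, membership_context, tree = tree)
  depths <- vapply(panel$branch_ids, branch_depth, integer(1), tree = tree)
  list(branch_ids = panel$branch_ids, ctxs = ctxs, depths = depths)
}

collapse_assignment_fast <- function(sample, pc, tree) {
  derived <- logical(length(pc$branch_ids))
  for (i in seq_along(pc$branch_ids)) {
    st <- membership_fast(sample, tree, "phylogenetic", pc$ctxs[[i]])
    if (st == "conflicting") return(NA_character_)
    derived[i] <- st == "derived"
  }
  if (!any(derived)) return(tree$root)
  deepest <- pc$branch_ids[derived & pc$depths == max(pc$depths[derived])]
  if (length(deepest) > 1) return(NA_character_)
  deepest
}

#' Haplogroup counts per population under a panel
#'
#' @param dataset An `hg_dataset`.
#' @param panel A `reduced_panel`, or `NULL` for full-resolution assignments
#'   (deepest derived branch over the whole tree).
#' @param tree The full `haplogroup_tree`.
#' @return Named list: population -> named integer vector of branch counts.
#' @export
haplogroup_counts <- function(dataset, panel, tree) {
  stopifnot(inherits(dataset, "hg_dataset"))
  if (is.null(panel)) {
    panel <- structure(list(branch_ids = setdiff(names(tree$branches), tree$root)),
                       class = "reduced_panel")
  }
  pops <- vapply(dataset$samples, `[[`, character(1), "population")
  pc <- panel_contexts(panel, tree)
  assign <- vapply(dataset$samples, collapse_assignment_fast, character(1),
                   pc = pc, tree = tree)
  out <- list()
  for (p in unique(pops)) {
    a <- assign[pops == p]
    a <- a[!is.na(a)]
    out[[p]] <- c(table(a))
  }
  out
}

#' Nei's gene diversity for lineage counts
#'
#' `D = n/(n-1) * (1 - sum(p_k^2))`, the unbiased expected-heterozygosity
#' analog for haploid lineage frequencies: 0 for a monomorphic sample,
#' exactly 1 when every lineage is observed once.
#'
#' @param counts Vector of haplogroup counts (n = sum, must be >= 2).
#' @return Diversity in \code{[0, 1]}.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    ysnpdb_abort("gene diversity requires at least 2 individuals", "ysnpdb_too_few")
  }
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Pairwise FST between two populations from haplogroup counts
#'
#' Two-level analysis of molecular variance on lineage frequencies with 0/1
#' inter-haplotype distances (0 for the same haplogroup, 1 otherwise). With
#' populations of sizes n1, n2 (N = n1 + n2) and within/pooled haplogroup
#' frequencies p, the sums of squared deviations are
#' `SSD_total = N (1 - sum(P^2)) / 2` and
#' `SSD_within = sum_p n_p (1 - sum(p_p^2)) / 2`; variance components follow
#' the moment equations `sigma2_w = SSD_within / (N - 2)`,
#' `sigma2_a = (SSD_among/(P-1) - sigma2_w) / n'` with
#' `n' = (N - (n1^2 + n2^2)/N) / (P - 1)`, and
#' `FST = sigma2_a / (sigma2_a + sigma2_w)` (0 when both components are 0).
#' Negative estimates are returned as computed unless `clamp = TRUE`.
#'
#' @param a,b Named vectors of haplogroup counts (each summing to >= 2).
#' @param clamp Clamp negative estimates to zero (default `FALSE`).
#' @return FST estimate, with variance components in attributes
#'   `sigma2_a` and `sigma2_w`.
#' @export
pairwise_fst <- function(a, b, clamp = FALSE) {
  a <- a[a > 0]
  b <- b[b > 0]
  n1 <- sum(a)
  n2 <- sum(b)
  if (n1 < 2 || n2 < 2) {
    ysnpdb_abort("pairwise FST requires at least 2 individuals per population",
                 "ysnpdb_too_few")
  }
  N <- n1 + n2
  hgs <- union(names(a), names(b))
  ca <- stats::setNames(numeric(length(hgs)), hgs)
  cb <- ca
  ca[names(a)] <- a
  cb[names(b)] <- b
  pooled <- (ca + cb) / N

  ssd_total <- N * (1 - sum(pooled^2)) / 2
  ssd_within <- n1 * (1 - sum((ca / n1)^2)) / 2 + n2 * (1 - sum((cb / n2)^2)) / 2
  ssd_among <- ssd_total - ssd_within

  sigma2_w <- ssd_within / (N - 2)
  n_prime <- (N - (n1^2 + n2^2) / N) / 1
  sigma2_a <- (ssd_among / 1 - sigma2_w) / n_prime

  denom <- sigma2_a + sigma2_w
  fst <- if (denom == 0) 0 else sigma2_a / denom
  if (clamp) fst <- max(0, fst)
  structure(fst, sigma2_a = sigma2_a, sigma2_w = sigma2_w)
}

#' Pairwise FST matrix over all populations
#'
#' Collapses every sample onto the panel, counts haplogroups per population
#' and fills a symmetric matrix of pairwise FST estimates with a zero
#' diagonal. Populations with fewer than 2 assignable samples are skipped
#' with a warning.
#'
#' @param dataset An `hg_dataset`.
#' @param panel A `reduced_panel` (or `NULL` for full resolution).
#' @param tree The full `haplogroup_tree`.
#' @param clamp Passed to [pairwise_fst()].
#' @return Symmetric numeric matrix with population dimnames.
#' @export
fst_matrix <- function(dataset, panel, tree, clamp = FALSE) {
  counts <- haplogroup_counts(dataset, panel, tree)
  ns <- vapply(counts, sum, numeric(1))
  small <- names(counts)[ns < 2]
  if (length(small)) {
    warning(sprintf("population(s) skipped for FST (n < 2): %s",
                    paste(small, collapse = ", ")))
    counts <- counts[ns >= 2]
  }
  labels <- names(counts)
  m <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  if (length(labels) >= 2) {
    for (i in seq_along(labels)[-1]) {
      for (j in seq_len(i - 1)) {
        v <- as.numeric(pairwise_fst(counts[[i]], counts[[j]], clamp = clamp))
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes (via
#' `stats::cmdscale`); coordinates come from the top-k positive eigenpairs
#' and each axis' explained fraction is its eigenvalue over the sum of all
#' positive eigenvalues.
#'
#' @param d Symmetric distance matrix (zero diagonal).
#' @param k Number of dimensions (default 2).
#' @return List with `points` (n x k coordinate matrix), `explained`
#'   (per-axis fractions) and `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    ysnpdb_abort("classical_mds requires a symmetric square matrix", "ysnpdb_bad_arguments")
  }
  k <- min(k, nrow(d) - 1)
  if (all(d == 0)) {
    return(list(points = matrix(0, nrow(d), k, dimnames = list(rownames(d), NULL)),
                explained = rep(0, k), eig = rep(0, nrow(d))))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pos <- sum(fit$eig[fit$eig > 0])
  explained <- if (pos > 0) pmax(fit$eig[seq_len(k)], 0) / pos else rep(0, k)
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate configurations can drop trailing axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  list(points = pts, explained = explained, eig = fit$eig)
}

#' Per-population summary at reduced and full resolution
#'
#' One row per population: sample size, then gene diversity, number of
#' unique haplogroups and the modal haplogroup (with its integer percent,
#' ties joined with "/") at reduced-panel resolution and at full resolution.
#' Rows are ordered from low to high reduced-panel gene diversity.
#'
#' @param dataset An `hg_dataset`.
#' @param panel A `reduced_panel`.
#' @param tree The full `haplogroup_tree`.
#' @return A data.frame.
#' @export
pop_summary_table <- function(dataset, panel, tree) {
  reduced <- haplogroup_counts(dataset, panel, tree)
  full <- haplogroup_counts(dataset, NULL, tree)
  pops <- names(reduced)
  modal <- function(counts) {
    mx <- max(counts)
    lineages <- names(counts)[counts == mx]
    sprintf("%s (%d%%)", paste(lineages, collapse = "/"),
            round_half_up(100 * mx / sum(counts)))
  }
  rows <- lapply(pops, function(p) {
    r <- reduced[[p]]
    f <- full[[p]]
    data.frame(
      population = p, n = sum(r),
      reduced_diversity = gene_diversity(r),
      reduced_unique_hgs = length(r[r > 0]),
      reduced_modal_hg = modal(r),
      full_diversity = gene_diversity(f),
      full_unique_hgs = length(f[f > 0]),
      full_modal_hg = modal(f),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$reduced_diversity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a distance matrix as square CSV with header labels
#'
#' @param m Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a distance matrix from square CSV or PHYLIP-style lower triangle
#'
#' Square CSV: header labels, first column row labels. Lower-triangle text:
#' first line the number of taxa, then one line per taxon `label d1 d2 ...`.
#'
#' @param path Input path.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_dist_csv <- function(path) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("matrix file not found: %s", path), "ysnpdb_missing_file")
  }
  first <- readLines(path, n = 1)
  if (!grepl(",", first, fixed = TRUE) && !is.na(suppressWarnings(as.integer(trimws(first))))) {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    labels <- character(n)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      labels[i] <- parts[1]
      if (i > 1) {
        vals <- as.numeric(parts[-1])
        m[i, seq_len(i - 1)] <- vals
        m[seq_len(i - 1), i] <- vals
      }
    }
    dimnames(m) <- list(labels, labels)
    return(m)
  }
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  dimnames(m) <- list(rownames(tab), colnames(tab))
  m
}
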