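#' Membership state of a sample at a branch
#'
#' Determines whether a sample belongs to the clade rooted at `branch_id`.
#'
#' In `direct` mode only calls at the branch's own defining SNPs (its
#' equivalence class, synonyms included) count: any derived call marks the
#' sample derived, otherwise any ancestral call marks it ancestral; when both
#' states are present the majority wins and an exact tie is `conflicting`;
#' with no call at the class the sample is `uninformative`.
#'
#' In `phylogenetic` mode the sample is additionally derived when any of its
#' calls is derived at a SNP defining a strict descendant of the branch, or
#' when its assigned haplogroup lies inside the branch's clade; ancestral
#' requires direct ancestral evidence and no derived evidence. Derived calls
#' on disjoint branches are never taken as ancestral evidence (the tree is
#' not assumed complete).
#'
#' @param sample A sample record.
#' @param branch_id Branch id.
#' @param tree A `haplogroup_tree`.
#' @param mode `"phylogenetic"` (default) or `"direct"`.
#' @return One of `"derived"`, `"ancestral"`, `"uninformative"`, `"conflicting"`.
#' @export
membership <- function(sample, branch_id, tree, mode = c("phylogenetic", "direct")) {
  mode <- match.arg(mode)
  if (is.null(tree$branches[[branch_id]])) {
    ysnpdb_abort(sprintf("unknown branch: '%s'", branch_id), "ysnpdb_unknown_name")
  }
  ctx <- membership_context(tree, branch_id)
  membership_fast(sample, tree, mode, ctx)
}

# precompute the per-branch sets membership needs, reusable across samples
membership_context <- function(tree, branch_id) {
  branch <- tree$branches[[branch_id]]
  class_names <- unlist(lapply(branch$snps, function(s) c(s$name, s$synonyms)),
                        use.names = FALSE)
  desc <- descendants(tree, branch_id)
  list(branch_id = branch_id,
       class_set = norm_name(class_names %||% character(0)),
       desc_set = desc,
       strict_desc_set = setdiff(desc, branch_id))
}

membership_fast <- function(sample, tree, mode, ctx) {
  calls <- sample$calls
  state <- "uninformative"
  n_d <- 0L
  n_a <- 0L
  if (nrow(calls)) {
    in_class <- norm_name(calls$snp_name) %in% ctx$class_set
    n_d <- sum(in_class & calls$state == "derived")
    n_a <- sum(in_class & calls$state == "ancestral")
  }
  direct <- if (n_d > 0 && n_a > 0) {
    if (n_d == n_a) "conflicting" else if (n_d > n_a) "derived" else "ancestral"
  } else if (n_d > 0) "derived" else if (n_a > 0) "ancestral" else "uninformative"

  if (mode == "direct") return(direct)

  if (direct == "derived") return("derived")
  # descendant-derived evidence or assigned haplogroup inside the clade
  extra <- FALSE
  if (nrow(calls)) {
    der <- calls$snp_name[calls$state == "derived"]
    if (length(der)) {
      hit <- tree$name_index[norm_name(der)]
      extra <- any(!is.na(hit) & hit %in% ctx$strict_desc_set)
    }
  }
  if (!extra && !is.na(sample$assigned_haplogroup)) {
    hg <- tree$name_index[norm_name(sample$assigned_haplogroup)]
    extra <- !is.na(hg) && unname(hg) %in% ctx$desc_set
  }
  if (extra) return("derived")
  direct
}

#' Per-region haplogroup frequency table
#'
#' For each region, counts samples informative for the queried haplogroup
#' (membership derived or ancestral) and samples carrying the derived state,
#' and reports their ratio: the number of samples with the derived allele
#' divided by the number of samples in which at least one SNP defining the
#' queried haplogroup was analyzed (in phylogenetic mode, membership can
#' additionally be established from sub-haplogroup evidence). For
#' paraphyletic queries such as `E*(xV13)`, samples with derived evidence
#' for an excluded clade are removed from numerator and denominator;
#' samples merely uninformative for the exclusion remain included.
#' Samples with conflicting evidence at the main branch are excluded from
#' both counts and listed in the table's `conflicts` field.
#'
#' @param dataset An `hg_dataset` whose `tree_version` matches `tree`.
#' @param query An `hg_query` or a query string (parsed against `tree`).
#' @param tree A `haplogroup_tree`.
#' @param mode Membership mode, `"phylogenetic"` (default) or `"direct"`.
#' @param scale `"absolute"` (fractions in 0..1) or `"relative"` (divided by
#'   the maximum observed regional frequency, so the peak region shows 1).
#' @param level `"country"` (region ids) or `"subregion"`.
#' @return A `frequency_table`: list with `cells` (data.frame: region_id,
#'   country_id, n_derived, n_informative, frequency, display_pct,
#'   interpolated), the query, mode, scale, level and QC `conflicts`.
#' @export
frequency_table <- function(dataset, query, tree,
                            mode = c("phylogenetic", "direct"),
                            scale = c("absolute", "relative"),
                            level = c("country", "subregion")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  level <- match.arg(level)
  stopifnot(inherits(dataset, "hg_dataset"), inherits(tree, "haplogroup_tree"))
  if (!identical(dataset$tree_version, tree$version)) {
    ysnpdb_abort(sprintf("dataset tree version '%s' does not match tree '%s'",
                         dataset$tree_version, tree$version),
                 "ysnpdb_version_mismatch")
  }
  query <- as_hg_query(query, tree)
  ctx_main <- membership_context(tree, query$main)
  ctx_excl <- lapply(query$exclusions, membership_context, tree = tree)

  keys <- character(0)
  key_country <- character(0)
  n_inf <- integer(0)
  n_der <- integer(0)
  conflicts <- character(0)

  bump <- function(key, country, informative, derived) {
    i <- match(key, keys)
    if (is.na(i)) {
      keys <<- c(keys, key)
      key_country <<- c(key_country, country)
      n_inf <<- c(n_inf, 0L)
      n_der <<- c(n_der, 0L)
      i <- length(keys)
    }
    if (informative) n_inf[i] <<- n_inf[i] + 1L
    if (derived) n_der[i] <<- n_der[i] + 1L
  }

  for (rec in dataset$samples) {
    key <- if (level == "subregion" && !is.na(rec$subregion_id)) rec$subregion_id else rec$region_id
    st <- membership_fast(rec, tree, mode, ctx_main)
    if (st == "conflicting") {
      conflicts <- c(conflicts, rec$sample_id)
      next
    }
    if (st == "uninformative") next
    excl_derived <- FALSE
    for (ctx in ctx_excl) {
      if (membership_fast(rec, tree, mode, ctx) == "derived") {
        excl_derived <- TRUE
        break
      }
    }
    if (excl_derived) next
    bump(key, rec$region_id, informative = TRUE, derived = (st == "derived"))
  }

  # registered regions without data appear as empty cells (interpolation targets)
  if (level == "country") {
    for (r in setdiff(dataset$region_registry, keys)) bump(r, r, FALSE, FALSE)
  } else {
    for (country in names(dataset$subregions)) {
      for (s in setdiff(dataset$subregions[[country]], keys)) bump(s, country, FALSE, FALSE)
    }
  }

  freq <- ifelse(n_inf > 0, n_der / n_inf, NA_real_)
  if (scale == "relative") {
    mx <- suppressWarnings(max(freq, na.rm = TRUE))
    if (is.finite(mx) && mx > 0) freq <- freq / mx
  }
  cells <- data.frame(
    region_id = keys, country_id = key_country,
    n_derived = n_der, n_informative = n_inf,
    frequency = freq,
    display_pct = ifelse(is.na(freq), NA_real_, round_half_up(100 * freq)),
    interpolated = FALSE, stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$region_id), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(query = query, mode = mode, scale = scale, level = level,
                 cells = cells, conflicts = conflicts,
                 tree_version = tree$version),
            class = "frequency_table")
}

#' Frequency table for a single Y-SNP
#'
#' Resolves the SNP (or any synonym/equivalent) to its branch and delegates
#' to [frequency_table()]; every name in one equivalence class yields an
#' identical table.
#'
#' @param dataset An `hg_dataset`.
#' @param snp_name SNP name, synonym, or haplogroup id.
#' @param tree A `haplogroup_tree`.
#' @param ... Passed to [frequency_table()].
#' @export
snp_frequency_table <- function(dataset, snp_name, tree, ...) {
  branch <- resolve_branch(tree, snp_name)
  frequency_table(dataset, parse_query(branch$id, tree), tree, ...)
}

#' Aggregate a subregion-level table to country level
#'
#' Derived and informative counts are summed over each country's subregions
#' and the frequency recomputed from the summed counts (not averaged over
#' subregion fractions).
#'
#' @param table A `frequency_table` at subregion level.
#' @return A `frequency_table` at country level.
#' @export
aggregate_to_country <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  if (table$level != "subregion") {
    ysnpdb_abort("aggregate_to_country expects a subregion-level table",
                 "ysnpdb_bad_arguments")
  }
  cells <- table$cells
  agg_d <- tapply(cells$n_derived, cells$country_id, sum)
  agg_i <- tapply(cells$n_informative, cells$country_id, sum)
  countries <- names(agg_d)
  freq <- ifelse(agg_i > 0, agg_d / agg_i, NA_real_)
  if (table$scale == "relative") {
    mx <- suppressWarnings(max(freq, na.rm = TRUE))
    if (is.finite(mx) && mx > 0) freq <- freq / mx
  }
  out <- data.frame(
    region_id = countries, country_id = countries,
    n_derived = as.integer(agg_d), n_informative = as.integer(agg_i),
    frequency = as.numeric(freq),
    display_pct = ifelse(is.na(freq), NA_real_, round_half_up(100 * as.numeric(freq))),
    interpolated = FALSE, stringsAsFactors = FALSE
  )
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(query = table$query, mode = table$mode, scale = table$scale,
                 level = "country", cells = out, conflicts = table$conflicts,
                 tree_version = table$tree_version),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %s (%s mode, %s scale, %s level)\n",
              format(x$query), x$mode, x$scale, x$level))
  print(x$cells, row.names = FALSE)
  if (length(x$conflicts)) {
    cat(sprintf("%d sample(s) excluded for conflicting calls: %s\n",
                length(x$conflicts), paste(x$conflicts, collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.frequency_table <- function(x, ...) x$cells

#' Export a frequency table as CSV
#'
#' Columns: region_id, n_derived, n_informative, frequency, display_pct,
#' interpolated.
#'
#' @param table A `frequency_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_frequency_csv <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  cols <- c("region_id", "n_derived", "n_informative", "frequency",
            "display_pct", "interpolated")
  utils::write.csv(table$cells[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a frequency table as GeoJSON for choropleth use
#'
#' Emits a FeatureCollection with one feature per region that has a
#' geometry, carrying `name`, `frequency`, `display_pct` and `interpolated`
#' properties.
#'
#' @param table A `frequency_table`.
#' @param geometries List of region geometries (see [read_regions_geojson()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_frequency_geojson <- function(table, geometries, path) {
  stopifnot(inherits(table, "frequency_table"))
  geom_ids <- vapply(geometries, `[[`, character(1), "region_id")
  feats <- list()
  for (i in seq_len(nrow(table$cells))) {
    cell <- table$cells[i, ]
    j <- match(cell$region_id, geom_ids)
    if (is.na(j)) next
    rings <- lapply(geometries[[j]]$rings, function(r) {
      lapply(seq_len(nrow(r)), function(k) c(r[k, "lon"], r[k, "lat"]))
    })
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(name = cell$region_id,
                        frequency = if (is.na(cell$frequency)) NULL else cell$frequency,
                        display_pct = if (is.na(cell$display_pct)) NULL else cell$display_pct,
                        interpolated = cell$interpolated),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
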