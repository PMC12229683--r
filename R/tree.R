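#' Load a haplogroup tree from JSON
#'
#' Reads a rooted Y-haplogroup tree in the package's JSON dialect:
#' \preformatted{
#' {"version": "...",
#'  "branches": [
#'    {"id": "R-L51", "parent": "R",
#'     "snps": [{"name": "L51", "synonyms": ["M412"], "position": 8502236},
#'              {"name": "Y410", "synonyms": [], "position": null}]}, ...]}
#' }
#' Each branch carries its defining SNP equivalence class: distinct SNPs that
#' mark the same branch (no known chromosome separates them), each with
#' optional synonyms (alternative names for the same physical SNP). The
#' loader validates the tree invariants: a single root, resolvable parents,
#' acyclicity, non-empty SNP sets on non-root branches, and tree-wide
#' uniqueness of every branch id, SNP name and synonym (case-insensitive).
#'
#' @param path Path to a tree JSON file.
#' @return An object of class `haplogroup_tree`: a list with elements
#'   `version`, `root`, `branches` (named list of branch records),
#'   `children` (named list of child id vectors) and `name_index`
#'   (named character vector mapping every normalized name to a branch id).
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("tree file not found: %s", path), "ysnpdb_missing_file")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      ysnpdb_abort(sprintf("cannot parse tree JSON '%s': %s", path, conditionMessage(e)),
                   "ysnpdb_parse_error")
    }
  )
  if (is.null(doc$branches)) {
    ysnpdb_abort("tree JSON lacks a 'branches' array", "ysnpdb_parse_error")
  }
  branches <- lapply(doc$branches, function(b) {
    snps <- lapply(b$snps %||% list(), function(s) {
      list(
        name = as.character(s$name),
        synonyms = vapply(s$synonyms %||% list(), as.character, character(1)),
        position = if (is.null(s$position)) NA_integer_ else as.integer(s$position)
      )
    })
    list(
      id = as.character(b$id),
      parent = if (is.null(b$parent)) NA_character_ else as.character(b$parent),
      snps = snps
    )
  })
  build_tree(branches, version = as.character(doc$version %||% "unversioned"))
}

# assemble + validate a haplogroup_tree from a list of branch records
build_tree <- function(branches, version) {
  ids <- vapply(branches, `[[`, character(1), "id")
  if (anyDuplicated(norm_name(ids))) {
    dup <- ids[duplicated(norm_name(ids))][1]
    ysnpdb_abort(sprintf("duplicate branch id: %s", dup), "ysnpdb_duplicate_branch")
  }
  names(branches) <- ids
  parents <- vapply(branches, `[[`, character(1), "parent")

  roots <- ids[is.na(parents)]
  if (length(roots) == 0) {
    ysnpdb_abort("tree has no root (every branch has a parent)", "ysnpdb_multiple_roots")
  }
  if (length(roots) > 1) {
    ysnpdb_abort(sprintf("tree has multiple roots: %s", paste(roots, collapse = ", ")),
                 "ysnpdb_multiple_roots")
  }
  unknown_parent <- setdiff(parents[!is.na(parents)], ids)
  if (length(unknown_parent)) {
    ysnpdb_abort(sprintf("parent id not found in tree: %s", unknown_parent[1]),
                 "ysnpdb_orphan_parent")
  }

  children <- split(ids[!is.na(parents)], parents[!is.na(parents)])
  # preserve file order of children
  children <- lapply(children, function(x) x[order(match(x, ids))])

  # name index: branch ids + every SNP primary name and synonym, all unique
  index_names <- norm_name(ids)
  index_targets <- ids
  for (b in branches) {
    if (!is.na(b$parent) && length(b$snps) == 0) {
      ysnpdb_abort(sprintf("non-root branch '%s' has no defining SNPs", b$id),
                   "ysnpdb_missing_snps")
    }
    for (s in b$snps) {
      if (!nzchar(s$name)) {
        ysnpdb_abort(sprintf("branch '%s' carries a SNP with an empty name", b$id),
                     "ysnpdb_parse_error")
      }
      nms <- c(s$name, s$synonyms)
      index_names <- c(index_names, norm_name(nms))
      index_targets <- c(index_targets, rep(b$id, length(nms)))
    }
  }
  if (anyDuplicated(index_names)) {
    dup <- index_names[duplicated(index_names)][1]
    ysnpdb_abort(sprintf("name '%s' appears more than once in the tree", dup),
                 "ysnpdb_duplicate_snp")
  }
  name_index <- stats::setNames(index_targets, index_names)

  tree <- structure(
    list(version = version, root = roots, branches = branches,
         children = children, name_index = name_index),
    class = "haplogroup_tree"
  )
  # connectivity: everything must be reachable from the root (no cycles)
  reach <- descendants(tree, roots)
  if (length(reach) != length(ids)) {
    stray <- setdiff(ids, reach)[1]
    ysnpdb_abort(sprintf("branch '%s' is not reachable from the root (cycle?)", stray),
                 "ysnpdb_disconnected")
  }
  tree
}

#' Resolve a haplogroup or SNP name to its branch
#'
#' A branch can be reached by its full haplogroup id (e.g. `"R-L51"`), by any
#' of its defining SNPs' primary names (e.g. `"L51"` or the equivalent
#' `"Y410"`), or by a synonym (e.g. `"M412"`). Matching is case-insensitive
#' and ignores surrounding whitespace; no fuzzy matching is done.
#'
#' @param tree A `haplogroup_tree`.
#' @param name Haplogroup id, SNP name or synonym.
#' @return The branch record (list with `id`, `parent`, `snps`).
#' @export
resolve_branch <- function(tree, name) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  key <- norm_name(name)
  if (length(key) != 1 || !nzchar(key)) {
    ysnpdb_abort("query name must be a single non-empty string", "ysnpdb_unknown_name")
  }
  hit <- tree$name_index[key]
  if (is.na(hit)) {
    ysnpdb_abort(sprintf("unknown haplogroup or SNP name: '%s'", name),
                 "ysnpdb_unknown_name")
  }
  tree$branches[[unname(hit)]]
}

#' Subtree branch ids (inclusive of the starting branch)
#'
#' @param tree A `haplogroup_tree`.
#' @param branch_id Branch to root the subtree at.
#' @return Character vector of branch ids in the subtree.
#' @export
descendants <- function(tree, branch_id) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (is.null(tree$branches[[branch_id]])) {
    ysnpdb_abort(sprintf("unknown branch: '%s'", branch_id), "ysnpdb_unknown_name")
  }
  out <- character(0)
  queue <- branch_id
  while (length(queue)) {
    b <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, b)
    queue <- c(queue, tree$children[[b]])
  }
  out
}

#' Path from the root to a branch
#'
#' @inheritParams descendants
#' @return Character vector of branch ids ordered root first, `branch_id` last.
#' @export
ancestors <- function(tree, branch_id) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (is.null(tree$branches[[branch_id]])) {
    ysnpdb_abort(sprintf("unknown branch: '%s'", branch_id), "ysnpdb_unknown_name")
  }
  path <- branch_id
  p <- tree$branches[[branch_id]]$parent
  while (!is.na(p)) {
    path <- c(p, path)
    p <- tree$branches[[p]]$parent
  }
  path
}

# depth of a branch: root has depth 0
branch_depth <- function(tree, branch_id) {
  length(ancestors(tree, branch_id)) - 1L
}

#' Export a subtree as newick or indented text
#'
#' Newick output labels nodes with branch ids and carries no branch lengths;
#' it re-parses (e.g. with `ape::read.tree`) to a topologically identical
#' subtree. The text format lists one branch per line, indented by depth,
#' with the branch's defining SNP names in brackets.
#'
#' @inheritParams descendants
#' @param format `"newick"` or `"text"`.
#' @return A single string.
#' @export
export_subtree <- function(tree, branch_id, format = c("newick", "text")) {
  format <- match.arg(format)
  if (is.null(tree$branches[[branch_id]])) {
    ysnpdb_abort(sprintf("unknown branch: '%s'", branch_id), "ysnpdb_unknown_name")
  }
  if (format == "newick") {
    rec <- function(b) {
      kids <- tree$children[[b]]
      if (is.null(kids) || !length(kids)) return(b)
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", b)
    }
    paste0(rec(branch_id), ";")
  } else {
    base_depth <- branch_depth(tree, branch_id)
    lines <- vapply(descendants(tree, branch_id), function(b) {
      snps <- vapply(tree$branches[[b]]$snps, `[[`, character(1), "name")
      indent <- strrep("  ", branch_depth(tree, b) - base_depth)
      sprintf("%s%s [%s]", indent, b, paste(snps, collapse = ", "))
    }, character(1))
    paste(lines, collapse = "\n")
  }
}

#' Write a haplogroup tree back to the JSON dialect
#'
#' @param tree A `haplogroup_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  branches <- lapply(unname(tree$branches), function(b) {
    list(
      id = b$id,
      parent = if (is.na(b$parent)) NULL else b$parent,
      snps = lapply(b$snps, function(s) {
        list(name = s$name,
             synonyms = as.list(s$synonyms),
             position = if (is.na(s$position)) NULL else s$position)
      })
    )
  })
  jsonlite::write_json(list(version = tree$version, branches = branches),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  n_snp <- sum(vapply(x$branches, function(b) {
    sum(vapply(b$snps, function(s) 1L + length(s$synonyms), integer(1)))
  }, integer(1)))
  cat(sprintf("<haplogroup_tree> version %s: %d branches, %d SNP names, root %s\n",
              x$version, length(x$branches), n_snp, x$root))
  invisible(x)
}
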