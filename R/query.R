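#' Parse a haplogroup query, including paraphyletic exclusions
#'
#' Grammar: either a plain name (haplogroup id, SNP name or synonym), or
#' `MAIN*(xE1, xE2, ...)` where each `Ei` names a strict descendant of
#' `MAIN` to exclude. `E*(xV13)` therefore selects all samples belonging to
#' haplogroup E except those belonging to E-V13 (a paraphyletic group).
#' Every token is resolved against the tree; unresolvable names, exclusions
#' outside the main clade, and malformed syntax are errors.
#'
#' @param text Query string.
#' @param tree A `haplogroup_tree`.
#' @return An `hg_query`: list with `main` (branch id), `exclusions`
#'   (character vector of branch ids, possibly empty) and `raw`.
#' @export
parse_query <- function(text, tree) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  raw <- text
  text <- trimws(text)
  if (!nzchar(text)) {
    ysnpdb_abort("empty query", "ysnpdb_malformed_query")
  }
  if (!grepl("*", text, fixed = TRUE)) {
    return(structure(list(main = resolve_branch(tree, text)$id,
                          exclusions = character(0), raw = raw),
                     class = "hg_query"))
  }
  m <- regmatches(text, regexec("^([^*()]+)\\*\\(([^()]*)\\)$", text))[[1]]
  if (length(m) != 3) {
    ysnpdb_abort(sprintf("malformed query syntax: '%s' (expected MAIN*(xA, xB, ...))", raw),
                 "ysnpdb_malformed_query")
  }
  main <- resolve_branch(tree, m[2])$id
  tokens <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) {
    ysnpdb_abort(sprintf("empty exclusion list in query '%s'", raw),
                 "ysnpdb_malformed_query")
  }
  exclusions <- vapply(tokens, function(tok) {
    if (!grepl("^[xX]", tok)) {
      ysnpdb_abort(sprintf("exclusion '%s' must start with 'x'", tok),
                   "ysnpdb_malformed_query")
    }
    resolve_branch(tree, substring(tok, 2))$id
  }, character(1), USE.NAMES = FALSE)
  main_clade <- descendants(tree, main)
  for (ex in exclusions) {
    if (ex == main || !(ex %in% main_clade)) {
      ysnpdb_abort(sprintf("exclusion '%s' is not a strict descendant of '%s'", ex, main),
                   "ysnpdb_not_a_descendant")
    }
  }
  structure(list(main = main, exclusions = unique(exclusions), raw = raw),
            class = "hg_query")
}

#' @export
format.hg_query <- function(x, ...) {
  if (!length(x$exclusions)) return(x$main)
  paste0(x$main, "*(", paste0("x", x$exclusions, collapse = ", "), ")")
}

#' @export
print.hg_query <- function(x, ...) {
  cat(sprintf("<hg_query> %s\n", format(x)))
  invisible(x)
}

#' Branch set selected by a query
#'
#' The subtree of the main haplogroup minus the subtrees of every excluded
#' clade (nested exclusions union harmlessly).
#'
#' @param query An `hg_query`.
#' @param tree A `haplogroup_tree`.
#' @return Character vector of branch ids.
#' @export
included_branches <- function(query, tree) {
  stopifnot(inherits(query, "hg_query"))
  inc <- descendants(tree, query$main)
  for (ex in query$exclusions) {
    inc <- setdiff(inc, descendants(tree, ex))
  }
  inc
}

# coerce a string or hg_query to hg_query
as_hg_query <- function(x, tree) {
  if (inherits(x, "hg_query")) x else parse_query(x, tree)
}
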