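#' Create an empty genotype dataset
#'
#' A dataset couples per-sample genotype records to the haplogroup tree
#' version they were validated against and to a registry of known regions
#' (countries, optionally with named subregions). Mixing records validated
#' against different tree versions is an error at query time.
#'
#' @param tree_version Version tag of the haplogroup tree the dataset is tied to.
#' @param region_registry Character vector of valid region (country) ids.
#' @param subregions Optional named list: region id -> character vector of
#'   valid subregion ids.
#' @return An object of class `hg_dataset`.
#' @export
new_dataset <- function(tree_version, region_registry, subregions = list()) {
  structure(
    list(samples = list(), tree_version = tree_version,
         region_registry = as.character(region_registry),
         subregions = subregions),
    class = "hg_dataset"
  )
}

# construct one sample record; calls is a data.frame(snp_name, state)
new_sample_record <- function(sample_id, population, region_id,
                              subregion_id = NA_character_,
                              assigned_haplogroup = NA_character_,
                              calls = empty_calls(), source_ref = NA_character_) {
  stopifnot(is.data.frame(calls), all(c("snp_name", "state") %in% names(calls)))
  list(sample_id = as.character(sample_id),
       population = as.character(population),
       region_id = as.character(region_id),
       subregion_id = as.character(subregion_id),
       assigned_haplogroup = as.character(assigned_haplogroup),
       calls = calls,
       source_ref = as.character(source_ref))
}

empty_calls <- function() {
  data.frame(snp_name = character(0), state = character(0),
             stringsAsFactors = FALSE)
}

#' Read per-sample genotype calls from caller output (tab-separated)
#'
#' Consumes the tab-separated per-marker dialect written by automated
#' Y-haplogrouping callers: header `sample_id, marker_name, haplogroup,
#' state`, one row per typed marker with state `D` (derived) or `A`
#' (ancestral). A summary row whose `marker_name` is `=HG` carries the
#' caller's haplogroup assignment for the sample in the `haplogroup` column.
#' The dialect itself has no population or region columns, so batch-wide
#' metadata can be supplied through the arguments.
#'
#' @param path Path to the TSV file.
#' @param population,region_id,subregion_id,source_ref Metadata applied to
#'   every record in the file.
#' @return List of sample records.
#' @export
read_yleaf <- function(path, population = NA, region_id = NA,
                       subregion_id = NA, source_ref = NA) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("genotype file not found: %s", path), "ysnpdb_missing_file")
  }
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "marker_name", "haplogroup", "state")
  if (!all(req %in% names(tab))) {
    ysnpdb_abort(sprintf("missing column(s) in %s: %s", path,
                         paste(setdiff(req, names(tab)), collapse = ", ")),
                 "ysnpdb_malformed_row")
  }
  is_hg <- tab$marker_name == "=HG"
  bad <- which(!is_hg & !(tab$state %in% c("D", "A")))
  if (length(bad)) {
    # +1 for the header line
    ysnpdb_abort(sprintf("unknown state token '%s' at line %d of %s",
                         tab$state[bad[1]], bad[1] + 1L, path),
                 "ysnpdb_unknown_state")
  }
  out <- list()
  for (sid in unique(tab$sample_id)) {
    rows <- tab[tab$sample_id == sid, , drop = FALSE]
    hg_rows <- rows[rows$marker_name == "=HG", , drop = FALSE]
    marker_rows <- rows[rows$marker_name != "=HG", , drop = FALSE]
    calls <- data.frame(
      snp_name = marker_rows$marker_name,
      state = ifelse(marker_rows$state == "D", "derived", "ancestral"),
      stringsAsFactors = FALSE
    )
    out[[sid]] <- new_sample_record(
      sample_id = sid, population = population, region_id = region_id,
      subregion_id = subregion_id,
      assigned_haplogroup = if (nrow(hg_rows)) hg_rows$haplogroup[1] else NA_character_,
      calls = calls, source_ref = source_ref
    )
  }
  unname(out)
}

#' Read per-sample genotype records from a manual-submission CSV
#'
#' Header: `sample_id, population, region, subregion, haplogroup,
#' snps_derived, snps_ancestral, source_ref`; the two SNP columns are
#' semicolon-separated lists of SNP names typed derived resp. ancestral.
#'
#' @param path Path to the CSV file.
#' @return List of sample records.
#' @export
read_manual <- function(path) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("genotype file not found: %s", path), "ysnpdb_missing_file")
  }
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "population", "region", "subregion", "haplogroup",
           "snps_derived", "snps_ancestral", "source_ref")
  if (!all(req %in% names(tab))) {
    ysnpdb_abort(sprintf("missing column(s) in %s: %s", path,
                         paste(setdiff(req, names(tab)), collapse = ", ")),
                 "ysnpdb_malformed_row")
  }
  split_snps <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  lapply(seq_len(nrow(tab)), function(i) {
    d <- split_snps(tab$snps_derived[i])
    a <- split_snps(tab$snps_ancestral[i])
    calls <- data.frame(
      snp_name = c(d, a),
      state = c(rep("derived", length(d)), rep("ancestral", length(a))),
      stringsAsFactors = FALSE
    )
    new_sample_record(
      sample_id = tab$sample_id[i], population = tab$population[i],
      region_id = tab$region[i],
      subregion_id = if (nzchar(tab$subregion[i])) tab$subregion[i] else NA_character_,
      assigned_haplogroup = if (nzchar(tab$haplogroup[i])) tab$haplogroup[i] else NA_character_,
      calls = calls, source_ref = tab$source_ref[i]
    )
  })
}

#' Validate a batch of sample records before ingest
#'
#' Reproduces the submission checks a curated repository runs: duplicated
#' sample names (within the batch or against the existing dataset),
#' misspelled country/region names, unresolvable assigned haplogroups and
#' internally conflicting duplicate calls are errors; SNP names not present
#' in the active tree are warnings (the call is dropped at ingest, since
#' tree-version drift is expected between genotyping panels and tree
#' releases). Nothing is raised: all findings are returned in the report.
#'
#' @param records List of sample records.
#' @param tree The active `haplogroup_tree`.
#' @param region_registry Character vector of valid region ids (defaults to
#'   the registry of `existing` when given).
#' @param existing Optional `hg_dataset` the batch is checked against.
#' @return A `validation_report`: list with `ok` (no error-severity issue)
#'   and `issues`, a data.frame with columns severity, code, message, sample_id.
#' @export
validate_batch <- function(records, tree, region_registry = NULL, existing = NULL) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (is.null(region_registry)) {
    if (is.null(existing)) {
      ysnpdb_abort("either region_registry or existing dataset is required",
                   "ysnpdb_bad_arguments")
    }
    region_registry <- existing$region_registry
  }
  issues <- list()
  add <- function(severity, code, message, sample_id = NA_character_) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      sample_id = sample_id, stringsAsFactors = FALSE
    )
  }

  ids <- vapply(records, `[[`, character(1), "sample_id")
  for (sid in unique(ids[duplicated(ids)])) {
    add("error", "duplicate_sample",
        sprintf("sample id '%s' appears more than once in the batch", sid), sid)
  }
  if (!is.null(existing)) {
    existing_ids <- vapply(existing$samples, `[[`, character(1), "sample_id")
    for (sid in unique(intersect(ids, existing_ids))) {
      add("error", "duplicate_sample",
          sprintf("sample id '%s' already exists in the dataset", sid), sid)
    }
  }

  reg_norm <- norm_name(region_registry)
  for (rec in records) {
    sid <- rec$sample_id
    if (!(norm_name(rec$region_id) %in% reg_norm)) {
      add("error", "unknown_region",
          sprintf("region '%s' is not a registered region name", rec$region_id), sid)
    }
    if (!is.na(rec$assigned_haplogroup)) {
      if (is.na(tree$name_index[norm_name(rec$assigned_haplogroup)])) {
        add("error", "unknown_haplogroup",
            sprintf("assigned haplogroup '%s' does not resolve in the tree",
                    rec$assigned_haplogroup), sid)
      }
    }
    if (nrow(rec$calls)) {
      resolved <- tree$name_index[norm_name(rec$calls$snp_name)]
      for (snp in unique(rec$calls$snp_name[is.na(resolved)])) {
        add("warning", "unknown_snp",
            sprintf("SNP '%s' does not resolve in the tree; call will be dropped",
                    snp), sid)
      }
      # conflicting duplicate calls at one SNP; identical duplicates pass
      st <- split(rec$calls$state, norm_name(rec$calls$snp_name))
      for (snp in names(st)[vapply(st, function(s) length(unique(s)) > 1, logical(1))]) {
        add("error", "conflicting_calls",
            sprintf("SNP '%s' has both derived and ancestral duplicate calls", snp), sid)
      }
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), code = character(0),
               message = character(0), sample_id = character(0),
               stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok = %s; %d issue(s)\n", x$ok, nrow(x$issues)))
  if (nrow(x$issues)) print(x$issues, row.names = FALSE)
  invisible(x)
}

#' Ingest validated records into a dataset
#'
#' Requires a passing validation report for the same batch. Calls whose SNP
#' name does not resolve in the tree are dropped (they were flagged as
#' warnings); identical duplicate calls are de-duplicated.
#'
#' @param dataset An `hg_dataset`.
#' @param records List of sample records.
#' @param report The `validation_report` for `records`.
#' @param tree The active `haplogroup_tree` (used to drop unresolvable calls).
#' @return The grown dataset.
#' @export
ingest <- function(dataset, records, report, tree) {
  stopifnot(inherits(dataset, "hg_dataset"), inherits(report, "validation_report"))
  if (!report$ok) {
    ysnpdb_abort("cannot ingest a batch whose validation report has errors",
                 "ysnpdb_failed_validation")
  }
  for (rec in records) {
    if (nrow(rec$calls)) {
      keep <- !is.na(tree$name_index[norm_name(rec$calls$snp_name)])
      calls <- rec$calls[keep, , drop = FALSE]
      calls <- calls[!duplicated(norm_name(calls$snp_name)), , drop = FALSE]
      rownames(calls) <- NULL
      rec$calls <- calls
    }
    dataset$samples[[rec$sample_id]] <- rec
  }
  dataset
}

#' Persist a dataset as JSON lines
#'
#' First line is a header record (`tree_version`, region registry); each
#' further line is one sample record.
#'
#' @param dataset An `hg_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "hg_dataset"))
  header <- jsonlite::toJSON(
    list(tree_version = dataset$tree_version,
         region_registry = as.list(dataset$region_registry),
         subregions = dataset$subregions),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  lines <- vapply(dataset$samples, function(rec) {
    as.character(jsonlite::toJSON(
      list(sample_id = rec$sample_id, population = rec$population,
           region_id = rec$region_id,
           subregion_id = if (is.na(rec$subregion_id)) NULL else rec$subregion_id,
           assigned_haplogroup = if (is.na(rec$assigned_haplogroup)) NULL else rec$assigned_haplogroup,
           snps_derived = as.list(rec$calls$snp_name[rec$calls$state == "derived"]),
           snps_ancestral = as.list(rec$calls$snp_name[rec$calls$state == "ancestral"]),
           source_ref = if (is.na(rec$source_ref)) NULL else rec$source_ref),
      auto_unbox = TRUE, null = "null", digits = NA
    ))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param path Path to a JSON-lines dataset file.
#' @return An `hg_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("dataset file not found: %s", path), "ysnpdb_missing_file")
  }
  lines <- readLines(path)
  if (!length(lines)) {
    ysnpdb_abort("dataset file is empty (no header record)", "ysnpdb_parse_error")
  }
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  ds <- new_dataset(
    tree_version = header$tree_version,
    region_registry = vapply(header$region_registry, as.character, character(1)),
    subregions = lapply(header$subregions %||% list(),
                        function(x) vapply(x, as.character, character(1)))
  )
  for (line in lines[-1]) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    d <- vapply(rec$snps_derived %||% list(), as.character, character(1))
    a <- vapply(rec$snps_ancestral %||% list(), as.character, character(1))
    ds$samples[[rec$sample_id]] <- new_sample_record(
      sample_id = rec$sample_id, population = rec$population,
      region_id = rec$region_id,
      subregion_id = rec$subregion_id %||% NA_character_,
      assigned_haplogroup = rec$assigned_haplogroup %||% NA_character_,
      calls = data.frame(snp_name = c(d, a),
                         state = c(rep("derived", length(d)),
                                   rep("ancestral", length(a))),
                         stringsAsFactors = FALSE),
      source_ref = rec$source_ref %||% NA_character_
    )
  }
  ds
}

#' @export
print.hg_dataset <- function(x, ...) {
  pops <- unique(vapply(x$samples, `[[`, character(1), "population"))
  cat(sprintf("<hg_dataset> %d samples, %d population(s), %d region(s), tree %s\n",
              length(x$samples), length(pops), length(x$region_registry),
              x$tree_version))
  invisible(x)
}

#' Number of samples in a dataset
#' @param x An `hg_dataset`.
#' @param ... Unused.
#' @export
length.hg_dataset <- function(x) length(x$samples)
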