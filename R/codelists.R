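#' Load a comorbidity code list
#'
#' Reads a delimited text file mapping clinical terminology codes (Read codes)
#' to comorbidity categories of one summary measure. The file must be CSV with
#' a header naming at least `code`, `term` and `category` columns. Codes are
#' treated as opaque, case-sensitive tokens (Read codes distinguish case) and
#' matched verbatim after trimming surrounding whitespace; no prefix or
#' hierarchy expansion is performed because published lists are already
#' exploded to individual codes.
#'
#' Duplicate rows -- identical `(code, category)` pairs -- are collapsed to a
#' single entry and the number collapsed is reported via `message()`. The same
#' code appearing under two *different* categories of the measure is retained:
#' a tumour code, for example, can legitimately serve both a lymphoma and a
#' metastatic-cancer category, so such rows are surfaced by
#' [validate_codelist()] rather than deleted.
#'
#' @param path Path to a CSV file with columns `code,term,category`.
#' @param measure `"charlson"` or `"elixhauser"`; determines the admissible
#'   category set (17 or 31 categories).
#' @return An object of class `codelist`: a list with elements `measure`,
#'   `entries` (data frame `code`, `term`, `category`) and `categories` (the
#'   measure's [category_registry()]).
#' @seealso [validate_codelist()], [merge_codelists()], [lookup()],
#'   [synthetic_codelists()]
#' @export
load_codelist <- function(path, measure = c("charlson", "elixhauser")) {
  measure <- match.arg(measure)
  if (!file.exists(path)) {
    stop("code list file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, colClasses = "character")
  needed <- c("code", "term", "category")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("code list ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  new_codelist(tab[needed], measure, source = path)
}

# internal constructor shared by load_codelist / merge_codelists / synthetic
# lists; trims codes, validates categories, collapses duplicate (code,
# category) pairs.
new_codelist <- function(entries, measure, source = "<in-memory>") {
  entries$code <- trimws(entries$code)
  if (any(entries$code == "")) {
    stop("code list ", source, ": empty code in row(s) ",
         paste(utils::head(which(entries$code == ""), 5), collapse = ", "),
         call. = FALSE)
  }
  entries$category <- trimws(entries$category)
  registry <- category_registry(measure)
  bad <- !(entries$category %in% registry$category)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("code list ", source, ": row ", i, " has category '",
         entries$category[i], "' which is not a ", measure, " category",
         call. = FALSE)
  }
  dup <- duplicated(entries[c("code", "category")])
  if (any(dup)) {
    message("load_codelist: collapsed ", sum(dup),
            " duplicate (code, category) row(s)")
    entries <- entries[!dup, , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(
    list(measure = measure, entries = entries, categories = registry),
    class = "codelist")
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist> measure:", x$measure, "-", nrow(x$entries),
      "entries across", length(unique(x$entries$category)), "of",
      nrow(x$categories), "categories\n")
  invisible(x)
}

#' @export
as.data.frame.codelist <- function(x, ...) x$entries

#' Write a code list back to CSV
#'
#' Inverse of [load_codelist()]; writing then re-loading yields an identical
#' code list.
#'
#' @param codelist A `codelist`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codelist <- function(codelist, path) {
  stopifnot(inherits(codelist, "codelist"))
  utils::write.csv(codelist$entries, path, row.names = FALSE)
  invisible(path)
}

#' Run the logic checks on a code list
#'
#' Enumerates every invariant violation and some informational facts about a
#' code list: duplicated `(code, category)` pairs, categories outside the
#' measure's category set, empty codes, and codes mapped to more than one
#' category within the measure (permitted, but worth human review). A list
#' returned by [load_codelist()] always reports zero duplicates and zero
#' unknown categories since the loader enforces both.
#'
#' @param codelist A `codelist`.
#' @return An object of class `codelist_validation`: list with
#'   `duplicate_pairs` (data frame), `unknown_categories` (character),
#'   `empty_codes` (count), `cross_category_codes` (character),
#'   `entry_count`, and `per_category_counts` (named integer vector over the
#'   full category set; sums to `entry_count`).
#' @export
validate_codelist <- function(codelist) {
  stopifnot(inherits(codelist, "codelist"))
  e <- codelist$entries
  dup <- duplicated(e[c("code", "category")]) |
    duplicated(e[c("code", "category")], fromLast = TRUE)
  cats <- codelist$categories$category
  unknown <- setdiff(unique(e$category), cats)
  per_cat <- table(factor(e$category, levels = cats))
  n_cat_per_code <- tapply(e$category, e$code, function(x) length(unique(x)))
  cross <- names(n_cat_per_code)[n_cat_per_code > 1]
  structure(list(
    duplicate_pairs = unique(e[dup, c("code", "category"), drop = FALSE]),
    unknown_categories = unknown,
    empty_codes = sum(trimws(e$code) == ""),
    cross_category_codes = sort(cross),
    entry_count = nrow(e),
    per_category_counts = stats::setNames(as.integer(per_cat), cats)
  ), class = "codelist_validation")
}

#' @export
print.codelist_validation <- function(x, ...) {
  cat("<codelist validation>", x$entry_count, "entries;",
      nrow(x$duplicate_pairs), "duplicate pairs;",
      length(x$unknown_categories), "unknown categories;",
      x$empty_codes, "empty codes;",
      length(x$cross_category_codes), "cross-category codes\n")
  invisible(x)
}

#' Merge independently developed code lists for one measure
#'
#' Combines several code lists for the same measure into their set union of
#' `(code, category)` pairs, and reports, per category, the codes present in a
#' strict subset of the inputs -- the discrepancies that, in a manual list
#' development workflow, two screeners would resolve through discussion. The
#' merge is idempotent, commutative and associative.
#'
#' @param ... `codelist` objects sharing one measure (or a single list of
#'   them).
#' @return A list with elements `merged` (a `codelist`) and `discrepancies`
#'   (data frame `code`, `category`, `n_lists`, `n_inputs`).
#' @export
merge_codelists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1]], "codelist")) {
    lists <- lists[[1]]
  }
  stopifnot(length(lists) >= 1L, all(vapply(lists, inherits, TRUE, "codelist")))
  measures <- unique(vapply(lists, `[[`, "", "measure"))
  if (length(measures) != 1L) {
    stop("cannot merge code lists of different measures: ",
         paste(measures, collapse = " vs "), call. = FALSE)
  }
  k <- length(lists)
  all_rows <- do.call(rbind, lapply(seq_along(lists), function(i) {
    e <- lists[[i]]$entries
    e$.list <- i
    e
  }))
  key <- paste(all_rows$code, all_rows$category, sep = "\r")
  n_lists <- tapply(all_rows$.list, key, function(x) length(unique(x)))
  first <- all_rows[!duplicated(key), c("code", "term", "category")]
  first <- first[order(first$category, first$code), , drop = FALSE]
  merged <- new_codelist(first, measures, source = "<merge>")
  fkey <- paste(merged$entries$code, merged$entries$category, sep = "\r")
  nl <- as.integer(n_lists[fkey])
  disc <- merged$entries[nl < k, c("code", "category"), drop = FALSE]
  disc$n_lists <- nl[nl < k]
  disc$n_inputs <- rep(k, nrow(disc))
  rownames(disc) <- NULL
  list(merged = merged, discrepancies = disc)
}

#' Look up the categories a code maps to
#'
#' Exact, case-sensitive match after whitespace trimming. Codes absent from
#' the list return an empty character vector: in real primary-care records
#' most codes are not comorbidity codes, and they are simply ignored.
#'
#' @param codelist A `codelist`.
#' @param code Character vector of codes (vectorised).
#' @return For a single code, a character vector of category identifiers
#'   (possibly empty). For several codes, a named list of such vectors.
#' @export
lookup <- function(codelist, code) {
  stopifnot(inherits(codelist, "codelist"))
  code <- trimws(code)
  hits <- lapply(code, function(cd) {
    sort(unique(codelist$entries$category[codelist$entries$code == cd]))
  })
  if (length(code) == 1L) hits[[1]] else stats::setNames(hits, code)
}
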