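#' Read a behavior catalog
#'
#' A catalog lists the coded unsafe behaviors used to annotate accident cases:
#' one row per behavior with a code of the form `B<k>`, a free-text label and a
#' category. The package ships a reconstructed catalog (see
#' [default_catalog()]) whose labels are only partially recoverable from public
#' sources; user catalogs follow the same CSV layout.
#'
#' @param path Path to a CSV file with header `code,label,category`.
#' @return A tibble with columns `code`, `label`, `category`, in file order.
#' @seealso [write_catalog()], [default_catalog()]
#' @export
load_catalog <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("code", "label", "category")
  if (!all(req %in% names(df))) {
    rlang::abort(sprintf("Catalog file must have header %s.", paste(req, collapse = ",")))
  }
  df <- tibble::as_tibble(df[req])
  assert_codes_wellformed(df$code, context = basename(path))
  if (anyDuplicated(df$code)) {
    dup <- df$code[duplicated(df$code)][1]
    rlang::abort(sprintf("Duplicate behavior code '%s' in catalog '%s'.", dup, basename(path)))
  }
  df
}

#' @rdname load_catalog
#' @param catalog A catalog tibble as returned by [load_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  readr::write_csv(catalog[c("code", "label", "category")], path, progress = FALSE)
  invisible(path)
}

#' The built-in reconstructed behavior catalog
#'
#' Returns the catalog of 73 coded unsafe behaviors shipped with the package.
#' Sixteen labels (B1, B2, B3, B6, B9, B10, B11, B12, B13, B14, B17, B18, B22,
#' B24, B27, B31) are recoverable from published accident analyses of Chinese
#' building construction; the remaining entries carry placeholder labels and
#' the category `"unlabelled"`. The placeholder part is a reconstruction, not
#' an authoritative list.
#'
#' @return A tibble with columns `code`, `label`, `category` (73 rows).
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "behavior_catalog_reconstructed.csv",
                      package = "unsafebn", mustWork = TRUE)
  load_catalog(path)
}

#' Read and write accident-case files
#'
#' An accident-case file has one row per case: a case identifier, an accident
#' type symbol, and the time-ordered behavior codes observed in the case,
#' joined with semicolons (e.g. `A1,F,B18;B14;B12`). Order reflects the time
#' sequence in the accident report and is preserved exactly.
#'
#' @param path Path to a CSV file with header `case_id,accident_type,codes`.
#' @param catalog Optional catalog tibble; when supplied, every code must
#'   resolve against it.
#' @param allowed_types Optional character vector of accident-type symbols to
#'   accept. The default (`NULL`) accepts any alphanumeric symbol so that
#'   non-modelled types survive loading and are removed later by
#'   [filter_cases()].
#' @return A tibble with columns `case_id`, `accident_type` and `sequence`
#'   (a list-column of ordered behavior codes).
#' @export
load_cases <- function(path, catalog = NULL, allowed_types = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("case_id", "accident_type", "codes")
  if (!all(req %in% names(df))) {
    rlang::abort(sprintf("Case file must have header %s.", paste(req, collapse = ",")))
  }
  seqs <- strsplit(ifelse(is.na(df$codes), "", df$codes), ";", fixed = TRUE)
  seqs <- lapply(seqs, function(x) trimws(x[nzchar(trimws(x))]))
  for (r in seq_along(seqs)) {
    cid <- df$case_id[r]
    if (!length(seqs[[r]])) {
      rlang::abort(sprintf("Case '%s' has an empty behavior sequence.", cid))
    }
    assert_codes_wellformed(seqs[[r]], context = sprintf("case '%s'", cid))
    if (anyDuplicated(seqs[[r]])) {
      dup <- seqs[[r]][duplicated(seqs[[r]])][1]
      rlang::abort(sprintf("Behavior '%s' appears more than once in case '%s'.", dup, cid))
    }
    if (!is.null(catalog)) {
      unknown <- setdiff(seqs[[r]], catalog$code)
      if (length(unknown)) {
        rlang::abort(sprintf("Unknown behavior code '%s' in case '%s' (not in catalog).",
                             unknown[1], cid))
      }
    }
    ty <- df$accident_type[r]
    if (is.na(ty) || !grepl("^[A-Za-z0-9]+$", ty)) {
      rlang::abort(sprintf("Malformed accident type symbol '%s' in case '%s'.", ty, cid))
    }
    if (!is.null(allowed_types) && !(ty %in% allowed_types)) {
      rlang::abort(sprintf("Unknown accident type symbol '%s' in case '%s'.", ty, cid))
    }
  }
  tibble::tibble(case_id = df$case_id, accident_type = df$accident_type,
                 sequence = seqs)
}

#' @rdname load_cases
#' @param cases A case tibble as returned by [load_cases()].
#' @export
write_cases <- function(cases, path) {
  out <- tibble::tibble(
    case_id = cases$case_id,
    accident_type = cases$accident_type,
    codes = vapply(cases$sequence, paste, character(1), collapse = ";")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter accident cases before chain extraction
#'
#' Removes cases that cannot enter the network: cases whose behavior sequence
#' is shorter than `min_chain_len` (single-behavior accidents carry no chain)
#' and cases of accident types outside the modelled set. The filter partitions
#' its input: every case is either retained or logged with a reason.
#'
#' @param cases Case tibble from [load_cases()].
#' @param min_chain_len Minimum sequence length to retain (default 2).
#' @param allowed_types Accident types kept for modelling (default
#'   [accident_types()]).
#' @return A list with elements `retained` (case tibble) and `exclusions`
#'   (tibble with `case_id`, `accident_type`, `reason`).
#' @export
filter_cases <- function(cases, min_chain_len = 2,
                         allowed_types = accident_types()) {
  len <- lengths(cases$sequence)
  type_ok <- cases$accident_type %in% allowed_types
  len_ok <- len >= min_chain_len
  keep <- type_ok & len_ok
  reason <- dplyr::case_when(
    !type_ok ~ "type not modelled",
    !len_ok & min_chain_len == 2 & len == 1 ~ "single behavior",
    !len_ok ~ sprintf("sequence shorter than %d", min_chain_len),
    TRUE ~ NA_character_
  )
  list(
    retained = cases[keep, , drop = FALSE],
    exclusions = tibble::tibble(
      case_id = cases$case_id[!keep],
      accident_type = cases$accident_type[!keep],
      reason = reason[!keep]
    )
  )
}

#' Extract directed behavior chains from filtered cases
#'
#' Each retained case yields one chain: the case's behavior codes in time
#' order, read as a directed chain (earlier behavior points to later one).
#' The union of codes appearing across chains — the "behaviors in use" — is
#' attached as an attribute and retrievable with [behaviors_in_use()]; it is
#' the column set used for modelling downstream.
#'
#' @param cases Filtered case tibble (every sequence of length at least 2);
#'   an unfiltered single-behavior case is a precondition error.
#' @return A tibble with columns `case_id`, `accident_type`, `codes`
#'   (list-column), carrying attribute `behaviors_in_use`.
#' @export
extract_chains <- function(cases) {
  len <- lengths(cases$sequence)
  if (any(len < 2)) {
    rlang::abort(sprintf(
      "Case '%s' has a single-behavior sequence; run filter_cases() before extract_chains().",
      cases$case_id[which(len < 2)[1]]
    ))
  }
  chains <- tibble::tibble(
    case_id = cases$case_id,
    accident_type = cases$accident_type,
    codes = cases$sequence
  )
  attr(chains, "behaviors_in_use") <- sort_codes(unique(unlist(chains$codes)))
  chains
}

#' @rdname extract_chains
#' @param chains A chain tibble from [extract_chains()] or [sample_chains()].
#' @export
behaviors_in_use <- function(chains) {
  biu <- attr(chains, "behaviors_in_use")
  if (is.null(biu)) biu <- sort_codes(unique(unlist(chains$codes)))
  biu
}

#' Binarize behavior chains into a case matrix
#'
#' Builds the case-by-behavior indicator table used for network learning: cell
#' (case, behavior) is `"Yes"` if the behavior occurs anywhere in the case's
#' chain and `"No"` otherwise. Time order is deliberately discarded here — it
#' is kept in the chain records — because the network treats behaviors as
#' unordered binary indicators.
#'
#' @param chains Chain tibble from [extract_chains()].
#' @param behavior_subset Ordered character vector of behavior codes defining
#'   the matrix columns; defaults to [behaviors_in_use()] of `chains`. Every
#'   code occurring in a chain must be in the subset.
#' @return A case-matrix tibble: `case_id`, `accident_type`, then one
#'   `"Yes"`/`"No"` column per behavior in `behavior_subset`.
#' @export
chains_to_matrix <- function(chains, behavior_subset = behaviors_in_use(chains)) {
  for (r in seq_len(nrow(chains))) {
    missing <- setdiff(chains$codes[[r]], behavior_subset)
    if (length(missing)) {
      rlang::abort(sprintf(
        "Behavior '%s' in chain of case '%s' is not in the behavior subset.",
        missing[1], chains$case_id[r]
      ))
    }
  }
  cols <- lapply(behavior_subset, function(b) {
    ifelse(vapply(chains$codes, function(cc) b %in% cc, logical(1)), "Yes", "No")
  })
  names(cols) <- behavior_subset
  out <- tibble::tibble(case_id = chains$case_id,
                        accident_type = chains$accident_type)
  dplyr::bind_cols(out, tibble::as_tibble(cols))
}

#' Read and write case matrices
#'
#' The case-matrix CSV has columns `case_id,accident_type,B...` with literal
#' `Yes`/`No` cells, matching the marking convention used when the indicator
#' table is assembled by hand.
#'
#' @param path Path to the CSV file.
#' @return `load_matrix()` returns a case-matrix tibble.
#' @export
load_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  df <- tibble::as_tibble(df)
  assert_case_matrix(df)
  assert_codes_wellformed(behavior_columns(df), context = basename(path))
  df
}

#' @rdname load_matrix
#' @param matrix A case-matrix tibble.
#' @export
write_matrix <- function(matrix, path) {
  assert_case_matrix(matrix)
  readr::write_csv(matrix, path, progress = FALSE)
  invisible(path)
}

#' Overall occurrence rate of a behavior across all cases
#'
#' The fraction of all cases (any accident type) in which the behavior is
#' marked `"Yes"` — the empirical prior rate at which the behavior contributes
#' to the modelled accidents.
#'
#' @param matrix A case-matrix tibble.
#' @param behavior A behavior code present in the matrix.
#' @return A fraction in \[0, 1\].
#' @export
behavior_prior <- function(matrix, behavior) {
  assert_case_matrix(matrix)
  if (!behavior %in% behavior_columns(matrix)) {
    rlang::abort(sprintf("Behavior '%s' is not a column of the case matrix.", behavior))
  }
  mean(matrix[[behavior]] == "Yes")
}
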