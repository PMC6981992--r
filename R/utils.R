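#' Accident types modelled by the network
#'
#' The four accident-type states of the class node, in canonical order:
#' struck-by (S), collapse (C), fall (F) and lifting (L).
#'
#' @return Character vector `c("S", "C", "F", "L")`.
#' @export
accident_types <- function() c("S", "C", "F", "L")

# numeric index k of a behavior code "B<k>"; NA if malformed
code_number <- function(code) {
  k <- suppressWarnings(as.integer(sub("^B([0-9]+)$", "\\1", code)))
  k[!grepl("^B[1-9][0-9]*$", code)] <- NA_integer_
  k
}

sort_codes <- function(codes) codes[order(code_number(codes))]

assert_codes_wellformed <- function(codes, context = "catalog") {
  bad <- which(is.na(code_number(codes)))
  if (length(bad)) {
    rlang::abort(sprintf(
      "Malformed behavior code '%s' in %s (entry %d): expected 'B<k>' with k a positive integer.",
      codes[bad[1]], context, bad[1]
    ))
  }
  invisible(codes)
}

#' Behavior columns of a case matrix
#'
#' The behavior-code columns of a case-matrix tibble, i.e. everything except
#' the `case_id` and `accident_type` bookkeeping columns.
#'
#' @param matrix A case-matrix tibble.
#' @return Character vector of behavior codes in column order.
#' @export
behavior_columns <- function(matrix) {
  setdiff(names(matrix), c("case_id", "accident_type"))
}

assert_case_matrix <- function(matrix) {
  if (!is.data.frame(matrix) || !all(c("case_id", "accident_type") %in% names(matrix))) {
    rlang::abort("A case matrix needs 'case_id' and 'accident_type' columns plus one Yes/No column per behavior.")
  }
  cols <- behavior_columns(matrix)
  if (!length(cols)) rlang::abort("Case matrix has no behavior columns.")
  for (cl in cols) {
    v <- matrix[[cl]]
    if (!all(v %in% c("Yes", "No"))) {
      rlang::abort(sprintf("Behavior column '%s' must contain only 'Yes'/'No'.", cl))
    }
  }
  invisible(matrix)
}

# "Yes"/"No" columns -> logical matrix (cases x behaviors)
indicator_matrix <- function(matrix) {
  cols <- behavior_columns(matrix)
  out <- vapply(cols, function(cl) matrix[[cl]] == "Yes", logical(nrow(matrix)))
  if (nrow(matrix) == 1L) out <- base::matrix(out, nrow = 1, dimnames = list(NULL, cols))
  out
}

# evidence normalizer: unnamed character = all Yes; named values must be Yes/No
as_evidence <- function(evidence) {
  if (is.null(evidence) || length(evidence) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.null(names(evidence)) || all(names(evidence) == "")) {
    ev <- stats::setNames(rep("Yes", length(evidence)), as.character(evidence))
  } else {
    ev <- stats::setNames(as.character(evidence), names(evidence))
  }
  if (anyDuplicated(names(ev))) {
    dup <- names(ev)[duplicated(names(ev))][1]
    rlang::abort(sprintf("Behavior '%s' is observed more than once in the evidence set.", dup))
  }
  if (!all(ev %in% c("Yes", "No"))) {
    rlang::abort("Evidence states must be 'Yes' or 'No'.")
  }
  ev
}
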