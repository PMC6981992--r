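#' Behavior posterior given an accident type (backward reasoning)
#'
#' Computes `P(behavior = Yes | Y = accident_type, extra_evidence)` exactly:
#' the probability that the behavior occurred given that an accident of the
#' stated type occurred, optionally with further behaviors already clamped.
#' The larger this posterior, the greater the behavior's impact within that
#' accident type.
#'
#' @inheritParams class_posterior
#' @param behavior Behavior code, not already clamped in `extra_evidence`.
#' @param accident_type One of the model's accident types.
#' @param extra_evidence Already-clamped behavior observations (see
#'   [class_posterior()]).
#' @return A probability.
#' @export
behavior_posterior <- function(model, behavior, accident_type,
                               extra_evidence = character()) {
  ev <- as_evidence(extra_evidence)
  if (!accident_type %in% model$classes) {
    rlang::abort(sprintf("Accident type '%s' is not in the model.", accident_type))
  }
  if (!behavior %in% model$features) {
    rlang::abort(sprintf("Behavior '%s' is not in the model.", behavior))
  }
  if (behavior %in% names(ev)) {
    rlang::abort(sprintf("Behavior '%s' is already clamped in the evidence.", behavior))
  }
  k <- accident_type
  denom <- class_likelihoods(model, ev)[[k]]
  numer <- class_likelihoods(model, c(ev, stats::setNames("Yes", behavior)))[[k]]
  numer / denom
}

#' Empirical frequency of a behavior within an accident type
#'
#' The fraction of cases in which the behavior is marked `"Yes"`. With
#' `per_type = TRUE` (default) the denominator is the number of cases of that
#' accident type; with `per_type = FALSE` it is all cases in the matrix. The
#' per-type base is the one used by the diagnosis eligibility filter.
#'
#' @param matrix A case-matrix tibble.
#' @param behavior Behavior code (a matrix column).
#' @param accident_type Accident type whose cases form the numerator (and,
#'   with `per_type = TRUE`, the denominator).
#' @param per_type Use cases of `accident_type` as the denominator (default)
#'   rather than all cases.
#' @return A fraction in \[0, 1\].
#' @export
behavior_frequency <- function(matrix, behavior, accident_type, per_type = TRUE) {
  assert_case_matrix(matrix)
  if (!behavior %in% behavior_columns(matrix)) {
    rlang::abort(sprintf("Behavior '%s' is not a column of the case matrix.", behavior))
  }
  in_type <- matrix$accident_type == accident_type
  if (!any(in_type)) {
    rlang::abort(sprintf("No cases of accident type '%s' in the matrix.", accident_type))
  }
  yes <- sum(matrix[[behavior]][in_type] == "Yes")
  yes / if (per_type) sum(in_type) else nrow(matrix)
}

#' Identify the critical group of unsafe behaviors for an accident type
#'
#' Iterative backward diagnosis. Starting from evidence "an accident of this
#' type occurred" (the class node clamped to `accident_type`), each round
#' computes `P(B = Yes | evidence)` for every not-yet-selected behavior whose
#' empirical frequency in that accident type is at least `frequency_floor`.
#' If the largest such posterior falls below `stop_posterior` the loop stops;
#' otherwise the argmax behavior (ties broken by lowest code number) joins the
#' critical group, is clamped to `"Yes"`, and the posteriors are updated.
#' Clamping can raise later posteriors, so selection-time posteriors need not
#' decrease monotonically.
#'
#' The frequency filter uses the per-type denominator by default and is
#' applied from the first iteration onward.
#'
#' @inheritParams behavior_frequency
#' @param model A `tan_model` sharing its behavior set with `matrix`.
#' @param frequency_floor Minimum within-type frequency for a behavior to be
#'   eligible (default 0.08).
#' @param stop_posterior Stop once no eligible behavior reaches this posterior
#'   (default 0.15).
#' @return A `diagnosis_trace` object: list with `accident_type`, `group`
#'   (selected codes in selection order), `steps` (tibble `step`, `behavior`,
#'   `posterior` at selection), `candidates` (tibble of every eligible
#'   behavior's posterior at every round, including the final stopping round),
#'   and `thresholds`.
#' @seealso [tidy.diagnosis_trace()], [autoplot.diagnosis_trace()]
#' @export
critical_group <- function(model, matrix, accident_type,
                           frequency_floor = 0.08, stop_posterior = 0.15,
                           per_type = TRUE) {
  assert_case_matrix(matrix)
  if (!accident_type %in% model$classes) {
    rlang::abort(sprintf("Accident type '%s' is not in the model.", accident_type))
  }
  if (!all(model$features %in% behavior_columns(matrix))) {
    rlang::abort("Model and case matrix must share the behavior set.")
  }
  stopifnot(frequency_floor > 0, frequency_floor < 1,
            stop_posterior > 0, stop_posterior < 1)
  freqs <- vapply(model$features, behavior_frequency, numeric(1),
                  matrix = matrix, accident_type = accident_type,
                  per_type = per_type)
  eligible <- model$features[freqs >= frequency_floor]
  selected <- character(0)
  evidence <- character(0)
  steps <- list()
  cand_rows <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(eligible, selected)
    if (!length(remaining)) break
    post <- vapply(remaining, function(b) {
      behavior_posterior(model, b, accident_type, extra_evidence = evidence)
    }, numeric(1))
    cand_rows[[step]] <- tibble::tibble(
      step = step, behavior = remaining, posterior = unname(post),
      frequency = unname(freqs[remaining])
    )
    if (max(post) < stop_posterior) break
    top <- remaining[post == max(post)]
    pick <- top[order(code_number(top))][1]
    selected <- c(selected, pick)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = step, behavior = pick, posterior = unname(post[[pick]])
    )
    evidence <- c(evidence, stats::setNames("Yes", pick))
  }
  structure(
    list(
      accident_type = accident_type,
      group = selected,
      steps = if (length(steps)) dplyr::bind_rows(steps) else
        tibble::tibble(step = integer(), behavior = character(), posterior = numeric()),
      candidates = dplyr::bind_rows(cand_rows),
      thresholds = c(frequency_floor = frequency_floor,
                     stop_posterior = stop_posterior)
    ),
    class = "diagnosis_trace"
  )
}

#' @export
print.diagnosis_trace <- function(x, ...) {
  cat(sprintf("Backward diagnosis for accident type %s\n", x$accident_type))
  cat(sprintf("  thresholds: frequency >= %.0f%%, stop when max posterior < %.0f%%\n",
              100 * x$thresholds[["frequency_floor"]],
              100 * x$thresholds[["stop_posterior"]]))
  if (!nrow(x$steps)) {
    cat("  critical group: (empty)\n")
  } else {
    cat(sprintf("  critical group: {%s}\n", paste(x$group, collapse = ", ")))
    for (r in seq_len(nrow(x$steps))) {
      cat(sprintf("   step %d: %s selected at P = %.1f%%\n",
                  x$steps$step[r], x$steps$behavior[r], 100 * x$steps$posterior[r]))
    }
  }
  invisible(x)
}

#' Tidy a diagnosis trace
#'
#' @param x A `diagnosis_trace` from [critical_group()].
#' @param ... Unused.
#' @return The per-round candidate tibble (`step`, `behavior`, `posterior`,
#'   `frequency`) with a logical `selected` column marking the behavior chosen
#'   at each round.
#' @method tidy diagnosis_trace
#' @export
tidy.diagnosis_trace <- function(x, ...) {
  sel <- paste(x$steps$step, x$steps$behavior)
  dplyr::mutate(x$candidates,
                selected = paste(.data$step, .data$behavior) %in% sel)
}

#' Glance at a diagnosis trace
#'
#' @param x A `diagnosis_trace`.
#' @param ... Unused.
#' @return One-row tibble: `accident_type`, `group_size`, `n_rounds`,
#'   `frequency_floor`, `stop_posterior`.
#' @method glance diagnosis_trace
#' @export
glance.diagnosis_trace <- function(x, ...) {
  tibble::tibble(
    accident_type = x$accident_type,
    group_size = length(x$group),
    n_rounds = if (nrow(x$candidates)) max(x$candidates$step) else 0L,
    frequency_floor = x$thresholds[["frequency_floor"]],
    stop_posterior = x$thresholds[["stop_posterior"]]
  )
}

#' Rank behaviors as root-node candidates
#'
#' A good reporting root is a behavior that (1) occurs in all four accident
#' types, (2) occurs often overall, and (3) has a weak accident attribute —
#' its occurrence shifts the accident-type distribution little, so no single
#' type dominates its interpretation. Candidates are ranked by criterion (1)
#' first; among behaviors occurring in every type, a small attribute-strength
#' spread (criterion 3) takes precedence over raw total occurrences
#' (criterion 2), because a frequent behavior that is strongly tied to one
#' type makes a poor neutral root. The spread is the range (max minus min)
#' across accident types of the smoothed empirical attribute strength
#' `P(Y = k | B = Yes) - P(Y = k)`.
#'
#' @inheritParams conditional_mutual_information
#' @return A tibble ranked best-first: `code`, per-type counts (`n_S`, `n_C`,
#'   `n_F`, `n_L`), `total`, `in_all_types`, `spread`, `rationale`.
#' @export
select_root <- function(matrix, alpha = 0.5) {
  assert_case_matrix(matrix)
  if (!nrow(matrix)) rlang::abort("Case matrix is empty.")
  feats <- behavior_columns(matrix)
  cls <- accident_types()
  n <- nrow(matrix)
  n_by_class <- vapply(cls, function(k) sum(matrix$accident_type == k), numeric(1))
  K <- sum(n_by_class > 0)
  prior <- (n_by_class + alpha) / (n + alpha * K)
  rows <- purrr::map_dfr(feats, function(b) {
    yes <- matrix[[b]] == "Yes"
    cnt <- vapply(cls, function(k) sum(yes & matrix$accident_type == k), numeric(1))
    total <- sum(cnt)
    # smoothed empirical P(Y = k | B = Yes) minus prior
    p_given_yes <- (cnt + alpha) / (total + alpha * K)
    strength <- p_given_yes - prior
    tibble::tibble(
      code = b,
      n_S = cnt[["S"]], n_C = cnt[["C"]], n_F = cnt[["F"]], n_L = cnt[["L"]],
      total = total,
      in_all_types = all(cnt[n_by_class > 0] >= 1),
      spread = max(strength) - min(strength)
    )
  })
  if (!any(rows$in_all_types)) {
    rlang::warn("No behavior occurs in all accident types; ranking falls back to total occurrences and attribute spread.")
  }
  rows <- rows[order(-rows$in_all_types, rows$spread, -rows$total,
                     code_number(rows$code)), ]
  rows$rank <- seq_len(nrow(rows))
  rows$rationale <- ifelse(
    rows$in_all_types,
    sprintf("occurs in all types; attribute spread %.3f; total %d occurrences",
            rows$spread, as.integer(rows$total)),
    sprintf("absent from at least one type; attribute spread %.3f; total %d occurrences",
            rows$spread, as.integer(rows$total))
  )
  tibble::as_tibble(rows)
}
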