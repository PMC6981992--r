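# Exact evidence likelihood per class by message passing on the feature tree.
# evidence: named character "Yes"/"No". Returns numeric vector over classes.
class_likelihoods <- function(model, evidence) {
  ev <- evidence
  unknown <- setdiff(names(ev), model$features)
  if (length(unknown)) {
    rlang::abort(sprintf("Evidence behavior '%s' is not in the model.", unknown[1]))
  }
  children <- split(names(model$parent)[!is.na(model$parent)],
                    model$parent[!is.na(model$parent)])
  topo <- topo_order(model)
  K <- length(model$classes)
  lik <- stats::setNames(numeric(K), model$classes)
  for (k in seq_len(K)) {
    msg <- list()
    for (v in rev(topo)) {
      cp <- model$cpts[[v]]
      np <- dim(cp$p)[3]
      allowed <- c(TRUE, TRUE)
      if (v %in% names(ev)) allowed <- c("No", "Yes") == ev[[v]]
      m <- numeric(np)
      for (t in seq_len(np)) {
        tot <- 0
        for (s in 1:2) {
          if (!allowed[s]) next
          val <- cp$p[s, k, t]
          for (ch in children[[v]]) val <- val * msg[[ch]][s]
          tot <- tot + val
        }
        m[t] <- tot
      }
      msg[[v]] <- m
    }
    lik[k] <- msg[[model$root]][1]
  }
  lik
}

#' Accident-type posterior under behavior evidence (forward reasoning)
#'
#' Computes `P(Y = k | evidence)` exactly for every accident type, by message
#' collection along the feature tree (unobserved behaviors marginalize out).
#' With empty evidence this is the smoothed class prior. Evidence is a set of
#' observed behavior states, typically `behavior = "Yes"`; negative findings
#' (`"No"`) are also supported.
#'
#' @param model A `tan_model` from [fit_tan()].
#' @param evidence Behavior observations: an unnamed character vector of codes
#'   (all observed `"Yes"`), or a named vector like `c(B14 = "Yes", B7 =
#'   "No")`. Observing the same code twice is an error.
#' @return A tibble with columns `accident_type` and `posterior` (sums to 1).
#' @examples
#' cfg <- generator_config(seed = 1)
#' model <- fit_tan(sample_cases(build_ground_truth(cfg), n = 300, seed = 2))
#' class_posterior(model, evidence = c("B14", "B12"))
#' @export
class_posterior <- function(model, evidence = character()) {
  ev <- as_evidence(evidence)
  lik <- class_likelihoods(model, ev)
  post <- model$class_prior * lik
  if (sum(post) <= 0) rlang::abort("Evidence has zero probability under the model.")
  tibble::tibble(accident_type = model$classes,
                 posterior = unname(post / sum(post)))
}

posterior_vector <- function(model, evidence) {
  cp <- class_posterior(model, evidence)
  stats::setNames(cp$posterior, cp$accident_type)
}

#' Posterior trajectory under accumulating evidence
#'
#' Inserts the observed behaviors one at a time, in the given order, and
#' records the accident-type posterior after each insertion (step 0 is the
#' no-evidence prior). The final row always equals [class_posterior()] on the
#' full set: order affects the path of the trajectory, never its endpoint.
#'
#' @inheritParams class_posterior
#' @param ordered_evidence Character vector of behavior codes in observation
#'   order (all observed `"Yes"`), or a named `"Yes"`/`"No"` vector.
#' @return A `prediction_trajectory` tibble: `step`, `behavior`, `state`, then
#'   one posterior column per accident type.
#' @seealso [autoplot.prediction_trajectory()]
#' @export
sequential_prediction <- function(model, ordered_evidence) {
  ev <- as_evidence(ordered_evidence)
  rows <- vector("list", length(ev) + 1)
  rows[[1]] <- c(step = 0, posterior_vector(model, character()))
  for (t in seq_along(ev)) {
    rows[[t + 1]] <- c(step = t, posterior_vector(model, ev[seq_len(t)]))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    out["step"],
    tibble::tibble(behavior = c(NA_character_, names(ev)),
                   state = c(NA_character_, unname(ev))),
    out[model$classes]
  )
  class(out) <- c("prediction_trajectory", class(out))
  out
}

#' Accident attribute strength of a behavior
#'
#' The accident attribute of a behavior for a given accident type is its
#' contribution to that type; its strength is operationalized as the change in
#' the type's posterior when the behavior is added as `"Yes"` evidence on top
#' of the current context:
#' `P(Y = k | context + {behavior = Yes}) - P(Y = k | context)`.
#' A behavior with a strong attribute for a type produces a large jump in that
#' type's posterior; a weak-attribute behavior barely moves it.
#'
#' @inheritParams class_posterior
#' @param behavior Behavior code, not already in `context`.
#' @param accident_type Optional single accident type; when omitted the
#'   strength is reported for every type.
#' @param context Evidence already in place (see [class_posterior()]).
#' @return If `accident_type` is given, a signed numeric scalar; otherwise a
#'   tibble with `accident_type` and `strength`.
#' @export
attribute_strength <- function(model, behavior, accident_type = NULL,
                               context = character()) {
  ctx <- as_evidence(context)
  if (behavior %in% names(ctx)) {
    rlang::abort(sprintf("Behavior '%s' is already in the evidence context.", behavior))
  }
  base <- posterior_vector(model, ctx)
  with_b <- posterior_vector(model, c(ctx, stats::setNames("Yes", behavior)))
  diff <- with_b - base
  if (is.null(accident_type)) {
    return(tibble::tibble(accident_type = model$classes, strength = unname(diff)))
  }
  if (!accident_type %in% model$classes) {
    rlang::abort(sprintf("Accident type '%s' is not in the model.", accident_type))
  }
  unname(diff[[accident_type]])
}

#' Exact posterior by full enumeration (test oracle)
#'
#' Computes a posterior by summing the model's joint distribution over every
#' completion of the unobserved variables. Deliberately independent of the
#' tree message-passing used by [class_posterior()]; it exists as a
#' brute-force cross-check and refuses models with more than 14 behaviors.
#'
#' @inheritParams class_posterior
#' @param query `"accident_type"` or a behavior code.
#' @param evidence Behavior observations as in [class_posterior()]; may also
#'   include an `accident_type` element to condition on the class.
#' @return A tibble with columns `state` and `probability`.
#' @export
brute_force_posterior <- function(model, query, evidence = character()) {
  m <- length(model$features)
  if (m > 14) {
    rlang::abort(sprintf("Enumeration over %d behaviors refused (bound is 14).", m))
  }
  ev <- if (length(evidence)) {
    if (is.null(names(evidence)) || all(names(evidence) == "")) {
      as_evidence(evidence)
    } else {
      evidence
    }
  } else {
    character(0)
  }
  class_ev <- NULL
  if ("accident_type" %in% names(ev)) {
    class_ev <- ev[["accident_type"]]
    ev <- ev[names(ev) != "accident_type"]
  }
  ev <- as_evidence(ev)
  if (!(query == "accident_type" || query %in% model$features)) {
    rlang::abort(sprintf("Unknown query variable '%s'.", query))
  }
  K <- length(model$classes)
  states <- as.matrix(expand.grid(rep(list(1:2), m)))  # 1 = No, 2 = Yes
  colnames(states) <- model$features
  keep <- rep(TRUE, nrow(states))
  for (b in names(ev)) {
    keep <- keep & states[, b] == match(ev[[b]], c("No", "Yes"))
  }
  states <- states[keep, , drop = FALSE]
  probs <- matrix(0, nrow(states), K)
  for (k in seq_len(K)) {
    if (!is.null(class_ev) && model$classes[k] != class_ev) next
    lp <- rep(log(model$class_prior[[k]]), nrow(states))
    for (f in model$features) {
      cp <- model$cpts[[f]]
      t <- if (is.na(cp$parent)) rep(1L, nrow(states)) else states[, cp$parent]
      lp <- lp + log(cp$p[cbind(states[, f], k, t)])
    }
    probs[, k] <- exp(lp)
  }
  if (query == "accident_type") {
    tot <- colSums(probs)
    tibble::tibble(state = model$classes, probability = tot / sum(tot))
  } else {
    tot <- vapply(1:2, function(s) sum(probs[states[, query] == s, ]), numeric(1))
    tibble::tibble(state = c("No", "Yes"), probability = tot / sum(tot))
  }
}
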