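#' Configuration for the synthetic accident-case generator
#'
#' Describes a ground-truth tree-augmented model from which paper-shaped case
#' matrices are sampled. The defaults emulate the study conditions of the
#' motivating accident data: 287 cases with accident-type frequencies
#' S:C:F:L = 33:39:191:24, 37 binary unsafe-behavior indicators, sparse
#' class-dependent background rates (each conditional rate between 2% and 10%
#' of cases of a type, the range spanned by the minor published per-type
#' column totals), one frequent type-neutral behavior (B14 at rate 0.25 in
#' every type), and planted high-lift behaviors per accident type that define
#' known critical sets.
#'
#' @param n_cases Default number of cases to sample (287).
#' @param class_probs Named probabilities over the accident types
#'   (default `c(S, C, F, L) = c(33, 39, 191, 24) / 287`).
#' @param n_behaviors Number of behavior indicators, coded `B1..B<n>`
#'   (default 37).
#' @param tree Feature-tree edges as a 2-column matrix/data frame
#'   (`parent`, `child`) or `NULL` for a random spanning tree drawn from
#'   `seed`.
#' @param cpts Explicit conditional tables, or `NULL` for random background
#'   rates. When given: a named list, one entry per behavior, each a list with
#'   `parent` (code or `NA`) and `p_yes` — a numeric vector over classes (no
#'   parent dependence) or a `K x 2` matrix (columns = parent No/Yes). When
#'   `cpts` is supplied it overrides `tree` and planting, and the model echoes
#'   the tables exactly.
#' @param background_range Bounds for random background conditional rates
#'   `P(B = Yes | Y, parent state)` (default `c(0.02, 0.10)`).
#' @param planted Data frame with columns `behavior`, `type`, `lift`: each row
#'   forces `P(B = Yes | Y = type) - P(B = Yes | Y != type) >= lift` by
#'   setting the rate to `baseline + lift` in the target type and `baseline`
#'   elsewhere. The default plants the strong-attribute behaviors of each
#'   accident type (e.g. PPE and hole-protection failures for falls).
#' @param common Named numeric vector of type-neutral behaviors and their
#'   rate in every class (default `c(B14 = 0.25)`).
#' @param baseline Off-type rate for planted behaviors (default 0.05).
#' @param seed Integer seed controlling every random choice made from this
#'   configuration (required; default 17).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 287,
                             class_probs = c(S = 33, C = 39, F = 191, L = 24) / 287,
                             n_behaviors = 37,
                             tree = NULL,
                             cpts = NULL,
                             background_range = c(0.02, 0.10),
                             planted = default_planted(),
                             common = c(B14 = 0.25),
                             baseline = 0.05,
                             seed = 17) {
  if (is.null(seed)) rlang::abort("A seed is required for every sampling configuration.")
  if (abs(sum(class_probs) - 1) > 1e-9) rlang::abort("Class probabilities must sum to 1.")
  if (!all(names(class_probs) %in% accident_types()) || anyDuplicated(names(class_probs))) {
    rlang::abort("Class probabilities must be named with distinct accident types.")
  }
  cfg <- structure(
    list(n_cases = n_cases, class_probs = class_probs, n_behaviors = n_behaviors,
         tree = tree, cpts = cpts, background_range = background_range,
         planted = planted, common = common, baseline = baseline,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.null(cfg$planted) && nrow(cfg$planted)) {
    for (r in seq_len(nrow(cfg$planted))) {
      lift <- cfg$planted$lift[r]
      if (lift <= 0 || cfg$baseline + lift >= 1) {
        rlang::abort(sprintf(
          "Infeasible planted lift (%s, %s, %.2f): rate %.2f outside (0, 1).",
          cfg$planted$behavior[r], cfg$planted$type[r], lift, cfg$baseline + lift))
      }
      if (!cfg$planted$type[r] %in% names(cfg$class_probs)) {
        rlang::abort(sprintf("Planted type '%s' is not a modelled class.", cfg$planted$type[r]))
      }
    }
  }
  invisible(cfg)
}

#' @rdname generator_config
#' @export
default_planted <- function() {
  tibble::tribble(
    ~behavior, ~type, ~lift,
    "B12", "F", 0.45,
    "B11", "F", 0.40,
    "B24", "F", 0.30,
    "B17", "C", 0.40,
    "B22", "C", 0.30,
    "B9",  "S", 0.35,
    "B1",  "S", 0.30,
    "B18", "L", 0.40,
    "B27", "L", 0.35,
    "B6",  "L", 0.30
  )
}

#' Build the ground-truth model behind a generator configuration
#'
#' Materializes the configuration into a fully specified `tan_model`
#' (structure plus conditional tables) together with the planted critical set
#' of each accident type: the behaviors whose true within-type occurrence
#' rate `P(B = Yes | Y = k)` is at least 0.15, the diagnosis stop threshold.
#' Deterministic given the configuration seed. Infeasible planted lifts raise
#' an error naming the offending triple.
#'
#' @param config A [generator_config()].
#' @return A `ground_truth` list: `model` (a `tan_model`), `planted_sets`
#'   (named list per accident type, ordered by decreasing true rate), and
#'   `config`.
#' @export
build_ground_truth <- function(config) {
  validate_config(config)
  cls <- names(config$class_probs)
  K <- length(cls)
  feats <- paste0("B", seq_len(config$n_behaviors))

  if (!is.null(config$cpts)) {
    feats <- names(config$cpts)
    parent <- vapply(config$cpts, function(cp) {
      if (is.null(cp$parent) || is.na(cp$parent)) NA_character_ else cp$parent
    }, character(1))
    root <- feats[is.na(parent)]
    if (length(root) != 1) rlang::abort("Explicit cpts must have exactly one parentless behavior.")
    cpts <- lapply(stats::setNames(feats, feats), function(f) {
      spec <- config$cpts[[f]]
      py <- spec$p_yes
      if (is.null(dim(py))) py <- matrix(py, nrow = K, ncol = if (is.na(parent[[f]])) 1 else 2)
      np <- ncol(py)
      p <- array(NA_real_, dim = c(2, K, np),
                 dimnames = list(state = c("No", "Yes"), class = cls,
                                 parent = if (np == 1) "(none)" else c("No", "Yes")))
      for (t in seq_len(np)) {
        p[2, , t] <- py[, t]
        p[1, , t] <- 1 - py[, t]
      }
      list(parent = parent[[f]], p = p)
    })
  } else {
    planted_beh <- if (is.null(config$planted)) character(0) else unique(config$planted$behavior)
    missing <- setdiff(c(planted_beh, names(config$common)), feats)
    if (length(missing)) {
      rlang::abort(sprintf("Behavior '%s' referenced by the config exceeds n_behaviors.", missing[1]))
    }
    drawn <- withr::with_seed(config$seed, {
      if (is.null(config$tree)) {
        shuffled <- sample(feats)
        par_idx <- c(NA_integer_, vapply(2:length(feats), function(i) sample.int(i - 1, 1), integer(1)))
        tr <- cbind(parent = shuffled[par_idx[-1]], child = shuffled[-1])
      } else {
        tr <- as.matrix(config$tree)
      }
      lo <- config$background_range[1]; hi <- config$background_range[2]
      rates <- array(lo + (hi - lo) * stats::rbeta(length(feats) * K * 2, 1.5, 1.5),
                     dim = c(length(feats), K, 2), dimnames = list(feats, cls, c("No", "Yes")))
      list(tree = tr, rates = rates)
    })
    tr <- drawn$tree
    rates <- drawn$rates
    # planted and type-neutral behaviors are parent-independent by construction
    for (b in names(config$common)) {
      rates[b, , ] <- config$common[[b]]
    }
    if (!is.null(config$planted)) {
      for (r in seq_len(nrow(config$planted))) {
        b <- config$planted$behavior[r]
        rates[b, , ] <- config$baseline
      }
      for (r in seq_len(nrow(config$planted))) {
        b <- config$planted$behavior[r]
        k <- config$planted$type[r]
        rates[b, k, ] <- config$baseline + config$planted$lift[r]
      }
    }
    parent <- stats::setNames(rep(NA_character_, length(feats)), feats)
    parent[tr[, 2]] <- tr[, 1]
    root <- feats[is.na(parent)]
    if (length(root) != 1) rlang::abort("Tree specification must leave exactly one root behavior.")
    cpts <- lapply(stats::setNames(feats, feats), function(f) {
      np <- if (is.na(parent[[f]])) 1L else 2L
      p <- array(NA_real_, dim = c(2, K, np),
                 dimnames = list(state = c("No", "Yes"), class = cls,
                                 parent = if (np == 1) "(none)" else c("No", "Yes")))
      for (t in seq_len(np)) {
        p[2, , t] <- rates[f, , t]
        p[1, , t] <- 1 - rates[f, , t]
      }
      list(parent = parent[[f]], p = p)
    })
  }

  model <- new_tan_model(cls, config$class_probs,
                         round(config$class_probs * config$n_cases),
                         feats, vapply(cpts, function(cp) cp$parent, character(1)),
                         root, cpts, alpha = 0, n = config$n_cases)
  sing <- feature_marginals(model)
  planted_sets <- lapply(stats::setNames(cls, cls), function(k) {
    ki <- match(k, cls)
    rate <- vapply(feats, function(f) sing[[f]][2, ki], numeric(1))
    hot <- rate[rate >= 0.15]
    names(sort(hot, decreasing = TRUE))
  })
  structure(list(model = model, planted_sets = planted_sets, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth accident model for synthetic sampling\n")
  print(x$model)
  for (k in names(x$planted_sets)) {
    cat(sprintf("  true critical set %s: {%s}\n", k,
                paste(x$planted_sets[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Sample synthetic accident cases from a ground-truth model
#'
#' Ancestral sampling: each case draws an accident type from the class prior,
#' then behavior states along the feature tree from the true conditional
#' tables. Bit-exact reproducible from `(truth, n, seed)`.
#'
#' @param truth A `ground_truth` from [build_ground_truth()].
#' @param n Number of cases (default the configured `n_cases`).
#' @param seed Integer seed for this sampling call (required).
#' @param class_counts Optional named integer vector over the accident types;
#'   when given, class labels are fixed to exactly these counts (summing to
#'   `n`) instead of being drawn from the prior, and only the behavior states
#'   are sampled. Useful for conditioning a fit on a known class composition.
#' @return A case-matrix tibble (`case_id`, `accident_type`, `B...` columns).
#' @export
sample_cases <- function(truth, n = truth$config$n_cases, seed,
                         class_counts = NULL) {
  if (missing(seed) || is.null(seed)) rlang::abort("sample_cases() requires a seed.")
  if (n < 1) rlang::abort("n must be at least 1.")
  model <- truth$model
  cls <- model$classes
  topo <- topo_order(model)
  withr::with_seed(as.integer(seed), {
    if (is.null(class_counts)) {
      y <- sample(cls, n, replace = TRUE, prob = model$class_prior)
    } else {
      if (!setequal(names(class_counts), cls) || sum(class_counts) != n) {
        rlang::abort("class_counts must cover every accident type and sum to n.")
      }
      y <- rep(names(class_counts), times = class_counts)
    }
    ki <- match(y, cls)
    states <- matrix(NA_integer_, n, length(model$features),
                     dimnames = list(NULL, model$features))
    for (f in topo) {
      cp <- model$cpts[[f]]
      t <- if (is.na(cp$parent)) rep(1L, n) else states[, cp$parent]
      p_yes <- cp$p[cbind(2L, ki, t)]
      states[, f] <- 1L + (stats::runif(n) < p_yes)
    }
    out <- tibble::tibble(
      case_id = sprintf("case%05d", seq_len(n)),
      accident_type = y
    )
    beh <- tibble::as_tibble(lapply(
      stats::setNames(model$features, model$features),
      function(f) c("No", "Yes")[states[, f]]
    ))
    dplyr::bind_cols(out, beh)
  })
}

#' Impose random time orderings to form behavior chains
#'
#' Turns sampled case rows back into time-ordered chains: for every case with
#' at least two `"Yes"` behaviors, the occurring behaviors are arranged in a
#' uniformly random order. Single-behavior and empty rows are skipped and
#' logged (retrievable via `attr(., "skipped")`). Orderings are uniform
#' because time order carries no probability in the model; the chains exist to
#' exercise the chain-extraction input path.
#'
#' @param matrix A case-matrix tibble.
#' @param seed Integer seed (required).
#' @return A chain tibble compatible with [chains_to_matrix()], with
#'   attributes `behaviors_in_use` and `skipped`.
#' @export
sample_chains <- function(matrix, seed) {
  if (missing(seed) || is.null(seed)) rlang::abort("sample_chains() requires a seed.")
  assert_case_matrix(matrix)
  ind <- indicator_matrix(matrix)
  n_yes <- rowSums(ind)
  keep <- n_yes >= 2
  codes <- withr::with_seed(as.integer(seed), {
    lapply(which(keep), function(r) sample(colnames(ind)[ind[r, ]]))
  })
  chains <- tibble::tibble(
    case_id = matrix$case_id[keep],
    accident_type = matrix$accident_type[keep],
    codes = codes
  )
  attr(chains, "behaviors_in_use") <- sort_codes(unique(unlist(codes)))
  attr(chains, "skipped") <- tibble::tibble(
    case_id = matrix$case_id[!keep],
    reason = ifelse(n_yes[!keep] == 1, "single behavior", "no behaviors")
  )
  chains
}
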