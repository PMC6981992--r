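# Shared fixtures, all built in code.

# Case matrix reproducing published per-type marginals: exact class counts
# (F=191, C=39, S=33, L=24) and exact per-type Yes counts for the behaviors
# of the published occurrence table. Only column marginals are meaningful;
# co-occurrence within rows is arbitrary (first-n filling).
table3_counts <- function() {
  tibble::tribble(
    ~behavior, ~F, ~C, ~S, ~L,
    "B12", 99, 5, 1, 4,
    "B11", 73, 2, 4, 1,
    "B14", 42, 8, 11, 11,
    "B6",  13, 2, 10, 12,
    "B24", 30, 2, 3, 0,
    "B13", 32, 2, 0, 0,
    "B1",  14, 0, 9, 5,
    "B31", 22, 2, 3, 1,
    "B9",  16, 0, 4, 3,
    "B16", 11, 9, 3, 0,
    "B18", 10, 0, 2, 9
  )
}

table3_matrix <- function() {
  class_n <- c(S = 33, C = 39, F = 191, L = 24)
  types <- rep(names(class_n), times = class_n)
  cnt <- table3_counts()
  cols <- lapply(cnt$behavior, function(b) {
    v <- rep("No", length(types))
    for (k in names(class_n)) {
      n_yes <- cnt[[k]][cnt$behavior == b]
      idx <- which(types == k)[seq_len(n_yes)]
      v[idx] <- "Yes"
    }
    v
  })
  names(cols) <- cnt$behavior
  dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("A%03d", seq_along(types)),
                   accident_type = types),
    tibble::as_tibble(cols)
  )
}

# Small case matrix with direct control over rows.
# rows: list of list(type =, yes = character vector); behaviors: column set.
make_matrix <- function(rows, behaviors) {
  cols <- lapply(behaviors, function(b) {
    vapply(rows, function(r) if (b %in% r$yes) "Yes" else "No", character(1))
  })
  names(cols) <- behaviors
  dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("A%d", seq_along(rows)),
                   accident_type = vapply(rows, `[[`, character(1), "type")),
    tibble::as_tibble(cols)
  )
}

# Fully specified small model via explicit ground-truth tables.
# p_yes_list: named list behavior -> list(parent=, p_yes=) as generator_config
# expects; class_probs default uniform over the four types.
explicit_model <- function(p_yes_list,
                           class_probs = c(S = .25, C = .25, F = .25, L = .25)) {
  cfg <- generator_config(n_cases = 100, class_probs = class_probs,
                          n_behaviors = length(p_yes_list), cpts = p_yes_list,
                          planted = NULL, common = NULL, seed = 1)
  build_ground_truth(cfg)$model
}

# Random fully specified model for property tests: random chain-free tree,
# conditional Yes-rates uniform on (0.05, 0.95). Deterministic given seed.
random_model <- function(m, seed) {
  withr::with_seed(seed, {
    feats <- paste0("B", seq_len(m))
    parent <- c(NA_integer_, vapply(2:m, function(i) sample.int(i - 1, 1), integer(1)))
    cpts <- lapply(seq_len(m), function(i) {
      np <- if (is.na(parent[i])) 1 else 2
      list(parent = if (is.na(parent[i])) NA_character_ else feats[parent[i]],
           p_yes = matrix(stats::runif(4 * np, 0.05, 0.95), nrow = 4, ncol = np))
    })
    names(cpts) <- feats
    pr <- stats::runif(4, 0.5, 1.5)
    explicit_model(cpts, class_probs = stats::setNames(pr / sum(pr), accident_types()))
  })
}

# Random evidence over a model's behaviors: n_obs observations, mixed states.
random_evidence <- function(model, n_obs, seed) {
  withr::with_seed(seed, {
    obs <- sample(model$features, n_obs)
    stats::setNames(sample(c("Yes", "No"), n_obs, replace = TRUE,
                           prob = c(0.7, 0.3)), obs)
  })
}

# Strongly coupled 8-behavior chain truth with uniform classes: designed for
# structure and parameter recovery (adjacent behaviors copy with noise 0.15,
# class-independent; root at 50%).
recovery_truth <- function() {
  feats <- paste0("B", 1:8)
  cpts <- lapply(seq_along(feats), function(i) {
    if (i == 1) {
      list(parent = NA_character_, p_yes = rep(0.5, 4))
    } else {
      list(parent = feats[i - 1],
           p_yes = matrix(rep(c(0.15, 0.85), each = 4), nrow = 4))
    }
  })
  names(cpts) <- feats
  cfg <- generator_config(n_cases = 100,
                          class_probs = c(S = .25, C = .25, F = .25, L = .25),
                          n_behaviors = 8, cpts = cpts, planted = NULL,
                          common = NULL, seed = 5)
  build_ground_truth(cfg)
}

# Hand-built tan_structure (bypasses CMI search) for parameter-recovery tests.
manual_structure <- function(features, parent, root) {
  edge_parent <- unname(parent[!is.na(parent)])
  edge_child <- names(parent)[!is.na(parent)]
  structure(
    list(
      features = features,
      edges = tibble::tibble(parent = edge_parent, child = edge_child),
      parent = parent,
      root = root,
      cmi = NULL
    ),
    class = "tan_structure"
  )
}

posterior_named <- function(model, evidence = character()) {
  cp <- class_posterior(model, evidence)
  stats::setNames(cp$posterior, cp$accident_type)
}

undirected_edge_set <- function(edges) {
  sort(apply(cbind(edges$parent, edges$child), 1, function(e) paste(sort(e), collapse = "-")))
}
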