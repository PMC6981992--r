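#' Conditional mutual information between two behaviors given accident type
#'
#' Computes `I(B_i; B_j | Y)` in nats from the smoothed empirical joint of the
#' two binary behavior indicators and the accident-type class:
#' `sum over (b_i, b_j, y) of p(b_i, b_j, y) * log[ p(b_i, b_j | y) / (p(b_i | y) p(b_j | y)) ]`,
#' where all probabilities come from cell counts with `alpha` added to each of
#' the `2 x 2 x K` cells. This is the edge weight used by the Chow-Liu step of
#' tree-augmented naive Bayes learning. Tiny negative values from floating
#' point are clamped to zero.
#'
#' @param matrix A case-matrix tibble (see [chains_to_matrix()]).
#' @param i,j Distinct behavior codes, both columns of `matrix`.
#' @param alpha Pseudocount added to every contingency cell (default 0.5).
#' @return A non-negative value in nats.
#' @export
conditional_mutual_information <- function(matrix, i, j, alpha = 0.5) {
  assert_case_matrix(matrix)
  if (identical(i, j)) rlang::abort("Behaviors i and j must differ.")
  if (!nrow(matrix)) rlang::abort("Case matrix is empty.")
  cols <- behavior_columns(matrix)
  if (!all(c(i, j) %in% cols)) {
    rlang::abort(sprintf("Behavior '%s' is not a column of the case matrix.",
                         setdiff(c(i, j), cols)[1]))
  }
  cls <- intersect(accident_types(), unique(matrix$accident_type))
  bi <- factor(matrix[[i]], levels = c("No", "Yes"))
  bj <- factor(matrix[[j]], levels = c("No", "Yes"))
  y <- factor(matrix$accident_type, levels = cls)
  n3 <- table(bi, bj, y) + alpha
  p <- n3 / sum(n3)
  p_y <- apply(p, 3, sum)
  p_iy <- apply(p, c(1, 3), sum)
  p_jy <- apply(p, c(2, 3), sum)
  val <- 0
  for (a in 1:2) for (b in 1:2) for (k in seq_along(cls)) {
    pj <- p[a, b, k]
    if (pj > 0) {
      val <- val + pj * log(pj * p_y[k] / (p_iy[a, k] * p_jy[b, k]))
    }
  }
  max(0, val)
}

#' Learn the tree-augmented naive Bayes structure
#'
#' Builds the feature tree of the model: a maximum-weight spanning tree over
#' all behavior pairs, weighted by [conditional_mutual_information()], then
#' oriented away from a root behavior. In the resulting directed structure
#' every behavior has the accident-type class as a parent plus at most one
#' behavior parent; the orientation root has the class only. The orientation
#' is a drawing choice: any root yields the same joint distribution (see
#' [reroot()]).
#'
#' Ties in edge weight are broken by lexicographic (numeric) behavior-code
#' order, then by edge insertion order, so structure learning is
#' deterministic.
#'
#' @inheritParams conditional_mutual_information
#' @param root Orientation root: a behavior code, or `"auto"` (the
#'   lowest-numbered behavior).
#' @return An object of class `tan_structure`: list with `features`, `edges`
#'   (tibble `parent`, `child` in orientation order), `parent` (named vector,
#'   `NA` for the root), `root`, and the pairwise `cmi` table.
#' @export
learn_tan_structure <- function(matrix, alpha = 0.5, root = "auto") {
  assert_case_matrix(matrix)
  feats <- behavior_columns(matrix)
  if (length(feats) < 2) rlang::abort("Structure learning needs at least 2 behaviors.")
  pairs <- utils::combn(sort_codes(feats), 2)
  cmi <- tibble::tibble(
    i = pairs[1, ], j = pairs[2, ],
    cmi = vapply(seq_len(ncol(pairs)),
                 function(e) conditional_mutual_information(matrix, pairs[1, e], pairs[2, e], alpha),
                 numeric(1))
  )
  ord <- order(-cmi$cmi, code_number(cmi$i), code_number(cmi$j))
  edges_sorted <- cmi[ord, ]
  # Kruskal over the complete CMI graph; comp maps feature -> component id
  comp <- stats::setNames(seq_along(feats), sort_codes(feats))
  tree <- list()
  for (e in seq_len(nrow(edges_sorted))) {
    a <- edges_sorted$i[e]; b <- edges_sorted$j[e]
    ra <- find_root(comp, a); rb <- find_root(comp, b)
    if (ra != rb) {
      comp[comp == rb] <- ra
      tree[[length(tree) + 1]] <- c(a, b)
      if (length(tree) == length(feats) - 1) break
    }
  }
  und <- do.call(rbind, tree)
  if (identical(root, "auto") || is.null(root)) {
    root <- sort_codes(feats)[1]
  }
  if (!root %in% feats) rlang::abort(sprintf("Orientation root '%s' is not a behavior in use.", root))
  parent <- orient_tree(und, feats, root)
  edge_parent <- unname(parent[!is.na(parent)])
  edge_child <- names(parent)[!is.na(parent)]
  structure(
    list(
      features = feats,
      edges = tibble::tibble(parent = edge_parent, child = edge_child),
      parent = parent,
      root = root,
      cmi = cmi
    ),
    class = "tan_structure"
  )
}

find_root <- function(comp, x) {
  r <- comp[[x]]
  nm <- names(comp)
  while (comp[[nm[r]]] != r) r <- comp[[nm[r]]]
  r
}

# orient undirected edge matrix (2-col character) away from root; returns
# named parent vector over feats (NA for root), names in feats order
orient_tree <- function(und, feats, root) {
  parent <- stats::setNames(rep(NA_character_, length(feats)), feats)
  if (is.null(und) || !nrow(und)) return(parent)
  adj <- lapply(stats::setNames(feats, feats), function(f) {
    c(und[und[, 1] == f, 2], und[und[, 2] == f, 1])
  })
  visited <- stats::setNames(rep(FALSE, length(feats)), feats)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in sort_codes(adj[[v]])) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  parent
}

#' Estimate smoothed conditional probability tables
#'
#' Fills every node of a tree-augmented structure with a conditional
#' probability table estimated from the case matrix by additive smoothing:
#' each cell is `(count + alpha) / (sum of counts + alpha * number of child
#' states)`. The class prior is estimated the same way from the class counts.
#' The small-cell adjustment (`alpha > 0`) guarantees no zero cells, so rare
#' behavior-accident combinations keep nonzero probability.
#'
#' Accident types with no cases in the matrix are dropped with a warning
#' rather than smoothed into existence.
#'
#' @inheritParams conditional_mutual_information
#' @param structure A `tan_structure` from [learn_tan_structure()].
#' @return An object of class `tan_model`; see [fit_tan()] for its contents.
#' @export
estimate_cpts <- function(matrix, structure, alpha = 0.5) {
  assert_case_matrix(matrix)
  if (!nrow(matrix)) rlang::abort("Case matrix is empty.")
  bad <- setdiff(unique(matrix$accident_type), accident_types())
  if (length(bad)) {
    rlang::abort(sprintf(
      "Accident type '%s' is not modelled; run filter_cases() first.", bad[1]))
  }
  feats <- structure$features
  if (!all(feats %in% behavior_columns(matrix))) {
    rlang::abort("Structure contains behaviors absent from the case matrix.")
  }
  classes <- intersect(accident_types(), unique(matrix$accident_type))
  dropped <- setdiff(accident_types(), classes)
  if (length(dropped)) {
    rlang::warn(sprintf("Accident type(s) %s have no cases and are dropped from the model.",
                        paste(dropped, collapse = ", ")))
  }
  K <- length(classes)
  y <- factor(matrix$accident_type, levels = classes)
  class_counts <- table(y)
  class_prior <- (as.numeric(class_counts) + alpha) / (nrow(matrix) + alpha * K)
  names(class_prior) <- classes

  cpts <- lapply(stats::setNames(feats, feats), function(f) {
    b <- factor(matrix[[f]], levels = c("No", "Yes"))
    pf <- structure$parent[[f]]
    if (is.na(pf)) {
      cnt <- table(b, y)  # 2 x K
      denom <- rep(as.numeric(class_counts), each = 2) + 2 * alpha
      p <- array((as.numeric(cnt) + alpha) / denom, dim = c(2, K, 1),
                 dimnames = list(state = c("No", "Yes"), class = classes, parent = "(none)"))
      list(parent = NA_character_, p = p)
    } else {
      bp <- factor(matrix[[pf]], levels = c("No", "Yes"))
      cnt <- table(b, y, bp)  # 2 x K x 2
      den <- table(y, bp)     # K x 2
      p <- array(NA_real_, dim = c(2, K, 2),
                 dimnames = list(state = c("No", "Yes"), class = classes, parent = c("No", "Yes")))
      for (k in seq_len(K)) for (t in 1:2) {
        d <- den[k, t] + 2 * alpha
        if (d == 0) {
          p[, k, t] <- 0.5  # unsmoothed, unobserved parent configuration
        } else {
          p[, k, t] <- (cnt[, k, t] + alpha) / d
        }
      }
      list(parent = pf, p = p)
    }
  })
  new_tan_model(classes, class_prior, as.numeric(class_counts), feats,
                structure$parent, structure$root, cpts, alpha, nrow(matrix))
}

new_tan_model <- function(classes, class_prior, class_counts, features,
                          parent, root, cpts, alpha, n) {
  structure(
    list(
      classes = classes,
      class_prior = class_prior,
      class_counts = stats::setNames(class_counts, classes),
      features = features,
      parent = parent,
      root = root,
      cpts = cpts,
      alpha = alpha,
      n = n
    ),
    class = "tan_model"
  )
}

#' Fit a tree-augmented naive Bayes accident model
#'
#' One-call wrapper: learns the feature tree with [learn_tan_structure()] and
#' estimates smoothed conditional probability tables with [estimate_cpts()].
#' The resulting model links the 4-state accident-type class node to binary
#' unsafe-behavior indicators, each with the class plus at most one behavior
#' as parents.
#'
#' @inheritParams learn_tan_structure
#' @return An object of class `tan_model`: a list with `classes`,
#'   `class_prior`, `class_counts`, `features`, `parent` (named vector, `NA`
#'   for the orientation root), `root`, `cpts` (per behavior: feature parent
#'   and a `2 x K x {1,2}` probability array), `alpha` and `n`.
#' @examples
#' cfg <- generator_config(seed = 1)
#' truth <- build_ground_truth(cfg)
#' cases <- sample_cases(truth, n = 200, seed = 2)
#' model <- fit_tan(cases)
#' class_posterior(model)
#' @export
fit_tan <- function(matrix, alpha = 0.5, root = "auto") {
  structure <- learn_tan_structure(matrix, alpha = alpha, root = root)
  estimate_cpts(matrix, structure, alpha = alpha)
}

#' Joint probability of one full assignment
#'
#' Evaluates the model's joint distribution at a complete assignment of the
#' class node and every behavior: the product of the class-prior entry and one
#' conditional-probability entry per behavior. The named vector must contain
#' `accident_type` plus a `"Yes"`/`"No"` state for every behavior in the
#' model.
#'
#' @param model A `tan_model`.
#' @param assignment Named character vector covering `accident_type` and all
#'   behaviors.
#' @return A probability.
#' @export
joint_probability <- function(model, assignment) {
  if (!"accident_type" %in% names(assignment)) {
    rlang::abort("Assignment is missing 'accident_type'.")
  }
  missing <- setdiff(model$features, names(assignment))
  if (length(missing)) {
    rlang::abort(sprintf("Assignment is missing behavior '%s'.", missing[1]))
  }
  k <- match(assignment[["accident_type"]], model$classes)
  if (is.na(k)) rlang::abort("Unknown accident type in assignment.")
  p <- model$class_prior[[k]]
  for (f in model$features) {
    cp <- model$cpts[[f]]
    s <- match(assignment[[f]], c("No", "Yes"))
    if (is.na(s)) rlang::abort(sprintf("State of '%s' must be 'Yes' or 'No'.", f))
    t <- if (is.na(cp$parent)) 1L else match(assignment[[cp$parent]], c("No", "Yes"))
    p <- p * cp$p[s, k, t]
  }
  unname(p)
}

# per-class singleton marginals P(B=s | Y=k) for every feature: list of 2 x K
feature_marginals <- function(model) {
  topo <- topo_order(model)
  sing <- list()
  for (f in topo) {
    cp <- model$cpts[[f]]
    if (is.na(cp$parent)) {
      sing[[f]] <- cp$p[, , 1]
      if (is.null(dim(sing[[f]]))) sing[[f]] <- matrix(sing[[f]], nrow = 2)
    } else {
      su <- sing[[cp$parent]]
      m <- matrix(0, 2, length(model$classes))
      for (k in seq_along(model$classes)) {
        m[, k] <- cp$p[, k, 1] * su[1, k] + cp$p[, k, 2] * su[2, k]
      }
      sing[[f]] <- m
    }
  }
  sing
}

topo_order <- function(model) {
  children <- split(names(model$parent)[!is.na(model$parent)],
                    model$parent[!is.na(model$parent)])
  out <- character(0); queue <- model$root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    queue <- c(queue, children[[v]])
  }
  out
}

#' Re-root the feature tree without changing the joint distribution
#'
#' Re-expresses the same model with a different behavior as the orientation
#' root of the feature tree. Edges on the path between the old and new root
#' are reversed and their conditional tables recomputed from the per-class
#' edge joints, so the joint distribution over all nodes is preserved exactly;
#' only the drawn direction of the arrows changes.
#'
#' @param model A `tan_model`.
#' @param new_root A behavior code in the model.
#' @return A `tan_model` rooted at `new_root`, representing the same joint.
#' @seealso [root_class_table()] for the accident-type-given-root report.
#' @export
reroot <- function(model, new_root) {
  if (!new_root %in% model$features) {
    rlang::abort(sprintf("Unknown behavior code '%s'.", new_root))
  }
  if (identical(new_root, model$root)) return(model)
  K <- length(model$classes)
  sing <- feature_marginals(model)
  # per-class joint on each undirected tree edge, indexed [state_a, state_b, k]
  edge_joint <- list()
  for (v in names(model$parent)[!is.na(model$parent)]) {
    u <- model$parent[[v]]
    J <- array(0, dim = c(2, 2, K))
    for (k in seq_len(K)) for (t in 1:2) {
      J[t, , k] <- sing[[u]][t, k] * model$cpts[[v]]$p[, k, t]
    }
    edge_joint[[paste(u, v, sep = "|")]] <- J  # [u state, v state, k]
  }
  und <- cbind(model$parent[!is.na(model$parent)], names(model$parent)[!is.na(model$parent)])
  parent <- orient_tree(und, model$features, new_root)
  cpts <- model$cpts
  for (f in model$features) {
    pf <- parent[[f]]
    if (is.na(pf)) {
      p <- array(sing[[f]], dim = c(2, K, 1),
                 dimnames = list(state = c("No", "Yes"), class = model$classes, parent = "(none)"))
      cpts[[f]] <- list(parent = NA_character_, p = p)
    } else {
      key_same <- paste(pf, f, sep = "|")
      key_flip <- paste(f, pf, sep = "|")
      if (!is.null(edge_joint[[key_same]])) {
        J <- edge_joint[[key_same]]        # [pf, f, k]
      } else {
        J0 <- edge_joint[[key_flip]]       # [f, pf, k]
        J <- aperm(J0, c(2, 1, 3))
      }
      p <- array(NA_real_, dim = c(2, K, 2),
                 dimnames = list(state = c("No", "Yes"), class = model$classes, parent = c("No", "Yes")))
      for (k in seq_len(K)) for (t in 1:2) {
        p[, k, t] <- J[t, , k] / sing[[pf]][t, k]
      }
      cpts[[f]] <- list(parent = pf, p = p)
    }
  }
  new_tan_model(model$classes, model$class_prior, model$class_counts,
                model$features, parent, new_root, cpts, model$alpha, model$n)
}

#' Accident-type distribution given the root behavior
#'
#' Reporting view associated with a rooted model: the properly normalized
#' conditional distribution of the accident type given each state of a
#' behavior, `P(Y | B = state)`, laid out with one row per behavior state
#' (Yes/No) and one column per accident type. Each row sums to 1.
#'
#' @param model A `tan_model`.
#' @param root Behavior to condition on; defaults to the model's orientation
#'   root.
#' @return A tibble: `behavior`, `state`, then one column per accident type.
#' @export
root_class_table <- function(model, root = model$root) {
  if (!root %in% model$features) {
    rlang::abort(sprintf("Unknown behavior code '%s'.", root))
  }
  sing <- feature_marginals(model)[[root]]  # 2 x K, P(B=s | Y=k)
  out <- matrix(0, 2, length(model$classes),
                dimnames = list(c("Yes", "No"), model$classes))
  for (si in 1:2) {
    s <- c("Yes", "No")[si]
    row <- model$class_prior * sing[match(s, c("No", "Yes")), ]
    out[si, ] <- row / sum(row)
  }
  dplyr::bind_cols(
    tibble::tibble(behavior = root, state = rownames(out)),
    tibble::as_tibble(out)
  )
}

#' @export
print.tan_model <- function(x, ...) {
  cat("Tree-augmented naive Bayes accident model\n")
  cat(sprintf("  classes:   %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  behaviors: %d (orientation root %s)\n", length(x$features), x$root))
  cat(sprintf("  cases:     %d (alpha = %g)\n", x$n, x$alpha))
  cat("  class prior:", paste(sprintf("%s=%.3f", x$classes, x$class_prior), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.tan_structure <- function(x, ...) {
  cat(sprintf("TAN feature tree: %d behaviors, %d edges, root %s\n",
              length(x$features), nrow(x$edges), x$root))
  invisible(x)
}

#' Tidy a fitted accident model
#'
#' Returns every conditional-probability entry of the model as one row:
#' `node`, `state`, `class`, `parent`, `parent_state`, `probability`. The
#' class prior appears under `node == "accident_type"`.
#'
#' @param x A `tan_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tan_model
#' @export
tidy.tan_model <- function(x, ...) {
  prior <- tibble::tibble(
    node = "accident_type", state = x$classes, class = NA_character_,
    parent = NA_character_, parent_state = NA_character_,
    probability = unname(x$class_prior)
  )
  rows <- purrr::map_dfr(x$features, function(f) {
    cp <- x$cpts[[f]]
    np <- dim(cp$p)[3]
    grid <- expand.grid(state = c("No", "Yes"), class = x$classes,
                        pstate = seq_len(np), stringsAsFactors = FALSE)
    tibble::tibble(
      node = f,
      state = grid$state,
      class = grid$class,
      parent = cp$parent,
      parent_state = if (np == 1) NA_character_ else c("No", "Yes")[grid$pstate],
      probability = cp$p[cbind(match(grid$state, c("No", "Yes")),
                               match(grid$class, x$classes), grid$pstate)]
    )
  })
  dplyr::bind_rows(prior, rows)
}

#' Glance at a fitted accident model
#'
#' @param x A `tan_model`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_classes`, `n_behaviors`, `n_edges`,
#'   `alpha` and `root`.
#' @method glance tan_model
#' @export
glance.tan_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = length(x$classes),
    n_behaviors = length(x$features),
    n_edges = sum(!is.na(x$parent)),
    alpha = x$alpha,
    root = x$root
  )
}

#' Serialize a fitted model to JSON and back
#'
#' The JSON document stores the structure (features, parent map, root), the
#' class prior and counts, every conditional-probability table, the smoothing
#' constant and the training size. `read_model(write_model(m, f))` reproduces
#' the model exactly at the precision of the decimal strings emitted (full
#' double precision).
#'
#' @param model A `tan_model`.
#' @param path Output (or input) JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns a
#'   `tan_model`.
#' @export
write_model <- function(model, path) {
  doc <- list(
    classes = model$classes,
    class_prior = as.list(model$class_prior),
    class_counts = as.list(model$class_counts),
    features = model$features,
    parent = lapply(as.list(model$parent), function(p) if (is.na(p)) NULL else p),
    root = model$root,
    alpha = model$alpha,
    n = model$n,
    cpts = lapply(model$cpts, function(cp) {
      list(parent = if (is.na(cp$parent)) NULL else cp$parent,
           dim = dim(cp$p), p = as.numeric(cp$p))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- unlist(doc$classes)
  feats <- unlist(doc$features)
  parent <- vapply(feats, function(f) {
    p <- doc$parent[[f]]
    if (is.null(p)) NA_character_ else p
  }, character(1))
  cpts <- lapply(stats::setNames(feats, feats), function(f) {
    cp <- doc$cpts[[f]]
    d <- unlist(cp$dim)
    p <- array(unlist(cp$p), dim = d,
               dimnames = list(state = c("No", "Yes"), class = classes,
                               parent = if (d[3] == 1) "(none)" else c("No", "Yes")))
    list(parent = if (is.null(cp$parent)) NA_character_ else cp$parent, p = p)
  })
  new_tan_model(classes,
                stats::setNames(unlist(doc$class_prior), classes),
                unlist(doc$class_counts), feats, parent, doc$root, cpts,
                doc$alpha, doc$n)
}
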