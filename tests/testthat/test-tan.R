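# direct summation over the raw 2 x 2 x K contingency table; written
# independently of the package's CMI routine
cmi_oracle <- function(matrix, i, j, alpha) {
  cls <- intersect(accident_types(), unique(matrix$accident_type))
  n3 <- array(0, dim = c(2, 2, length(cls)))
  for (r in seq_len(nrow(matrix))) {
    a <- if (matrix[[i]][r] == "Yes") 2 else 1
    b <- if (matrix[[j]][r] == "Yes") 2 else 1
    k <- match(matrix$accident_type[r], cls)
    n3[a, b, k] <- n3[a, b, k] + 1
  }
  n3 <- n3 + alpha
  p <- n3 / sum(n3)
  total <- 0
  for (k in seq_along(cls)) {
    pk <- sum(p[, , k])
    for (a in 1:2) for (b in 1:2) {
      pab <- p[a, b, k]
      if (pab > 0) {
        total <- total + pab * log((pab / pk) / ((sum(p[a, , k]) / pk) * (sum(p[, b, k]) / pk)))
      }
    }
  }
  total
}

test_that("conditional mutual information matches closed forms and the enumeration oracle", {
  # deterministic copy within every class: I = H(B) = ln 2
  rows <- list()
  for (k in c("S", "C", "F", "L")) {
    rows <- c(rows,
              rep(list(list(type = k, yes = c("B1", "B2"))), 2),
              rep(list(list(type = k, yes = character(0))), 2))
  }
  m_copy <- make_matrix(rows, behaviors = c("B1", "B2"))
  expect_equal(conditional_mutual_information(m_copy, "B1", "B2", alpha = 0),
               log(2), tolerance = 1e-12)

  # count-wise independence within every class: I = 0
  rows_ind <- list()
  for (k in c("F", "S")) {
    for (y1 in c(TRUE, FALSE)) for (y2 in c(TRUE, FALSE)) {
      yes <- c(if (y1) "B1", if (y2) "B2")
      rows_ind <- c(rows_ind, replicate(4, list(type = k, yes = yes), simplify = FALSE))
    }
  }
  m_ind <- make_matrix(rows_ind, behaviors = c("B1", "B2"))
  expect_equal(conditional_mutual_information(m_ind, "B1", "B2", alpha = 0), 0,
               tolerance = 1e-12)

  # random 3-behavior fixture vs full-table summation, smoothed and not
  truth <- build_ground_truth(generator_config(
    n_cases = 60, n_behaviors = 3, planted = NULL, common = NULL,
    background_range = c(0.2, 0.8), seed = 3
  ))
  mx <- sample_cases(truth, n = 60, seed = 4)
  for (a in c(0, 0.5, 1)) {
    expect_equal(conditional_mutual_information(mx, "B1", "B3", alpha = a),
                 cmi_oracle(mx, "B1", "B3", a), tolerance = 1e-12)
  }

  expect_error(conditional_mutual_information(mx, "B1", "B1"), "differ")
  expect_error(conditional_mutual_information(mx[0, ], "B1", "B2"), "empty")
})

test_that("CMI is symmetric", {
  truth <- build_ground_truth(generator_config(
    n_cases = 80, n_behaviors = 4, planted = NULL, common = NULL,
    background_range = c(0.1, 0.9), seed = 8
  ))
  mx <- sample_cases(truth, n = 80, seed = 9)
  for (pair in list(c("B1", "B2"), c("B2", "B4"), c("B3", "B1"))) {
    expect_equal(conditional_mutual_information(mx, pair[1], pair[2]),
                 conditional_mutual_information(mx, pair[2], pair[1]),
                 tolerance = 1e-12)
  }
})

test_that("structure learning picks the two strongest of three CMI edges", {
  # B2 copies B1 with little noise; B3 copies B1 with much noise
  cpts <- list(
    B1 = list(parent = NA_character_, p_yes = rep(0.5, 4)),
    B2 = list(parent = "B1", p_yes = matrix(rep(c(0.05, 0.95), each = 4), nrow = 4)),
    B3 = list(parent = "B1", p_yes = matrix(rep(c(0.35, 0.65), each = 4), nrow = 4))
  )
  model <- explicit_model(cpts)
  truth <- list(model = model)
  mx <- sample_cases(structure(truth, class = "ground_truth"), n = 4000, seed = 11)
  c12 <- conditional_mutual_information(mx, "B1", "B2")
  c13 <- conditional_mutual_information(mx, "B1", "B3")
  c23 <- conditional_mutual_information(mx, "B2", "B3")
  expect_true(c12 > c13 && c13 > c23)  # the planted ordering holds empirically
  st <- learn_tan_structure(mx)
  expect_setequal(undirected_edge_set(st$edges), c("B1-B2", "B1-B3"))
  expect_equal(nrow(st$edges), length(st$features) - 1)

  # two behaviors: the single edge is the tree
  st2 <- learn_tan_structure(mx[, c("case_id", "accident_type", "B1", "B2")])
  expect_equal(undirected_edge_set(st2$edges), "B1-B2")
})

test_that("orientation root defaults to the lowest-numbered behavior and must exist", {
  m <- make_matrix(
    list(list(type = "F", yes = "B7"), list(type = "F", yes = "B10"),
         list(type = "S", yes = c("B7", "B10")), list(type = "S", yes = "B2")),
    behaviors = c("B10", "B7", "B2")
  )
  st <- learn_tan_structure(m)
  expect_equal(st$root, "B2")
  expect_true(is.na(st$parent[["B2"]]))
  expect_error(learn_tan_structure(m, root = "B99"), "B99")
})

test_that("smoothed CPT estimation reproduces the closed-form class prior", {
  fix <- table3_matrix()
  model <- fit_tan(fix, alpha = 0.5)
  expect_equal(unname(model$class_prior[c("F", "C", "S", "L")]),
               c(191.5, 39.5, 33.5, 24.5) / 289, tolerance = 1e-12)
  expect_equal(round(unname(model$class_prior[c("F", "C", "S", "L")]), 4),
               c(0.6626, 0.1367, 0.1159, 0.0848))
})

test_that("alpha = 0 leaves zero counts at exactly zero; alpha > 0 keeps cells strictly inside (0,1)", {
  m <- make_matrix(
    list(list(type = "F", yes = "B1"), list(type = "F", yes = "B1"),
         list(type = "S", yes = "B2"), list(type = "S", yes = character(0))),
    behaviors = c("B1", "B2")
  )
  suppressWarnings({
    m0 <- fit_tan(m, alpha = 0)
    ms <- fit_tan(m, alpha = 0.5)
  })
  # B1 never occurs in S cases
  expect_equal(unname(m0$cpts$B1$p["Yes", "S", 1]), 0)
  cells <- unlist(lapply(ms$cpts, function(cp) as.numeric(cp$p)))
  expect_true(all(cells > 0 & cells < 1))
})

test_that("CPT columns are normalized for every parent configuration", {
  truth <- build_ground_truth(generator_config(seed = 21))
  mx <- sample_cases(truth, n = 400, seed = 22)
  model <- fit_tan(mx)
  for (f in model$features) {
    p <- model$cpts[[f]]$p
    sums <- apply(p, c(2, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("parameter recovery error shrinks with sample size", {
  truth <- recovery_truth()
  st <- manual_structure(truth$model$features, truth$model$parent, truth$model$root)
  err <- vapply(c(2000L, 20000L), function(n) {
    mx <- sample_cases(truth, n = n, seed = 31)
    fit <- estimate_cpts(mx, st, alpha = 0.5)
    max(vapply(truth$model$features, function(f) {
      max(abs(fit$cpts[[f]]$p - truth$model$cpts[[f]]$p))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("the model joint is a normalized distribution and matches hand products", {
  model <- random_model(6, seed = 41)
  total <- 0
  grid <- expand.grid(rep(list(c("No", "Yes")), 6), stringsAsFactors = FALSE)
  names(grid) <- model$features
  for (k in model$classes) {
    for (r in seq_len(nrow(grid))) {
      asn <- c(accident_type = k, unlist(grid[r, ]))
      total <- total + joint_probability(model, asn)
    }
  }
  expect_equal(total, 1, tolerance = 1e-9)

  # 2-feature hand check: P(Y) * P(B1 | Y) * P(B2 | Y, B1)
  cpts <- list(
    B1 = list(parent = NA_character_, p_yes = c(0.3, 0.4, 0.5, 0.6)),
    B2 = list(parent = "B1", p_yes = matrix(c(0.1, 0.2, 0.3, 0.4,
                                              0.7, 0.8, 0.9, 0.6), nrow = 4))
  )
  m2 <- explicit_model(cpts)
  expect_equal(
    joint_probability(m2, c(accident_type = "C", B1 = "Yes", B2 = "No")),
    0.25 * 0.4 * (1 - 0.8)
  )
  expect_error(joint_probability(m2, c(accident_type = "C", B1 = "Yes")), "B2")
})

test_that("re-rooting preserves the joint and reports a normalized class table", {
  model <- random_model(5, seed = 43)
  grid <- expand.grid(rep(list(c("No", "Yes")), 5), stringsAsFactors = FALSE)
  names(grid) <- model$features
  for (new_root in model$features) {
    rr <- reroot(model, new_root)
    expect_equal(rr$root, new_root)
    for (k in model$classes) {
      for (r in seq_len(nrow(grid))) {
        asn <- c(accident_type = k, unlist(grid[r, ]))
        expect_equal(joint_probability(rr, asn), joint_probability(model, asn),
                     tolerance = 1e-9)
      }
    }
  }
  # identity reroot
  expect_identical(reroot(model, model$root), model)
  expect_error(reroot(model, "B99"), "B99")

  tab <- root_class_table(reroot(model, "B2"))
  expect_equal(tab$state, c("Yes", "No"))
  expect_equal(rowSums(as.matrix(tab[, model$classes])), c(1, 1),
               ignore_attr = TRUE)
})

test_that("models survive a JSON round trip exactly", {
  truth <- build_ground_truth(generator_config(n_behaviors = 6, planted = NULL, common = NULL, seed = 51))
  mx <- sample_cases(truth, n = 150, seed = 52)
  model <- fit_tan(mx)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back, model)
  ev <- c("B2", "B5")
  expect_equal(class_posterior(back, ev), class_posterior(model, ev))
})

test_that("tidy and glance expose the fitted tables", {
  truth <- build_ground_truth(generator_config(n_behaviors = 4, planted = NULL, common = NULL, seed = 61))
  mx <- sample_cases(truth, n = 100, seed = 62)
  model <- fit_tan(mx)
  td <- tidy(model)
  expect_true(all(c("node", "state", "class", "probability") %in% names(td)))
  expect_equal(sum(td$node == "accident_type"), 4L)
  # every feature contributes 2 states x 4 classes x parent configs
  gl <- glance(model)
  expect_equal(gl$n_behaviors, 4L)
  expect_equal(gl$n_edges, 3L)
  expect_equal(gl$n, 100L)
})

test_that("classes absent from training are dropped with a warning", {
  m <- make_matrix(
    list(list(type = "F", yes = "B1"), list(type = "F", yes = "B2"),
         list(type = "S", yes = c("B1", "B2")), list(type = "S", yes = "B1")),
    behaviors = c("B1", "B2")
  )
  expect_warning(model <- fit_tan(m), "C, L")
  expect_setequal(model$classes, c("S", "F"))
  expect_equal(sum(model$class_prior), 1)
})
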