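test_that("behavior posteriors match the enumeration oracle and respect preconditions", {
  model <- random_model(8, seed = 91)
  for (case in list(list(b = "B3", k = "S", ev = character()),
                    list(b = "B6", k = "F", ev = c(B1 = "Yes")),
                    list(b = "B2", k = "L", ev = c(B4 = "Yes", B7 = "No")))) {
    got <- behavior_posterior(model, case$b, case$k, extra_evidence = case$ev)
    oracle <- brute_force_posterior(model, case$b,
                                    c(case$ev, accident_type = case$k))
    expect_equal(got, oracle$probability[oracle$state == "Yes"],
                 tolerance = 1e-9)
  }
  expect_error(behavior_posterior(model, "B1", "F", c(B1 = "Yes")), "clamped")
  # clamping the behavior itself yields a point mass (oracle identity)
  pm <- brute_force_posterior(model, "B5", c(B5 = "Yes", accident_type = "F"))
  expect_equal(pm$probability[pm$state == "Yes"], 1)
})

test_that("a class-independent root behavior's posterior is its marginal", {
  cpts <- list(
    B1 = list(parent = NA_character_, p_yes = rep(0.35, 4)),
    B2 = list(parent = "B1", p_yes = matrix(c(0.1, 0.2, 0.3, 0.4,
                                              0.5, 0.6, 0.7, 0.8), nrow = 4))
  )
  model <- explicit_model(cpts)
  for (k in model$classes) {
    expect_equal(behavior_posterior(model, "B1", k), 0.35, tolerance = 1e-12)
  }
})

test_that("behavior frequency uses the per-type denominator from published counts", {
  fix <- table3_matrix()
  expect_equal(behavior_frequency(fix, "B6", "S"), 10 / 33)
  expect_equal(behavior_frequency(fix, "B6", "S", per_type = FALSE), 10 / 287)
  # absent from a type, and an all-Yes column
  m <- make_matrix(
    list(list(type = "F", yes = c("B1", "B2")), list(type = "F", yes = "B1"),
         list(type = "S", yes = "B1")),
    behaviors = c("B1", "B2")
  )
  expect_equal(behavior_frequency(m, "B2", "S"), 0)
  expect_equal(behavior_frequency(m, "B1", "F"), 1)
  expect_error(behavior_frequency(m, "B1", "L"), "No cases")
})

test_that("diagnosis stops immediately when no posterior reaches the threshold", {
  # rates clear the 8% frequency floor but stay below the 15% stop threshold
  truth <- build_ground_truth(generator_config(
    n_behaviors = 6, planted = NULL, common = NULL,
    background_range = c(0.09, 0.115), seed = 93
  ))
  mx <- sample_cases(truth, n = 2000, seed = 94)
  model <- fit_tan(mx)
  tr <- critical_group(model, mx, "F")
  expect_equal(tr$group, character(0))
  expect_equal(max(tr$candidates$step), 1L)
  expect_equal(nrow(tr$steps), 0L)
})

test_that("diagnosis recovers a planted dependent set in planted order", {
  truth <- build_ground_truth(generator_config(seed = 17))
  mx <- sample_cases(truth, n = 5000, seed = 95)
  model <- fit_tan(mx)
  tr <- critical_group(model, mx, "F")
  expect_equal(tr$group, truth$planted_sets$F)
  # every selection respects both thresholds
  sel_freq <- vapply(tr$group, behavior_frequency, numeric(1),
                     matrix = mx, accident_type = "F")
  expect_true(all(sel_freq >= tr$thresholds[["frequency_floor"]]))
  expect_true(all(tr$steps$posterior >= tr$thresholds[["stop_posterior"]]))
})

test_that("each diagnosis step's selected posterior equals the enumeration oracle", {
  truth <- build_ground_truth(generator_config(
    n_behaviors = 9,
    planted = tibble::tibble(behavior = c("B2", "B5"), type = "F",
                             lift = c(0.45, 0.3)),
    common = NULL, seed = 96
  ))
  mx <- sample_cases(truth, n = 3000, seed = 97)
  model <- fit_tan(mx)
  tr <- critical_group(model, mx, "F")
  expect_gt(nrow(tr$steps), 0)
  clamped <- character(0)
  for (r in seq_len(nrow(tr$steps))) {
    b <- tr$steps$behavior[r]
    oracle <- brute_force_posterior(
      model, b,
      c(stats::setNames(rep("Yes", length(clamped)), clamped), accident_type = "F")
    )
    expect_equal(tr$steps$posterior[r],
                 oracle$probability[oracle$state == "Yes"], tolerance = 1e-9)
    clamped <- c(clamped, b)
  }
})

test_that("diagnosis traces are deterministic and column-order invariant", {
  truth <- build_ground_truth(generator_config(seed = 17))
  mx <- sample_cases(truth, n = 2000, seed = 98)
  model <- fit_tan(mx)
  t1 <- critical_group(model, mx, "L")
  t2 <- critical_group(model, mx, "L")
  expect_identical(t1, t2)
  # permute behavior columns of the matrix; model unchanged
  perm <- mx[, c("case_id", "accident_type",
                 withr::with_seed(1, sample(behavior_columns(mx))))]
  t3 <- critical_group(model, perm, "L")
  expect_equal(t3$group, t1$group)
})

test_that("tidy and glance summarize a diagnosis trace", {
  truth <- build_ground_truth(generator_config(seed = 17))
  mx <- sample_cases(truth, n = 2000, seed = 99)
  model <- fit_tan(mx)
  tr <- critical_group(model, mx, "C")
  td <- tidy(tr)
  expect_true(all(c("step", "behavior", "posterior", "frequency", "selected") %in% names(td)))
  expect_equal(sum(td$selected), length(tr$group))
  gl <- glance(tr)
  expect_equal(gl$group_size, length(tr$group))
  expect_equal(gl$accident_type, "C")
})

test_that("root selection ranks frequent, type-neutral behaviors first", {
  fix <- table3_matrix()
  ranking <- select_root(fix)
  # B14 and B12 both occur in every type; B12 has the larger total but a much
  # stronger fall attribute, so B14 must outrank it
  r14 <- which(ranking$code == "B14")
  r12 <- which(ranking$code == "B12")
  expect_true(ranking$in_all_types[r14] && ranking$in_all_types[r12])
  expect_gt(ranking$total[r12], ranking$total[r14])
  expect_lt(r14, r12)
  expect_gt(ranking$spread[r12], ranking$spread[r14])
  expect_match(ranking$rationale[r12], "spread")
  # behaviors missing from a type are flagged
  expect_false(ranking$in_all_types[ranking$code == "B13"])  # absent in S and L

  # a single behavior present in all four types ranks first
  m <- make_matrix(
    list(list(type = "F", yes = c("B1", "B2")), list(type = "C", yes = "B1"),
         list(type = "S", yes = "B1"), list(type = "L", yes = c("B1", "B3"))),
    behaviors = c("B1", "B2", "B3")
  )
  expect_equal(select_root(m)$code[1], "B1")
})

test_that("root selection warns when no behavior spans all types", {
  m <- make_matrix(
    list(list(type = "F", yes = "B1"), list(type = "C", yes = "B2"),
         list(type = "S", yes = "B1"), list(type = "L", yes = "B2")),
    behaviors = c("B1", "B2")
  )
  expect_warning(ranking <- select_root(m), "falls back")
  expect_equal(nrow(ranking), 2L)
})

test_that("ties in diagnosis posteriors break toward the lower code number", {
  # B4 and B9 are exchangeable by construction: identical tables, same parent
  cpts <- list(
    B1 = list(parent = NA_character_, p_yes = rep(0.3, 4)),
    B4 = list(parent = "B1", p_yes = matrix(rep(c(0.2, 0.6), each = 4), nrow = 4)),
    B9 = list(parent = "B1", p_yes = matrix(rep(c(0.2, 0.6), each = 4), nrow = 4))
  )
  model <- explicit_model(cpts)
  mx <- sample_cases(structure(list(model = model), class = "ground_truth"),
                     n = 400, seed = 7)
  tr <- critical_group(model, mx, "F")
  expect_true(all(c("B4", "B9") %in% tr$group))
  expect_lt(which(tr$group == "B4"), which(tr$group == "B9"))
})
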