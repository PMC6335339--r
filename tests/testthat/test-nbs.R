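null_pair_config <- function(seed, n_nodes = 20, n_per = 12) {
  synthetic_config(n_nodes = n_nodes,
                   group_sizes = c(converter = n_per, control = n_per),
                   base_density = 0.3, planted_edges = 10,
                   effect_converter = 1, effect_nonconverter = 1,
                   covariate_betas = c(age = 0, sex = 0, education = 0),
                   seed = seed)
}

test_that("edgewise t statistics match the pooled t-test per edge", {
  co <- sample_cohort(null_pair_config(71))
  et <- edgewise_tstats(co, c("converter", "control"), covariate_cols = NULL)
  man <- co$manifest
  idx <- et$index_map[et$mask, , drop = FALSE]
  for (k in sample(nrow(idx), 10)) {
    w <- vapply(man$subject_id, function(id)
      co$matrices[[id]][idx[k, 1], idx[k, 2]], numeric(1))
    tt <- t.test(w[man$group == "converter"], w[man$group == "control"],
                 var.equal = TRUE)
    expect_equal(et$t[k], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("identical groups give all-zero t and zero-variance tally", {
  co <- sample_cohort(null_pair_config(72, n_per = 6))
  # make the two groups carry identical matrices
  man <- co$manifest
  conv <- man$subject_id[man$group == "converter"]
  ctrl <- man$subject_id[man$group == "control"]
  for (i in seq_along(conv)) co$matrices[[ctrl[i]]] <- co$matrices[[conv[i]]]
  et <- edgewise_tstats(co, c("converter", "control"), covariate_cols = NULL)
  expect_equal(max(abs(et$t)), 0)
})

test_that("component extraction sizes suprathreshold subgraphs correctly", {
  edge_nodes <- rbind(c(1, 2), c(2, 3), c(7, 8), c(4, 5))
  t <- c(3, 3, 3, 1)
  comps <- extract_components(t, edge_nodes, 2)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$size_edges, 2)  # 1-2-3 chain
  expect_equal(comps[[1]]$size_nodes, 3)
  expect_equal(comps[[2]]$size_edges, 1)  # 7-8

  expect_length(extract_components(c(1, 1), rbind(c(1, 2), c(2, 3)), 2), 0)

  n <- 6
  idx <- edge_index_map(n)
  all_comps <- extract_components(rep(5, nrow(idx)), idx, 2)
  expect_length(all_comps, 1)
  expect_equal(all_comps[[1]]$size_edges, n * (n - 1) / 2)

  # one-sided directions respect the sign
  expect_length(extract_components(c(-3, 3), rbind(c(1, 2), c(3, 4)), 2,
                                   "greater"), 1)
  expect_length(extract_components(c(-3, 3), rbind(c(1, 2), c(3, 4)), 2,
                                   "less"), 1)
})

test_that("lowering the primary threshold never shrinks components", {
  co <- sample_cohort(null_pair_config(73))
  et <- edgewise_tstats(co, c("converter", "control"))
  en <- et$index_map[et$mask, , drop = FALSE]
  sizes <- vapply(c(3, 2.5, 2, 1.5), function(thr) {
    comps <- extract_components(et$t, en, thr)
    if (length(comps)) max(vapply(comps, `[[`, 1L, "size_edges")) else 0L
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("NBS is deterministic and invariant to group-pair orientation", {
  co <- sample_cohort(null_pair_config(74))
  a <- nbs_test(co, c("converter", "control"), n_perm = 200, seed = 9)
  b <- nbs_test(co, c("converter", "control"), n_perm = 200, seed = 9)
  expect_identical(a$null_max_sizes, b$null_max_sizes)
  expect_identical(lapply(a$components, `[[`, "corrected_p"),
                   lapply(b$components, `[[`, "corrected_p"))

  # two-sided: swapping the pair flips t but leaves corrected p unchanged
  swapped <- nbs_test(co, c("control", "converter"), n_perm = 200, seed = 9)
  expect_equal(vapply(swapped$components, `[[`, 1, "corrected_p"),
               vapply(a$components, `[[`, 1, "corrected_p"))
  expect_equal(length(swapped$components), length(a$components))

  # corrected p obeys its defining bound
  for (cm in a$components) {
    expect_gt(cm$corrected_p, 0)
    expect_lte(cm$corrected_p, 1)
    expect_equal(cm$corrected_p,
                 (1 + sum(a$null_max_sizes >= cm$size_edges)) / (1 + 200))
  }
})

test_that("planted effects concentrate edgewise signal on planted edges", {
  cfg <- synthetic_config(n_nodes = 30,
                          group_sizes = c(converter = 20, control = 20),
                          planted_edges = 25, effect_converter = 0.5,
                          seed = 75)
  co <- sample_cohort(cfg)
  et <- edgewise_tstats(co, c("converter", "control"))
  idx <- et$index_map[et$mask, , drop = FALSE]
  pe <- co$truth$planted_edges
  key <- paste(idx[, 1], idx[, 2])
  planted <- key %in% paste(pe[, 1], pe[, 2])
  expect_gt(mean(abs(et$t[planted])), mean(abs(et$t[!planted])))
  # converter weights are reduced, so converter-vs-control t < 0 on average
  expect_lt(mean(et$t[planted]), 0)
})

test_that("component strength is the mean subject weight over the edge set", {
  m <- devectorize_edges(c(2, 4, 0), 3)  # w12=2, w13=4
  expect_equal(component_strength(m, rbind(c(1, 2))), 2)
  expect_equal(component_strength(m, rbind(c(1, 2), c(1, 3))), 3)
  expect_equal(component_strength(matrix(0, 3, 3), rbind(c(1, 2))), 0)
  expect_error(component_strength(m, matrix(0, 0, 2)), "empty")
})
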