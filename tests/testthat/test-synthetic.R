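test_that("template has the requested density, connectivity and hub skew", {
  cfg <- synthetic_config(seed = 51)
  tpl <- make_template(cfg)
  expect_equal(nrow(tpl$edges), round(0.15 * 4005))
  g <- igraph::graph_from_edgelist(tpl$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  # right-skewed degrees: a minority of clearly high-degree nodes
  k <- tpl$degree
  expect_gt(max(k), mean(k) + 2 * sd(k))
  expect_gt(mean(k > mean(k) + sd(k)), 0)
  expect_lt(mean(k > mean(k) + sd(k)), 0.25)

  # determinism
  expect_identical(make_template(cfg), tpl)
  # saturation
  full <- make_template(synthetic_config(n_nodes = 12, base_density = 1,
                                         seed = 1))
  expect_equal(nrow(full$edges), 66)
  # density too low to connect
  expect_error(make_template(synthetic_config(n_nodes = 90,
                                              base_density = 0.005,
                                              seed = 1)),
               "too low")
})

test_that("cohorts are deterministic and structurally valid", {
  cfg <- small_config(seed = 52)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a$manifest, b$manifest)  # includes clinical scores
  expect_identical(a$matrices, b$matrices)
  for (m in a$matrices[1:5]) {
    expect_true(isSymmetric(unname(m)))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0) && all(is.finite(m)))
    expect_true(all(m == round(m)))  # streamline counts are integers
  }
  expect_equal(sort(unique(a$manifest$group)),
               c("control", "converter", "nonconverter"))
  expect_true(all(a$manifest$age >= 50 & a$manifest$age <= 78))
  expect_true(all(a$manifest$sex %in% 0:1))
  # planted edges lie in the template and form a connected subgraph
  pe <- a$truth$planted_edges
  tk <- paste(a$truth$template$edges[, 1], a$truth$template$edges[, 2])
  expect_true(all(paste(pe[, 1], pe[, 2]) %in% tk))
  gp <- igraph::graph_from_edgelist(pe, directed = FALSE)
  comp <- igraph::components(gp)
  expect_equal(sum(comp$csize > 1), 1)
})

test_that("planted weakening scales group mean weights as configured", {
  # Monte-Carlo check against configured means: converter mean on planted
  # edges ~ half the control mean at effect 0.5
  cfg <- synthetic_config(n_nodes = 30,
                          group_sizes = c(converter = 26, control = 26),
                          planted_edges = 30, effect_converter = 0.5,
                          covariate_betas = c(age = 0, sex = 0, education = 0),
                          seed = 53)
  co <- sample_cohort(cfg)
  pe <- co$truth$planted_edges
  man <- co$manifest
  mean_on <- function(ids) {
    mean(vapply(ids, function(id)
      mean(co$matrices[[id]][cbind(pe[, 1], pe[, 2])]), numeric(1)))
  }
  m_conv <- mean_on(man$subject_id[man$group == "converter"])
  m_ctrl <- mean_on(man$subject_id[man$group == "control"])
  expect_equal(m_conv / m_ctrl, 0.5, tolerance = 0.1)
})

test_that("null configuration yields centered edgewise statistics", {
  cfg <- synthetic_config(n_nodes = 24,
                          group_sizes = c(converter = 14, control = 14),
                          planted_edges = 10,
                          effect_converter = 1, effect_nonconverter = 1,
                          covariate_betas = c(age = 0, sex = 0, education = 0),
                          base_density = 0.3, seed = 54)
  co <- sample_cohort(cfg)
  et <- edgewise_tstats(co, c("converter", "control"), covariate_cols = NULL)
  expect_lt(abs(mean(et$t)), 3 / sqrt(length(et$t)))
  expect_gt(sd(et$t), 0.7)  # roughly t-distributed, not degenerate
})

test_that("null cohorts give uniform ANCOVA p-values (exchangeability)", {
  # 200 simulated null cohorts; omnibus p on network strength should be
  # uniform (KS test at 5% does not reject)
  ps <- vapply(1:200, function(r) {
    cfg <- synthetic_config(n_nodes = 16,
                            group_sizes = c(converter = 8, nonconverter = 8,
                                            control = 8),
                            base_density = 0.3, planted_edges = 5,
                            effect_converter = 1, effect_nonconverter = 1,
                            covariate_betas = c(age = 0, sex = 0,
                                                education = 0),
                            seed = 5000 + r)
    co <- sample_cohort(cfg)
    sp <- vapply(co$matrices, function(m) mean(colSums(m)), numeric(1))
    ancova_omnibus(sp, co$manifest$group,
                   co$manifest[, c("age", "sex", "education")])$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.05)
})

test_that("clinical scores track global efficiency with ordered group offsets", {
  co <- sample_cohort(synthetic_config(seed = 55))
  man <- co$manifest
  eg <- co$truth$global_efficiency
  # ordered offsets: control > nonconverter > converter on every score
  for (sc in c("MMSE", "MoCA", "AVLT_IR")) {
    mu <- tapply(man[[sc]], man$group, mean)
    expect_gt(mu[["control"]], mu[["nonconverter"]])
    expect_gt(mu[["nonconverter"]], mu[["converter"]])
  }
  # positive within-group association with efficiency by construction
  conv <- man$group == "converter"
  expect_gt(cor(man$MMSE[conv], eg[conv]), 0)
})
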