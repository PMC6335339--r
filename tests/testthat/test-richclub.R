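make_group <- function(masks) lapply(masks, function(m) m * 1)

test_that("backbone keeps edges present in strictly more than the threshold", {
  base <- matrix(0, 4, 4)
  e12 <- base; e12[1, 2] <- e12[2, 1] <- 1
  # edge 1-2 in 5/5 subjects, edge 3-4 in 4/5
  e34 <- base; e34[3, 4] <- e34[4, 3] <- 1
  subs <- c(replicate(4, e12 + e34, simplify = FALSE), list(e12))
  bb <- build_backbone(subs, 0.8)
  expect_equal(bb$edge_mask[1, 2], 1)  # 100% > 80%
  expect_equal(bb$edge_mask[3, 4], 0)  # exactly 80% dropped (strict >)

  expect_warning(build_backbone(replicate(3, base, simplify = FALSE), 0.8),
                 "empty")
})

test_that("hub identification uses the mean + sample-sd degree cut", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 5
  bb <- build_backbone(replicate(3, star, simplify = FALSE), 0.8)
  # degrees (4,1,1,1,1): mean 1.6, sample sd ~1.342, cut ~2.94
  expect_equal(identify_hubs(bb), 1L)

  ring <- ring_lattice(6, 2)
  bbr <- build_backbone(replicate(3, ring, simplify = FALSE), 0.8)
  expect_warning(h <- identify_hubs(bbr), "constant")
  expect_length(h, 0)

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  bbk <- build_backbone(replicate(3, k5, simplify = FALSE), 0.8)
  expect_warning(hk <- identify_hubs(bbk), "constant")
  expect_length(hk, 0)
})

test_that("edge classes partition the backbone by hub membership", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  bb <- build_backbone(replicate(3, star, simplify = FALSE), 0.8)
  cls <- classify_edges(bb, identify_hubs(bb))
  ut <- upper.tri(cls)
  expect_equal(sum(cls[ut] == "feeder", na.rm = TRUE), 4)
  expect_equal(sum(cls[ut] == "rich_club", na.rm = TRUE), 0)
  expect_equal(sum(cls[ut] == "local", na.rm = TRUE), 0)

  expect_true(all(classify_edges(bb, integer(0))[bb$edge_mask > 0] == "local"))
  expect_true(all(classify_edges(bb, 1:5)[bb$edge_mask > 0] == "rich_club"))
})

test_that("class strengths sum to backbone-restricted subject strength", {
  co <- sample_cohort(small_config(seed = 81))
  ids <- co$manifest$subject_id[co$manifest$group == "control"]
  bb <- build_backbone(co$matrices[ids], 0.8)
  cls <- classify_edges(bb, identify_hubs(bb))
  for (id in ids[1:4]) {
    m <- co$matrices[[id]]
    s <- subject_class_strengths(m, cls)
    expect_true(all(s >= 0))
    restricted <- sum((m * bb$edge_mask)[upper.tri(m)])
    expect_equal(sum(s), restricted)
    expect_equal(subject_class_strengths(2 * m, cls), 2 * s)  # linearity
  }
  # unit-weight subject gives class edge counts
  unit <- bb$edge_mask
  su <- subject_class_strengths(unit, cls)
  expect_equal(sum(su), sum(bb$edge_mask) / 2)
  # all-zero subject
  expect_equal(unname(subject_class_strengths(matrix(0, nrow(unit), ncol(unit)),
                                              cls)),
               c(0, 0, 0))
})

test_that("backbones shrink monotonically in the consistency threshold", {
  co <- sample_cohort(small_config(seed = 82))
  ids <- co$manifest$subject_id[co$manifest$group == "converter"]
  prev <- build_backbone(co$matrices[ids], 0.5)
  for (cons in c(0.7, 0.9)) {
    cur <- build_backbone(co$matrices[ids], cons)
    expect_true(all(cur$edge_mask <= prev$edge_mask))
    prev <- cur
  }
  # hubs invariant to uniform rescaling (binary degree)
  bb1 <- build_backbone(co$matrices[ids], 0.8)
  bb2 <- build_backbone(lapply(co$matrices[ids], function(m) 7 * m), 0.8)
  expect_identical(identify_hubs(bb1), identify_hubs(bb2))
})

test_that("group-mean sparsity network keeps the strongest mean edges", {
  m1 <- devectorize_edges(c(10, 2, 1), 3)
  m2 <- devectorize_edges(c(8, 2, 1), 3)
  # mean weights: w12=9, w13=2, w23=1; one edge at sparsity 1/3
  net <- groupmean_sparsity_network(list(m1, m2), 1 / 3)
  expect_equal(net[1, 2], 1)
  expect_equal(sum(net) / 2, 1)
  # saturation keeps every nonzero mean edge
  expect_equal(sum(groupmean_sparsity_network(list(m1, m2), 1)) / 2, 3)

  # 90 nodes at 10% sparsity -> floor(0.1 * 4005) = 400 edges
  set.seed(83)
  dense <- random_weighted_graph(90, density = 0.3, wmax = 50)
  net90 <- groupmean_sparsity_network(list(dense), 0.1)
  expect_equal(sum(net90) / 2, 400)
})

test_that("richclub_analysis builds per-group backbones and strength table", {
  co <- sample_cohort(small_config(seed = 84))
  rc <- richclub_analysis(co)
  expect_equal(nrow(rc$strengths), nrow(co$manifest))
  expect_equal(rc$strengths$subject_id, co$manifest$subject_id)
  expect_true(all(c("rich_club", "feeder", "local") %in% names(rc$strengths)))
  expect_length(rc$backbones, 3)
  pooled <- richclub_analysis(co, pooled = TRUE)
  expect_true(pooled$pooled)
})
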