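#' Configuration for the synthetic connectome cohort generator
#'
#' Defaults emulate a three-group clinical DTI study: three groups of 26
#' elderly subjects (converter / nonconverter / control), 90-node
#' streamline-count weighted networks, a hub-bearing population template, a
#' connected set of planted edges whose weights are multiplicatively weakened
#' in the patient groups, log-linear covariate effects of age, sex and
#' education on edge weights, and clinical scores (MMSE, MoCA, AVLT immediate
#' recall) generated as noisy linear functions of each subject's global
#' efficiency with group offsets ordered control > nonconverter > converter.
#'
#' @param n_nodes number of network nodes (default 90).
#' @param group_sizes named integer vector of subjects per group.
#' @param base_density fraction of possible edges present in the population
#'   template (default 0.15).
#' @param weight_scale mean streamline count on template edges (default 50).
#' @param dispersion negative-binomial `size` parameter for subject-level
#'   counts (smaller = more overdispersed; default 8).
#' @param planted_edges either an integer (size of a randomly grown connected
#'   edge set, seeded at a high-degree node) or a two-column matrix of node
#'   pairs; default 150 edges, ~25% of the default template.
#' @param effect_converter,effect_nonconverter multiplicative weight factors
#'   applied to planted edges in each patient group (1 = no effect).
#' @param covariate_betas named numeric vector of log-linear slopes on edge
#'   weights for centered `age`, `sex`, `education`.
#' @param score_slope clinical-score change per cohort standard deviation of
#'   global efficiency (default 5; sized so that within-group correlations
#'   between scores and efficiency are recoverable at n = 26).
#' @param score_noise_sd clinical-score noise standard deviation (default 1.3).
#' @param seed integer seed (default 20190110).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_nodes = 90,
                             group_sizes = c(converter = 26, nonconverter = 26,
                                             control = 26),
                             base_density = 0.15,
                             weight_scale = 50,
                             dispersion = 8,
                             planted_edges = 150,
                             effect_converter = 0.6,
                             effect_nonconverter = 0.8,
                             covariate_betas = c(age = -0.005, sex = 0.05,
                                                 education = 0.005),
                             score_slope = 5,
                             score_noise_sd = 1.3,
                             seed = 20190110) {
  stopifnot(n_nodes >= 3,
            base_density > 0, base_density <= 1,
            weight_scale > 0, dispersion > 0,
            effect_converter > 0, effect_converter <= 1,
            effect_nonconverter > 0, effect_nonconverter <= 1,
            all(group_sizes >= 2), length(group_sizes) >= 2,
            score_noise_sd >= 0)
  if (is.null(names(group_sizes))) {
    stop("group_sizes must be a named vector")
  }
  betas <- c(age = 0, sex = 0, education = 0)
  betas[names(covariate_betas)] <- covariate_betas
  cfg <- list(n_nodes = as.integer(n_nodes), group_sizes = group_sizes,
              base_density = base_density, weight_scale = weight_scale,
              dispersion = dispersion, planted_edges = planted_edges,
              effect_converter = effect_converter,
              effect_nonconverter = effect_nonconverter,
              covariate_betas = betas, score_slope = score_slope,
              score_noise_sd = score_noise_sd, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build the population template network
#'
#' A connected graph at the requested density with a right-skewed degree
#' distribution (a minority of high-degree hub nodes, as seen in empirical
#' connectomes), constructed by preferential attachment of a random spanning
#' tree followed by propensity-weighted sampling of the remaining edges.
#' Template mean weights decay with node-index distance as a crude proxy for
#' the distance dependence of streamline counts, normalized so their mean is
#' `weight_scale`.
#'
#' @param config a [synthetic_config()].
#' @return list with `edges` (two-column matrix, i < j), `mu` (mean weight per
#'   edge), `n_nodes`, and `degree` (template degree per node).
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_nodes
  n_possible <- n * (n - 1) / 2
  n_edges <- round(config$base_density * n_possible)
  if (n_edges < n - 1) {
    stop(sprintf("base_density %.3g too low to connect %d nodes",
                 config$base_density, n))
  }
  with_seed(derive_seed(config$seed, "template"), {
    propensity <- exp(rnorm(n, sd = 0.8))
    order <- sample.int(n)
    # preferential-attachment spanning tree ensures connectivity + hub skew
    edges <- matrix(0L, n_edges, 2)
    for (k in 2:n) {
      v <- order[k]
      prev <- order[seq_len(k - 1L)]
      u <- if (k == 2) prev else sample(prev, 1, prob = propensity[prev])
      edges[k - 1L, ] <- sort(c(u, v))
    }
    n_extra <- n_edges - (n - 1L)
    if (n_extra > 0) {
      idx <- edge_index_map(n)
      key <- (edges[seq_len(n - 1L), 1] - 1) * n + edges[seq_len(n - 1L), 2]
      allkey <- (idx[, 1] - 1) * n + idx[, 2]
      avail <- which(!(allkey %in% key))
      w <- propensity[idx[avail, 1]] * propensity[idx[avail, 2]]
      pick <- sample(avail, n_extra, prob = w)
      edges[n:(n_edges), ] <- idx[pick, , drop = FALSE]
    }
    mu <- config$weight_scale * exp(-3 * abs(edges[, 1] - edges[, 2]) / n)
    mu <- mu * config$weight_scale / mean(mu)
    deg <- tabulate(edges, nbins = n)
    list(edges = edges, mu = mu, n_nodes = n, degree = deg)
  })
}

# grow a connected planted edge set of size k over the template,
# seeded at the highest-degree node
grow_planted_edges <- function(template, k) {
  edges <- template$edges
  if (k > nrow(edges)) stop("planted edge set larger than template")
  start <- which.max(template$degree)
  in_set <- rep(FALSE, nrow(edges))
  nodes <- rep(FALSE, template$n_nodes)
  nodes[start] <- TRUE
  for (step in seq_len(k)) {
    cand <- which(!in_set & (nodes[edges[, 1]] | nodes[edges[, 2]]))
    if (!length(cand)) break
    e <- if (length(cand) == 1L) cand else sample(cand, 1)
    in_set[e] <- TRUE
    nodes[edges[e, 1]] <- TRUE
    nodes[edges[e, 2]] <- TRUE
  }
  edges[in_set, , drop = FALSE]
}

#' Simulate a synthetic three-group connectome cohort
#'
#' Per subject, each template edge weight is drawn from a negative binomial
#' with mean = template mean x group effect (planted edges only) x
#' exp(sum of covariate beta x centered covariate). Covariates follow the
#' demographic structure of an elderly memory-clinic cohort: age uniform on
#' 50-78 years, sex balanced binary, education uniform on 0-20 years.
#' Clinical scores are linear in the subject's realized global efficiency
#' plus noise, with group offsets ordered control > nonconverter > converter.
#'
#' @param config a [synthetic_config()].
#' @return a `cohort` object with a `truth` element recording the planted
#'   edges, effects, covariate betas and per-subject global efficiency.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  template <- make_template(config)
  n <- config$n_nodes
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_sub <- length(groups)
  edges <- template$edges
  eidx <- cbind(edges[, 1], edges[, 2])

  with_seed(derive_seed(config$seed, "cohort"), {
    planted <- if (is.matrix(config$planted_edges)) {
      config$planted_edges
    } else {
      grow_planted_edges(template, as.integer(config$planted_edges))
    }
    pkey <- (planted[, 1] - 1) * n + planted[, 2]
    ekey <- (edges[, 1] - 1) * n + edges[, 2]
    is_planted <- ekey %in% pkey
    if (!all(pkey %in% ekey)) stop("planted edges must lie in the template")

    age <- runif(n_sub, 50, 78)
    sex <- unlist(lapply(config$group_sizes, function(g) {
      s <- rep(c(0L, 1L), length.out = g)
      sample(s)
    }), use.names = FALSE)
    education <- runif(n_sub, 0, 20)
    betas <- config$covariate_betas
    cov_mult <- exp(betas["age"] * (age - 64) + betas["sex"] * (sex - 0.5) +
                    betas["education"] * (education - 10))

    effect_of <- c(converter = config$effect_converter,
                   nonconverter = config$effect_nonconverter)
    matrices <- vector("list", n_sub)
    eglob <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      eff <- if (groups[s] %in% names(effect_of)) effect_of[[groups[s]]] else 1
      mu_s <- template$mu * ifelse(is_planted, eff, 1) * cov_mult[s]
      w <- rnbinom(length(mu_s), size = config$dispersion, mu = mu_s)
      m <- matrix(0, n, n)
      m[eidx] <- w
      m[eidx[, c(2, 1)]] <- w
      matrices[[s]] <- m
      eglob[s] <- global_efficiency(m)
    }
    ids <- sprintf("sub%03d", seq_len(n_sub))
    names(matrices) <- ids

    z <- if (sd(eglob) > 0) (eglob - mean(eglob)) / sd(eglob) else rep(0, n_sub)
    score_spec <- list(
      MMSE    = c(base = 26, converter = -2.9, nonconverter = -0.7, control = 2.0),
      MoCA    = c(base = 21.5, converter = -3.9, nonconverter = -0.9, control = 5.0),
      AVLT_IR = c(base = 6.6, converter = -1.8, nonconverter = -0.8, control = 2.7))
    scores <- lapply(score_spec, function(sp) {
      off <- ifelse(groups %in% names(sp), sp[groups], 0)
      sp[["base"]] + off + config$score_slope * z +
        rnorm(n_sub, sd = config$score_noise_sd)
    })

    man <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                      education = education, stringsAsFactors = FALSE)
    for (nm in names(scores)) man[[nm]] <- scores[[nm]]

    truth <- list(planted_edges = planted,
                  effect_converter = config$effect_converter,
                  effect_nonconverter = config$effect_nonconverter,
                  covariate_betas = betas,
                  template = template,
                  global_efficiency = setNames(eglob, ids))
    new_cohort(manifest = man, matrices = matrices, truth = truth)
  })
}
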