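simple_tables <- function() {
  substances <- tibble::tibble(
    substance_id = c("S1", "S2", "S3", "S4"),
    group = c("GA", "GA", "GB", "GB"),
    formulation = "extract",
    excluded = c(FALSE, FALSE, FALSE, TRUE)
  )
  endpoints <- tibble::tibble(
    endpoint_id = c("E01", "E02", "C01"),
    direction = "increase",
    is_counter_screen = c(FALSE, FALSE, TRUE),
    paired_primary = c(NA, NA, "E01")
  )
  calls <- dplyr::bind_rows(lapply(substances$substance_id, function(s) {
    dplyr::bind_rows(
      make_call(s, "E01",
        label = if (s == "S1") "active" else "inactive",
        pod = 10, wauc = 0.4
      ),
      make_call(s, "E02",
        label = if (s %in% c("S1", "S2")) "active" else "inactive",
        pod = 0.1, wauc = 0.2
      ),
      make_call(s, "C01", label = "inactive")
    )
  }))
  list(substances = substances, endpoints = endpoints, calls = calls)
}

test_that("profile matrices impute non-active cells and drop exclusions", {
  tt <- simple_tables()
  mat <- build_matrices(tt$calls, tt$substances, tt$endpoints,
    imputation_pod = 1000
  )
  # excluded substance dropped
  expect_equal(mat$substances, c("S1", "S2", "S3"))
  # POD matrix covers primary endpoints only; wAUC covers all readouts
  expect_equal(mat$endpoints_pod, c("E01", "E02"))
  expect_equal(mat$endpoints_wauc, c("C01", "E01", "E02"))
  # active cell: log10 of the median POD
  expect_equal(mat$log10_pod["S1", "E01"], 1)
  expect_equal(mat$log10_pod["S1", "E02"], -1)
  # inactive cell: log10 of the 1000 ug/mL imputation POD = 3
  expect_equal(mat$log10_pod["S3", "E01"], 3)
  # wAUC: median for actives, 0 otherwise
  expect_equal(mat$wauc["S1", "E01"], 0.4)
  expect_equal(mat$wauc["S3", "E01"], 0)

  # an inconclusive call is imputed exactly like an inactive one
  calls2 <- tt$calls
  calls2$label[calls2$substance_id == "S2" & calls2$endpoint_id == "E02"] <-
    "inconclusive"
  mat2 <- build_matrices(calls2, tt$substances, tt$endpoints)
  expect_equal(mat2$log10_pod["S2", "E02"], 3)
  expect_equal(mat2$wauc["S2", "E02"], 0)

  expect_error(
    build_matrices(tt$calls[-1, ], tt$substances, tt$endpoints),
    "missing call"
  )
})

test_that("heatmap clustering is Euclidean average-linkage with stable ties", {
  m <- matrix(c(0, 0, 0, 0, 3, 4),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("x", "y"))
  )
  cl <- cluster_orders(m)
  # identical rows merge first at height 0; average linkage then merges
  # the pair with c at distance 5
  expect_equal(cl$row_tree$height, c(0, 5))
  first <- cl$row_tree$merge[1, ]
  expect_setequal(first, c(-1, -2))
  # single-row matrix: trivial order, no tree
  cl1 <- cluster_orders(m[1, , drop = FALSE])
  expect_equal(cl1$row_order, "a")
  expect_null(cl1$row_tree)
})

test_that("pairwise correlation applies the qHTS assignment rules", {
  w <- rbind(
    S1 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    S2 = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
    S3 = c(0, 0, 0, 0, 0, 0),
    S4 = c(0, 0, 0, 0, 0, 0),
    S5 = c(0.2, 0.4, 0.5, 0.7, 0.8, 0.9)
  )
  corr <- pairwise_correlation(w)
  # anticorrelated pair (raw rho = -1) assigned 0
  expect_equal(corr["S1", "S2"], 0)
  # both all-zero: 1; exactly one all-zero: 0
  expect_equal(corr["S3", "S4"], 1)
  expect_equal(corr["S1", "S3"], 0)
  # monotone pair keeps its Spearman rho of 1
  expect_equal(corr["S1", "S5"], 1)
  expect_true(isSymmetric(corr))
  expect_true(all(diag(corr) == 1))
  expect_true(all(corr >= 0 & corr <= 1))
})

test_that("correlation matrix stays symmetric in [0,1] on simulated studies", {
  study <- generate_study(tiny_design(seed = 21))
  res <- suppressWarnings(run_pipeline(
    study$wells, study$substances, study$endpoints,
    config = utils::modifyList(default_config(), list(tsne_iterations = 50))
  ))
  corr <- res$correlation
  expect_true(isSymmetric(unname(corr)))
  expect_true(all(corr >= 0 & corr <= 1))
  expect_true(all(diag(corr) == 1))
})

test_that("group correlation curves pair within groups and against most active lots", {
  corr <- matrix(0.5, 7, 7)
  diag(corr) <- 1
  ids <- c("A1", "A2", "A3", "B1", "B2", "C1", "C2")
  dimnames(corr) <- list(ids, ids)
  corr["A1", "A2"] <- corr["A2", "A1"] <- 0.9
  groups <- stats::setNames(c("GA", "GA", "GA", "GB", "GB", "GC", "GC"), ids)
  activity <- tibble::tibble(
    substance_id = ids,
    n_active = c(3, 1, 1, 5, 0, 2, 2),
    sum_abs_wauc = c(1, 1, 1, 2, 0, 0.5, 0.9)
  )
  out <- group_correlation_curves(corr, groups, activity, min_group_size = 3)
  # only GA qualifies (3 members): C(3,2) = 3 within pairs
  expect_equal(unique(out$group), "GA")
  within <- out[out$type == "within", ]
  expect_equal(nrow(within), 3)
  expect_setequal(within$value, c(0.9, 0.5, 0.5))
  # between: each of the 3 members vs most active lot of GB (B1) and of
  # GC (C2, tie on n_active broken by larger total |wAUC|)
  between <- out[out$type == "between", ]
  expect_equal(nrow(between), 6)
  expect_setequal(unique(between$other_group), c("GB", "GC"))
  # cumulative fractions rise to 1 within each distribution
  expect_true(all(tapply(out$cum_frac, paste(out$group, out$type), max) == 1))

  expect_warning(
    group_correlation_curves(corr, groups, activity, min_group_size = 4),
    "no group"
  )
})

test_that("endpoint enrichment reproduces the hand-computed two-group F", {
  mat <- structure(
    list(
      log10_pod = matrix(c(1, 2, 3, 4),
        ncol = 1,
        dimnames = list(c("S1", "S2", "S3", "S4"), "E01")
      ),
      substances = c("S1", "S2", "S3", "S4"), endpoints_pod = "E01"
    ),
    class = "profile_matrices"
  )
  groups <- stats::setNames(c("GA", "GA", "GB", "GB"), mat$substances)
  res <- endpoint_enrichment(mat, groups)
  # SSB = 4 (df 1), SSW = 1 (df 2) -> F = 8
  expect_equal(res$f_value_1, 8)
  expect_equal(res$rank, 1)

  # all values identical: degenerate, ranked last
  mat$log10_pod <- cbind(mat$log10_pod,
    E02 = rep(3, 4), E03 = c(1, 1, 3, 3)
  )
  res2 <- endpoint_enrichment(mat, groups)
  expect_equal(res2$f_value_1[res2$endpoint_id == "E01"], 8)
  expect_true(is.na(res2$f_value_1[res2$endpoint_id == "E02"]))
  expect_match(res2$flag[res2$endpoint_id == "E02"], "degenerate")
  expect_equal(res2$rank[res2$endpoint_id == "E02"], 3)
  # zero within-group variance with real separation: +Inf, ranked first
  expect_equal(res2$f_value_1[res2$endpoint_id == "E03"], Inf)
  expect_equal(res2$rank[res2$endpoint_id == "E03"], 1)
})

test_that("in-package F agrees with the reference one-way ANOVA", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    ng <- sample(2:6, k, replace = TRUE)
    g <- rep(paste0("G", seq_len(k)), times = ng)
    v <- stats::rnorm(length(g), mean = as.integer(factor(g)))
    mat <- structure(
      list(
        log10_pod = matrix(v,
          ncol = 1,
          dimnames = list(paste0("S", seq_along(v)), "E01")
        ),
        substances = paste0("S", seq_along(v)), endpoints_pod = "E01"
      ),
      class = "profile_matrices"
    )
    groups <- stats::setNames(g, mat$substances)
    mine <- endpoint_enrichment(mat, groups)$f_value_1
    ref <- stats::oneway.test(v ~ g, var.equal = TRUE)$statistic
    expect_lt(abs(mine - unname(ref)), 1e-10)
  }
})

test_that("the F-ratio compares fine against coarse groupings", {
  v <- c(1, 1.1, 4, 4.1, 1, 1.2, 3.9, 4.2)
  subs <- paste0("S", 1:8)
  mat <- structure(
    list(
      log10_pod = matrix(v, ncol = 1, dimnames = list(subs, "E01")),
      substances = subs, endpoints_pod = "E01"
    ),
    class = "profile_matrices"
  )
  coarse <- stats::setNames(rep(c("GA", "GB"), each = 4), subs)
  fine <- stats::setNames(
    rep(c("GA/lo", "GA/hi", "GB/lo", "GB/hi"), each = 2), subs
  )
  res <- endpoint_enrichment(mat, coarse, fine)
  expect_true(is.finite(res$f_value_1) && is.finite(res$f_value_2))
  expect_equal(res$f_ratio, res$f_value_2 / res$f_value_1)
  expect_gt(res$f_ratio, 1)
})

test_that("substance ranking follows the three scenarios with dense ranks", {
  tt <- simple_tables()
  mat <- build_matrices(tt$calls, tt$substances, tt$endpoints)
  rk <- rank_substances(mat, tt$calls, scheme = "n_active")
  r <- function(s) rk[rk$substance_id == s, ]
  expect_equal(r("S1")$n_active, 2)
  expect_equal(r("S2")$n_active, 1)
  expect_equal(r("S3")$n_active, 0)
  # most potent POD among actives; imputation POD when active nowhere
  expect_equal(r("S1")$min_pod, 0.1)
  expect_equal(r("S3")$min_pod, 1000)
  # dense ranks, rank 1 most active
  expect_equal(r("S1")$rank, 1)
  expect_equal(r("S2")$rank, 2)
  expect_equal(r("S3")$rank, 3)
})

test_that("ranking schemes carry their stated invariances", {
  study <- generate_study(tiny_design(seed = 31))
  norm <- normalize_wells(study$wells, study$endpoints)
  fit <- fit_curves(norm)
  calls <- call_study(fit$metrics)
  mat <- build_matrices(calls, study$substances, study$endpoints)
  base <- rank_substances(mat, calls)

  # n_active invariant under monotone rescaling of wAUC
  mat2 <- mat
  mat2$wauc <- mat$wauc^3
  resc <- rank_substances(mat2, calls)
  expect_equal(resc$rank_n_active, base$rank_n_active)

  # sum_z_wauc invariant under affine per-endpoint rescaling of wAUC
  mat3 <- mat
  scale <- stats::setNames(
    stats::runif(ncol(mat$wauc), 0.5, 2),
    colnames(mat$wauc)
  )
  mat3$wauc <- sweep(mat$wauc, 2, scale[colnames(mat$wauc)], `*`)
  aff <- rank_substances(mat3, calls)
  expect_equal(aff$rank_sum_z_wauc, base$rank_sum_z_wauc)
  expect_equal(aff$sum_z_wauc, base$sum_z_wauc, tolerance = 1e-10)
})

test_that("a group-specific potent endpoint attains the top F rank", {
  design <- tiny_design(seed = 51, noise_sd = 3, active_rate = 0)
  study <- generate_study(design)
  # make group G01 (and only it) potently active in endpoint E01
  tr <- study$truths
  g1 <- study$substances$substance_id[study$substances$group == "G01"]
  sel <- tr$substance_id %in% g1 & tr$endpoint_id == "E01"
  tr$active_true[sel] <- TRUE
  tr$top[sel] <- 90
  tr$ec50_true[sel] <- 1
  tr$hill_coefficient[sel] <- 1.5
  study$truths <- tr
  set.seed(99)
  wells <- simulate_wells(design, tr, study$substances, study$endpoints)
  norm <- normalize_wells(wells, study$endpoints)
  calls <- call_study(fit_curves(norm)$metrics)
  mat <- build_matrices(calls, study$substances, study$endpoints)
  res <- endpoint_enrichment(mat, mat$groups)
  expect_equal(res$endpoint_id[res$rank == 1], "E01")
})

test_that("constituent-amplified studies yield F-ratio > 1 on amplified endpoints", {
  design <- noiseless_design(
    constituent_ec50_factor = 0.05, lot_variability = 0.02,
    active_rate = 0.5, seed = 71
  )
  study <- generate_study(design)
  norm <- normalize_wells(study$wells, study$endpoints)
  calls <- call_study(fit_curves(norm)$metrics)
  mat <- build_matrices(calls, study$substances, study$endpoints)
  fine <- stats::setNames(
    paste(study$substances$group, study$substances$formulation, sep = "/"),
    study$substances$substance_id
  )
  res <- endpoint_enrichment(mat, mat$groups, fine)
  # endpoints carrying an active (hence constituent-amplified) truth
  amplified <- unique(study$truths$endpoint_id[study$truths$active_true])
  amplified <- intersect(amplified, mat$endpoints_pod)
  got <- res[res$endpoint_id %in% amplified & is.finite(res$f_ratio), ]
  expect_gt(nrow(got), 0)
  expect_true(all(got$f_ratio > 1))
})

test_that("t-SNE embedding is shaped, seeded and groups identical profiles", {
  study <- generate_study(tiny_design(seed = 61))
  res <- suppressWarnings(run_pipeline(
    study$wells, study$substances, study$endpoints,
    config = utils::modifyList(default_config(), list(tsne_iterations = 600))
  ))
  emb <- res$embedding
  expect_equal(nrow(emb), length(res$matrices$substances))
  expect_equal(names(emb), c("substance_id", "tsne1", "tsne2"))

  # same seed: identical coordinates
  emb2 <- suppressWarnings(embed_2d(res$matrices, iterations = 600, seed = 1))
  emb3 <- suppressWarnings(embed_2d(res$matrices, iterations = 600, seed = 1))
  expect_identical(emb2, emb3)

  # substances with identical wAUC rows embed closer than the 5th
  # percentile of pairwise distances
  mat <- res$matrices
  mat$wauc["G01_L2", ] <- mat$wauc["G01_L1", ]
  emb4 <- suppressWarnings(embed_2d(mat, iterations = 600, seed = 3))
  xy <- as.matrix(emb4[, c("tsne1", "tsne2")])
  rownames(xy) <- emb4$substance_id
  dd <- as.matrix(stats::dist(xy))
  twin <- dd["G01_L1", "G01_L2"]
  expect_lte(twin, stats::quantile(dd[upper.tri(dd)], 0.05))

  small <- mat
  small$wauc <- mat$wauc[1:3, ]
  expect_error(embed_2d(small), "at least 4")
})
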