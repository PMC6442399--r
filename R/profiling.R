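#' Build the substances x endpoints profile matrices
#'
#' Assembles the two matrices all downstream analytics run on:
#' * `log10_pod` over the primary endpoints -- active cells carry
#'   log10(median POD); inactive and inconclusive cells are imputed with
#'   log10 of `imputation_pod` (default 1000 ug/mL, i.e. 3);
#' * `wauc` over all assay readouts including counter screens -- median
#'   wAUC for active cells, 0 otherwise.
#'
#' Substances flagged as excluded (e.g. autofluorescence) are dropped.
#'
#' @param calls Call table from [call_study()] (after any flagging).
#' @param substances Substance table with `substance_id`, `group`,
#'   `excluded`.
#' @param endpoints Endpoint table with `endpoint_id`,
#'   `is_counter_screen`.
#' @param imputation_pod POD in ug/mL imputed for non-active cells.
#' @return A `profile_matrices` list: `log10_pod`, `wauc`, `substances`,
#'   `endpoints_pod`, `endpoints_wauc`, `groups` (named character
#'   vector), `imputation_pod`.
#' @export
build_matrices <- function(calls, substances, endpoints,
                           imputation_pod = 1000) {
  keep <- substances$substance_id[!substances$excluded]
  calls <- calls[calls$substance_id %in% keep, ]
  subs <- sort(unique(keep))
  eps_all <- sort(unique(endpoints$endpoint_id))
  eps_primary <- sort(endpoints$endpoint_id[!endpoints$is_counter_screen])

  want <- tidyr::expand_grid(substance_id = subs, endpoint_id = eps_all)
  have <- paste(calls$substance_id, calls$endpoint_id)
  missing <- want[!paste(want$substance_id, want$endpoint_id) %in% have, ]
  if (nrow(missing) > 0) {
    stop(
      "integrity error: missing call(s) for ",
      paste(utils::head(
        paste(missing$substance_id, missing$endpoint_id, sep = " x "), 5
      ), collapse = ", "),
      call. = FALSE
    )
  }

  cell <- function(sub, ep) match(paste(sub, ep), have)
  grid_pod <- tidyr::expand_grid(s = subs, e = eps_primary)
  idx <- cell(grid_pod$s, grid_pod$e)
  active <- calls$label[idx] == "active"
  pod_vals <- ifelse(active & !is.na(calls$median_pod[idx]),
    log10(calls$median_pod[idx]), log10(imputation_pod)
  )
  log10_pod <- matrix(pod_vals,
    nrow = length(subs), ncol = length(eps_primary), byrow = TRUE,
    dimnames = list(subs, eps_primary)
  )

  grid_w <- tidyr::expand_grid(s = subs, e = eps_all)
  idxw <- cell(grid_w$s, grid_w$e)
  w_vals <- ifelse(calls$label[idxw] == "active",
    calls$median_wauc[idxw], 0
  )
  wauc <- matrix(w_vals,
    nrow = length(subs), ncol = length(eps_all), byrow = TRUE,
    dimnames = list(subs, eps_all)
  )

  groups <- stats::setNames(
    substances$group[match(subs, substances$substance_id)], subs
  )
  structure(
    list(
      log10_pod = log10_pod, wauc = wauc, substances = subs,
      endpoints_pod = eps_primary, endpoints_wauc = eps_all,
      groups = groups, imputation_pod = imputation_pod
    ),
    class = "profile_matrices"
  )
}

#' Hierarchical clustering orders for the activity heatmap
#'
#' Agglomerative clustering of heatmap rows and columns using Euclidean
#' distance and the average linkage (UPGMA) criterion. Rows and columns
#' are sorted lexicographically before clustering so tie-breaking is
#' deterministic.
#'
#' @param mat Numeric matrix (e.g. the log10 POD matrix) with row and
#'   column names.
#' @return List with `row_order`, `col_order` (names in display order)
#'   and the `hclust` trees (`NULL` for a single-row/column matrix).
#' @export
cluster_orders <- function(mat) {
  one_axis <- function(m) {
    if (nrow(m) < 2) {
      return(list(order = rownames(m), tree = NULL))
    }
    m <- m[order(rownames(m)), , drop = FALSE]
    tree <- stats::hclust(stats::dist(m, method = "euclidean"),
      method = "average"
    )
    list(order = rownames(m)[tree$order], tree = tree)
  }
  rows <- one_axis(mat)
  cols <- one_axis(t(mat))
  list(
    row_order = rows$order, col_order = cols$order,
    row_tree = rows$tree, col_tree = cols$tree
  )
}

#' Pairwise substance correlation with the qHTS assignment rules
#'
#' Spearman rank correlation between substances' wAUC response vectors
#' over all assay readouts, post-processed by the profile-comparison
#' assignment rules: negative correlations are set to 0; when the rank
#' correlation is undefined because a vector is constant, the pair is
#' assigned 1 if both substances have all-zero responses and 0
#' otherwise. The diagonal is 1.
#'
#' @param x A `profile_matrices` object or a substances x readouts wAUC
#'   matrix.
#' @return Symmetric substance x substance matrix with entries in
#'   `[0, 1]`.
#' @export
pairwise_correlation <- function(x) {
  w <- if (inherits(x, "profile_matrices")) x$wauc else x
  rho <- suppressWarnings(stats::cor(t(w), method = "spearman"))
  all_zero <- rowSums(w != 0) == 0
  und <- which(is.na(rho), arr.ind = TRUE)
  if (nrow(und) > 0) {
    rho[und] <- ifelse(all_zero[und[, 1]] & all_zero[und[, 2]], 1, 0)
  }
  rho[rho < 0] <- 0
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(w), rownames(w))
  rho
}

#' Within- and between-group correlation distributions
#'
#' For every botanical group with at least `min_group_size` lots:
#' * *within* -- the correlations of all unordered pairs inside the
#'   group;
#' * *between* -- the correlations of each group member with the most
#'   active lot of every other group (most active by number of active
#'   primary endpoints, ties broken by larger total |wAUC|).
#'
#' Values are returned sorted with cumulative fractions per group and
#' distribution type, ready for cumulative-distribution plotting.
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param groups Named character vector mapping substance to group.
#' @param activity Ranking table from [rank_substances()] (used to pick
#'   each group's most active lot).
#' @param min_group_size Minimum lots per qualifying group (default 3).
#' @return Tibble with `group`, `type` (within/between), `other_group`,
#'   `value`, `cum_frac`.
#' @export
group_correlation_curves <- function(corr, groups, activity,
                                     min_group_size = 3) {
  groups <- groups[rownames(corr)]
  sizes <- table(groups)
  qualifying <- names(sizes)[sizes >= min_group_size]
  if (length(qualifying) == 0) {
    warning("no group has >= ", min_group_size, " members")
    return(tibble::tibble(
      group = character(), type = character(),
      other_group = character(), value = numeric(), cum_frac = numeric()
    ))
  }
  most_active <- vapply(unique(groups), function(g) {
    members <- names(groups)[groups == g]
    a <- activity[activity$substance_id %in% members, ]
    a <- a[order(-a$n_active, -a$sum_abs_wauc, a$substance_id), ]
    a$substance_id[1]
  }, character(1))

  rows <- lapply(qualifying, function(g) {
    members <- names(groups)[groups == g]
    pairs <- utils::combn(members, 2)
    within <- tibble::tibble(
      group = g, type = "within", other_group = NA_character_,
      value = corr[cbind(pairs[1, ], pairs[2, ])]
    )
    others <- setdiff(unique(groups), g)
    between <- dplyr::bind_rows(lapply(others, function(og) {
      tibble::tibble(
        group = g, type = "between", other_group = og,
        value = corr[members, most_active[og]]
      )
    }))
    dplyr::bind_rows(within, between)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$group, .data$type)
  out <- dplyr::arrange(out, .data$value, .by_group = TRUE)
  out <- dplyr::mutate(out, cum_frac = seq_len(dplyr::n()) / dplyr::n())
  dplyr::ungroup(out)
}

# Classical one-way ANOVA F from sums of squares, with explicit handling
# of the degenerate cases (zero within-group variance; all values equal).
oneway_f <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]
  groups <- groups[ok]
  n <- length(values)
  k <- length(unique(groups))
  if (k < 2 || n <= k) {
    return(list(f = NA_real_, flag = "degenerate"))
  }
  grand <- mean(values)
  mg <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ssb <- sum(ng * (mg - grand)^2)
  ssw <- sum((values - mg[groups])^2)
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(f = NA_real_, flag = "degenerate"))
    }
    return(list(f = Inf, flag = "zero_within_variance"))
  }
  list(f = (ssb / (k - 1)) / (ssw / (n - k)), flag = "")
}

#' Rank endpoints by group enrichment of activity
#'
#' For each endpoint, a one-way ANOVA F-statistic is computed on the
#' imputed log10 POD values over the coarse grouping (botanical groups):
#' a higher F marks activities that are more consistent within certain
#' groups. When a fine grouping is also given (e.g. splitting extracts
#' from their purported active constituents), a second F is computed and
#' the F-ratio `F_fine / F_coarse` ranks the endpoints by how much the
#' finer structure explains; endpoints are otherwise ranked by F.
#' An endpoint with zero within-group variance but non-zero
#' between-group variance is reported as `Inf` and ranked first; an
#' endpoint with no variance at all is flagged degenerate and ranked
#' last.
#'
#' @param matrices A `profile_matrices` object.
#' @param coarse_groups Named vector mapping substance to coarse group.
#' @param fine_groups Optional named vector mapping substance to fine
#'   group.
#' @return Tibble with `endpoint_id`, `f_value_1`, `f_value_2`,
#'   `f_ratio`, `flag`, `rank` (dense, descending by F or F-ratio).
#' @export
endpoint_enrichment <- function(matrices, coarse_groups,
                                fine_groups = NULL) {
  mat <- matrices$log10_pod
  subs <- rownames(mat)
  cg <- coarse_groups[subs]
  sizes <- table(cg)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  res <- lapply(colnames(mat), function(ep) {
    f1 <- oneway_f(mat[, ep], cg)
    f2 <- list(f = NA_real_, flag = "")
    if (!is.null(fine_groups)) {
      fg <- fine_groups[subs]
      keep <- !is.na(fg)
      f2 <- oneway_f(mat[keep, ep], fg[keep])
    }
    tibble::tibble(
      endpoint_id = ep,
      f_value_1 = f1$f,
      f_value_2 = f2$f,
      f_ratio = if (!is.null(fine_groups) && is.finite(f1$f) &&
        !is.na(f2$f) && f1$f > 0) {
        f2$f / f1$f
      } else {
        NA_real_
      },
      flag = paste(c(
        if (nzchar(f1$flag)) paste0("coarse_", f1$flag),
        if (nzchar(f2$flag)) paste0("fine_", f2$flag)
      ), collapse = ";")
    )
  })
  res <- dplyr::bind_rows(res)
  key <- if (is.null(fine_groups)) res$f_value_1 else res$f_ratio
  key[is.na(key)] <- -Inf # degenerate endpoints rank last
  res$rank <- dplyr::dense_rank(dplyr::desc(key))
  dplyr::arrange(res, .data$rank, .data$endpoint_id)
}

#' Rank substances by overall biological activity
#'
#' Three ranking scenarios over the primary endpoints:
#' 1. `n_active` -- number of active endpoint calls (broad activity);
#' 2. `min_pod` -- the most potent POD among the active calls (the
#'    imputation POD when a substance is active nowhere);
#' 3. `sum_z_wauc` -- sum of per-endpoint Z-score-scaled wAUC values
#'    over the active calls, weighting potency and efficacy together.
#'
#' Z-scores are computed per endpoint across the substance set; with
#' `z_active_only = TRUE` (default) the mean and SD are taken over the
#' active cells of that endpoint only. Endpoints whose Z-score is
#' undefined (fewer than 2 contributing cells, or zero variance)
#' contribute 0 and are marked degenerate. Ranks are dense, ties share a
#' rank, rank 1 is the most active (respectively most potent).
#'
#' @param matrices A `profile_matrices` object.
#' @param calls Call table consistent with `matrices`.
#' @param scheme Ranking scheme for the `rank` column.
#' @param z_active_only Whether Z-scaling uses active cells only.
#' @return Tibble with `substance_id`, `n_active`, `min_pod`,
#'   `sum_z_wauc`, `sum_abs_wauc`, `degenerate_z`, per-scheme ranks and
#'   `rank` for the chosen scheme.
#' @export
rank_substances <- function(matrices, calls,
                            scheme = c("n_active", "min_pod", "sum_z_wauc"),
                            z_active_only = TRUE) {
  scheme <- match.arg(scheme)
  subs <- matrices$substances
  eps <- matrices$endpoints_pod
  cl <- calls[calls$substance_id %in% subs & calls$endpoint_id %in% eps, ]
  active_mat <- matrix(FALSE, length(subs), length(eps),
    dimnames = list(subs, eps)
  )
  pod_mat <- matrix(NA_real_, length(subs), length(eps),
    dimnames = list(subs, eps)
  )
  wauc_mat <- matrices$wauc[subs, eps, drop = FALSE]
  active_mat[cbind(cl$substance_id, cl$endpoint_id)] <- cl$label == "active"
  pod_mat[cbind(cl$substance_id, cl$endpoint_id)] <- cl$median_pod

  z_mat <- matrix(0, length(subs), length(eps), dimnames = list(subs, eps))
  degenerate <- rep(FALSE, length(eps))
  for (j in seq_along(eps)) {
    cells <- if (z_active_only) which(active_mat[, j]) else seq_along(subs)
    v <- wauc_mat[cells, j]
    if (length(v) < 2 || stats::sd(v) == 0) {
      degenerate[j] <- TRUE
      next
    }
    z_mat[cells, j] <- (v - mean(v)) / stats::sd(v)
  }

  n_active <- unname(rowSums(active_mat))
  min_pod <- vapply(seq_along(subs), function(i) {
    p <- pod_mat[i, active_mat[i, ]]
    p <- p[!is.na(p)]
    if (length(p) == 0) matrices$imputation_pod else min(p)
  }, numeric(1))
  sum_z <- unname(rowSums(z_mat * active_mat))
  sum_abs <- unname(rowSums(abs(wauc_mat) * active_mat))

  out <- tibble::tibble(
    substance_id = subs,
    n_active = n_active,
    min_pod = min_pod,
    sum_z_wauc = sum_z,
    sum_abs_wauc = sum_abs,
    degenerate_z = any(degenerate),
    rank_n_active = dplyr::dense_rank(dplyr::desc(n_active)),
    rank_min_pod = dplyr::dense_rank(min_pod),
    rank_sum_z_wauc = dplyr::dense_rank(dplyr::desc(sum_z))
  )
  out$rank <- out[[paste0("rank_", scheme)]]
  dplyr::arrange(out, .data$rank, .data$substance_id)
}

#' Two-dimensional t-SNE embedding of activity profiles
#'
#' Embeds substances in 2-D from their wAUC response vectors over all
#' assay readouts. The Euclidean distance matrix is precalculated and
#' fed to t-SNE directly (no PCA preselection); the exact (theta = 0)
#' algorithm is used so that a fixed seed reproduces coordinates
#' bit-for-bit. When the substance set is too small for the requested
#' perplexity (fewer than `3 * perplexity + 2` substances) the
#' perplexity is reduced with a warning.
#'
#' @param matrices A `profile_matrices` object.
#' @param perplexity t-SNE perplexity (default 30).
#' @param iterations Number of gradient iterations (default 5000).
#' @param seed Random seed for the embedding initialization.
#' @return Tibble with `substance_id`, `tsne1`, `tsne2`.
#' @export
embed_2d <- function(matrices, perplexity = 30, iterations = 5000,
                     seed = 1) {
  w <- matrices$wauc
  n <- nrow(w)
  if (n < 4) {
    stop("need at least 4 substances to embed", call. = FALSE)
  }
  if (n < 3 * perplexity + 2) {
    perplexity <- floor((n - 2) / 3)
    warning("perplexity reduced to ", perplexity, " for ", n, " substances")
  }
  d <- as.matrix(stats::dist(w, method = "euclidean"))
  set.seed(seed)
  fit <- Rtsne::Rtsne(d,
    dims = 2, perplexity = perplexity, theta = 0,
    max_iter = iterations, is_distance = TRUE, pca = FALSE,
    verbose = FALSE
  )
  tibble::tibble(
    substance_id = rownames(w),
    tsne1 = fit$Y[, 1],
    tsne2 = fit$Y[, 2]
  )
}
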