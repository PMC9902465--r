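#' CV-stable candidate features
#'
#' Features selected in every outer fold of a nested-CV run: the
#' intersection of the per-fold selected sets. These are the candidates
#' subsequently screened by the group t-test with FDR correction.
#'
#' @param report A `cv_report`.
#' @return Character vector of feature names (possibly empty).
#' @export
stable_candidates <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  Reduce(intersect, report$selected)
}

#' Group two-sample t-tests with FDR correction
#'
#' Two-sided two-sample t-tests (pooled variance by default, Welch by
#' flag) per feature, Benjamini-Hochberg adjusted across the supplied
#' candidate set. Features with zero variance in both groups get p = 1
#' and a flag.
#'
#' @param table A [feature_table()] (or matrix with `labels`).
#' @param labels Labels when `table` is a matrix.
#' @param features Optional character vector restricting the candidate
#'   set (e.g. from [stable_candidates()]).
#' @param alpha FDR threshold for the `significant` column.
#' @param welch Use Welch's unequal-variance test.
#' @return Tibble: feature, t, p, q, direction (`case>control` or
#'   `case<control`), significant, degenerate.
#' @export
group_ttest_fdr <- function(table, labels = NULL, features = NULL,
                            alpha = 0.05, welch = FALSE) {
  if (inherits(table, "feature_table")) {
    x <- table$features
    y <- table$labels
  } else {
    x <- as.matrix(table)
    y <- factor(labels, levels = c("control", "case"))
  }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (min(table(y)) < 2) abort("both groups need at least 2 subjects")
  case <- x[y == "case", , drop = FALSE]
  ctrl <- x[y == "control", , drop = FALSE]
  n1 <- nrow(case)
  n0 <- nrow(ctrl)
  m1 <- colMeans(case)
  m0 <- colMeans(ctrl)
  v1 <- apply(case, 2, var)
  v0 <- apply(ctrl, 2, var)
  degenerate <- v1 == 0 & v0 == 0
  if (welch) {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  t_val <- ifelse(degenerate, 0, (m1 - m0) / se)
  p_val <- ifelse(degenerate, 1, 2 * pt(-abs(t_val), df))
  q_val <- p.adjust(p_val, method = "BH")
  tibble::tibble(
    feature = colnames(x),
    t = unname(t_val), p = unname(p_val), q = unname(q_val),
    direction = unname(ifelse(m1 >= m0, "case>control", "case<control")),
    significant = unname(q_val < alpha),
    degenerate = unname(degenerate)
  )
}

#' Final biomarker reporting rules
#'
#' Applies the per-modality reporting convention: sparse low-rank (SLR)
#' connections are sorted by p and the top 20 kept; SSGSR keeps every
#' significant connection; for the dynamics-based high-order measure each
#' cluster is scored by how many significant cluster-pairs it appears in
#' and the 10 highest-count clusters are kept (ties toward the lower
#' cluster id).
#'
#' @param rows Tibble from [group_ttest_fdr()] for one modality.
#' @param modality `"SLR"`, `"SSGSR"`, `"dHOFC"`, or `"other"` (keep all
#'   significant).
#' @param top_k Override of the per-modality count (20 for SLR, 10
#'   clusters for dHOFC).
#' @return For connection-type modalities, the filtered tibble; for the
#'   dynamic high-order measure, a list with `clusters` (tibble of
#'   cluster, count, rank) and `pairs` (the significant pair rows).
#' @export
rank_and_report <- function(rows, modality = c("SLR", "SSGSR", "dHOFC",
                                               "other"),
                            top_k = NULL) {
  modality <- match.arg(modality)
  sig <- dplyr::filter(rows, .data$significant)
  if (modality == "SLR") {
    k <- top_k %||% 20L
    dplyr::slice_head(dplyr::arrange(sig, .data$p), n = k)
  } else if (modality == "SSGSR" || modality == "other") {
    dplyr::arrange(sig, .data$p)
  } else {
    k <- top_k %||% 10L
    # Feature names look like "dHOFC|C3-C7": count cluster appearances.
    pair_ids <- sub("^[^|]*\\|", "", sig$feature)
    cl <- unlist(strsplit(pair_ids, "-"))
    cl <- as.integer(sub("^C", "", cl))
    counts <- table(cl)
    tab <- tibble::tibble(
      cluster = as.integer(names(counts)),
      count = as.integer(counts)
    )
    tab <- dplyr::arrange(tab, dplyr::desc(.data$count), .data$cluster)
    tab$rank <- seq_len(nrow(tab))
    list(clusters = dplyr::slice_head(tab, n = k), pairs = sig)
  }
}

# 26-connected components of a logical 3D array; returns an integer
# label array (0 = background).
connected_components_26 <- function(mask3d) {
  d <- dim(mask3d)
  labels <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  todo <- which(mask3d)
  next_label <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1L
      x <- rem %% d[1] + 1L
      nb <- sweep(offs, 2, c(x, y, z), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask3d[lin] & labels[lin] == 0L]
      labels[lin] <- next_label
      queue <- c(queue, lin)
    }
  }
  labels
}

voxel_tmap <- function(mat1, mat0) {
  n1 <- ncol(mat1)
  n0 <- ncol(mat0)
  m1 <- rowMeans(mat1)
  m0 <- rowMeans(mat0)
  v1 <- rowSums((mat1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((mat0 - m0)^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_val <- (m1 - m0) / se
  t_val[se == 0] <- 0
  t_val
}

#' Voxel-wise group test with permutation cluster-extent correction
#'
#' Computes a voxel-wise two-sample t-map between the groups' summary
#' maps, thresholds it at the two-tailed `voxel_p` quantile, groups the
#' surviving voxels into 26-connected clusters, and corrects at the
#' cluster level with a permutation null of maximum cluster extents
#' (group labels permuted `n_perm` times). Clusters whose extent exceeds
#' the `1 - cluster_p` null quantile are reported.
#'
#' @param maps_case,maps_control Lists of `voxel_map`s (one per subject)
#'   on a common mask, or V x S matrices of in-mask values.
#' @param mask Required when matrices are supplied.
#' @param voxel_p Voxel-level two-tailed threshold (default 0.001).
#' @param cluster_p Cluster-level threshold (default 0.05).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Permutation seed.
#' @return A list: `clusters` tibble (id, size, peak_t, peak x/y/z, sign,
#'   p_cluster), the `t_map` array, the extent threshold and null
#'   distribution. No suprathreshold voxels gives an empty tibble.
#' @export
voxel_cluster_test <- function(maps_case, maps_control, mask = NULL,
                               voxel_p = 0.001, cluster_p = 0.05,
                               n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  as_vmat <- function(maps) {
    if (is.matrix(maps)) return(maps)
    if (is.null(mask)) mask <<- maps[[1]]$mask
    sapply(maps, function(m) m$values[mask])
  }
  mat1 <- as_vmat(maps_case)
  mat0 <- as_vmat(maps_control)
  if (is.null(mask)) abort("`mask` is required with matrix input")
  n1 <- ncol(mat1)
  n0 <- ncol(mat0)
  df <- n1 + n0 - 2
  t_crit <- qt(1 - voxel_p / 2, df)

  cluster_sizes <- function(t_vec) {
    supra <- abs(t_vec) > t_crit
    if (!any(supra)) return(list(labels = NULL, sizes = integer(0)))
    sup3d <- unmask_map(mask, supra) > 0
    labs <- connected_components_26(sup3d)
    list(labels = labs, sizes = tabulate(labs[labs > 0]))
  }

  t_obs <- voxel_tmap(mat1, mat0)
  obs <- cluster_sizes(t_obs)

  all_mat <- cbind(mat1, mat0)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n1 + n0)
      tb <- voxel_tmap(all_mat[, idx[seq_len(n1)], drop = FALSE],
                       all_mat[, idx[n1 + seq_len(n0)], drop = FALSE])
      sz <- cluster_sizes(tb)$sizes
      if (length(sz) == 0) 0L else max(sz)
    }, integer(1))
  })
  extent_crit <- quantile(null_max, 1 - cluster_p, type = 1, names = FALSE)

  if (length(obs$sizes) == 0) {
    clusters <- tibble::tibble(
      cluster = integer(0), size = integer(0), peak_t = numeric(0),
      x = integer(0), y = integer(0), z = integer(0),
      sign = character(0), p_cluster = numeric(0)
    )
  } else {
    t_map3d <- unmask_map(mask, t_obs)
    rows <- lapply(seq_along(obs$sizes), function(cl) {
      vox <- which(obs$labels == cl)
      peak <- vox[which.max(abs(t_map3d[vox]))]
      coord <- arrayInd(peak, dim(mask))
      tibble::tibble(
        cluster = cl, size = obs$sizes[cl],
        peak_t = t_map3d[peak],
        x = coord[1], y = coord[2], z = coord[3],
        sign = ifelse(t_map3d[peak] > 0, "case>control", "case<control"),
        p_cluster = mean(null_max >= obs$sizes[cl])
      )
    })
    clusters <- dplyr::filter(dplyr::bind_rows(rows),
                              .data$size > extent_crit)
  }
  list(clusters = clusters, t_map = unmask_map(mask, t_obs),
       t_crit = t_crit, extent_crit = extent_crit, null_max = null_max)
}
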