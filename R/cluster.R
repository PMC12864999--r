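#' Nonparametric cluster-based permutation testing
#'
#' Multiple-comparison correction for channel x frequency x time EEG volumes:
#' sample-level statistics (independent t, paired t, or one-way F) are
#' computed per voxel, suprathreshold voxels (sample-level p below
#' `alpha_sample`) are organized into clusters connected through spatial
#' (channel neighbourhood), spectral (+-1 frequency bin) or temporal (+-1 time
#' bin) adjacency, and each cluster's summed statistic is referred to a
#' Monte-Carlo null distribution of maximum cluster statistics obtained by
#' randomly re-drawing the group assignment (or flipping pairs) 4000 times.
#'
#' @name cluster_permutation
NULL

# coerce subject volumes (list of tfr_volume / power_spectrum, or array with
# subject as first dim) into subjects x voxels matrix plus axis descriptors
as_subject_matrix <- function(x) {
  if (is.list(x) && !is.array(x)) {
    first <- x[[1]]
    if (inherits(first, "tfr_volume")) {
      dims <- dim(first$power)
      axes <- list(channels = first$channel_labels, freqs = first$freqs,
                   times = first$times)
      mat <- t(vapply(x, function(v) as.vector(v$power),
                      numeric(prod(dims))))
    } else if (inherits(first, "power_spectrum")) {
      # spectra are 1-time-bin volumes
      dims <- c(dim(first$power), 1L)
      axes <- list(channels = first$channel_labels, freqs = first$freqs,
                   times = 0)
      mat <- t(vapply(x, function(v) as.vector(v$power),
                      numeric(prod(dims))))
    } else stop("unsupported volume type")
  } else if (is.array(x) && length(dim(x)) == 4L) {
    dims <- dim(x)[-1]
    axes <- list(channels = dimnames(x)[[2]], freqs = NULL, times = NULL)
    mat <- matrix(x, dim(x)[1], prod(dims))
  } else stop("expected a list of volumes or a 4-d array (subject first)")
  list(mat = mat, dims = dims, axes = axes)
}

#' Voxel adjacency for a channel x frequency x time volume
#'
#' Builds the compressed (CSR) voxel neighbourhood used by the cluster
#' search: two voxels are adjacent when they share frequency and time on
#' neighbouring channels, or differ by one frequency bin or one time bin on
#' the same channel.
#'
#' @param channel_adjacency logical channels x channels matrix (ordered as
#'   the volume's channel axis).
#' @param n_freq,n_time axis lengths.
#' @return list with 0-based `ptr` and `idx` CSR vectors and `n_voxels`.
#' @export
build_voxel_adjacency <- function(channel_adjacency, n_freq, n_time) {
  nch <- nrow(channel_adjacency)
  V <- nch * n_freq * n_time
  c0 <- rep(seq_len(nch) - 1L, times = n_freq * n_time)
  f0 <- rep(rep(seq_len(n_freq) - 1L, each = nch), times = n_time)
  t0 <- rep(seq_len(n_time) - 1L, each = nch * n_freq)
  vox <- function(c, f, t) c + nch * (f + n_freq * t)
  from <- integer(0); to <- integer(0)
  # frequency adjacency
  sel <- f0 < n_freq - 1L
  a <- vox(c0[sel], f0[sel], t0[sel]); b <- a + nch
  from <- c(from, a, b); to <- c(to, b, a)
  # time adjacency
  sel <- t0 < n_time - 1L
  a <- vox(c0[sel], f0[sel], t0[sel]); b <- a + nch * n_freq
  from <- c(from, a, b); to <- c(to, b, a)
  # channel adjacency (matrix already symmetric: both directions included)
  pairs <- which(channel_adjacency, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ft <- expand.grid(f = seq_len(n_freq) - 1L, t = seq_len(n_time) - 1L)
    a <- outer(pairs[, 1] - 1L, nch * (ft$f + n_freq * ft$t), `+`)
    b <- outer(pairs[, 2] - 1L, nch * (ft$f + n_freq * ft$t), `+`)
    from <- c(from, as.vector(a)); to <- c(to, as.vector(b))
  }
  o <- order(from)
  counts <- tabulate(from + 1L, nbins = V)
  list(ptr = c(0L, cumsum(counts)), idx = as.integer(to[o]), n_voxels = V)
}

#' Sample-level statistic volume
#'
#' Computes the per-voxel statistic and its sample-level p-value across
#' subjects: two-tailed independent-samples t (pooled variance), two-tailed
#' paired t, or upper-tail one-way F over two or more groups.
#'
#' @param group_a,group_b subject volumes: lists of `tfr_volume` /
#'   `power_spectrum` objects or 4-d arrays (subject first). For `kind =
#'   "F"` additional groups can be supplied via `groups`.
#' @param kind `"independent_t"`, `"paired_t"` or `"F"`.
#' @param groups optional list of all groups (overrides `group_a`/`group_b`)
#'   for the F statistic.
#' @return list with `stat` and `p` arrays (channel x freq x time), `df`,
#'   `kind`, and the axis descriptors.
#' @export
samplewise_stat <- function(group_a, group_b = NULL,
                            kind = c("independent_t", "paired_t", "F"),
                            groups = NULL) {
  kind <- match.arg(kind)
  if (is.null(groups)) groups <- list(group_a, group_b)
  parts <- lapply(groups, as_subject_matrix)
  dims <- parts[[1]]$dims
  if (!all(vapply(parts, function(p) identical(p$dims, dims), logical(1))))
    stop("group volumes must share axes")
  mats <- lapply(parts, `[[`, "mat")
  ns <- vapply(mats, nrow, integer(1))
  if (any(ns < 2)) stop("need at least 2 subjects per group")
  if (kind == "paired_t" && length(unique(ns)) != 1)
    stop("paired statistic requires equal subject counts")
  if (kind == "independent_t" || kind == "paired_t") {
    if (length(mats) != 2) stop("t statistics compare exactly 2 groups")
    if (kind == "independent_t") {
      df <- sum(ns) - 2
      mA <- colMeans(mats[[1]]); mB <- colMeans(mats[[2]])
      vA <- apply(mats[[1]], 2, var); vB <- apply(mats[[2]], 2, var)
      sp2 <- ((ns[1] - 1) * vA + (ns[2] - 1) * vB) / df
      tt <- (mA - mB) / sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
    } else {
      D <- mats[[1]] - mats[[2]]
      df <- ns[1] - 1
      tt <- colMeans(D) / sqrt(apply(D, 2, var) / ns[1])
    }
    p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    stat <- tt
  } else {
    k <- length(mats)
    if (k < 2) stop("F requires at least 2 groups")
    ntot <- sum(ns)
    X <- do.call(rbind, mats)
    grand <- colMeans(X)
    ssb <- Reduce(`+`, lapply(mats, function(m)
      nrow(m) * (colMeans(m) - grand)^2))
    sst <- colSums(sweep(X, 2, grand)^2)
    ssw <- sst - ssb
    df <- c(k - 1, ntot - k)
    stat <- (ssb / df[1]) / (ssw / df[2])
    p <- pf(stat, df[1], df[2], lower.tail = FALSE)
  }
  list(stat = array(stat, dims), p = array(p, dims), df = df, kind = kind,
       axes = parts[[1]]$axes, dims = dims)
}

# internal: cluster the observed volume; returns list of clusters
observed_clusters <- function(stat, p, alpha_sample, vadj, kind, axes) {
  pv <- as.vector(p); sv <- as.vector(stat)
  ok <- is.finite(pv) & is.finite(sv)     # degenerate voxels (0/0) never seed
  supra_pos <- ok & pv < alpha_sample & sv > 0
  supra_neg <- ok & pv < alpha_sample & sv < 0
  if (kind == "F") supra_neg[] <- FALSE
  res <- list()
  for (pol in c("positive", "negative")) {
    supra <- if (pol == "positive") supra_pos else supra_neg
    if (!any(supra)) next
    lab <- cpp_label_clusters(supra, vadj$ptr, vadj$idx)
    for (id in seq_len(max(lab))) {
      vox <- which(lab == id)
      dims <- dim(stat)
      ai <- arrayInd(vox, dims)
      members <- data.frame(channel = ai[, 1], freq = ai[, 2], time = ai[, 3])
      if (!is.null(axes$channels))
        members$channel_label <- axes$channels[ai[, 1]]
      if (!is.null(axes$freqs)) members$freq_hz <- axes$freqs[ai[, 2]]
      if (!is.null(axes$times)) members$time_s <- axes$times[ai[, 3]]
      res[[length(res) + 1L]] <- structure(list(
        members = members, polarity = if (kind == "F") "single_sided" else pol,
        cluster_stat = sum(stat[vox]), p_value = NA_real_,
        significant = NA), class = "cluster_result")
    }
  }
  res
}

#' Form clusters from a statistic volume (without Monte-Carlo scoring)
#'
#' Partitions suprathreshold voxels (sample-level `p < alpha_sample`,
#' strictly; voxels with p exactly at the threshold are excluded) into
#' connected components, separately per polarity for t statistics. Any
#' suprathreshold voxel can seed a cluster (no minimum size).
#'
#' @param stat,p statistic and p-value arrays (channel x freq x time), e.g.
#'   from [samplewise_stat()].
#' @param alpha_sample sample-level threshold (default 0.05).
#' @param neighbours a `neighbour_graph` ([channel_neighbours()]).
#' @param channel_labels labels of the volume's channel axis (to index the
#'   neighbour graph); taken from `dimnames(stat)[[1]]` when present.
#' @param kind statistic kind (polarity handling; default `"independent_t"`).
#' @param axes optional axis descriptor list (`channels`, `freqs`, `times`).
#' @return list of `cluster_result` objects with unscored p-values.
#' @export
form_clusters <- function(stat, p, alpha_sample = 0.05, neighbours,
                          channel_labels = dimnames(stat)[[1]],
                          kind = "independent_t", axes = NULL) {
  stopifnot(identical(dim(stat), dim(p)))
  ch_adj <- subset_channel_adjacency(neighbours, channel_labels, dim(stat)[1])
  vadj <- build_voxel_adjacency(ch_adj, dim(stat)[2], dim(stat)[3])
  if (is.null(axes)) axes <- list(channels = channel_labels)
  observed_clusters(stat, p, alpha_sample, vadj, kind, axes)
}

subset_channel_adjacency <- function(neighbours, channel_labels, nch) {
  if (is.null(neighbours)) return(matrix(FALSE, nch, nch))
  stopifnot(inherits(neighbours, "neighbour_graph"))
  if (is.null(channel_labels)) {
    if (nrow(neighbours$adjacency) != nch)
      stop("channel_labels required to align the neighbour graph")
    return(neighbours$adjacency)
  }
  ix <- match(channel_labels, neighbours$labels)
  if (anyNA(ix)) stop("channels missing from the neighbour graph: ",
                      paste(channel_labels[is.na(ix)], collapse = ", "))
  neighbours$adjacency[ix, ix, drop = FALSE]
}

# internal: null distribution of max cluster statistics
null_max_distribution <- function(mats, kind, n_rand, thr, vadj, block = 250L) {
  ns <- vapply(mats, nrow, integer(1))
  ntot <- sum(ns)
  X <- do.call(rbind, mats)
  X2 <- X^2
  V <- ncol(X)
  null_pos <- numeric(n_rand)
  null_neg <- numeric(n_rand)
  done <- 0L
  k <- length(mats)
  Stot <- colSums(X); S2tot <- colSums(X2)
  while (done < n_rand) {
    nb <- min(block, n_rand - done)
    if (kind == "paired_t") {
      D <- mats[[1]] - mats[[2]]
      S <- matrix(sample(c(-1, 1), nb * ns[1], replace = TRUE), nb, ns[1])
      M <- (S %*% D) / ns[1]
      d2 <- colSums(D^2)
      v <- sweep(-(ns[1] * M^2), 2, d2, `+`) / (ns[1] - 1)
      tmat <- M / sqrt(v / ns[1])
      stats <- tmat
      thr_pos <- thr; thr_neg <- -thr
    } else if (kind == "independent_t") {
      L <- matrix(0, nb, ntot)
      for (r in seq_len(nb))
        L[r, sample.int(ntot, ns[1])] <- 1
      SA <- L %*% X; SA2 <- L %*% X2
      SB <- sweep(-SA, 2, Stot, `+`)
      SB2 <- sweep(-SA2, 2, S2tot, `+`)
      vA <- SA2 - SA^2 / ns[1]
      vB <- SB2 - SB^2 / ns[2]
      sp2 <- (vA + vB) / (ntot - 2)
      stats <- (SA / ns[1] - SB / ns[2]) /
        sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
      thr_pos <- thr; thr_neg <- -thr
    } else {                               # F
      grand <- Stot / ntot
      sst <- S2tot - ntot * grand^2
      ssb <- matrix(0, nb, V)
      perms <- vapply(seq_len(nb), function(r) sample.int(ntot),
                      integer(ntot))
      offs <- c(0L, cumsum(ns))
      for (g in seq_len(k)) {
        Lg <- matrix(0, nb, ntot)
        rows <- rep(seq_len(nb), each = ns[g])
        cols <- as.vector(perms[(offs[g] + 1L):offs[g + 1L], , drop = FALSE])
        Lg[cbind(rows, cols)] <- 1
        mg <- (Lg %*% X) / ns[g]
        ssb <- ssb + ns[g] * sweep(mg, 2, grand)^2
      }
      ssw <- sweep(-ssb, 2, sst, `+`)
      stats <- (ssb / (k - 1)) / (ssw / (ntot - k))
      thr_pos <- thr; thr_neg <- -Inf
    }
    mm <- cpp_max_cluster_sums(stats, thr_pos, thr_neg, vadj$ptr, vadj$idx)
    null_pos[(done + 1):(done + nb)] <- mm[, 1]
    null_neg[(done + 1):(done + nb)] <- mm[, 2]
    done <- done + nb
  }
  list(pos = null_pos, neg = null_neg)
}

#' Cluster-based permutation test
#'
#' Runs the full procedure: observed sample-level statistics, cluster
#' formation, and a Monte-Carlo null distribution built by pooling the
#' subjects and re-drawing group labels (respecting group sizes; the paired
#' variant randomly flips pairs), recording per randomization the maximum
#' cluster statistic separately for positive and negative clusters. The
#' observed data is included in the null denominator, `p = (b + 1)/(R + 1)`,
#' so p is never exactly 0. A cluster is significant when its Monte-Carlo p
#' falls below `alpha_cluster` (default 0.025 per tail for t statistics,
#' 0.05 for the single-sided F).
#'
#' @inheritParams samplewise_stat
#' @param n_randomizations Monte-Carlo randomizations (default 4000).
#' @param alpha_sample sample-level threshold for cluster formation.
#' @param alpha_cluster cluster-level significance threshold.
#' @param neighbours a `neighbour_graph`; `NULL` for no spatial adjacency
#'   (channels treated as mutually non-adjacent).
#' @param seed optional integer seed (bit-reproducible results).
#' @param label_matrix optional matrix of pre-specified group-A index sets
#'   (rows = randomizations; independent t only), e.g. the exhaustive
#'   enumeration of all splits for oracle checks.
#' @return object of class `cluster_test`: list with `clusters` (scored
#'   `cluster_result`s), `stat`, `p`, `null_max_pos`, `null_max_neg`,
#'   `n_randomizations`, `alpha_sample`, `alpha_cluster`, `kind`, `df`.
#' @export
permutation_test <- function(group_a, group_b = NULL,
                             kind = c("independent_t", "paired_t", "F"),
                             n_randomizations = 4000,
                             alpha_sample = 0.05,
                             alpha_cluster = NULL,
                             neighbours = NULL,
                             seed = NULL, groups = NULL,
                             label_matrix = NULL) {
  kind <- match.arg(kind)
  if (is.null(alpha_cluster)) alpha_cluster <- if (kind == "F") 0.05 else 0.025
  if (!is.null(seed)) set.seed(seed)
  if (n_randomizations < 100)
    warning("fewer than 100 randomizations: Monte-Carlo p resolution is coarse")
  obs <- samplewise_stat(group_a, group_b, kind, groups = groups)
  if (is.null(groups)) groups <- list(group_a, group_b)
  parts <- lapply(groups, as_subject_matrix)
  mats <- lapply(parts, `[[`, "mat")
  nch <- obs$dims[1]
  ch_adj <- subset_channel_adjacency(neighbours, obs$axes$channels, nch)
  vadj <- build_voxel_adjacency(ch_adj, obs$dims[2], obs$dims[3])
  thr <- if (kind == "F") qf(1 - alpha_sample, obs$df[1], obs$df[2])
         else qt(1 - alpha_sample / 2, obs$df)
  clusters <- observed_clusters(obs$stat, obs$p, alpha_sample, vadj, kind,
                                obs$axes)
  if (!is.null(label_matrix)) {
    stopifnot(kind == "independent_t")
    ns <- vapply(mats, nrow, integer(1))
    X <- do.call(rbind, mats)
    nr <- nrow(label_matrix)
    null_pos <- numeric(nr); null_neg <- numeric(nr)
    for (r in seq_len(nr)) {
      ia <- label_matrix[r, ]
      st <- samplewise_stat(
        groups = list(array(X[ia, , drop = FALSE],
                            c(ns[1], obs$dims)),
                      array(X[-ia, , drop = FALSE], c(ns[2], obs$dims))),
        kind = "independent_t")
      mm <- cpp_max_cluster_sums(matrix(as.vector(st$stat), 1), thr, -thr,
                                 vadj$ptr, vadj$idx)
      null_pos[r] <- mm[1, 1]; null_neg[r] <- mm[1, 2]
    }
    nulls <- list(pos = null_pos, neg = null_neg)
    n_randomizations <- nr
  } else {
    nulls <- null_max_distribution(mats, kind, n_randomizations, thr, vadj)
  }
  for (i in seq_along(clusters)) {
    cs <- clusters[[i]]$cluster_stat
    tol <- 1e-8 * (1 + abs(cs))           # ties at the observed value count
    b <- if (cs >= 0) sum(nulls$pos >= cs - tol)
         else sum(nulls$neg <= cs + tol)
    clusters[[i]]$p_value <- (b + 1) / (n_randomizations + 1)
    clusters[[i]]$significant <- clusters[[i]]$p_value < alpha_cluster
  }
  structure(list(clusters = clusters, stat = obs$stat, p = obs$p,
                 df = obs$df, kind = kind, axes = obs$axes,
                 null_max_pos = nulls$pos, null_max_neg = nulls$neg,
                 n_randomizations = n_randomizations,
                 alpha_sample = alpha_sample, alpha_cluster = alpha_cluster),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %d randomizations): %d cluster(s)\n",
              x$kind, x$n_randomizations, length(x$clusters)))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d voxels, sum stat %.2f, p = %.4f%s\n",
                cl$polarity, nrow(cl$members), cl$cluster_stat, cl$p_value,
                if (isTRUE(cl$significant)) " *" else ""))
  invisible(x)
}

#' Export cluster test results as JSON and a TSV summary
#' @param test a `cluster_test`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the summary data.frame.
#' @export
write_cluster_results <- function(test, json_path = NULL, tsv_path = NULL) {
  summary <- data.frame(
    cluster = seq_along(test$clusters),
    polarity = vapply(test$clusters, `[[`, character(1), "polarity"),
    n_voxels = vapply(test$clusters, function(c) nrow(c$members), integer(1)),
    cluster_stat = vapply(test$clusters, `[[`, numeric(1), "cluster_stat"),
    p_value = vapply(test$clusters, `[[`, numeric(1), "p_value"),
    significant = vapply(test$clusters, `[[`, logical(1), "significant"))
  if (!is.null(tsv_path))
    write.table(summary, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(kind = test$kind, n_randomizations = test$n_randomizations,
           alpha_sample = test$alpha_sample,
           alpha_cluster = test$alpha_cluster,
           clusters = lapply(test$clusters, function(c)
             list(polarity = c$polarity, cluster_stat = c$cluster_stat,
                  p_value = c$p_value, significant = c$significant,
                  members = c$members))),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(summary)
}
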