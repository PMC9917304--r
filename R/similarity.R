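#' Pixel-wise Euclidean distance between response maps
#'
#' \deqn{d(o_1, o_2) = \sqrt{\sum_{x,y} (I_{o_1}(x,y) - I_{o_2}(x,y))^2}}
#' over the in-mask pixels, where \eqn{I_o(x,y)} is the biphasic amplitude
#' map of odor \eqn{o}. Both maps must share shape and mask. Setting
#' `squared = TRUE` returns the squared distance (sensitivity variant).
#'
#' @param map_a,map_b `response_map`s with identical shape and mask.
#' @param squared return the squared distance instead.
#' @return A nonnegative scalar.
#' @export
euclidean_distance <- function(map_a, map_b, squared = FALSE) {
  stopifnot(inherits(map_a, "response_map"), inherits(map_b, "response_map"))
  if (!identical(dim(map_a$amplitude), dim(map_b$amplitude)) ||
      !identical(map_a$mask$include, map_b$mask$include))
    stop("maps have mismatched shapes or masks")
  sel <- map_a$mask$include
  ss <- sum((map_a$amplitude[sel] - map_b$amplitude[sel])^2)
  if (squared) ss else sqrt(ss)
}

#' All-pairs distance matrix for one bee
#'
#' Euclidean distances between the (presentation-averaged) response maps of
#' every stimulus pair within one animal. For the 16-odorant panel this
#' populates the 120 unordered pairs.
#'
#' @param maps list of `response_map`s, one per stimulus, sharing one mask;
#'   labels are taken from `stimulus_id` (or `names(maps)`).
#' @param squared use squared distances.
#' @return A [dist_matrix()] with provenance `"per-bee"`.
#' @export
pairwise_distances <- function(maps, squared = FALSE) {
  if (length(maps) < 2) stop("need at least 2 stimuli")
  labels <- names(maps) %||% vapply(maps, function(m)
    as.character(m$stimulus_id), character(1))
  if (anyDuplicated(labels)) stop("duplicate stimulus labels")
  n <- length(maps)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- euclidean_distance(maps[[i]], maps[[j]],
                                             squared = squared)
  dist_matrix(m, labels = labels, provenance = "per-bee")
}

#' Same-odorant versus different-odorant map distances
#'
#' Quantifies odor-code reliability: within each bee, the distance between
#' the two presentations of the same odorant (averaged over odorants) is
#' compared with the distance between presentations of different odorants
#' (averaged over all cross-odorant presentation pairs, 4 per odor pair).
#' The two per-bee means are compared across bees with a paired t test and a
#' Wilcoxon matched-pairs test.
#'
#' @param maps flat list of per-presentation `response_map`s with `bee_id`,
#'   `stimulus_id` and `presentation_index` (1 or 2) set; every bee must have
#'   exactly 2 presentations of every stimulus.
#' @return An object of class `same_diff_result`: list with `per_bee`
#'   (data frame `bee`, `same`, `different`), `t` (from [paired_t()]) and
#'   `wilcoxon` (from [wilcoxon_matched()]).
#' @export
same_vs_different <- function(maps) {
  info <- data.frame(
    bee = vapply(maps, function(m) as.character(m$bee_id), character(1)),
    stim = vapply(maps, function(m) as.character(m$stimulus_id), character(1)),
    pres = vapply(maps, function(m) as.integer(m$presentation_index),
                  integer(1)))
  per_bee <- lapply(split(seq_along(maps), info$bee), function(idx) {
    sub <- info[idx, ]
    stims <- unique(sub$stim)
    cnt <- table(sub$stim, sub$pres)
    if (!all(dim(cnt) == c(length(stims), 2L)) || !all(cnt == 1L))
      stop("bee ", sub$bee[1],
           ": every stimulus needs exactly 2 presentations")
    get <- function(s, p) maps[[idx[which(sub$stim == s & sub$pres == p)]]]
    same <- vapply(stims, function(s)
      euclidean_distance(get(s, 1), get(s, 2)), numeric(1))
    ns <- length(stims)
    diffs <- c()
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      diffs <- c(diffs,
                 euclidean_distance(get(stims[i], 1), get(stims[j], 1)),
                 euclidean_distance(get(stims[i], 1), get(stims[j], 2)),
                 euclidean_distance(get(stims[i], 2), get(stims[j], 1)),
                 euclidean_distance(get(stims[i], 2), get(stims[j], 2)))
    data.frame(bee = sub$bee[1], same = mean(same), different = mean(diffs))
  })
  per_bee <- do.call(rbind, per_bee)
  rownames(per_bee) <- NULL
  structure(list(per_bee = per_bee,
                 t = paired_t(per_bee$same, per_bee$different),
                 wilcoxon = wilcoxon_matched(per_bee$same, per_bee$different)),
            class = "same_diff_result")
}

#' @export
print.same_diff_result <- function(x, ...) {
  cat("Same vs different odorant distances (n = ", nrow(x$per_bee),
      " bees)\n", sep = "")
  cat("  mean same:      ", round(mean(x$per_bee$same), 3), "\n",
      "  mean different: ", round(mean(x$per_bee$different), 3), "\n", sep = "")
  cat("  paired t = ", round(x$t$t, 3), ", df = ", x$t$df, ", p = ",
      format(x$t$p, digits = 3), "\n", sep = "")
  cat("  Wilcoxon V = ", x$wilcoxon$statistic, ", p = ",
      format(x$wilcoxon$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Mean and SEM of per-bee distance matrices
#'
#' Entrywise mean across bees, with the matrix of standard errors of the
#' mean returned alongside.
#'
#' @param dms list of [dist_matrix()] objects with identical labels.
#' @return A list with `mean` (a `dist_matrix`, provenance
#'   `"cross-bee-mean"`), `sem` (matrix) and `n`.
#' @export
mean_distance_matrix <- function(dms) {
  if (!length(dms)) stop("no matrices")
  labs <- dms[[1]]$labels
  for (d in dms) if (!identical(d$labels, labs))
    stop("distance matrices have mismatched labels")
  arr <- simplify2array(lapply(dms, `[[`, "values"))
  if (length(dms) == 1L) {
    mn <- dms[[1]]$values
    sem <- matrix(NA_real_, nrow(mn), ncol(mn))
  } else {
    mn <- apply(arr, c(1, 2), mean)
    sem <- apply(arr, c(1, 2), sd) / sqrt(length(dms))
  }
  list(mean = dist_matrix(mn, labels = labs, provenance = "cross-bee-mean"),
       sem = sem, n = length(dms))
}

#' Ward hierarchical clustering of odor distances
#'
#' Agglomerative clustering of the odorants under the Ward criterion
#' (`ward.D2`: squared-distance update on Euclidean distances via
#' Lance-Williams). Merge heights are checked to be nondecreasing.
#'
#' @param distances a [dist_matrix()].
#' @return An object of class `odor_dendrogram`: list with `merge`,
#'   `height`, `labels` and the underlying `hclust` object.
#' @export
ward_clustering <- function(distances) {
  stopifnot(inherits(distances, "dist_matrix"))
  if (length(distances$labels) < 2) stop("need at least 2 stimuli to cluster")
  hc <- hclust(as.dist(distances$values), method = "ward.D2")
  if (any(diff(hc$height) < -1e-8))
    warning("merge heights are not monotone; input may not be a metric")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc),
            class = "odor_dendrogram")
}

#' @export
print.odor_dendrogram <- function(x, ...) {
  cat("Ward dendrogram (", length(x$labels), " leaves)\n", sep = "")
  bp <- first_bipartition(x)
  cat("  first bipartition: {", paste(bp[[1]], collapse = ", "), "} | {",
      paste(bp[[2]], collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
plot.odor_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, hang = -1, xlab = "", sub = "", ...)
  invisible(x)
}

#' @export
as.hclust.odor_dendrogram <- function(x, ...) x$hclust

#' @rdname ward_clustering
#' @param dendrogram an `odor_dendrogram`.
#' @return `first_bipartition()`: list of the two label sets split by the
#'   top-most merge.
#' @export
first_bipartition <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "odor_dendrogram"))
  ct <- cutree(dendrogram$hclust, k = 2)
  split(names(ct), ct)
}

#' Newick-like text form of a dendrogram
#'
#' @param dendrogram an `odor_dendrogram`.
#' @param digits branch-length digits.
#' @return A single Newick string (heights as branch labels).
#' @export
dendrogram_newick <- function(dendrogram, digits = 6) {
  stopifnot(inherits(dendrogram, "odor_dendrogram"))
  hc <- dendrogram$hclust
  rec <- function(i) {
    if (i < 0) return(hc$labels[-i])
    paste0("(", rec(hc$merge[i, 1]), ",", rec(hc$merge[i, 2]), "):",
           signif(hc$height[i], digits))
  }
  paste0(rec(nrow(hc$merge)), ";")
}

#' Mantel permutation test between distance matrices
#'
#' Pearson correlation between the upper triangles of two labeled distance
#' matrices, with significance from joint row/column permutations of the
#' second matrix: `p = (#{|r_perm| >= |r_obs|} + 1) / (n_permutations + 1)`.
#' When the number of objects is small enough that `factorial(n)` does not
#' exceed `exhaustive_cap`, all permutations are enumerated instead and the
#' p-value is exact.
#'
#' @param d1,d2 [dist_matrix()] objects with the same labels (d2 is
#'   reordered to d1's label order if needed).
#' @param n_permutations Monte Carlo permutation count (default 9999).
#' @param seed optional seed for the permutation draws.
#' @param exhaustive_cap enumerate exhaustively when `factorial(n)` is at
#'   most this (default 40320 = 8!).
#' @return An object of class `mantel_result`: `r`, `r_squared`, `p`,
#'   `n_permutations`, `method` (`"permutation"` or `"exhaustive"`).
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = NULL,
                        exhaustive_cap = 40320) {
  stopifnot(inherits(d1, "dist_matrix"), inherits(d2, "dist_matrix"))
  if (!setequal(d1$labels, d2$labels))
    stop("distance matrices have different labels")
  ord <- match(d1$labels, d2$labels)
  v1 <- d1$values
  v2 <- d2$values[ord, ord]
  ut <- upper.tri(v1)
  x <- v1[ut]
  if (var(x) == 0 || var(v2[ut]) == 0)
    stop("degenerate input: zero off-diagonal variance")
  r_obs <- cor(x, v2[ut])
  n <- nrow(v1)
  if (factorial(n) <= exhaustive_cap) {
    perms <- all_permutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      cor(x, v2[p, p][ut])
    }, numeric(1))
    p_val <- sum(abs(rs) >= abs(r_obs) - 1e-12) / nrow(perms)
    method <- "exhaustive"
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (abs(cor(x, v2[p, p][ut])) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    p_val <- (hits + 1) / (n_permutations + 1)
    method <- "permutation"
    n_perm <- n_permutations
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p = p_val,
                 n_permutations = n_perm, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test (", x$method, ", ", x$n_permutations, " permutations)\n",
      "  r = ", round(x$r, 4), "  R^2 = ", round(x$r_squared, 4),
      "  p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
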