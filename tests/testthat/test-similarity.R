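test_that("Euclidean map distance: closed forms and scalar-loop oracle", {
  set.seed(10)
  a <- rand_map(3, 3)
  expect_equal(euclidean_distance(a, a), 0)

  # differing by delta at exactly k pixels -> delta * sqrt(k)
  b <- a; b$amplitude[1, 1:2] <- b$amplitude[1, 1:2] + 0.7
  expect_equal(euclidean_distance(a, b), 0.7 * sqrt(2), tolerance = 1e-12)

  d <- rand_map(3, 3)
  ss <- 0
  for (i in 1:3) for (j in 1:3)
    ss <- ss + (a$amplitude[i, j] - d$amplitude[i, j])^2
  expect_equal(euclidean_distance(a, d), sqrt(ss), tolerance = 1e-12)
  expect_equal(euclidean_distance(a, d, squared = TRUE), ss,
               tolerance = 1e-12)

  msk <- roi_mask(matrix(rep_len(c(TRUE, FALSE), 9), 3, 3))
  expect_error(euclidean_distance(a, rand_map(3, 3, msk)), "mismatched")
})

test_that("map distances satisfy the metric axioms on a fixed mask", {
  set.seed(11)
  msk <- roi_mask(matrix(runif(20) > 0.3, 4, 5))
  maps <- lapply(1:6, function(i) rand_map(4, 5, msk))
  for (i in 1:6) expect_equal(euclidean_distance(maps[[i]], maps[[i]]), 0)
  for (tri in 1:10) {
    ijk <- sample(6, 3)
    dij <- euclidean_distance(maps[[ijk[1]]], maps[[ijk[2]]])
    dji <- euclidean_distance(maps[[ijk[2]]], maps[[ijk[1]]])
    dik <- euclidean_distance(maps[[ijk[1]]], maps[[ijk[3]]])
    dkj <- euclidean_distance(maps[[ijk[3]]], maps[[ijk[2]]])
    expect_equal(dij, dji, tolerance = 1e-12)
    expect_lte(dij, dik + dkj + 1e-12)
  }
})

test_that("pairwise distances: 16 stimuli give 120 pairs; loop oracle", {
  set.seed(12)
  maps16 <- lapply(1:16, function(i) rand_map(4, 4, stim = paste0("o", i)))
  names(maps16) <- paste0("o", 1:16)
  dm <- pairwise_distances(maps16)
  expect_equal(dim(dm$values), c(16L, 16L))
  expect_equal(sum(upper.tri(dm$values)), 120L)
  expect_true(all(dm$values[upper.tri(dm$values)] > 0))

  two <- list(a = make_map(matrix(1, 2, 2)), b = make_map(matrix(1, 2, 2)))
  expect_true(all(pairwise_distances(two)$values == 0))

  maps4 <- lapply(1:4, function(i) rand_map(3, 3))
  names(maps4) <- letters[1:4]
  dm4 <- pairwise_distances(maps4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dm4$values[i, j],
                 euclidean_distance(maps4[[i]], maps4[[j]]),
                 tolerance = 1e-12)

  dup <- list(a = maps4[[1]], a = maps4[[2]])
  expect_error(pairwise_distances(dup), "duplicate")
})

test_that("same-vs-different distances match a hand-worked 2-bee example", {
  vals <- list(
    b1 = list(X = list(c(0, 0), c(1, 0)), Y = list(c(3, 4), c(3, 4))),
    b2 = list(X = list(c(2, 0), c(2, 0)), Y = list(c(0, 0), c(0, 2))))
  maps <- toy_presentation_maps(vals)
  res <- same_vs_different(maps)
  pb <- res$per_bee[order(res$per_bee$bee), ]
  expect_equal(pb$same, c((1 + 0) / 2, (0 + 2) / 2))
  d1 <- mean(c(5, 5, sqrt(20), sqrt(20)))
  d2 <- mean(c(2, sqrt(8), 2, sqrt(8)))
  expect_equal(pb$different, c(d1, d2), tolerance = 1e-12)
  # closed-form paired t on the two per-bee pairs
  dd <- pb$same - pb$different
  expect_equal(res$t$t, mean(dd) / (sd(dd) / sqrt(2)), tolerance = 1e-12)
  expect_equal(res$t$df, 1)

  # relabelling which presentation is 1 vs 2 changes nothing
  maps_swapped <- lapply(maps, function(m) {
    if (m$bee_id == "b1") m$presentation_index <- 3L - m$presentation_index
    m
  })
  res2 <- same_vs_different(maps_swapped)
  expect_equal(res2$per_bee[order(res2$per_bee$bee), c("same", "different")],
               pb[, c("same", "different")], ignore_attr = TRUE)

  expect_error(same_vs_different(maps[-1]), "exactly 2 presentations")
})

test_that("zero presentation noise makes same-odor distances exactly zero", {
  vals <- list(
    b1 = list(X = list(c(1, 2), c(1, 2)), Y = list(c(4, 0), c(4, 0))),
    b2 = list(X = list(c(0, 1), c(0, 1)), Y = list(c(2, 2), c(2, 2))))
  res <- same_vs_different(toy_presentation_maps(vals))
  expect_true(all(res$per_bee$same == 0))
  expect_true(all(res$per_bee$different > 0))
})

test_that("cross-bee mean matrix and SEM", {
  m1 <- dist_matrix(matrix(c(0, 2, 2, 0), 2), labels = c("a", "b"))
  m2 <- dist_matrix(matrix(c(0, 4, 4, 0), 2), labels = c("a", "b"))
  mm <- mean_distance_matrix(list(m1, m2))
  expect_equal(mm$mean$values["a", "b"], 3)
  expect_equal(mm$sem["a" == rownames(m1$values), 2][[1]], 1)
  expect_equal(mm$mean$provenance, "cross-bee-mean")

  single <- mean_distance_matrix(list(m1))
  expect_equal(single$mean$values, m1$values)

  set.seed(13)
  ms <- lapply(1:5, function(i) rand_dist(4))
  got <- mean_distance_matrix(ms)$mean$values
  want <- matrix(0, 4, 4)
  for (m in ms) want <- want + m$values
  expect_equal(got, want / 5, ignore_attr = TRUE, tolerance = 1e-12)

  m3 <- dist_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("a", "c"))
  expect_error(mean_distance_matrix(list(m1, m3)), "labels")
})

# brute-force Ward.D2 agglomeration for points on a line: merge height
# sqrt(2 |A||B| / (|A|+|B|)) * |centroid difference|
ward_line_oracle <- function(x) {
  clusters <- as.list(seq_along(x))
  heights <- c()
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      na <- length(clusters[[i]]); nb <- length(clusters[[j]])
      h <- sqrt(2 * na * nb / (na + nb)) *
        abs(mean(x[clusters[[i]]]) - mean(x[clusters[[j]]]))
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]],
                                           clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

test_that("Ward clustering matches the exhaustive agglomeration oracle", {
  # two items at distance d merge at height d
  d2 <- dist_matrix(matrix(c(0, 3.2, 3.2, 0), 2), labels = c("a", "b"))
  w2 <- ward_clustering(d2)
  expect_equal(w2$height, 3.2)

  # 4 points on a line at 0, 1, 10, 11
  x <- c(0, 1, 10, 11)
  dm <- dist_matrix(as.matrix(dist(x)), labels = paste0("p", 1:4))
  w <- ward_clustering(dm)
  oracle <- ward_line_oracle(x)
  expect_equal(w$height, oracle$heights, tolerance = 1e-12)
  bp <- first_bipartition(w)
  expect_true(setequal(bp[[1]], c("p1", "p2")) ||
              setequal(bp[[2]], c("p1", "p2")))

  # heights nondecreasing on metric inputs
  set.seed(14)
  for (rep in 1:10) {
    rd <- rand_dist(7)
    expect_true(all(diff(ward_clustering(rd)$height) >= -1e-10))
  }
  expect_error(ward_clustering(dist_matrix(matrix(0, 1, 1), labels = "a")),
               "at least 2")

  # Newick serialisation mentions every leaf once
  nw <- dendrogram_newick(w)
  expect_true(all(vapply(paste0("p", 1:4), grepl, logical(1), x = nw,
                         fixed = TRUE)))
})

test_that("Mantel test: self-comparison, exhaustive enumeration, and
          affine invariance", {
  set.seed(15)
  d1 <- rand_dist(16)
  self <- mantel_test(d1, d1, n_permutations = 999, seed = 1,
                      exhaustive_cap = 0)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 1000)

  # 4 labels: exact p over the 24 relabelings vs Monte Carlo at 10,000 draws
  da <- rand_dist(4); db <- rand_dist(4)
  exact <- mantel_test(da, db)
  expect_equal(exact$method, "exhaustive")
  expect_equal(exact$n_permutations, 24)
  mc <- mantel_test(da, db, n_permutations = 10000, seed = 7,
                    exhaustive_cap = 0)
  tol <- 3 * sqrt(exact$p * (1 - exact$p) / 10000) + 2e-4
  expect_lt(abs(mc$p - exact$p), tol)

  # affine transform of the entries leaves r at exactly 1
  v <- d1$values
  v2 <- 0.5 + 2 * v; diag(v2) <- 0
  daff <- dist_matrix(v2, labels = d1$labels)
  expect_equal(mantel_test(d1, daff, n_permutations = 99, seed = 2,
                           exhaustive_cap = 0)$r, 1, tolerance = 1e-12)

  zero <- dist_matrix(matrix(0, 4, 4), labels = paste0("o", 1:4))
  expect_error(mantel_test(zero, db), "zero off-diagonal variance")
  d_other <- rand_dist(16, labels = paste0("x", 1:16))
  expect_error(mantel_test(d1, d_other), "different labels")
})

test_that("Mantel r agrees with an independent implementation", {
  set.seed(16)
  da <- rand_dist(10); db <- rand_dist(10)
  ours <- mantel_test(da, db, n_permutations = 499, seed = 3)
  ref <- vegan::mantel(as.dist(da$values), as.dist(db$values),
                       permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})
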