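test_that("SD selection drops invariant probes and honours top_k", {
  tb <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       a = c(5, 0, 10), b = c(5, 1, 2), c = c(5, 2, 12))
  sds <- apply(as.matrix(tb[, -1]), 1, sd)
  out <- sd_select(tb, min_sd = 0)
  expect_false("p1" %in% out$probe_id)           # constant probe always dropped
  expect_equal(sd_select(tb, top_k = 3), tb)     # top_k = n is the identity

  tb2 <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        a = c(0, 0, 0), b = c(0, 2, 10))
  # SDs are 0, sqrt(2), 5*sqrt(2); min_sd = 2 keeps one probe -> error (< 2 left)
  expect_error(sd_select(tb2, min_sd = 2), "lower the threshold")
  expect_error(sd_select(tb2, min_sd = 2, top_k = 2), "exactly one")
})

test_that("correlation-distance average-linkage clustering orders merges correctly", {
  set.seed(31)
  base <- rnorm(50)
  m <- cbind(A = base + rnorm(50, 0, 0.05),
             B = base + rnorm(50, 0, 0.05),
             C = rnorm(50))
  tree <- cluster_samples(m)
  expect_equal(sort(tree$members[[1]]), c("A", "B"))   # tight pair first
  expect_equal(sort(tree$members[[2]]), c("A", "B", "C"))

  dup <- cbind(A = base, B = base, C = rnorm(50))
  tdup <- cluster_samples(dup)
  expect_equal(tdup$height[1], 0, tolerance = 1e-12)   # r = 1, distance 0
  expect_equal(sort(tdup$members[[1]]), c("A", "B"))

  anti <- cbind(A = base, B = -base, C = base + rnorm(50, 0, 0.01))
  tanti <- cluster_samples(anti)
  expect_equal(sort(tanti$members[[1]]), c("A", "C"))
  expect_equal(tanti$height[2], max(tanti$height))     # anticorrelated joins last
  expect_gt(tanti$height[2], 1.5)                      # distance near 2

  const <- cbind(A = rep(1, 10), B = rnorm(10))
  expect_error(cluster_samples(const), "zero-variance")
})

test_that("hand-rolled agglomeration agrees with stats::hclust on tie-free data", {
  set.seed(77)
  for (i in 1:5) {
    m <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
    ours <- cluster_samples(m)
    ref <- stats::hclust(stats::as.dist(1 - cor(m)), method = "average")
    expect_equal(ours$height, ref$height, tolerance = 1e-12)
    # every one of our clusters must be a single group of the reference tree
    # cut just above the corresponding merge height
    for (k in seq_along(ours$members)) {
      ct <- stats::cutree(ref, h = ours$height[k] + 1e-10)
      grp <- ct[ours$members[[k]]]
      expect_true(length(unique(grp)) == 1)
    }
  }
})

test_that("dendrogram member sets form a laminar family", {
  set.seed(13)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  tree <- cluster_samples(m)
  expect_true(is_laminar_sets(tree$members))
  expect_equal(length(tree$members[[length(tree$members)]]), 6)  # root = all
})

test_that("multiscale bootstrap is seed-deterministic with supports in [0,1]", {
  set.seed(19)
  m <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
  t1 <- multiscale_bootstrap(m, replicates = 60, seed = 4)
  t2 <- multiscale_bootstrap(m, replicates = 60, seed = 4)
  expect_identical(tidy(t1), tidy(t2))
  expect_true(all(t1$nodes$au >= 0 & t1$nodes$au <= 1))
  expect_true(all(t1$nodes$bp >= 0 & t1$nodes$bp <= 1))
  # the root contains all leaves and always reappears
  root <- t1$nodes[t1$nodes$node == nrow(t1$merge), ]
  expect_equal(root$au, 1)
  expect_equal(root$bp, 1)
})

test_that("fitted bp agrees with the raw appearance fraction at scale 1", {
  set.seed(23)
  base <- rnorm(80)
  m <- cbind(A = base + rnorm(80, 0, 0.4), B = base + rnorm(80, 0, 0.4),
             C = rnorm(80), D = rnorm(80) * 0.7 + rnorm(80, 0, 0.8),
             E = rnorm(80), F = rnorm(80))
  B_reps <- 200
  tr <- multiscale_bootstrap(m, replicates = B_reps, seed = 6)
  i1 <- which(abs(tr$scales - 1) < 1e-9)
  for (k in seq_len(nrow(tr$nodes))) {
    raw <- tr$bp_table[k, i1] / B_reps
    se <- sqrt(max(raw * (1 - raw), 1 / B_reps) / B_reps)
    expect_lte(abs(tr$nodes$bp[k] - raw), 3 * se + 1e-9)
  }
})

test_that("a well-separated planted split earns high AU support", {
  set.seed(41)
  n <- 150
  shift <- c(0, 0, 0, 5, 5, 5)                 # two groups, effect >> noise
  m <- sapply(1:6, function(j) rnorm(n) + shift[j] * (seq_len(n) <= 60))
  colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  tr <- multiscale_bootstrap(m, replicates = 200, seed = 2)
  sig <- vapply(tr$nodes$members,
                function(v) paste(sort(v), collapse = ","), character(1))
  au_split <- tr$nodes$au[sig == "a1,a2,a3" | sig == "b1,b2,b3"]
  expect_gte(length(au_split), 1)
  expect_true(all(au_split >= 0.95))
})

test_that("supports are invariant to sample column permutation", {
  set.seed(55)
  m <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
  t1 <- multiscale_bootstrap(m, replicates = 80, seed = 9)
  t2 <- multiscale_bootstrap(m[, c(4, 2, 6, 1, 3, 5)], replicates = 80, seed = 9)
  sig1 <- vapply(t1$nodes$members, function(v) paste(sort(v), collapse = ","),
                 character(1))
  sig2 <- vapply(t2$nodes$members, function(v) paste(sort(v), collapse = ","),
                 character(1))
  expect_setequal(sig1, sig2)
  expect_equal(t1$nodes$au[order(sig1)], t2$nodes$au[order(sig2)],
               tolerance = 1e-12)
  expect_equal(t1$nodes$bp[order(sig1)], t2$nodes$bp[order(sig2)],
               tolerance = 1e-12)
})

test_that("highlighting returns exactly the nodes above the AU threshold", {
  set.seed(3)
  m <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
  tr <- multiscale_bootstrap(m, replicates = 50, seed = 8)
  hi <- highlight_clusters(tr, au_threshold = 0)
  expect_equal(nrow(hi), sum(tr$nodes$au > 0) - 1)     # root excluded
  none <- highlight_clusters(tr, au_threshold = 1)
  expect_equal(nrow(none), 0)
  manual <- tr$nodes$node[tr$nodes$au > 0.5 & tr$nodes$node != nrow(tr$merge)]
  expect_equal(highlight_clusters(tr, 0.5)$node, manual)
})

test_that("cluster_containing finds the smallest enclosing cluster", {
  set.seed(31)
  base <- rnorm(50)
  m <- cbind(A = base + rnorm(50, 0.05), B = base + rnorm(50, 0.05),
             C = rnorm(50), D = rnorm(50))
  tree <- cluster_samples(m)
  expect_equal(sort(cluster_containing(tree, c("A", "B"))), c("A", "B"))
  expect_equal(length(cluster_containing(tree, c("A", "B", "C", "D"))), 4)
  expect_error(cluster_containing(tree, "nope"), "unknown sample")
})
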