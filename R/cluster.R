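#' Select high-variability probes by standard deviation
#'
#' Drops probes expressed near-identically in all samples so that clustering
#' reflects the variation between samples rather than the common expression
#' floor. Either an absolute SD threshold or a top-k selection can be used
#' (exactly one of the two).
#'
#' @param signals A tibble `probe_id` + one numeric column per sample.
#' @param min_sd Keep probes with across-sample SD strictly above this value.
#' @param top_k Keep the `top_k` probes with the largest across-sample SD.
#' @return The filtered signals tibble (at least 2 probes, or an error).
#' @export
sd_select <- function(signals, min_sd = NULL, top_k = NULL) {
  stopifnot(is.data.frame(signals), names(signals)[1] == "probe_id")
  if (is.null(min_sd) == is.null(top_k)) {
    abort("supply exactly one of min_sd or top_k")
  }
  m <- as.matrix(signals[, -1, drop = FALSE])
  if (ncol(m) < 2) abort("sd_select() needs at least 2 samples")
  sds <- apply(m, 1, sd)
  if (!is.null(min_sd)) {
    keep <- sds > min_sd
    if (sum(keep) < 2) {
      abort(paste0("fewer than 2 probes exceed min_sd = ", min_sd,
                   "; lower the threshold (max probe SD is ",
                   format(max(sds), digits = 4), ")"))
    }
  } else {
    top_k <- min(top_k, nrow(m))
    if (top_k < 2) abort("top_k must be at least 2")
    keep <- rank(-sds, ties.method = "first") <= top_k
  }
  signals[keep, , drop = FALSE]
}

# Average-linkage (UPGMA) agglomeration over a distance matrix with a
# deterministic tie-break: among equally close pairs, merge the pair whose
# sorted smallest-member labels come first lexicographically.
avg_link <- function(D, labels) {
  n <- nrow(D)
  active <- as.list(seq_len(n))            # member leaf indices per cluster
  sizes <- rep(1L, n)
  node_of <- -seq_len(n)                   # hclust coding: -leaf, +internal
  minlab <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)
  d <- D
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    dd <- d[idx, idx, drop = FALSE]
    diag(dd) <- Inf
    mn <- min(dd)
    cand <- which(dd <= mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(rc) {
        paste(sort(c(minlab[idx[rc[1]]], minlab[idx[rc[2]]])), collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- idx[cand[1, 1]]; j <- idx[cand[1, 2]]
    # child with the lexicographically smallest member label renders first
    merge[step, ] <- if (minlab[i] <= minlab[j]) c(node_of[i], node_of[j]) else
      c(node_of[j], node_of[i])
    height[step] <- mn
    members[[step]] <- sort(c(active[[i]], active[[j]]))
    # Lance-Williams update for average linkage, cluster i absorbs j
    others <- setdiff(which(alive), c(i, j))
    if (length(others) > 0) {
      d[i, others] <- (sizes[i] * d[i, others] + sizes[j] * d[j, others]) /
        (sizes[i] + sizes[j])
      d[others, i] <- d[i, others]
    }
    active[[i]] <- members[[step]]
    sizes[i] <- sizes[i] + sizes[j]
    minlab[i] <- min(minlab[i], minlab[j])
    node_of[i] <- step
    alive[j] <- FALSE
  }
  list(merge = merge, height = height, members = members)
}

cor_dist <- function(m) {
  v <- apply(m, 2, sd)
  if (any(v == 0)) {
    abort(paste0("zero-variance sample column(s): ",
                 paste(colnames(m)[v == 0], collapse = ", "),
                 "; correlation distance is undefined"))
  }
  1 - cor(m)
}

leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cluster samples by correlation distance and average linkage
#'
#' Pairwise sample distance is one minus the Pearson correlation of their
#' probe intensity vectors; agglomeration is average linkage (UPGMA) with a
#' deterministic lexicographic smallest-member tie-break.
#'
#' @param signals A tibble `probe_id` + one numeric column per sample
#'   (typically [sd_select()] output), or a probes x samples matrix.
#' @return A `sample_dendrogram`: `labels`, hclust-style `merge` and
#'   `height`, `members` (leaf-label sets per internal node), `order`.
#'   Convert with [as.hclust()] for the standard tool chain.
#' @export
cluster_samples <- function(signals) {
  m <- if (is.matrix(signals)) signals else {
    stopifnot(is.data.frame(signals), names(signals)[1] == "probe_id")
    as.matrix(signals[, -1, drop = FALSE])
  }
  if (ncol(m) < 2) abort("need at least 2 samples to cluster")
  if (nrow(m) < 2) abort("need at least 2 probes to cluster")
  labels <- colnames(m)
  fit <- avg_link(cor_dist(m), labels)
  structure(
    list(labels = labels,
         merge = fit$merge,
         height = fit$height,
         members = lapply(fit$members, function(ix) labels[ix]),
         order = leaf_order(fit$merge),
         method = "average",
         dist.method = "1 - Pearson correlation"),
    class = "sample_dendrogram"
  )
}

#' @export
as.hclust.sample_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$method, call = match.call(),
         dist.method = x$dist.method),
    class = "hclust"
  )
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat(sprintf("Sample dendrogram: %d leaves (%s, %s linkage)\n",
              length(x$labels), x$dist.method, x$method))
  if (inherits(x, "supported_dendrogram")) {
    print(tidy(x))
  }
  invisible(x)
}

node_signature <- function(labels) paste(sort(labels), collapse = "\r")

is_laminar <- function(member_sets) {
  k <- length(member_sets)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- member_sets[[i]]; b <- member_sets[[j]]
      ab <- length(intersect(a, b))
      if (ab != 0 && ab != min(length(a), length(b))) return(FALSE)
    }
  }
  TRUE
}

#' Multiscale-bootstrap cluster support (AU and BP values)
#'
#' Assesses the stability of every cluster of the sample dendrogram by
#' resampling probe rows with replacement at several resample sizes
#' (`scales` x the number of probes), reclustering, and recording how often
#' each original cluster reappears. The per-scale appearance probabilities
#' `BP_r` are probit-transformed (`z_r = qnorm(1 - BP_r)`) and fitted by
#' weighted least squares to `z_r = v * sqrt(r) + c / sqrt(r)`; the
#' approximately unbiased support is `AU = 1 - pnorm(v - c)` and the plain
#' bootstrap probability `BP = 1 - pnorm(v + c)`. AU corrects the bias that
#' makes the plain bootstrap probability conservative for large clusters.
#'
#' @param signals A tibble `probe_id` + sample columns, or a matrix.
#' @param scales Relative resample sizes (default 0.5 to 1.4 by 0.1; must
#'   include 1 so the plain bootstrap is observable).
#' @param replicates Bootstrap replicates per scale (default 1000).
#' @param seed Master seed; per-scale substreams are derived from it, so the
#'   result is reproducible and invariant to sample column order.
#' @param bp_clip Clipping bound for appearance probabilities before the
#'   probit transform (default `1/(replicates + 1)`).
#' @return A `supported_dendrogram`: the [cluster_samples()] tree plus a
#'   `nodes` tibble (`node`, `members` list, `height`, `au`, `bp`, `v`, `c`,
#'   `residual`, `flag`) and the per-scale appearance-count matrix
#'   (`bp_table`). Clusters never observed at any scale get `au = bp = 0`
#'   and flag `"never_observed"`; clusters observed in every replicate are
#'   snapped to `au = bp = 1` with flag `"at_ceiling"`.
#' @export
multiscale_bootstrap <- function(signals, scales = seq(0.5, 1.4, by = 0.1),
                                 replicates = 1000, seed = 1, bp_clip = NULL) {
  m <- if (is.matrix(signals)) signals else {
    stopifnot(is.data.frame(signals), names(signals)[1] == "probe_id")
    as.matrix(signals[, -1, drop = FALSE])
  }
  if (any(scales <= 0)) abort("all scales must be positive")
  if (!any(abs(scales - 1) < 1e-9)) abort("scales must include 1.0")
  if (replicates < 1) abort("replicates must be >= 1")
  B <- as.integer(replicates)
  if (is.null(bp_clip)) bp_clip <- 1 / (B + 1)

  tree <- cluster_samples(m)
  n_nodes <- length(tree$members)
  sigs <- vapply(tree$members, node_signature, character(1))
  n_probes <- nrow(m)

  # Deterministic per-scale substreams from the master seed.
  set.seed(as.integer(seed))
  scale_seeds <- sample.int(.Machine$integer.max, length(scales))

  counts <- matrix(0L, n_nodes, length(scales),
                   dimnames = list(NULL, paste0("r", scales)))
  for (si in seq_along(scales)) {
    set.seed(scale_seeds[si])
    n_r <- ceiling(n_probes * scales[si])
    for (b in seq_len(B)) {
      idx <- sample.int(n_probes, n_r, replace = TRUE)
      rep_sigs <- tryCatch({
        fit <- avg_link(cor_dist(m[idx, , drop = FALSE]), tree$labels)
        vapply(fit$members, function(ix) node_signature(tree$labels[ix]),
               character(1))
      }, error = function(e) character(0))  # degenerate resample: no clusters
      hit <- sigs %in% rep_sigs
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }

  bp_raw <- counts / B
  bp_fit <- pmin(pmax(bp_raw, bp_clip), 1 - bp_clip)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  nodes <- purrr::map_dfr(seq_len(n_nodes), function(k) {
    raw <- bp_raw[k, ]
    bpv <- bp_fit[k, ]
    z <- qnorm(1 - bpv)
    w <- B / (bpv * (1 - bpv))
    fit <- stats::lm.wfit(X, z, w)
    v <- unname(fit$coefficients[1]); cc <- unname(fit$coefficients[2])
    au <- 1 - pnorm(v - cc)
    bp <- 1 - pnorm(v + cc)
    resid <- sqrt(sum(w * fit$residuals^2) / length(z))
    flag <- "ok"
    if (all(raw == 0)) { au <- 0; bp <- 0; flag <- "never_observed" }
    if (all(raw == 1)) { au <- 1; bp <- 1; flag <- "at_ceiling" }
    tibble::tibble(node = k, members = list(tree$members[[k]]),
                   height = tree$height[k], au = au, bp = bp,
                   v = unname(v), c = unname(cc), residual = resid, flag = flag)
  })

  tree$nodes <- nodes
  tree$bp_table <- counts
  tree$scales <- scales
  tree$replicates <- B
  tree$bp_clip <- bp_clip
  tree$seed <- seed
  class(tree) <- c("supported_dendrogram", class(tree))
  tree
}

#' @method tidy supported_dendrogram
#' @export
tidy.supported_dendrogram <- function(x, ...) {
  out <- x$nodes
  out$members <- vapply(out$members, function(v) paste(sort(v), collapse = ","),
                        character(1))
  out
}

#' @method glance supported_dendrogram
#' @export
glance.supported_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    n_nodes = nrow(x$nodes),
    replicates = x$replicates,
    n_scales = length(x$scales),
    min_au = min(x$nodes$au),
    max_au = max(x$nodes$au)
  )
}

#' Clusters exceeding an AU support threshold
#'
#' @param tree A [multiscale_bootstrap()] result.
#' @param au_threshold Support cut-off (default 0.95).
#' @return The `nodes` tibble restricted to internal nodes (root excluded)
#'   with `au > au_threshold`.
#' @export
highlight_clusters <- function(tree, au_threshold = 0.95) {
  stopifnot(inherits(tree, "supported_dendrogram"))
  root <- nrow(tree$merge)
  tree$nodes[tree$nodes$au > au_threshold & tree$nodes$node != root, ]
}

#' Smallest cluster containing a set of samples
#'
#' @param tree A `sample_dendrogram`.
#' @param samples Character vector of leaf labels.
#' @return The member labels of the smallest internal node containing all of
#'   `samples`.
#' @export
cluster_containing <- function(tree, samples) {
  stopifnot(inherits(tree, "sample_dendrogram"))
  if (!all(samples %in% tree$labels)) abort("unknown sample label(s)")
  sizes <- vapply(tree$members, length, integer(1))
  has <- vapply(tree$members, function(mem) all(samples %in% mem), logical(1))
  tree$members[[which(has)[which.min(sizes[has])]]]
}
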