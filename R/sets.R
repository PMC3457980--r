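#' Partition identifier sets into exclusive Venn regions
#'
#' Every identifier in the union of the input sets belongs to exactly one
#' region, named by its membership signature (e.g. `"A&B"`). Regions are
#' pairwise disjoint and their sizes sum to the union size.
#'
#' @param sets A named list of 2--4 character vectors.
#' @return A `deg_partition` tibble: `region` (signature string), `degree`
#'   (number of member sets), `n`, `ids` (list column). Regions are ordered
#'   by degree then signature; empty regions are omitted.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("venn_partition() needs a named list of id vectors")
  }
  if (anyDuplicated(names(sets))) abort("duplicate set names")
  if (length(sets) < 2 || length(sets) > 4) {
    abort("venn_partition() supports 2 to 4 sets")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  out <- tibble::tibble(id = ids, region = sig,
                        degree = rowSums(member)) |>
    dplyr::group_by(.data$region, .data$degree) |>
    dplyr::summarise(n = dplyr::n(), ids = list(.data$id), .groups = "drop") |>
    dplyr::arrange(.data$degree, .data$region)
  structure(out, class = c("deg_partition", class(out)),
            set_names = names(sets),
            set_sizes = vapply(sets, length, integer(1)))
}

#' @method glance deg_partition
#' @export
glance.deg_partition <- function(x, ...) {
  tibble::tibble(
    n_sets = length(attr(x, "set_names")),
    n_regions = nrow(x),
    union_size = sum(x$n)
  )
}

#' Compare single-knockdown DEG regions with a combined knockdown
#'
#' For every exclusive Venn region of the single-knockdown DEG sets, counts
#' how many of its members recur in the combined (multi-siRNA) DEG set, and
#' how many combined DEGs appear in no single set at all.
#'
#' @param singles A named list of DEG id sets (the single knockdowns), or a
#'   `deg_partition` built from them.
#' @param combined Character vector of combined-knockdown DEG ids.
#' @return A list: `regions` (tibble `region`, `n_region`, `n_in_combined`),
#'   `combined_unique` (count of combined DEGs outside the union of singles),
#'   `combined_total`, and `unique_fraction`.
#' @export
compare_to_combined <- function(singles, combined) {
  part <- if (inherits(singles, "deg_partition")) singles else venn_partition(singles)
  combined <- unique(as.character(combined))
  regions <- part |>
    tibble::as_tibble() |>
    dplyr::mutate(n_region = .data$n,
                  n_in_combined = vapply(.data$ids,
                                         function(v) sum(v %in% combined),
                                         integer(1))) |>
    dplyr::select("region", "n_region", "n_in_combined")
  union_ids <- unique(unlist(part$ids, use.names = FALSE))
  uniq <- sum(!combined %in% union_ids)
  list(
    regions = regions,
    combined_unique = uniq,
    combined_total = length(combined),
    unique_fraction = if (length(combined) > 0) uniq / length(combined) else NA_real_
  )
}

#' Hypergeometric over-representation test for two gene lists
#'
#' One-sided upper-tail test of the observed overlap `k` between a DEG set of
#' size `m` and a target set of size `n` drawn from a universe of `N`
#' identifiers: `p = P(X >= k)` with `X ~ Hypergeometric(N, m, n)` (Fisher's
#' exact test, enrichment direction). The natural universe is the set of
#' probes that survived detection filtering, since only those could have been
#' called differentially expressed.
#'
#' @param deg_set,target_set Character id vectors from a shared universe.
#' @param universe_size Total number of identifiers that could have appeared
#'   in either list.
#' @return An `enrichment_result` one-row tibble: `k`, `m`, `n`, `N`,
#'   `expected` (`m*n/N`), `p_value`, `test`.
#' @export
enrichment_test <- function(deg_set, target_set, universe_size) {
  deg_set <- unique(as.character(deg_set))
  target_set <- unique(as.character(target_set))
  m <- length(deg_set)
  n <- length(target_set)
  N <- universe_size
  if (N < length(union(deg_set, target_set))) {
    abort("universe_size is smaller than the union of the two sets")
  }
  k <- length(intersect(deg_set, target_set))
  p <- if (k == 0) 1 else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  structure(
    tibble::tibble(k = k, m = m, n = n, N = N,
                   expected = m * n / N,
                   p_value = p,
                   test = "hypergeometric upper tail"),
    class = c("enrichment_result", class(tibble::tibble()))
  )
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(x)
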