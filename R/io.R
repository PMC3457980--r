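#' Read a probe-profile table
#'
#' Reads the canonical tab-delimited probe-profile format: one row per probe
#' with columns `PROBE_ID`, `PROBE_CLASS` (`regular` or `negative_control`),
#' then for every sample `<id>.AVG_Signal` and `<id>.Detection_Pval`. This is
#' the layout of an Illumina sample-probe-profile export reduced to the
#' columns the pipeline uses.
#'
#' @param path Path to a tab-delimited file.
#'
#' @return A tibble with one row per probe, validated: unique probe ids,
#'   paired signal/detection columns per sample, non-negative signals and
#'   detection p-values in \[0, 1\].
#' @seealso [write_probe_profile()], [profile_samples()]
#' @export
read_probe_profile <- function(path) {
  profile <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  # numeric conversion through base strtod: exact round-trip of full-precision
  # decimal representations (fast multi-threaded parsers can be off by 1 ulp)
  for (cl in setdiff(names(profile), c("PROBE_ID", "PROBE_CLASS"))) {
    profile[[cl]] <- as.numeric(profile[[cl]])
  }
  validate_probe_profile(profile, path = path)
  profile
}

#' Write a probe-profile table
#'
#' Writes the canonical tab-delimited probe-profile format. Signals are
#' written with full round-trip precision; detection p-values are stored to
#' six significant digits (part of the on-disk contract). The writer is
#' deterministic: the same table always produces a byte-identical file.
#'
#' @param profile A probe-profile tibble (see [read_probe_profile()]).
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(profile, path) {
  validate_probe_profile(profile)
  out <- profile
  pcols <- grep("\\.Detection_Pval$", names(out), value = TRUE)
  for (cl in pcols) out[[cl]] <- signif(out[[cl]], 6)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Sample identifiers of a probe-profile table
#'
#' @param profile A probe-profile tibble.
#' @return Character vector of sample ids, in column order.
#' @export
profile_samples <- function(profile) {
  sub("\\.AVG_Signal$", "", grep("\\.AVG_Signal$", names(profile), value = TRUE))
}

#' Signal columns of a probe-profile table as a tidy tibble
#'
#' @param profile A probe-profile tibble.
#' @param probes Optional character vector restricting (and ordering) rows.
#' @return A tibble `probe_id` plus one numeric column per sample.
#' @export
profile_signals <- function(profile, probes = NULL) {
  extract_paired(profile, "AVG_Signal", probes)
}

#' Detection p-value columns of a probe-profile table as a tidy tibble
#'
#' @inheritParams profile_signals
#' @return A tibble `probe_id` plus one numeric column per sample.
#' @export
profile_detection <- function(profile, probes = NULL) {
  extract_paired(profile, "Detection_Pval", probes)
}

extract_paired <- function(profile, suffix, probes = NULL) {
  ids <- profile_samples(profile)
  cols <- paste0(ids, ".", suffix)
  out <- dplyr::select(profile, "PROBE_ID", dplyr::all_of(cols))
  names(out) <- c("probe_id", ids)
  if (!is.null(probes)) {
    out <- out[match(probes, out$probe_id), , drop = FALSE]
  }
  tibble::as_tibble(out)
}

validate_probe_profile <- function(profile, path = NULL) {
  where <- if (is.null(path)) "" else paste0(" in '", path, "'")
  nm <- names(profile)
  if (!identical(nm[1:2], c("PROBE_ID", "PROBE_CLASS"))) {
    abort(paste0("probe profile", where,
                 ": first two columns must be PROBE_ID, PROBE_CLASS"))
  }
  ids <- profile_samples(profile)
  if (length(ids) < 1) {
    abort(paste0("probe profile", where, ": no <sample>.AVG_Signal columns found"))
  }
  need <- c(paste0(ids, ".AVG_Signal"), paste0(ids, ".Detection_Pval"))
  missing <- setdiff(need, nm)
  if (length(missing) > 0) {
    abort(paste0("probe profile", where, ": missing paired column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra_p <- setdiff(sub("\\.Detection_Pval$", "",
                         grep("\\.Detection_Pval$", nm, value = TRUE)), ids)
  if (length(extra_p) > 0) {
    abort(paste0("probe profile", where, ": Detection_Pval column(s) without ",
                 "a matching AVG_Signal column: ", paste(extra_p, collapse = ", ")))
  }
  dup <- profile$PROBE_ID[duplicated(profile$PROBE_ID)]
  if (length(dup) > 0) {
    line <- which(duplicated(profile$PROBE_ID))[1] + 1L
    abort(paste0("probe profile", where, ": duplicate probe_id '", dup[1],
                 "' (line ", line, ")"))
  }
  bad_class <- !profile$PROBE_CLASS %in% c("regular", "negative_control")
  if (any(bad_class)) {
    line <- which(bad_class)[1] + 1L
    abort(paste0("probe profile", where, ": PROBE_CLASS must be 'regular' or ",
                 "'negative_control' (line ", line, ")"))
  }
  for (id in ids) {
    sig <- profile[[paste0(id, ".AVG_Signal")]]
    bad <- which(!is.finite(sig) | sig < 0)
    if (length(bad) > 0) {
      abort(paste0("probe profile", where, ": negative or non-finite signal in ",
                   id, ".AVG_Signal at line ", bad[1] + 1L,
                   " (probe ", profile$PROBE_ID[bad[1]], ")"))
    }
    p <- profile[[paste0(id, ".Detection_Pval")]]
    bad <- which(!is.finite(p) | p < 0 | p > 1)
    if (length(bad) > 0) {
      abort(paste0("probe profile", where, ": detection p-value outside [0, 1] in ",
                   id, ".Detection_Pval at line ", bad[1] + 1L,
                   " (probe ", profile$PROBE_ID[bad[1]], ", value ", p[bad[1]], ")"))
    }
  }
  invisible(profile)
}

#' Read or write a plain-text gene/probe list
#'
#' One identifier per line. Duplicates are removed preserving first
#' occurrence; an empty file reads as an empty list.
#'
#' @param path File path.
#' @return `read_gene_list()`: a character vector of unique ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  unique(trimws(lines))
}

#' @rdname read_gene_list
#' @param ids Character vector of identifiers.
#' @return `write_gene_list()`: `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}

#' Read or write a flat run-configuration file
#'
#' A minimal `key = value` format, one pair per line, `#` comments allowed;
#' nesting is expressed with dotted keys (`sim.n_probes = 1000`). Values that
#' parse as numbers are returned numeric, `TRUE`/`FALSE` as logical,
#' everything else as character.
#'
#' @param path File path.
#' @return `read_run_config()`: a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse1 <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  setNames(lapply(vals, parse1), keys)
}

#' @rdname read_run_config
#' @param config A named list of scalar values.
#' @return `write_run_config()`: `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                 character(1))
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

#' Export a dendrogram to Newick
#'
#' Branch lengths are differences between merge heights (leaves sit at height
#' 0); when the tree carries AU/BP supports, internal nodes are labelled
#' `"AU|BP"` as percentages rounded to integers. Labels containing spaces or
#' Newick metacharacters are single-quoted.
#'
#' @param tree A [cluster_samples()] or [multiscale_bootstrap()] result.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "sample_dendrogram"))
  merge <- tree$merge
  height <- tree$height
  labels <- tree$labels
  n_int <- nrow(merge)
  supports <- if (inherits(tree, "supported_dendrogram")) tree$nodes else NULL

  quote_label <- function(x) {
    if (grepl("[] ,:;()'[]", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  node_label <- function(k) {
    if (is.null(supports)) return("")
    row <- supports[supports$node == k, ]
    sprintf("%d|%d", round(row$au * 100), round(row$bp * 100))
  }
  render <- function(idx, parent_height) {
    if (idx < 0) {             # leaf
      h <- parent_height
      paste0(quote_label(labels[-idx]), ":", sprintf("%.10g", h))
    } else {
      h <- height[idx]
      kids <- paste(render(merge[idx, 1], h), render(merge[idx, 2], h), sep = ",")
      paste0("(", kids, ")", node_label(idx), ":",
             sprintf("%.10g", parent_height - h))
    }
  }
  root <- n_int
  kids <- paste(render(merge[root, 1], height[root]),
                render(merge[root, 2], height[root]), sep = ",")
  nwk <- paste0("(", kids, ")", node_label(root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
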