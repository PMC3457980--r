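#' Define a treated-vs-control contrast
#'
#' Pairs one knockdown array with its siRNA-concentration-matched control
#' array. With a single array per condition the analysis unit is this pair.
#'
#' @param name Contrast label.
#' @param treated Treated (siRNA) sample id.
#' @param control Control sample id.
#' @return A one-row tibble with columns `name`, `treated`, `control`.
#' @export
contrast_spec <- function(name, treated, control) {
  if (identical(treated, control)) {
    abort("contrast treated and control samples must differ")
  }
  tibble::tibble(name = name, treated = treated, control = control)
}

#' Default contrasts of the six-array knockdown design
#'
#' The single knockdowns are compared against the low-concentration control
#' (`controlPlus`); the triple knockdown is paired with the high-concentration
#' control (`controlTriplePlus`) so that equal siRNA doses are compared.
#'
#' @return A four-row contrast tibble.
#' @export
default_contrasts <- function() {
  dplyr::bind_rows(
    contrast_spec("siFUS", "siFUS", "controlPlus"),
    contrast_spec("siEWS", "siEWS", "controlPlus"),
    contrast_spec("siTAF15", "siTAF15", "controlPlus"),
    contrast_spec("siTriple", "siTriple", "controlTriplePlus")
  )
}

#' Background-subtracted expression ratio
#'
#' `(treated - background) / (control - background)`, defined only when both
#' background-subtracted signals are positive; otherwise the ratio is `NA`
#' (an invalid record, not an error): a signal at or below background carries
#' no fold-change information.
#'
#' @param treated,control Numeric signal vectors (same length or length 1).
#' @param background Scalar background intensity.
#' @return Numeric vector of ratios, `NA` where invalid.
#' @export
compute_ratio <- function(treated, control, background) {
  stopifnot(length(background) == 1, is.finite(background))
  num <- treated - background
  den <- control - background
  ifelse(num > 0 & den > 0, num / den, NA_real_)
}

#' Classify a probe as up, down or unchanged
#'
#' The single-replicate DEG rule: `up` iff ratio > `up_threshold` and the
#' treated-group detection p-value < `alpha`; `down` iff ratio <
#' `down_threshold` and the control-group detection p-value < `alpha`;
#' otherwise `none`. All inequalities are strict. Invalid ratios (`NA`)
#' classify as `none`.
#'
#' @param ratio Numeric ratio vector (`NA` = invalid).
#' @param treated_p,control_p Detection p-value vectors.
#' @param up_threshold,down_threshold Ratio cut-offs (defaults 2 and 0.5).
#' @param alpha Detection p-value cut-off (default 0.05).
#' @return Character vector in `c("up", "down", "none")`.
#' @export
classify_deg <- function(ratio, treated_p, control_p,
                         up_threshold = 2, down_threshold = 0.5, alpha = 0.05) {
  up <- !is.na(ratio) & ratio > up_threshold & treated_p < alpha
  down <- !is.na(ratio) & ratio < down_threshold & control_p < alpha
  dplyr::case_when(up ~ "up", down ~ "down", .default = "none")
}

#' Call differentially expressed genes for one contrast
#'
#' Applies [compute_ratio()] and [classify_deg()] to every retained probe of
#' a preprocessed profile.
#'
#' @param prep A [preprocess_profile()] result.
#' @param contrast A one-row contrast tibble ([contrast_spec()]).
#' @param background Background intensity; defaults to the estimate carried
#'   by `prep`.
#' @param use_raw Compute ratios on raw (unnormalized) signals instead of the
#'   quantile-normalized ones; preserves the literal raw-intensity reading of
#'   the ratio formula.
#' @inheritParams classify_deg
#'
#' @return A `deg_table` tibble with one row per retained probe: `probe_id`,
#'   `treated_signal`, `control_signal`, `treated_p`, `control_p`, `ratio`,
#'   `valid`, `direction`. Contrast, thresholds and background are attached
#'   as attributes; see [glance.deg_table()] for the summary counts.
#' @export
call_degs <- function(prep, contrast, background = NULL, use_raw = FALSE,
                      up_threshold = 2, down_threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(prep, "bead_prep"), nrow(contrast) == 1)
  sig <- if (use_raw) prep$raw_signals else prep$signals
  for (s in c(contrast$treated, contrast$control)) {
    if (!s %in% names(sig)) {
      abort(paste0("unknown sample id in contrast: '", s, "'"))
    }
  }
  if (is.null(background)) background <- prep$background$value
  if (inherits(background, "background_estimate")) background <- background$value

  tab <- tibble::tibble(
    probe_id = sig$probe_id,
    treated_signal = sig[[contrast$treated]],
    control_signal = sig[[contrast$control]],
    treated_p = prep$detection_p[[contrast$treated]],
    control_p = prep$detection_p[[contrast$control]]
  )
  tab$ratio <- compute_ratio(tab$treated_signal, tab$control_signal, background)
  tab$valid <- !is.na(tab$ratio)
  tab$direction <- classify_deg(tab$ratio, tab$treated_p, tab$control_p,
                                up_threshold, down_threshold, alpha)
  structure(tab,
            class = c("deg_table", class(tab)),
            contrast = contrast$name,
            treated = contrast$treated,
            control = contrast$control,
            background = background,
            thresholds = c(up = up_threshold, down = down_threshold, alpha = alpha))
}

#' Summarize a DEG table
#'
#' @param x A `deg_table`.
#' @param ... Unused.
#' @return A one-row tibble: contrast, probe counts by direction, number of
#'   invalid records, and the thresholds/background used.
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    contrast = attr(x, "contrast"),
    n_probes = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_deg = sum(x$direction != "none"),
    n_invalid = sum(!x$valid),
    up_threshold = th[["up"]],
    down_threshold = th[["down"]],
    alpha = th[["alpha"]],
    background = attr(x, "background")
  )
}

#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Identifiers of the called DEGs
#'
#' @param deg_table A [call_degs()] result.
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return Character vector of probe ids.
#' @export
deg_ids <- function(deg_table, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") deg_table$direction != "none"
          else deg_table$direction == direction
  deg_table$probe_id[keep]
}

#' Collapse probe-level calls to gene level
#'
#' Optional gene-level view: per gene symbol, the probe with the largest
#' absolute log2 ratio represents the gene. Off the main path — the pipeline
#' counts probes, which is what a per-probe ratio rule natively produces.
#'
#' @param deg_table A [call_degs()] result.
#' @param probe_to_gene A tibble with columns `probe_id`, `gene`.
#' @return A `deg_table`-shaped tibble with one row per gene (column `gene`
#'   replacing `probe_id`, winning probe kept in `probe_id`).
#' @export
collapse_to_genes <- function(deg_table, probe_to_gene) {
  stopifnot(all(c("probe_id", "gene") %in% names(probe_to_gene)))
  joined <- dplyr::inner_join(tibble::as_tibble(deg_table), probe_to_gene,
                              by = "probe_id")
  joined |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(abs(log2(.data$ratio)), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::relocate("gene")
}
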