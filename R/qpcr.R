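#' Back-calculated initial template amount from a Cq value
#'
#' Under exponential amplification with per-cycle efficiency `E`, a reaction
#' crossing threshold at cycle `Cq` started from an amount proportional to
#' `E^(-Cq)` (arbitrary units). With `E = 2` (100% efficiency) this reduces
#' to the classic `2^(-Cq)` back-transformation.
#'
#' @param cq Numeric vector of quantification-cycle values (> 0).
#' @param efficiency Amplification efficiency as fold per cycle, in (1, 2\]
#'   (default 2, i.e. perfect doubling).
#' @return Numeric vector of initial amounts (arbitrary units).
#' @export
x0 <- function(cq, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2)) {
    abort("efficiency must be in (1, 2] (fold per cycle)")
  }
  if (any(cq <= 0)) abort("Cq values must be positive")
  efficiency^(-cq)
}

#' Reference-normalized relative expression from qPCR Cq values
#'
#' Efficiency-corrected relative quantification: each well's Cq is
#' back-transformed to a linear-scale initial amount with [x0()], technical
#' replicates are averaged on the X0 scale (the linear scale the method is
#' built around, not on the Cq scale), the target is normalized to the
#' reference gene within each sample, and expression is reported relative to
#' the control sample:
#' `value = (X0_target/X0_ref)_sample / (X0_target/X0_ref)_control`.
#' The replicate scatter of each of the four X0 means is propagated to the
#' ratio by first-order (relative-variance) error propagation.
#'
#' With all efficiencies equal to 2, `value` equals the classic
#' `2^(-ddCq)` quantity. Adding a constant to every Cq leaves `value`
#' unchanged (the shift cancels in the double ratio).
#'
#' @param wells A tibble of replicate wells with columns `sample`, `gene`,
#'   `cq`, and optionally `efficiency` (default 2; must be constant within a
#'   gene, since the standard-curve efficiency is a property of the assay).
#' @param control Control sample id (the denominator condition).
#' @param reference Reference (housekeeping) gene id (default `"GAPDH"`).
#' @return A tibble with one row per (sample, gene) excluding the reference
#'   gene: `gene`, `sample`, `control`, `value` (fold vs control), `sd`
#'   (propagated from technical replicates; 0 when replicates are absent),
#'   `n_replicates`.
#' @export
relative_expression <- function(wells, control, reference = "GAPDH") {
  stopifnot(is.data.frame(wells),
            all(c("sample", "gene", "cq") %in% names(wells)))
  if (!"efficiency" %in% names(wells)) wells$efficiency <- 2
  if (!control %in% wells$sample) {
    abort(paste0("control sample '", control, "' not present in wells"))
  }
  if (!reference %in% wells$gene) {
    abort(paste0("reference gene '", reference, "' not present in wells"))
  }
  eff_per_gene <- wells |>
    dplyr::distinct(.data$gene, .data$efficiency) |>
    dplyr::count(.data$gene)
  if (any(eff_per_gene$n > 1)) {
    abort(paste0("efficiency differs across wells of the same assay: ",
                 paste(eff_per_gene$gene[eff_per_gene$n > 1], collapse = ", ")))
  }

  agg <- wells |>
    dplyr::mutate(x0 = x0(.data$cq, .data$efficiency)) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(mean_x0 = mean(.data$x0),
                     sd_x0 = ifelse(dplyr::n() > 1, sd(.data$x0), 0),
                     n_replicates = dplyr::n(), .groups = "drop")

  ref <- agg |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::select("sample", ref_x0 = "mean_x0", ref_sd = "sd_x0")
  targets <- agg |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::inner_join(ref, by = "sample")
  missing_ref <- setdiff(unique(agg$sample), ref$sample)
  if (length(missing_ref) > 0) {
    abort(paste0("reference gene '", reference, "' missing for sample(s): ",
                 paste(missing_ref, collapse = ", ")))
  }

  ctrl <- targets |>
    dplyr::filter(.data$sample == control) |>
    dplyr::select("gene", ctrl_x0 = "mean_x0", ctrl_sd = "sd_x0",
                  ctrl_ref_x0 = "ref_x0", ctrl_ref_sd = "ref_sd")
  out <- targets |>
    dplyr::inner_join(ctrl, by = "gene") |>
    dplyr::mutate(
      value = (.data$mean_x0 / .data$ref_x0) /
              (.data$ctrl_x0 / .data$ctrl_ref_x0),
      sd = .data$value * sqrt((.data$sd_x0 / .data$mean_x0)^2 +
                              (.data$ref_sd / .data$ref_x0)^2 +
                              (.data$ctrl_sd / .data$ctrl_x0)^2 +
                              (.data$ctrl_ref_sd / .data$ctrl_ref_x0)^2),
      control = control
    ) |>
    dplyr::select("gene", "sample", "control", "value", "sd", "n_replicates") |>
    dplyr::arrange(.data$gene, .data$sample)
  structure(out, class = c("relative_expression", class(out)))
}

#' @method tidy relative_expression
#' @export
tidy.relative_expression <- function(x, ...) tibble::as_tibble(x)
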