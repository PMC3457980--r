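#' Configuration for a synthetic six-array knockdown experiment
#'
#' Defines a BeadChip-like experiment with three single knockdowns
#' (`siFUS`, `siEWS`, `siTAF15`), one triple knockdown (`siTriple`) and two
#' controls matched to the single and triple siRNA concentrations
#' (`controlPlus`, `controlTriplePlus`). Regular-probe baselines are
#' log-normal; per-array measurement noise is log-normal; negative-control
#' probes are drawn identically in every array with mean `negctrl_mean`.
#' Knockdown effects are multiplicative folds planted on probes expressed
#' well above background (baseline above `fold_range[2] * negctrl_mean`, so
#' that a maximal down-fold still leaves signal above background — an effect
#' on an unexpressed transcript is unobservable under a ratio rule).
#'
#' The defaults emulate the scale of a whole-genome six-array study: 48,803
#' probes, a background of 28 intensity units, roughly 0.6% of probes
#' perturbed per knockdown, with 14% of each single knockdown's effects
#' shared between siFUS and siTAF15, 7% shared by all three, and 80% of the
#' triple knockdown's effects unique to it.
#'
#' @param n_probes Total probes including negative controls.
#' @param n_negative_controls Number of negative-control probes.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of regular
#'   probe baseline intensities.
#' @param noise_log_sd Natural-log sd of per-array measurement noise.
#' @param negctrl_mean Mean negative-control intensity (the intended
#'   background).
#' @param negctrl_log_sd Natural-log sd of negative-control intensities.
#' @param frac_deg_per_group Fraction of regular probes perturbed per
#'   knockdown.
#' @param frac_shared_fus_taf15 Fraction of each single knockdown's effects
#'   shared between siFUS and siTAF15 (includes the all-three share).
#' @param frac_shared_all Fraction shared by all three single knockdowns.
#' @param frac_triple_unique Fraction of the triple knockdown's effects
#'   absent from every single knockdown.
#' @param fold_range Multiplicative effect-size range `(low, high)`,
#'   `low > 1`.
#' @param down_fraction Fraction of planted effects that are decreases.
#' @param seed Integer seed; the same configuration always yields the same
#'   experiment.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_probes = 48803,
                       n_negative_controls = 800,
                       baseline_log_mean = 4.0,
                       baseline_log_sd = 1.5,
                       noise_log_sd = 0.08,
                       negctrl_mean = 28,
                       negctrl_log_sd = 0.4,
                       frac_deg_per_group = 0.0064,
                       frac_shared_fus_taf15 = 0.14,
                       frac_shared_all = 0.07,
                       frac_triple_unique = 0.80,
                       fold_range = c(2.5, 8),
                       down_fraction = 0.56,
                       seed = 1L) {
  cfg <- list(n_probes = n_probes, n_negative_controls = n_negative_controls,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, noise_log_sd = noise_log_sd,
              negctrl_mean = negctrl_mean, negctrl_log_sd = negctrl_log_sd,
              frac_deg_per_group = frac_deg_per_group,
              frac_shared_fus_taf15 = frac_shared_fus_taf15,
              frac_shared_all = frac_shared_all,
              frac_triple_unique = frac_triple_unique,
              fold_range = fold_range, down_fraction = down_fraction,
              seed = as.integer(seed))
  for (f in c("frac_deg_per_group", "frac_shared_fus_taf15", "frac_shared_all",
              "frac_triple_unique", "down_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(paste0("sim_config field '", f, "' must be a fraction in [0, 1]"))
    }
  }
  if (cfg$frac_shared_all > cfg$frac_shared_fus_taf15) {
    abort("sim_config: frac_shared_all must not exceed frac_shared_fus_taf15")
  }
  for (f in c("baseline_log_sd", "noise_log_sd", "negctrl_log_sd")) {
    if (cfg[[f]] < 0) abort(paste0("sim_config field '", f, "' must be >= 0"))
  }
  for (f in c("negctrl_mean", "baseline_log_mean")) {
    if (cfg[[f]] <= 0) abort(paste0("sim_config field '", f, "' must be positive"))
  }
  if (length(cfg$fold_range) != 2 || cfg$fold_range[1] <= 1 ||
      cfg$fold_range[2] < cfg$fold_range[1]) {
    abort("sim_config field 'fold_range' must be (low, high) with low > 1")
  }
  if (cfg$n_negative_controls >= cfg$n_probes) {
    abort("sim_config: n_negative_controls must be smaller than n_probes")
  }
  if (cfg$n_negative_controls < 1 || cfg$n_probes < 2) {
    abort("sim_config: n_probes and n_negative_controls must be positive")
  }
  structure(cfg, class = "sim_config")
}

sim_groups <- function() {
  c("siFUS", "siEWS", "siTAF15", "siTriple", "controlPlus", "controlTriplePlus")
}

#' Simulate a probe-profile experiment with known ground truth
#'
#' Draws a six-array probe-profile table under a [sim_config()] and records
#' every planted effect. Knockdown groups perturb disjoint-or-shared probe
#' sets according to the configured sharing structure; the triple knockdown
#' inherits the union of the single-knockdown effects (same fold, not
#' resampled) plus an independent triple-unique set. Both control arrays are
#' draws from the same null distribution. Detection p-values are computed
#' per array against that array's negative-control intensities with
#' [compute_detection_p()].
#'
#' @param config A [sim_config()].
#' @return A list with `profile` (canonical probe-profile tibble) and
#'   `truth` (tibble `probe_id`, `group`, `log2_fold` of planted effects).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- sim_groups()
  n_reg <- config$n_probes - config$n_negative_controls
  reg_ids <- sprintf("P%06d", seq_len(n_reg))
  nc_ids <- sprintf("NC%04d", seq_len(config$n_negative_controls))

  baseline <- rlnorm(n_reg, config$baseline_log_mean, config$baseline_log_sd)

  truth <- plant_effects(config, baseline, reg_ids)
  effect_mat <- matrix(0, n_reg, length(groups),
                       dimnames = list(reg_ids, groups))
  if (nrow(truth) > 0) {
    effect_mat[cbind(match(truth$probe_id, reg_ids),
                     match(truth$group, groups))] <- truth$log2_fold
  }

  sig <- matrix(0, config$n_probes, length(groups),
                dimnames = list(c(reg_ids, nc_ids), groups))
  nc_meanlog <- log(config$negctrl_mean) - config$negctrl_log_sd^2 / 2
  for (g in seq_along(groups)) {
    noise <- if (config$noise_log_sd > 0) {
      exp(rnorm(n_reg, 0, config$noise_log_sd))
    } else rep(1, n_reg)
    sig[seq_len(n_reg), g] <- baseline * 2^effect_mat[, g] * noise
    sig[n_reg + seq_len(config$n_negative_controls), g] <-
      rlnorm(config$n_negative_controls, nc_meanlog, config$negctrl_log_sd)
  }

  det <- matrix(0, config$n_probes, length(groups))
  for (g in seq_along(groups)) {
    ncv <- sig[n_reg + seq_len(config$n_negative_controls), g]
    det[, g] <- compute_detection_p(sig[, g], ncv)
  }

  profile <- tibble::tibble(
    PROBE_ID = c(reg_ids, nc_ids),
    PROBE_CLASS = rep(c("regular", "negative_control"),
                      c(n_reg, config$n_negative_controls))
  )
  for (g in seq_along(groups)) {
    profile[[paste0(groups[g], ".AVG_Signal")]] <- sig[, g]
    profile[[paste0(groups[g], ".Detection_Pval")]] <- det[, g]
  }
  list(profile = profile, truth = truth)
}

# Draw the planted-effect map honouring the sharing structure. Effects on
# shared probes are identical across the sharing groups; the triple group
# reuses every single-group effect and adds its own unique set.
plant_effects <- function(config, baseline, reg_ids) {
  n_reg <- length(baseline)
  n_deg <- round(config$frac_deg_per_group * n_reg)
  empty <- tibble::tibble(probe_id = character(0), group = character(0),
                          log2_fold = numeric(0))
  if (n_deg == 0) return(empty)

  eligible <- which(baseline > config$fold_range[2] * config$negctrl_mean)
  n_all <- round(config$frac_shared_all * n_deg)
  n_ft <- round(config$frac_shared_fus_taf15 * n_deg)
  n_ft_only <- n_ft - n_all
  n_fus_u <- n_deg - n_ft
  n_taf_u <- n_deg - n_ft
  n_ews_u <- n_deg - n_all
  n_union <- n_all + n_ft_only + n_fus_u + n_taf_u + n_ews_u
  n_triple_u <- if (config$frac_triple_unique >= 1) {
    abort("frac_triple_unique must be < 1 when single-knockdown effects exist")
  } else {
    round(n_union * config$frac_triple_unique / (1 - config$frac_triple_unique))
  }
  need <- n_union + n_triple_u
  if (length(eligible) < need) {
    abort(paste0("only ", length(eligible), " probes have baseline above ",
                 "fold_range[2] * negctrl_mean but ", need,
                 " planted effects are requested; raise baseline_log_mean or ",
                 "lower frac_deg_per_group"))
  }
  picked <- sample(eligible, need)
  splits <- rep(c("all", "ft", "fus", "taf", "ews", "triple"),
                c(n_all, n_ft_only, n_fus_u, n_taf_u, n_ews_u, n_triple_u))
  draw_effect <- function(n) {
    fold <- runif(n, config$fold_range[1], config$fold_range[2])
    sign <- ifelse(runif(n) < config$down_fraction, -1, 1)
    sign * log2(fold)
  }
  eff <- draw_effect(need)
  ids <- reg_ids[picked]

  assign_to <- list(all = c("siFUS", "siEWS", "siTAF15"),
                    ft = c("siFUS", "siTAF15"),
                    fus = "siFUS", taf = "siTAF15", ews = "siEWS",
                    triple = character(0))
  rows <- purrr::map_dfr(seq_along(ids), function(i) {
    gs <- assign_to[[splits[i]]]
    single <- if (length(gs) > 0) {
      tibble::tibble(probe_id = ids[i], group = gs, log2_fold = eff[i])
    } else empty
    # the triple knockdown carries every effect (union) plus its unique set
    dplyr::bind_rows(single,
                     tibble::tibble(probe_id = ids[i], group = "siTriple",
                                    log2_fold = eff[i]))
  })
  dplyr::arrange(rows, .data$group, .data$probe_id)
}

#' Write or read a planted-truth table
#'
#' @param truth A truth tibble (`probe_id`, `group`, `log2_fold`).
#' @param path File path.
#' @return `write_truth()`: `path` invisibly; `read_truth()`: the tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    group = readr::col_character(),
    log2_fold = readr::col_double()
  ), progress = FALSE)
}

#' Planted probe ids for one group
#'
#' @param truth A truth tibble.
#' @param group Group label, e.g. `"siFUS"`.
#' @return Character vector of perturbed probe ids.
#' @export
truth_ids <- function(truth, group) {
  unique(truth$probe_id[truth$group == group])
}
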