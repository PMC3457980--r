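test_that("background-subtracted ratios follow the formula and flag degenerates", {
  expect_equal(compute_ratio(228, 128, 28), 2)
  expect_equal(compute_ratio(150, 150, 28), 1)
  expect_equal(compute_ratio(57, 57, 3), 1)
  expect_true(is.na(compute_ratio(100, 28, 28)))   # zero denominator
  expect_true(is.na(compute_ratio(28, 100, 28)))   # zero numerator
  expect_true(is.na(compute_ratio(10, 100, 28)))   # below background
})

test_that("the DEG rule classifies by strict thresholds and detection calls", {
  # a 17-fold induction with confident detection is up
  expect_equal(classify_deg(17, 0.001, 0.5), "up")
  # 1.8-fold misses the > 2 criterion whatever the p-value
  expect_equal(classify_deg(1.8, 1e-6, 1e-6), "none")
  expect_equal(classify_deg(0.4, 0.9, 0.01), "down")
  expect_equal(classify_deg(2.5, 0.2, 0.2), "none")  # undetected in treated
  expect_equal(classify_deg(NA_real_, 0.001, 0.001), "none")
  # thresholds are strict
  expect_equal(classify_deg(2, 0.001, 0.001), "none")
  expect_equal(classify_deg(0.5, 0.001, 0.001), "none")
})

test_that("ratio antisymmetry: swapping treated and control inverts the call", {
  set.seed(21)
  t <- runif(200, 30, 500); c <- runif(200, 30, 500)
  r <- compute_ratio(t, c, 28)
  r_swap <- compute_ratio(c, t, 28)
  expect_equal(r_swap, 1 / r, tolerance = 1e-12)
  pt <- runif(200, 0, 0.04); pc <- runif(200, 0, 0.04)
  d <- classify_deg(r, pt, pc)
  d_swap <- classify_deg(r_swap, pc, pt)
  expect_equal(d_swap == "up", d == "down")
  expect_equal(d_swap == "down", d == "up")
  # no record is ever both up and down
  expect_true(all(d %in% c("up", "down", "none")))
})

test_that("increasing the treated signal never demotes an up call", {
  grid <- seq(30, 2000, by = 10)
  calls <- classify_deg(compute_ratio(grid, 100, 28), 0.01, 0.01)
  first_up <- match("up", calls)
  expect_false(is.na(first_up))
  expect_true(all(calls[first_up:length(calls)] == "up"))
})

test_that("a null experiment yields zero DEGs and unit ratios", {
  cfg <- small_cfg(frac_deg_per_group = 0, noise_log_sd = 0)
  sim <- simulate_experiment(cfg)
  prep <- preprocess_profile(sim$profile)
  dt <- call_degs(prep, contrast_spec("siFUS", "siFUS", "controlPlus"))
  g <- glance(dt)
  expect_equal(g$n_up, 0)
  expect_equal(g$n_down, 0)
  expect_true(all(abs(dt$ratio[dt$valid] - 1) < 1e-12))
})

test_that("planted folds of 4 up and 0.25 down are recovered exactly", {
  set.seed(8)
  n <- 2000
  baseline <- rlnorm(n, 6.5, 0.5)          # all well above background
  treated <- baseline
  treated[1:50] <- baseline[1:50] * 4
  treated[51:100] <- baseline[51:100] * 0.25
  noise <- function(x) x * exp(rnorm(n, 0, 0.02))
  cols <- c("kd", "ctrl", "o1", "o2", "o3", "o4")
  sig <- cbind(kd = noise(treated), ctrl = noise(baseline),
               o1 = noise(baseline), o2 = noise(baseline),
               o3 = noise(baseline), o4 = noise(baseline))
  negctrl <- rlnorm(80, log(28) - 0.08, 0.4)
  det <- apply(sig, 2, compute_detection_p, negctrl_intensities = negctrl)
  profile <- make_profile(
    rbind(sig, matrix(rep(negctrl, 6), 80, 6, dimnames = list(NULL, cols))),
    rbind(det, matrix(0.5, 80, 6, dimnames = list(NULL, cols))),
    probe_class = rep(c("regular", "negative_control"), c(n, 80)))
  prep <- preprocess_profile(profile)
  # on the raw intensity scale the planted calls are recovered exactly
  dt <- call_degs(prep, contrast_spec("kd", "kd", "ctrl"), use_raw = TRUE)
  g <- glance(dt)
  expect_equal(g$n_up, 50)
  expect_equal(g$n_down, 50)
  expect_setequal(deg_ids(dt, "up"), sprintf("P%04d", 1:50))
  expect_setequal(deg_ids(dt, "down"), sprintf("P%04d", 51:100))
  # quantile normalization equalizes the columns against the single perturbed
  # array, compressing ratios near the thresholds: recovery stays high but is
  # not exact
  dtn <- call_degs(prep, contrast_spec("kd", "kd", "ctrl"))
  recovered <- deg_ids(dtn)
  expect_gte(mean(sprintf("P%04d", 1:100) %in% recovered), 0.9)
  expect_lte(length(setdiff(recovered, sprintf("P%04d", 1:100))) /
               (nrow(dtn) - 100), 0.01)
})

test_that("call_degs validates contrast samples and records provenance", {
  cfg <- small_cfg()
  prep <- preprocess_profile(simulate_experiment(cfg)$profile)
  expect_error(call_degs(prep, contrast_spec("x", "nope", "controlPlus")),
               "unknown sample id")
  dt <- call_degs(prep, contrast_spec("siFUS", "siFUS", "controlPlus"))
  expect_equal(attr(dt, "thresholds"),
               c(up = 2, down = 0.5, alpha = 0.05))
  expect_equal(attr(dt, "background"), prep$background$value)
  expect_equal(nrow(dt), prep$retained_count)
  # use_raw switches the intensity source
  dtr <- call_degs(prep, contrast_spec("siFUS", "siFUS", "controlPlus"),
                   use_raw = TRUE)
  expect_equal(dtr$treated_signal, prep$raw_signals$siFUS)
})

test_that("contrast construction rejects self-pairs and ships study defaults", {
  expect_error(contrast_spec("x", "a", "a"), "must differ")
  dc <- default_contrasts()
  expect_equal(dc$control[dc$treated == "siTriple"], "controlTriplePlus")
  expect_equal(unique(dc$control[dc$treated != "siTriple"]), "controlPlus")
})

test_that("gene-level collapse keeps the strongest probe per gene", {
  tab <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    treated_signal = c(100, 400, 50), control_signal = c(100, 100, 100),
    treated_p = 0.01, control_p = 0.01,
    ratio = c(1.5, 4, 0.2), valid = TRUE,
    direction = c("none", "up", "down")
  )
  class(tab) <- c("deg_table", class(tab))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        gene = c("G1", "G1", "G2"))
  out <- collapse_to_genes(tab, map)
  expect_equal(nrow(out), 2)
  expect_equal(out$probe_id[out$gene == "G1"], "p2")
})
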