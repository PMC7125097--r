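#' Run the full single-animal pipeline
#'
#' Block-averages a raw recording, computes the six autoregulation indices,
#' estimates the LLA from (ABP, LDF), partitions each index above/below the
#' LLA, computes above-LLA index SDs, and derives the multi-window ABPopt
#' for each index.
#'
#' @param rec a `raw_recording`.
#' @param wconfig a [wavelet_config()].
#' @param truth optional `ground_truth` carried through for recovery
#'   summaries.
#' @return list with `sw`, `indices`, `lla`, `paired` (above/below means per
#'   index), `sd_above` (per index), `abpopt` (per index,
#'   `abpopt_estimate`s), `truth`, `animal_id`.
#' @export
run_animal <- function(rec, wconfig = wavelet_config(), truth = NULL) {
  sw <- block_average(rec)
  idx <- all_indices(sw, wconfig)
  lla <- find_lla(sw)
  paired <- lapply(idx, paired_above_below, sw = sw, lla = lla)
  sd_above <- vapply(idx, function(ix) {
    abp <- sw$abp[match(ix$time_s, sw$time_s)]
    v <- ix$value[is.finite(ix$value) & is.finite(abp) & abp >= lla$lla]
    if (length(v) > 1) stats::sd(v) else NA_real_
  }, numeric(1))
  abpopt <- lapply(idx, multiwindow_abpopt, sw = sw, lla = lla)
  list(sw = sw, indices = idx, lla = lla, paired = paired,
       sd_above = sd_above, abpopt = abpopt, truth = truth,
       animal_id = rec$animal_id)
}

#' Simulate a cohort of piglet recordings
#'
#' Draws per-animal true LLAs uniformly from `lla_range` (true ABPopt is
#' `lla + abpopt_offset`) and generates one recording per animal with
#' deterministic per-animal seeds derived from `seed`.
#'
#' @param n number of animals.
#' @param seed cohort base seed.
#' @param lla_range range (mmHg) of true LLAs.
#' @param abpopt_offset true ABPopt minus true LLA (mmHg).
#' @param ... further arguments passed to [sim_config()].
#' @return list of `generate_recording()` results.
#' @export
simulate_cohort <- function(n, seed = 1L, lla_range = c(35, 55),
                            abpopt_offset = 20, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  llas <- stats::runif(n, lla_range[1], lla_range[2])
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    cfg <- sim_config(lla_true = llas[i],
                      abpopt_true = llas[i] + abpopt_offset,
                      seed = seeds[i],
                      animal_id = sprintf("sim%02d", i), ...)
    generate_recording(cfg)
  })
}

#' Run the cohort experiment end to end
#'
#' Simulates (or accepts) a cohort, runs the per-animal pipeline, and
#' computes the cohort statistics: per-index paired ROC of below- vs
#' above-LLA per-animal means with DeLong comparisons of each
#' wavelet/correlation pair, paired t-tests on the above-LLA index SDs,
#' and Pearson + Bland-Altman agreement of wavelet vs correlation ABPopt.
#'
#' @param n_animals cohort size (used when `recordings` is NULL).
#' @param seed cohort seed.
#' @param recordings optional list of `generate_recording()`-style results
#'   to analyze instead of simulating.
#' @param wconfig a [wavelet_config()].
#' @param ... passed to [simulate_cohort()].
#' @return list with `animals` (per-animal results), `stats` (see
#'   [cohort_stats()]), `seed`.
#' @export
run_cohort <- function(n_animals = 30L, seed = 1L, recordings = NULL,
                       wconfig = wavelet_config(), ...) {
  if (is.null(recordings))
    recordings <- simulate_cohort(n_animals, seed = seed, ...)
  animals <- lapply(recordings, function(r)
    run_animal(r$recording, wconfig = wconfig, truth = r$truth))
  list(animals = animals, stats = cohort_stats(animals), seed = seed)
}

#' Index names and wavelet/correlation pairings
#'
#' The six autoregulation indices the pipeline computes, and the three
#' wavelet/correlation pairs compared throughout the evaluation.
#' @export
INDEX_NAMES <- c("PRx", "COx", "HVx", "wPRx", "wCOx", "wHVx")

#' @rdname INDEX_NAMES
#' @export
INDEX_PAIRS <- list(c("PRx", "wPRx"), c("COx", "wCOx"), c("HVx", "wHVx"))

#' Cohort-level statistics from per-animal results
#'
#' @param animals list of [run_animal()] results.
#' @return list with `roc` (per-index `roc_result` on per-animal paired
#'   means, positive class = below LLA), `delong` (per wavelet/correlation
#'   pair), `sd_table` (per-animal above-LLA SDs), `sd_tests` (paired t,
#'   correlation minus wavelet), `abpopt_table`, `abpopt_agreement`
#'   (Pearson r and Bland-Altman per pair), `vertex_counts` (animals with an
#'   identified ABPopt per index), `paired_tests` (below vs above means),
#'   and `lla_table`.
#' @export
cohort_stats <- function(animals) {
  pull_means <- function(side) vapply(
    INDEX_NAMES,
    function(nm) vapply(animals, function(an) an$paired[[nm]][[side]],
                        numeric(1)),
    numeric(length(animals)))
  above <- pull_means("above"); below <- pull_means("below")

  roc <- lapply(INDEX_NAMES, function(nm) {
    sc <- c(above[, nm], below[, nm])
    lab <- rep(c(FALSE, TRUE), each = length(animals))
    ok <- is.finite(sc)
    roc_with_cutoff(sc[ok], lab[ok])
  })
  names(roc) <- INDEX_NAMES

  delong <- lapply(INDEX_PAIRS, function(pr) {
    sc_a <- c(above[, pr[1]], below[, pr[1]])
    sc_b <- c(above[, pr[2]], below[, pr[2]])
    lab <- rep(c(FALSE, TRUE), each = length(animals))
    ok <- is.finite(sc_a) & is.finite(sc_b)
    delong_test(sc_a[ok], sc_b[ok], lab[ok])
  })
  names(delong) <- vapply(INDEX_PAIRS, paste, collapse = "_vs_", "")

  sd_table <- t(vapply(animals, function(an) an$sd_above,
                       numeric(length(INDEX_NAMES))))
  colnames(sd_table) <- INDEX_NAMES
  sd_tests <- lapply(INDEX_PAIRS, function(pr)
    paired_t(sd_table[, pr[1]], sd_table[, pr[2]]))
  names(sd_tests) <- names(delong)

  paired_tests <- lapply(INDEX_NAMES, function(nm) {
    ok <- is.finite(below[, nm]) & is.finite(above[, nm])
    paired_t(below[ok, nm], above[ok, nm])
  })
  names(paired_tests) <- INDEX_NAMES

  abpopt_table <- t(vapply(animals, function(an)
    vapply(INDEX_NAMES, function(nm) an$abpopt[[nm]]$abpopt, numeric(1)),
    numeric(length(INDEX_NAMES))))
  colnames(abpopt_table) <- INDEX_NAMES
  abpopt_agreement <- lapply(INDEX_PAIRS, function(pr) {
    a <- abpopt_table[, pr[2]]; b <- abpopt_table[, pr[1]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(NULL)
    bland_altman(a[ok], b[ok])
  })
  names(abpopt_agreement) <- names(delong)
  vertex_counts <- colSums(is.finite(abpopt_table))

  lla_table <- data.frame(
    animal = vapply(animals, function(an) an$animal_id, ""),
    lla = vapply(animals, function(an) an$lla$lla, numeric(1)),
    lla_true = vapply(animals, function(an)
      if (is.null(an$truth)) NA_real_ else an$truth$lla_true, numeric(1)),
    abpopt_true = vapply(animals, function(an)
      if (is.null(an$truth)) NA_real_ else an$truth$abpopt_true, numeric(1))
  )

  list(roc = roc, delong = delong, sd_table = sd_table, sd_tests = sd_tests,
       paired_tests = paired_tests, abpopt_table = abpopt_table,
       abpopt_agreement = abpopt_agreement, vertex_counts = vertex_counts,
       lla_table = lla_table,
       above_means = above, below_means = below)
}

#' Table of per-index discrimination statistics
#'
#' One row per index: n, AUC, p vs chance, Youden cutoff, sensitivity and
#' specificity with 95% CIs.
#'
#' @param stats a [cohort_stats()] result.
#' @return data.frame.
#' @export
discrimination_table <- function(stats) {
  do.call(rbind, lapply(INDEX_NAMES, function(nm) {
    r <- stats$roc[[nm]]
    data.frame(index = nm, n = r$n_pos, auc = r$auc, p = r$p_vs_chance,
               cutoff = r$cutoff,
               sensitivity = r$sensitivity,
               sens_lo = r$sens_ci[1], sens_hi = r$sens_ci[2],
               specificity = r$specificity,
               spec_lo = r$spec_ci[1], spec_hi = r$spec_ci[2])
  }))
}

# Polynomial rolling hash of a deparse()d object (stays within 2^31 so
# integer arithmetic is exact), for provenance stamps in outputs.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write cohort results to JSON
#'
#' Serializes the cohort statistics (plus seed and a config hash for
#' provenance) as JSON.
#'
#' @param cohort a [run_cohort()] result.
#' @param path output path.
#' @param config optional configuration object to hash into the stamp.
#' @return `path`, invisibly.
#' @export
write_cohort_json <- function(cohort, path, config = NULL) {
  st <- cohort$stats
  out <- list(
    seed = cohort$seed,
    config_hash = .config_hash(config %||% "default"),
    discrimination = discrimination_table(st),
    delong = st$delong,
    sd_tests = st$sd_tests,
    sd_means = as.list(colMeans(st$sd_table, na.rm = TRUE)),
    abpopt = as.data.frame(st$abpopt_table),
    abpopt_agreement = st$abpopt_agreement,
    vertex_counts = as.list(st$vertex_counts),
    lla = st$lla_table
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Error-bar U-curve plot for one binned index curve
#'
#' Base-graphics error-bar chart of the Fisher-transformed index means
#' against the 5-mmHg bin centres, with the fitted quadratic and its vertex
#' when one exists.
#'
#' @param curve a `binned_index_curve`.
#' @param main plot title.
#' @return the [fit_u_vertex()] result (or NULL), invisibly.
#' @export
plot_u_curve <- function(curve, main = "index vs ABP") {
  sem <- ifelse(is.na(curve$sem_z), 0, curve$sem_z)
  ylim <- range(curve$mean_z - sem, curve$mean_z + sem)
  plot(curve$bin_center, curve$mean_z, pch = 19, xlab = "ABP (mmHg)",
       ylab = "Fisher-z index", main = main, ylim = ylim)
  arrows(curve$bin_center, curve$mean_z - sem, curve$bin_center,
         curve$mean_z + sem, angle = 90, code = 3, length = 0.03)
  fit <- if (nrow(curve) >= 4) fit_u_vertex(curve) else NULL
  if (!is.null(fit) && fit$shape != "none") {
    xs <- seq(min(curve$bin_center), max(curve$bin_center), length.out = 100)
    lines(xs, fit$c + fit$b * xs + fit$a * xs^2, col = "steelblue")
    abline(v = fit$vertex, lty = 2, col = "steelblue")
  }
  invisible(fit)
}

#' Bland-Altman plot of two ABPopt estimates
#'
#' @param a,b paired estimates (a - b on the y axis).
#' @param main plot title.
#' @return the [bland_altman()] result, invisibly.
#' @export
plot_bland_altman <- function(a, b, main = "Bland-Altman") {
  ba <- bland_altman(a, b)
  ok <- is.finite(a) & is.finite(b)
  plot((a[ok] + b[ok]) / 2, a[ok] - b[ok], pch = 19,
       xlab = "mean (mmHg)", ylab = "difference (mmHg)", main = main)
  abline(h = c(ba$bias, ba$loa_lower, ba$loa_upper),
         lty = c(1, 2, 2), col = "firebrick")
  invisible(ba)
}
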