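#' Default end-to-end pipeline configuration
#'
#' Every stage seed derives deterministically from the global `seed`, so a
#' rerun with the same configuration is byte-identical. The default scale is
#' deliberately small (a desk-scale study: few participants, short
#' sequences, modest stimulus manifest) so the whole pipeline runs in
#' seconds; the parametric peak table used for model fitting keeps the full
#' 34 x 7 study design.
#'
#' @param seed Global integer seed.
#' @param n_participants Participants for the parametric peak table.
#' @param conditions Named jitter rates for the modeled conditions.
#' @param epoch_participants,epoch_conditions Scale of the waveform-level
#'   (epoch) demonstration path.
#' @param n_sounds Events per roving sequence.
#' @param sfreq Epoch sampling rate, Hz.
#' @param noise_sd Epoch noise SD, uV.
#' @param manifest_n_per_cell Patterns per (f0, condition) manifest cell.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_participants = 34L,
                       conditions = jitter_schedule()[2:8],
                       epoch_participants = 4L, epoch_conditions = 4L,
                       n_sounds = 120L, sfreq = 250,
                       noise_sd = 1, manifest_n_per_cell = 10L) {
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 conditions = conditions,
                 epoch_participants = epoch_participants,
                 epoch_conditions = epoch_conditions,
                 n_sounds = n_sounds, sfreq = sfreq, noise_sd = noise_sd,
                 manifest_n_per_cell = manifest_n_per_cell),
            class = "run_config")
}

stage_seed <- function(config, offset) {
  (config$seed + 1000L * offset) %% .Machine$integer.max
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, in order: stimulus manifest, labeled roving sequence, synthetic
#' epochs measured through the ERP path, parametric peak table, sigmoid /
#' linear / quadratic / null mixed-model fits with likelihood-ratio tests,
#' and per-condition t-tests plus repeated-measures ANOVA. Writes the
#' tabular artifacts as CSV and a machine-readable `summary.json` (stage
#' seeds, timings, fit parameters) into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("inharmmn_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # 1. stimulus manifest (no audio rendered)
  t0 <- tic()
  manifest <- stimulus_manifest(seq(200, 500, by = 50),
                                jitter_schedule()[1:8],
                                config$manifest_n_per_cell,
                                seed = stage_seed(config, 1L))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  timings$manifest <- toc(t0)

  # 2. roving sequence with role labels
  t0 <- tic()
  set.seed(stage_seed(config, 2L))
  sequence <- label_events(generate_roving_sequence(config$n_sounds))
  utils::write.csv(sequence$events, file.path(out_dir, "sequence.csv"),
                   row.names = FALSE)
  timings$sequence <- toc(t0)

  # 3. synthetic epochs -> measured peak table (waveform path, small scale)
  t0 <- tic()
  gp_epochs <- generative_params(
    conditions = config$conditions[seq_len(config$epoch_conditions)],
    n_participants = config$epoch_participants,
    seed = stage_seed(config, 3L))
  epoch_sets <- list()
  for (p in seq_len(config$epoch_participants)) {
    for (ci in seq_len(config$epoch_conditions)) {
      set.seed(stage_seed(config, 3L) + 97L * p + ci)
      epoch_sets[[length(epoch_sets) + 1L]] <-
        generate_epochs(gp_epochs, sequence, participant = p, condition = ci,
                        sfreq = config$sfreq, noise_sd = config$noise_sd)
    }
  }
  measured <- peak_table_from_epochs(epoch_sets, gp_epochs$conditions)
  utils::write.csv(measured, file.path(out_dir, "peaks_measured.csv"),
                   row.names = FALSE)
  timings$epochs <- toc(t0)

  # 4. parametric peak table at study scale + model fits
  t0 <- tic()
  gp <- generative_params(conditions = config$conditions,
                          n_participants = config$n_participants,
                          seed = stage_seed(config, 4L))
  peaks <- generate_peak_table(gp)
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)

  fit_sig <- fit_sigmoid_mixed(peaks)
  fit_null <- fit_null_mixed(peaks)
  fit_lin <- fit_polynomial_mixed(peaks, degree = 1L)
  fit_quad_p3a <- fit_polynomial_mixed(peaks, response = "p3a_amplitude",
                                       degree = 2L)
  lrt_sig <- lr_test(fit_null, fit_sig)
  lrt_lin <- lr_test(fit_null, fit_lin)
  vertex <- quadratic_vertex(fit_quad_p3a)
  ttests <- amplitude_ttests(peaks)
  anova <- rm_anova(peaks)
  utils::write.csv(ttests, file.path(out_dir, "ttests.csv"), row.names = FALSE)
  timings$models <- toc(t0)

  summary <- list(
    seed = config$seed,
    stage_seeds = vapply(1:4, function(i) stage_seed(config, i), numeric(1)),
    timings_sec = timings,
    n_manifest_rows = nrow(manifest),
    sequence_roles = as.list(table(sequence$events$role)),
    sigmoid_fit = list(L = fit_sig$L, k = fit_sig$k, I0 = fit_sig$I0,
                       inflection_jitter = inflection_to_jitter(fit_sig$I0),
                       sigma_L = fit_sig$sigma_L, sigma = fit_sig$sigma,
                       loglik = fit_sig$loglik, aic = fit_sig$aic,
                       bic = fit_sig$bic, converged = fit_sig$converged),
    linear_fit = list(aic = fit_lin$aic, bic = fit_lin$bic,
                      loglik = fit_lin$loglik),
    lrt_sigmoid_vs_null = lrt_sig,
    lrt_linear_vs_null = lrt_lin,
    p3a_quadratic_vertex = vertex,
    anova = list(f = anova$f_value, df = c(anova$df_num, anova$df_den),
                 gg_epsilon = anova$gg_epsilon, p_gg = anova$p_gg)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Build the small deterministic fixture set used by the tests
#'
#' `scale = "small"`: a 4-participant x 4-condition peak table, a labeled
#' 30-tone roving sequence and 3 staircase blocks. `scale = "full"` uses the
#' study-scale design (34 x 7, 600-tone sequence, 15 blocks).
#'
#' @param scale `"small"` or `"full"`.
#' @param seed Integer seed.
#' @return List with `peaks`, `sequence`, `staircase_runs`, `params`.
#' @export
make_fixtures <- function(scale = c("small", "full"), seed = 42L) {
  scale <- match.arg(scale)
  dims <- if (scale == "small") {
    list(p = 4L, cond = jitter_schedule()[2:5], n_sounds = 30L, blocks = 3L)
  } else {
    list(p = 34L, cond = jitter_schedule()[2:8], n_sounds = 600L, blocks = 15L)
  }
  params <- generative_params(n_participants = dims$p, conditions = dims$cond,
                              seed = seed)
  peaks <- generate_peak_table(params)
  set.seed(seed + 1L)
  sequence <- label_events(generate_roving_sequence(dims$n_sounds))
  set.seed(seed + 2L)
  obs <- logistic_observer()
  runs <- lapply(seq_len(dims$blocks),
                 function(b) run_staircase(obs, sample(c(0L, 10L), 1L)))
  list(peaks = peaks, sequence = sequence, staircase_runs = runs,
       params = params)
}
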