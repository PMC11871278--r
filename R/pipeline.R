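#' Run the full scoring and relevance pipeline
#'
#' Chains every stage end to end for a set of videos: visual salience
#' score from salience maps, EEG feature extraction and brain consistency
#' score, local matching ratio over an `(l, theta_c)` grid, permutation
#' baseline and Cohen's d — then writes the results bundle. Videos come
#' either from files (PNG stacks + EEG CSVs) or from the seeded synthetic
#' generators.
#'
#' @param config configuration list or path to a YAML file with the same
#'   structure. Recognised fields:
#'   \describe{
#'     \item{`seed`}{integer; drives every stochastic stage.}
#'     \item{`synthetic`}{list: `n_videos` plus any [synthetic_spec()]
#'       argument; `coupling = "null"` forces uncoupled cohorts.}
#'     \item{`videos`}{file mode: list of entries with `video_id`,
#'       `salience_dir`, and `eeg` (vector of per-subject sample CSVs).}
#'     \item{`theta_s`}{visual threshold in pixels or `"auto"`.}
#'     \item{`window_s`}{EEG segment length in seconds (default 1).}
#'     \item{`theta_s_cos`}{consistency threshold; `NULL` = per-video
#'       median calibration.}
#'     \item{`bands`, `features`, `channel_group`}{feature subsetting.}
#'     \item{`grid`}{list with `l` and `theta_c` vectors.}
#'     \item{`criterion`, `smooth_v`, `smooth_b`, `n_perm`, `d_mode`}{as
#'       in [brainsource()]; smoothers as `list(kind=, sigma=/width=)`.}
#'     \item{`out_dir`}{where to write the bundle; `NULL` skips writing.}
#'   }
#' @return List with `fit` (the [brainsource()] object), `scores` (long
#'   data.frame of per-video series), `theta` (per-video consistency
#'   thresholds) and `paths` of any files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% stop_invalid("config$seed is required")
  grid <- config$grid %||% list(l = 5L, theta_c = 0.4)
  window_s <- config$window_s %||% 1
  mk_smoother <- function(x, default) {
    if (is.null(x)) return(default)
    do.call(smoother, x)
  }
  smooth_v <- mk_smoother(config$smooth_v, smoother("gaussian", sigma = 1))
  smooth_b <- mk_smoother(config$smooth_b, smoother("gaussian", sigma = 2))

  videos <- stage("inputs", {
    if (!is.null(config$synthetic)) synthetic_videos(config, seed, window_s)
    else if (!is.null(config$videos)) file_videos(config, window_s)
    else stop_invalid("config needs either `synthetic` or `videos`")
  })

  scores <- stage("scores", {
    lapply(videos, function(v) {
      s_v <- visual_score_series(v$maps, theta_s = config$theta_s %||% NULL)
      channels <- if (!is.null(config$channel_group))
        channel_group(v$recordings[[1L]]$channel_names,
                      config$channel_group)
      else NULL
      tensor <- eeg_feature_tensor(v$recordings, window_s = window_s,
                                   channels = channels)
      if (!is.null(config$bands) || !is.null(config$features))
        tensor <- select_features(tensor, bands = config$bands,
                                  features = config$features)
      n_steps <- min(length(s_v), dim(tensor)[2L])
      s_b <- brain_score_series(tensor[, seq_len(n_steps), , drop = FALSE],
                                theta_s_cos = config$theta_s_cos %||% NULL)
      list(video_id = v$video_id, s_v = s_v[seq_len(n_steps)], s_b = s_b,
           theta_s_cos = attr(s_b, "theta_s_cos"))
    })
  })

  fit <- stage("relevance", {
    brainsource(lapply(scores, `[[`, "s_v"), lapply(scores, `[[`, "s_b"),
                l = grid$l, theta_c = grid$theta_c,
                criterion = config$criterion %||% "spearman",
                smooth_v = smooth_v, smooth_b = smooth_b,
                n_perm = config$n_perm %||% 10L, seed = seed,
                d_mode = config$d_mode %||% "standard")
  })

  score_df <- do.call(rbind, lapply(scores, function(s)
    data.frame(video_id = s$video_id, t = seq_along(s$s_v),
               s_v = as.numeric(s$s_v), s_b = as.numeric(s$s_b))))
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    paths <- stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      hash <- config_hash(config)
      p_scores <- file.path(config$out_dir, "scores.csv")
      con <- file(p_scores, "w")
      writeLines(sprintf("# eegsalience %s config=%s seed=%d",
                         as.character(utils::packageVersion("eegsalience")),
                         hash, seed), con)
      utils::write.csv(score_df, con, row.names = FALSE)
      close(con)
      p_grid <- file.path(config$out_dir, "effect_sizes.csv")
      con <- file(p_grid, "w")
      writeLines(sprintf("# eegsalience %s config=%s seed=%d",
                         as.character(utils::packageVersion("eegsalience")),
                         hash, seed), con)
      utils::write.csv(fit$grid, con, row.names = FALSE)
      close(con)
      p_json <- file.path(config$out_dir, "results.json")
      jsonlite::write_json(
        list(package = "eegsalience",
             version = as.character(utils::packageVersion("eegsalience")),
             config_hash = hash, seed = seed, config = config,
             grid = fit$grid,
             theta_s_cos = vapply(scores, `[[`, 0, "theta_s_cos")),
        p_json, auto_unbox = TRUE, digits = NA)
      c(scores = p_scores, grid = p_grid, json = p_json)
    })
  }
  list(fit = fit, scores = score_df,
       theta = vapply(scores, `[[`, 0, "theta_s_cos"), paths = paths)
}

# Tag stage errors and log per-stage timing to stderr.
stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop_invalid(sprintf("[%s] %s", name, conditionMessage(e))))
  message(sprintf("[eegsalience] stage %-9s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

synthetic_videos <- function(config, seed, window_s) {
  sy <- config$synthetic
  n_videos <- sy$n_videos %||% 2L
  seeds <- derive_seeds(seed, n_videos)
  lapply(seq_len(n_videos), function(v) {
    args <- sy[setdiff(names(sy), c("n_videos", "coupling"))]
    args$window_s <- args$window_s %||% window_s
    args$seed <- seeds[v]
    spec <- do.call(synthetic_spec, args)
    if (identical(sy$coupling, "null"))
      spec$coupling <- rep(0, spec$n_steps)
    maps <- gen_salience_stack(spec)
    list(video_id = maps$video_id, maps = maps,
         recordings = gen_eeg_cohort(spec))
  })
}

file_videos <- function(config, window_s) {
  lapply(config$videos, function(v) {
    maps <- read_salience_dir(v$salience_dir, frame_period = window_s,
                              video_id = v$video_id %||% NULL)
    recs <- lapply(v$eeg, read_eeg_csv)
    list(video_id = maps$video_id, maps = maps, recordings = recs)
  })
}
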