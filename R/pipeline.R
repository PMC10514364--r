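# End-to-end detection pipeline: (simulate | read) -> band-pass -> segment
# -> label -> 22-feature extraction -> optional class balancing -> feature
# selection -> stratified k-fold CV detection -> metric report, with every
# intermediate exportable and all randomness funneled through one seed.

#' Pipeline run configuration
#'
#' Collects every tunable of the detection pipeline with the package
#' defaults. Input is either a [synth_spec] (`synth`) or an EDF path plus
#' annotation path.
#'
#' @param synth A [synth_spec] for synthetic input, or `NULL` when reading
#'   files.
#' @param edf,annotations Paths to an EDF recording and a plain-text
#'   annotation file (used when `synth` is `NULL`).
#' @param channel Channel to read from the EDF (default `"Cz-A1"`).
#' @param filter A [filter_spec] (default 0.5–30 Hz, order 4).
#' @param zero_phase Use forward-backward filtering (default FALSE).
#' @param window_s,step_s Sliding-window length and step in seconds
#'   (defaults 0.5 and 0.1).
#' @param min_overlap Labeling overlap threshold (default 0.5).
#' @param balance_ratio Negatives kept per positive by seeded undersampling
#'   before selection/CV; `NULL` disables balancing (default 1).
#' @param selection Selection method: `"none"`, `"relieff"`, `"cfs"`,
#'   `"sfs-consistency"`, `"sfs-error"`, or `"interact"`.
#' @param selection_params Extra arguments for the selector (e.g.
#'   `threshold`, `bins`, `c_threshold`).
#' @param model Classifier: `"lda"`, `"lsvm"` or `"dt"` (default `"dt"`).
#' @param folds CV folds (default 5).
#' @param beta F-score beta (default 1).
#' @param features Character subset of `c("time", "spectral", "chaotic")`.
#' @param band,rolloff_c Spectral-feature parameters.
#' @param m,tau,q Chaotic-feature parameters.
#' @param seed Master seed for the run (default 1).
#' @return A `"kc_config"` list.
#' @export
kc_config <- function(synth = synth_spec(), edf = NULL, annotations = NULL,
                      channel = "Cz-A1", filter = filter_spec(),
                      zero_phase = FALSE, window_s = 0.5, step_s = 0.1,
                      min_overlap = 0.5, balance_ratio = 1,
                      selection = "none", selection_params = list(),
                      model = "dt", folds = 5L, beta = 1,
                      features = c("time", "spectral", "chaotic"),
                      band = c(0.5, 4), rolloff_c = 0.85,
                      m = 3, tau = NULL, q = 2, seed = 1L) {
  structure(list(synth = synth, edf = edf, annotations = annotations,
                 channel = channel, filter = filter, zero_phase = zero_phase,
                 window_s = window_s, step_s = step_s,
                 min_overlap = min_overlap, balance_ratio = balance_ratio,
                 selection = selection, selection_params = selection_params,
                 model = model, folds = as.integer(folds), beta = beta,
                 features = features, band = band, rolloff_c = rolloff_c,
                 m = m, tau = tau, q = q, seed = as.integer(seed)),
            class = "kc_config")
}

# selector closure for crossvalidate(); seeded deterministically
.make_selector <- function(method, params = list(), seed = 1L) {
  if (is.null(method) || method == "none") return(NULL)
  function(fm) {
    args <- c(list(fm), params)
    switch(method,
      relieff = do.call(relieff, c(args, list(seed = seed))),
      cfs = do.call(cfs, args),
      `sfs-consistency` = do.call(sfs, c(args, list(measure = "consistency",
                                                    seed = seed))),
      `sfs-error` = do.call(sfs, c(args, list(measure = "classifier_error",
                                              seed = seed))),
      interact = do.call(interact_select, args),
      stop("unknown selection method: ", method))
  }
}

# seeded 1:ratio undersampling of the majority negatives
.balance <- function(fm, ratio, seed) {
  if (is.null(ratio)) return(fm)
  pos <- which(fm$y == 1L); neg <- which(fm$y == 0L)
  keep_n <- min(length(neg), ceiling(ratio * length(pos)))
  set.seed(seed)
  keep <- sort(c(pos, sample(neg, keep_n)))
  feature_matrix(fm$X[keep, , drop = FALSE], fm$y[keep], fm$meta)
}

# config echo for reports: drop non-serializable/path entries
.config_echo <- function(config) {
  echo <- unclass(config)
  echo$filter <- unclass(echo$filter)
  if (!is.null(echo$synth)) echo$synth <- unclass(echo$synth)
  echo$edf <- NULL; echo$annotations <- NULL
  echo
}

#' Run the full k-complex detection pipeline
#'
#' Executes filter -> segment -> label -> feature extraction -> balancing ->
#' selection -> stratified k-fold cross-validated detection, per the run
#' configuration. When a selector is configured it is fit inside every
#' training fold (no test-fold leakage); the selection reported in the run
#' artifacts is additionally computed once on the full balanced data to
#' document the retained dimensionality.
#'
#' @param config A [kc_config].
#' @param out_dir Optional directory for artifacts (`segments.csv`,
#'   `features.csv`, `selection.json`, `report.json`).
#' @return A `"kc_report"`: list with `config` (echo), `n_segments`,
#'   `class_counts`, `selection` (method, selected names, count), `cv`
#'   (per-fold metrics, mean, sd), and `model`.
#' @export
run_pipeline <- function(config = kc_config(), out_dir = NULL) {
  stopifnot(inherits(config, "kc_config"))
  if (!is.null(config$synth)) {
    sim <- generate_recording(config$synth)
    rec <- sim$recording; ann <- sim$annotations
  } else {
    if (is.null(config$edf) || is.null(config$annotations))
      stop("config must provide either 'synth' or 'edf' + 'annotations'")
    rec <- read_edf(config$edf, config$channel)
    ann <- read_annotations(config$annotations)
  }
  rec <- bandpass(rec, config$filter, zero_phase = config$zero_phase)
  segs <- segment_recording(rec, config$window_s, config$step_s)
  segs <- label_segments(segs, ann, config$min_overlap)
  fm <- extract_features(segs,
                         time = "time" %in% config$features,
                         spectral = "spectral" %in% config$features,
                         chaotic = "chaotic" %in% config$features,
                         band = config$band, rolloff_c = config$rolloff_c,
                         m = config$m, tau = config$tau, q = config$q)
  fm_bal <- .balance(fm, config$balance_ratio, seed = config$seed + 1L)

  selector <- .make_selector(config$selection, config$selection_params,
                             seed = config$seed)
  global_sel <- if (is.null(selector)) NULL else selector(fm_bal)
  bundle <- crossvalidate(fm_bal, model = config$model, k = config$folds,
                          seed = config$seed + 2L, selector = selector,
                          beta = config$beta)

  selection <- list(
    method = config$selection,
    selected = if (is.null(global_sel)) colnames(fm$X) else global_sel$selected,
    n_selected = if (is.null(global_sel)) ncol(fm$X)
                 else length(global_sel$selected),
    per_fold = bundle$selected)
  report <- structure(list(
    config = .config_echo(config),
    n_segments = length(segs),
    class_counts = list(kcomplex = sum(fm$y == 1L),
                        non_kcomplex = sum(fm$y == 0L),
                        balanced_n = nrow(fm_bal$X)),
    selection = selection,
    cv = list(folds = bundle$folds, mean = as.list(bundle$mean),
              sd = as.list(bundle$sd)),
    model = config$model), class = "kc_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(as.data.frame(segs),
                     file.path(out_dir, "segments.csv"), row.names = FALSE)
    utils::write.csv(data.frame(fm$X, label = fm$y, check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(selection[c("method", "selected", "n_selected")],
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.kc_report <- function(x, ...) {
  cat(sprintf("<kc_report> %s, selection=%s (%d features), %d segments\n",
              x$model, x$selection$method, x$selection$n_selected,
              x$n_segments))
  for (m in names(x$cv$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$cv$mean[[m]], x$cv$sd[[m]]))
  invisible(x)
}

#' Compare selection methods across classifiers
#'
#' Runs the shared pipeline stages once, then cross-validates every
#' combination of selection method (plus the mandatory no-selection
#' baseline) and classifier, returning one row per cell. Cells whose
#' selector or classifier fails are kept with `NA` metrics and the error
#' message in `error`.
#'
#' @param config A [kc_config] (its `selection`/`model` fields are ignored).
#' @param methods Selection methods to compare (default all five).
#' @param models Classifiers to compare (default all three).
#' @param out_dir Optional directory for `comparison.csv` and
#'   `comparison.json`.
#' @return Data frame with columns `selection`, `model`, `n_selected`
#'   (fold-mean), the five metric means and sds, and `error`.
#' @export
compare_methods <- function(config = kc_config(),
                            methods = c("relieff", "cfs", "sfs-consistency",
                                        "sfs-error", "interact"),
                            models = c("lda", "lsvm", "dt"),
                            out_dir = NULL) {
  stopifnot(inherits(config, "kc_config"), length(models) >= 1L)
  base <- config
  base$selection <- "none"
  if (!is.null(base$synth)) {
    sim <- generate_recording(base$synth)
    rec <- sim$recording; ann <- sim$annotations
  } else {
    rec <- read_edf(base$edf, base$channel)
    ann <- read_annotations(base$annotations)
  }
  rec <- bandpass(rec, base$filter, zero_phase = base$zero_phase)
  segs <- label_segments(segment_recording(rec, base$window_s, base$step_s),
                         ann, base$min_overlap)
  fm <- .balance(extract_features(segs,
                                  time = "time" %in% base$features,
                                  spectral = "spectral" %in% base$features,
                                  chaotic = "chaotic" %in% base$features,
                                  band = base$band, rolloff_c = base$rolloff_c,
                                  m = base$m, tau = base$tau, q = base$q),
                 base$balance_ratio, seed = base$seed + 1L)
  compare_features(fm, base, methods = methods, models = models,
                   out_dir = out_dir)
}
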