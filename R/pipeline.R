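#' Default experiment configuration
#'
#' @param seed Master seed; every stochastic stage derives its own
#'   substream from it.
#' @param scenario `"default"` (backbone + subtle class shifts, full noise
#'   model) or `"complementary"` (block-complementary marker scenario) for
#'   simulated data.
#' @param pretreat `"auto"` (rank the six candidate methods per block and
#'   pick the best) or a list `list(ftmir =, nir =)` of fixed method names.
#' @param selections Subset of `c("pcs", "rfe", "boruta", "vip")`.
#' @param fusion_levels Subset of `c("low", "mid", "high")`.
#' @param eps High-level voting tie width.
#' @param split_ratio Calibration fraction.
#' @param n_per_class Simulated class sizes.
#' @param n_tree0 Initial forest size for OOB tuning.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1, scenario = "default",
                           pretreat = "auto",
                           selections = c("pcs", "rfe", "boruta", "vip"),
                           fusion_levels = c("low", "mid", "high"),
                           eps = 0.01, split_ratio = 2 / 3,
                           n_per_class = c(40, 40, 36, 40, 40),
                           n_tree0 = 2000) {
  stopifnot(eps > 0, split_ratio > 0, split_ratio < 1)
  structure(list(seed = seed, scenario = scenario, pretreat = pretreat,
                 exclude_ftmir = list(c(4000, 3700), c(2620, 1800)),
                 selections = if (length(selections))
                   match.arg(selections, c("pcs", "rfe", "boruta", "vip"),
                             several.ok = TRUE) else character(0),
                 fusion_levels = match.arg(fusion_levels,
                                           c("low", "mid", "high"),
                                           several.ok = TRUE),
                 eps = eps, split_ratio = split_ratio,
                 n_per_class = n_per_class, n_tree0 = n_tree0),
            class = "run_config")
}

# fit PLS-DA and tuned RF on a calibration matrix; return models, report
# entries, and score matrices for both sets
fit_family <- function(Xcal, ycal, Xval, yval, dataset, seed, n_tree0,
                       classes) {
  pl <- fit_plsda(Xcal, ycal, A = "auto",
                  seed = substream_seed(seed, paste0(dataset, "-plsda")))
  cfg <- tune_rf(Xcal, ycal, seed = substream_seed(seed, paste0(dataset, "-tune")),
                 n_tree0 = n_tree0)
  rf <- fit_rf(Xcal, ycal, n_tree = cfg$n_tree, m_try = cfg$m_try,
               seed = substream_seed(seed, paste0(dataset, "-rf")))
  entries <- list(
    list(dataset = dataset, model = "PLS-DA", set = "calibration",
         true = ycal, predicted_sets = as.list(plsda_classes(pl, Xcal))),
    list(dataset = dataset, model = "PLS-DA", set = "validation",
         true = yval, predicted_sets = as.list(plsda_classes(pl, Xval))),
    list(dataset = dataset, model = "RF", set = "calibration",
         true = ycal, predicted_sets = as.list(rf_classes(rf, Xcal))),
    list(dataset = dataset, model = "RF (OOB)", set = "calibration",
         true = ycal, predicted_sets = as.list(rf_classes(rf))),
    list(dataset = dataset, model = "RF", set = "validation",
         true = yval, predicted_sets = as.list(rf_classes(rf, Xval))))
  list(plsda = pl, rf = rf, rf_config = cfg, entries = entries,
       scores = list(
         plsda_cal = plsda_scores(pl, Xcal), plsda_val = plsda_scores(pl, Xval),
         rf_cal = rf_scores(rf, Xcal), rf_val = rf_scores(rf, Xval)))
}

#' Run the full two-block fusion experiment
#'
#' Executes the whole protocol: simulate (or take) paired blocks, exclude
#' the uninformative FT-MIR regions, rank pretreatments per block and apply
#' the best, split per class by Kennard-Stone at 2:1, fit single-block
#' PLS-DA and OOB-tuned RF models, run the requested variable selections,
#' and build the requested fusion levels (low, optionally with VIP
#' reselection; mid and high for each selection route), with high-level
#' fusion decided by fuzzy-operator voting. Returns report tables in the
#' per-class efficiency + accuracy layout plus a manifest of stage
#' bookkeeping.
#'
#' Mid-level selections are computed on the full sample set (the reference
#' protocol) and therefore leak validation information into the selection;
#' the manifest carries an explicit warning. High-level selections use the
#' calibration set only.
#'
#' @param config A [default_config()].
#' @param data `"simulate"` or a list with [spectral_block()] elements
#'   `ftmir` and `nir`.
#' @return List of class `run_result`: `report` (data.frame), `manifest`,
#'   and `details` (fitted models, selections, decisions).
#' @export
run_experiment <- function(config = default_config(), data = "simulate") {
  seed <- config$seed
  log_ <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_ <<- c(log_, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed after [",
           paste(log_, collapse = "; "), "]: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- data ---------------------------------------------------------------
  if (identical(data, "simulate")) {
    blocks <- stage("simulate", if (config$scenario == "complementary") {
      sc <- make_complementary_scenario(seed, config$n_per_class)
      list(ftmir = sc$ftmir, nir = sc$nir)
    } else {
      simulate_blocks(config$n_per_class, seed = seed)
    })
    note("simulated blocks: FT-MIR %d x %d, NIR %d x %d",
         nrow(blocks$ftmir$X), ncol(blocks$ftmir$X),
         nrow(blocks$nir$X), ncol(blocks$nir$X))
  } else blocks <- data
  ftmir <- stage("exclude-regions",
                 exclude_regions(blocks$ftmir, config$exclude_ftmir))
  nir <- blocks$nir
  note("after region exclusion: FT-MIR %d variables, NIR %d variables",
       ncol(ftmir$X), ncol(nir$X))
  warnings <- character(0)

  # --- pretreatment -------------------------------------------------------
  if (identical(config$pretreat, "auto")) {
    pre_split <- split_by_class(list(ftmir, nir), config$split_ratio)
    rk_f <- rank_pretreatments(ftmir, pre_split,
                               seed = substream_seed(seed, "rank-ftmir"))
    rk_n <- rank_pretreatments(nir, pre_split,
                               seed = substream_seed(seed, "rank-nir"))
    methods <- list(ftmir = rk_f$best, nir = rk_n$best)
    pretreat_reports <- list(ftmir = rk_f$reports, nir = rk_n$reports)
  } else {
    methods <- config$pretreat
    pretreat_reports <- NULL
  }
  ftmir <- stage("pretreat", apply_pretreatment(ftmir, methods$ftmir))
  nir <- stage("pretreat", apply_pretreatment(nir, methods$nir))
  note("pretreatment: FT-MIR %s, NIR %s", methods$ftmir, methods$nir)

  # --- split --------------------------------------------------------------
  split <- stage("split", split_by_class(list(ftmir, nir), config$split_ratio))
  cal <- calibration_mask(ftmir, split)
  note("split: %d calibration / %d validation", sum(cal), sum(!cal))
  y <- ftmir$labels
  classes <- sort(unique(y))
  ycal <- y[cal]; yval <- y[!cal]
  Xf_cal <- ftmir$X[cal, , drop = FALSE]; Xf_val <- ftmir$X[!cal, , drop = FALSE]
  Xn_cal <- nir$X[cal, , drop = FALSE]; Xn_val <- nir$X[!cal, , drop = FALSE]

  # --- single-block models ------------------------------------------------
  fam_f <- stage("single-block models",
                 fit_family(Xf_cal, ycal, Xf_val, yval, "FT-MIR", seed,
                            config$n_tree0, classes))
  fam_n <- stage("single-block models",
                 fit_family(Xn_cal, ycal, Xn_val, yval, "NIR", seed,
                            config$n_tree0, classes))
  entries <- c(fam_f$entries, fam_n$entries)
  details <- list(split = split, methods = methods,
                  pretreat_reports = pretreat_reports,
                  single = list(ftmir = fam_f, nir = fam_n))

  # --- selections ---------------------------------------------------------
  selections <- list()
  if ("pcs" %in% config$selections) {
    # unsupervised PCA on all samples; the same components serve mid and
    # high level (the reference protocol)
    selections$pcs <- list(ftmir = pca_extract(ftmir$X),
                           nir = pca_extract(nir$X))
    note("PCs kept: FT-MIR %d, NIR %d", selections$pcs$ftmir$n_kept,
         selections$pcs$nir$n_kept)
    warnings <- c(warnings,
      "PCs selection uses all samples (calibration + validation): information leakage into the validation metrics")
  }
  scoped <- intersect(config$selections, c("rfe", "boruta"))
  need_mid <- "mid" %in% config$fusion_levels
  need_high <- "high" %in% config$fusion_levels
  for (m in scoped) {
    sel_fun <- if (m == "rfe") {
      function(X, lab, tag) rfe_select(X, lab, seed = substream_seed(seed, tag))
    } else {
      function(X, lab, tag) boruta_select(X, lab, seed = substream_seed(seed, tag))
    }
    if (need_mid) {
      selections[[paste0(m, "_all")]] <- list(
        ftmir = sel_fun(ftmir$X, y, paste0(m, "-ftmir-all")),
        nir = sel_fun(nir$X, y, paste0(m, "-nir-all")))
      warnings <- c(warnings, sprintf(
        "%s mid-level selection uses all samples: information leakage into the validation metrics", m))
    }
    if (need_high) {
      selections[[paste0(m, "_cal")]] <- list(
        ftmir = sel_fun(Xf_cal, ycal, paste0(m, "-ftmir-cal")),
        nir = sel_fun(Xn_cal, ycal, paste0(m, "-nir-cal")))
    }
  }
  details$selections <- selections

  # --- low-level fusion ---------------------------------------------------
  if ("low" %in% config$fusion_levels) {
    fused <- low_level_fuse(ftmir, nir)
    note("low-level fused matrix: %d x %d", nrow(fused), ncol(fused))
    fam_low <- fit_family(fused[cal, , drop = FALSE], ycal,
                          fused[!cal, , drop = FALSE], yval,
                          "Low-level", seed, config$n_tree0, classes)
    entries <- c(entries, fam_low$entries)
    details$low <- fam_low
    if ("vip" %in% config$selections) {
      sel_vip <- vip_select(fam_low$plsda)
      note("low-level VIP > 1 variables: %d", length(sel_vip$indices))
      fam_vip <- fit_family(fused[cal, sel_vip$indices, drop = FALSE], ycal,
                            fused[!cal, sel_vip$indices, drop = FALSE], yval,
                            "Low-level (VIP)", seed, config$n_tree0, classes)
      entries <- c(entries, fam_vip$entries)
      details$low_vip <- list(selection = sel_vip, family = fam_vip)
    }
  }

  # --- mid-level fusion ---------------------------------------------------
  route_label <- c(pcs = "PCs", rfe = "RFE", boruta = "Bo")
  if (need_mid) {
    for (m in config$selections) {
      if (m == "vip") next
      sel <- if (m == "pcs") selections$pcs else selections[[paste0(m, "_all")]]
      if (is.null(sel)) next
      fused <- mid_level_fuse(ftmir$X, sel$ftmir, nir$X, sel$nir)
      tag <- sprintf("Mid-level (%s)", route_label[m])
      note("%s matrix: %d x %d", tag, nrow(fused), ncol(fused))
      fam <- fit_family(fused[cal, , drop = FALSE], ycal,
                        fused[!cal, , drop = FALSE], yval,
                        tag, seed, config$n_tree0, classes)
      entries <- c(entries, fam$entries)
      details[[paste0("mid_", m)]] <- fam
    }
  }

  # --- high-level fusion --------------------------------------------------
  if (need_high) {
    decisions <- list()
    for (m in config$selections) {
      if (m == "vip") next
      sel <- if (m == "pcs") selections$pcs else selections[[paste0(m, "_cal")]]
      if (is.null(sel)) next
      Ff <- feature_matrix(ftmir$X, sel$ftmir)
      Fn <- feature_matrix(nir$X, sel$nir)
      tag <- sprintf("High-level (%s)", route_label[m])
      note("%s per-block features: FT-MIR %d, NIR %d", tag, ncol(Ff), ncol(Fn))
      fam_hf <- fit_family(Ff[cal, , drop = FALSE], ycal,
                           Ff[!cal, , drop = FALSE], yval,
                           paste0("FT-MIR (", route_label[m], ")"),
                           seed, config$n_tree0, classes)
      fam_hn <- fit_family(Fn[cal, , drop = FALSE], ycal,
                           Fn[!cal, , drop = FALSE], yval,
                           paste0("NIR (", route_label[m], ")"),
                           seed, config$n_tree0, classes)
      entries <- c(entries, fam_hf$entries, fam_hn$entries)
      for (fam_name in c("plsda", "rf")) {
        sc <- if (fam_name == "plsda") {
          list(cal = list(fam_hf$scores$plsda_cal, fam_hn$scores$plsda_cal),
               val = list(fam_hf$scores$plsda_val, fam_hn$scores$plsda_val))
        } else {
          list(cal = list(fam_hf$scores$rf_cal, fam_hn$scores$rf_cal),
               val = list(fam_hf$scores$rf_val, fam_hn$scores$rf_val))
        }
        model_lab <- if (fam_name == "plsda") "PLS-DA" else "RF"
        hv_cal <- high_level_fuse(sc$cal[[1]], sc$cal[[2]], config$eps)
        hv_val <- high_level_fuse(sc$val[[1]], sc$val[[2]], config$eps)
        entries <- c(entries, list(
          list(dataset = tag, model = model_lab, set = "calibration",
               true = ycal, predicted_sets = hv_cal$predicted_sets),
          list(dataset = tag, model = model_lab, set = "validation",
               true = yval, predicted_sets = hv_val$predicted_sets)))
        decisions[[paste(m, fam_name, sep = "_")]] <-
          list(calibration = hv_cal, validation = hv_val)
      }
    }
    details$high_decisions <- decisions
  }

  report <- build_report(entries, classes)
  manifest <- list(config = unclass(config), seed = seed,
                   pretreatment = methods,
                   split_counts = split$class_counts,
                   log = log_, warnings = warnings)
  structure(list(report = report, manifest = manifest, details = details),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  df <- x$report
  df$accuracy <- format_percent(df$accuracy)
  print(df, digits = 3)
  if (length(x$manifest$warnings))
    cat("warnings:\n", paste("-", x$manifest$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Write report tables and manifest of a run
#'
#' Writes `report_calibration.csv`, `report_validation.csv` and
#' `run_manifest.json` under `dir`.
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$report
  utils::write.csv(rep[rep$set == "calibration", ],
                   file.path(dir, "report_calibration.csv"), row.names = FALSE)
  utils::write.csv(rep[rep$set == "validation", ],
                   file.path(dir, "report_validation.csv"), row.names = FALSE)
  man <- result$manifest
  man$split_counts <- as.data.frame(man$split_counts)
  jsonlite::write_json(man, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
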