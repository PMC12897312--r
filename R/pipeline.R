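#' Configure the experiment grid
#'
#' Describes a full replication sweep: which indicators to model, which
#' preprocessing methods, wavelength modes (`"full"` spectrum or `"spa"`
#' feature selection), and regression algorithms to cross, plus the SPXY
#' train fraction, SPA settings, CNN training profile, and the base seed
#' from which every cell's seed is derived deterministically.
#'
#' @param dataset A [vn_dataset()], a `synthetic_dataset`, or a
#'   [synthetic_config()] (generated on demand).
#' @param indicators Character vector of reference columns to model.
#' @param preprocessing Methods to sweep (subset of NONE/DT/FD/MSC/SG/
#'   SNV/SS).
#' @param models Algorithms to sweep (subset of PLS/SVR/CNN).
#' @param modes Wavelength modes (subset of `"full"`, `"spa"`).
#' @param train_fraction SPXY training fraction (default 0.7, the 7:3
#'   split).
#' @param spa An [spa_config()] used for `"spa"` cells.
#' @param cnn_epochs CNN training epochs for grid cells (100 in the
#'   default desk profile; 500 in the full profile).
#' @param seed Base integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset,
                            indicators = indicator_names(),
                            preprocessing = c("DT", "FD", "MSC", "SG", "SNV", "SS"),
                            models = c("PLS", "SVR", "CNN"),
                            modes = c("full", "spa"),
                            train_fraction = 0.7,
                            spa = spa_config(),
                            cnn_epochs = 100L,
                            seed = 1L) {
  stopifnot(length(indicators) >= 1, length(preprocessing) >= 1,
            length(models) >= 1, length(modes) >= 1)
  models <- match.arg(toupper(models), c("PLS", "SVR", "CNN"), several.ok = TRUE)
  modes <- match.arg(tolower(modes), c("full", "spa"), several.ok = TRUE)
  structure(
    list(
      dataset = dataset, indicators = indicators,
      preprocessing = toupper(preprocessing), models = models, modes = modes,
      train_fraction = train_fraction, spa = spa,
      cnn_epochs = as.integer(cnn_epochs), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

resolve_dataset <- function(dataset) {
  if (inherits(dataset, "synthetic_config")) dataset <- generate_dataset(dataset)
  if (inherits(dataset, "synthetic_dataset")) {
    dataset <- vn_dataset(dataset$spectra, dataset$references)
  }
  stopifnot(inherits(dataset, "vn_dataset"))
  dataset
}

#' Run the full experiment grid
#'
#' For each indicator: one SPXY split of the raw spectra; then for every
#' (preprocessing, wavelength mode, model) combination the preprocessor
#' is fitted on the training rows only and applied to both sets, SPA
#' selection (spa mode) runs on the preprocessed training rows only, the
#' model is trained on the training set, and metrics are computed on both
#' the calibration and the prediction set. Cell failures are recorded
#' with their reason and never abort the sweep. Every cell's seed is
#' derived from the config seed, so reruns of an identical config are
#' identical.
#'
#' @param config A [pipeline_config()].
#' @param progress Print one line per cell as it completes.
#' @return A `grid_result`: `records` (one data-frame row per cell) and
#'   `details` (per-cell list with predictions, selections, and
#'   hyperparameters).
#' @export
run_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- resolve_dataset(config$dataset)
  records <- list()
  details <- list()
  cell_id <- 0L

  for (ind_i in seq_along(config$indicators)) {
    ind <- config$indicators[ind_i]
    if (!ind %in% names(ds$references)) {
      stop("indicator not found in references: ", ind)
    }
    y <- ds$references[[ind]]
    split <- spxy_split(ds$spectra, y, config$train_fraction, indicator = ind)
    tr <- split$train_indices
    te <- split$test_indices
    x_raw <- ds$spectra$reflectance
    wl <- as.numeric(ds$spectra$grid)

    for (prep in config$preprocessing) {
      fp <- fit_preprocessor(prep, x_raw[tr, , drop = FALSE], wavelengths = wl)
      x_tr <- transform_spectra(fp, x_raw[tr, , drop = FALSE])
      x_te <- if (length(te)) transform_spectra(fp, x_raw[te, , drop = FALSE]) else
        x_raw[integer(0), , drop = FALSE]

      for (mode in config$modes) {
        sel <- NULL
        if (mode == "spa") {
          spa_cfg <- config$spa
          spa_cfg$seed <- config$seed + 1000L * ind_i
          sel <- tryCatch(
            select_wavelengths(x_tr, y[tr], spa_cfg),
            error = function(e) e
          )
        }
        for (model in config$models) {
          cell_id <- cell_id + 1L
          cell_seed <- config$seed + cell_id
          rec <- list(
            indicator = ind, preprocessing = prep, model = model, mode = mode,
            status = "ok", error = NA_character_,
            cal_r2 = NA_real_, cal_rmse = NA_real_, cal_rpd = NA_real_,
            pred_r2 = NA_real_, pred_rmse = NA_real_, pred_rpd = NA_real_,
            n_cal = length(tr), n_pred = length(te),
            n_wavelengths = ncol(x_raw), hyper = NA_character_
          )
          det <- list(split = split)
          res <- tryCatch({
            if (inherits(sel, "error")) stop("SPA failed: ", conditionMessage(sel))
            xtr <- x_tr
            xte <- x_te
            if (mode == "spa") {
              idx <- sel$selected_indices
              xtr <- x_tr[, idx, drop = FALSE]
              xte <- x_te[, idx, drop = FALSE]
              det$selection <- sel
              rec$n_wavelengths <- length(idx)
            }
            fit <- switch(model,
              PLS = train_pls(xtr, y[tr], seed = cell_seed),
              SVR = train_svr(xtr, y[tr], seed = cell_seed),
              CNN = train_cnn(xtr, y[tr],
                epochs = config$cnn_epochs, seed = cell_seed,
                X_monitor = if (length(te)) xte else NULL,
                y_monitor = if (length(te)) y[te] else NULL
              )
            )
            pred_cal <- stats::predict(fit, xtr)
            mc <- compute_metrics(y[tr], pred_cal)
            rec$cal_r2 <- mc$r2; rec$cal_rmse <- mc$rmse; rec$cal_rpd <- mc$rpd
            if (length(te) >= 2) {
              pred_te <- stats::predict(fit, xte)
              mp <- compute_metrics(y[te], pred_te)
              rec$pred_r2 <- mp$r2; rec$pred_rmse <- mp$rmse; rec$pred_rpd <- mp$rpd
              det$pred_test <- pred_te
            }
            det$pred_cal <- pred_cal
            det$model_diag <- fit$diagnostics
            rec$hyper <- switch(model,
              PLS = sprintf("ncomp=%d", fit$diagnostics$ncomp),
              SVR = sprintf(
                "kernel=%s,C=%g,gamma=%s",
                fit$diagnostics$kernel, fit$diagnostics$C, fit$diagnostics$gamma
              ),
              CNN = sprintf("epochs=%d,lr=%g", config$cnn_epochs, 1e-3)
            )
            TRUE
          }, error = function(e) e)
          if (inherits(res, "error")) {
            rec$status <- "failed"
            rec$error <- conditionMessage(res)
          }
          key <- paste(ind, prep, model, mode, sep = "|")
          records[[key]] <- as.data.frame(rec, stringsAsFactors = FALSE)
          details[[key]] <- det
          if (progress) {
            message(sprintf(
              "[%s] %s: Rp2=%.3f", key, rec$status,
              if (is.na(rec$pred_r2)) NA else rec$pred_r2
            ))
          }
        }
      }
    }
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  structure(list(records = records, details = details, config = config),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<grid_result> %d cells (%d ok, %d failed)\n",
    nrow(x$records), sum(x$records$status == "ok"), sum(x$records$status != "ok")
  ))
  invisible(x)
}

model_simplicity_rank <- function(model) match(model, c("PLS", "SVR", "CNN"))

#' Select the best model per indicator
#'
#' Rule: maximize prediction-set R2; ties go to the higher RPD, then the
#' lower prediction RMSE, then the simpler model (PLS before SVR before
#' CNN). Indicators whose cells all failed get an explicit `"no model"`
#' entry.
#'
#' @param grid A `grid_result` from [run_grid()].
#' @return A `best_model_report`: `winners` (one row per indicator) and
#'   `ranked` (the full ranked table).
#' @export
select_best <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  rec <- grid$records
  winners <- list()
  ranked <- list()
  for (ind in unique(rec$indicator)) {
    sub <- rec[rec$indicator == ind & rec$status == "ok" & !is.na(rec$pred_r2), , drop = FALSE]
    if (nrow(sub) == 0) {
      winners[[ind]] <- data.frame(
        indicator = ind, preprocessing = NA, model = "no model", mode = NA,
        pred_r2 = NA_real_, pred_rmse = NA_real_, pred_rpd = NA_real_,
        cal_r2 = NA_real_, hyper = NA, stringsAsFactors = FALSE
      )
      next
    }
    ord <- order(
      -sub$pred_r2, -sub$pred_rpd, sub$pred_rmse,
      model_simplicity_rank(sub$model)
    )
    sub <- sub[ord, , drop = FALSE]
    ranked[[ind]] <- sub
    winners[[ind]] <- sub[1, c(
      "indicator", "preprocessing", "model", "mode",
      "pred_r2", "pred_rmse", "pred_rpd", "cal_r2", "hyper"
    )]
  }
  structure(
    list(
      winners = do.call(rbind, c(winners, make.row.names = FALSE)),
      ranked = ranked
    ),
    class = "best_model_report"
  )
}

#' @export
print.best_model_report <- function(x, ...) {
  cat("<best_model_report>\n")
  print(x$winners)
  invisible(x)
}

#' Write grid reports to disk
#'
#' Summary CSVs plus figure files: grouped bar charts of R2/RPD and RMSE
#' per combination, predicted-vs-reference scatter plots for each
#' indicator's winning model, SPA wavelength-position plots, and CNN loss
#' curves where those cells exist. Rendering reads only the persisted
#' grid, so re-rendering recomputes nothing.
#'
#' @param grid A `grid_result`.
#' @param best A `best_model_report` (computed from `grid` if missing).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(grid, best = NULL, dir = "results/reports") {
  stopifnot(inherits(grid, "grid_result"))
  if (is.null(best)) best <- select_best(grid)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p_summary <- file.path(dir, "grid_summary.csv")
  utils::write.csv(grid$records, p_summary, row.names = FALSE)
  p_best <- file.path(dir, "best_models.csv")
  utils::write.csv(best$winners, p_best, row.names = FALSE)
  paths <- c(paths, p_summary, p_best)

  ok <- grid$records[grid$records$status == "ok", , drop = FALSE]
  if (nrow(ok)) {
    ok$combo <- paste(ok$preprocessing, ok$model, ok$mode, sep = "-")
    g <- ggplot2::ggplot(ok, ggplot2::aes(x = combo, y = pred_r2, fill = model)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~indicator, scales = "free_x") +
      ggplot2::labs(x = NULL, y = expression(R[p]^2)) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1, size = 6))
    p1 <- file.path(dir, "prediction_r2.png")
    ggplot2::ggsave(p1, g, width = 10, height = 6, dpi = 150)
    g2 <- g + ggplot2::aes(y = pred_rpd) + ggplot2::labs(y = "RPD")
    p2 <- file.path(dir, "prediction_rpd.png")
    ggplot2::ggsave(p2, g2, width = 10, height = 6, dpi = 150)
    g3 <- g + ggplot2::aes(y = pred_rmse) + ggplot2::labs(y = "RMSEP")
    p3 <- file.path(dir, "prediction_rmse.png")
    ggplot2::ggsave(p3, g3, width = 10, height = 6, dpi = 150)
    paths <- c(paths, p1, p2, p3)
  }

  # winner scatter plots
  ds <- resolve_dataset(grid$config$dataset)
  for (i in seq_len(nrow(best$winners))) {
    w <- best$winners[i, ]
    if (identical(w$model, "no model")) next
    key <- paste(w$indicator, w$preprocessing, w$model, w$mode, sep = "|")
    det <- grid$details[[key]]
    if (is.null(det$pred_test)) next
    y <- ds$references[[w$indicator]]
    dfp <- data.frame(
      reference = y[det$split$test_indices],
      predicted = det$pred_test
    )
    gsc <- ggplot2::ggplot(dfp, ggplot2::aes(reference, predicted)) +
      ggplot2::geom_point(color = "steelblue") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(
        title = sprintf(
          "%s: %s-%s (%s), Rp2 = %.3f", w$indicator, w$preprocessing,
          w$model, w$mode, w$pred_r2
        ),
        x = "reference", y = "predicted"
      ) +
      ggplot2::theme_bw()
    psc <- file.path(dir, sprintf("scatter_%s.png", w$indicator))
    ggplot2::ggsave(psc, gsc, width = 5, height = 5, dpi = 150)
    paths <- c(paths, psc)
  }

  # SPA position plots and CNN loss curves, where present
  for (key in names(grid$details)) {
    det <- grid$details[[key]]
    tag <- gsub("[^A-Za-z0-9]+", "_", key)
    if (!is.null(det$selection)) {
      wlv <- as.numeric(ds$spectra$grid)[det$selection$selected_indices]
      dsel <- data.frame(wavelength = wlv)
      gw <- ggplot2::ggplot(dsel, ggplot2::aes(x = wavelength, y = 0)) +
        ggplot2::geom_point(shape = 3, color = "firebrick") +
        ggplot2::labs(x = "wavelength (nm)", y = NULL, title = key) +
        ggplot2::theme_bw() +
        ggplot2::theme(
          axis.text.y = ggplot2::element_blank(),
          axis.ticks.y = ggplot2::element_blank()
        )
      pw <- file.path(dir, sprintf("spa_positions_%s.png", tag))
      ggplot2::ggsave(pw, gw, width = 8, height = 1.8, dpi = 150)
      paths <- c(paths, pw)
    }
    if (!is.null(det$model_diag$history)) {
      h <- det$model_diag$history
      dfl <- data.frame(
        epoch = seq_along(h$train_loss),
        calibration = h$train_loss,
        prediction = if (is.null(h$monitor_loss)) NA_real_ else h$monitor_loss
      )
      dfl <- stats::reshape(
        dfl, direction = "long", varying = c("calibration", "prediction"),
        v.names = "loss", timevar = "set",
        times = c("calibration", "prediction")
      )
      gl <- ggplot2::ggplot(dfl, ggplot2::aes(epoch, loss, color = set)) +
        ggplot2::geom_line() +
        ggplot2::labs(title = key, y = "MSE loss") +
        ggplot2::theme_bw()
      pl <- file.path(dir, sprintf("cnn_loss_%s.png", tag))
      ggplot2::ggsave(pl, gl, width = 6, height = 4, dpi = 150)
      paths <- c(paths, pl)
    }
  }
  invisible(paths)
}
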