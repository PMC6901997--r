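#' Grid search over the filter-bank size
#'
#' The two architecture hyperparameters that matter most are the number of
#' temporal filters per branch `F_T` and the ratio `D = F_T / F_S`. This
#' helper enumerates their combinations, trains one model per valid
#' combination (those where `F_S = F_T / D` is an integer), and reports the
#' best validation accuracy of each — the usual two-stage search in which
#' `D` is scanned first and `F_S` adjusted under the best `D`.
#'
#' @param train_ds,valid_ds `eeg_epochs` datasets.
#' @param F_T_values,D_values grids to enumerate.
#' @param model_fields named list of further [model_config()] fields
#'   (kernel lengths, pooling geometry, ...); `C`, `T`, `N_C` default to
#'   the data's dimensions.
#' @param cfg a [train_config()].
#' @param init weight initialization scheme, see [initialize_weights()].
#' @return tibble with one row per trained combination: `F_T`, `D`, `F_S`,
#'   `valid_accuracy`, `best_epoch`.
#' @export
grid_search <- function(train_ds, valid_ds,
                        F_T_values = c(10L, 20L, 40L),
                        D_values = c(0.5, 1, 2),
                        model_fields = list(), cfg = train_config(),
                        init = "scaled") {
  rows <- list()
  for (ft in F_T_values) {
    for (d in D_values) {
      fs <- ft / d
      if (abs(fs - round(fs)) > 1e-8 || fs < 1) next
      fields <- utils::modifyList(model_fields,
                                  list(F_T = as.integer(ft),
                                       F_S = as.integer(round(fs))))
      fields$D <- NULL
      mcfg <- resolve_model_config(fields, train_ds)
      fit <- train(build_model(mcfg, init = init, seed = cfg$seed),
                   train_ds, valid_ds, cfg)
      best <- attr(fit$history, "best_epoch")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        F_T = as.integer(ft), D = d, F_S = as.integer(round(fs)),
        valid_accuracy = fit$history$valid_accuracy[best],
        best_epoch = best)
    }
  }
  if (!length(rows))
    stop("no (F_T, D) combination gives an integer F_S >= 1", call. = FALSE)
  do.call(rbind, rows)
}
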