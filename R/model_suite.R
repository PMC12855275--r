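#' Enumerate the a-priori candidate condition models
#'
#' Builds the 19 competing model formulations for one sex. Every model
#' carries the per-bear random intercept; models 4, 8a--c, 9a--c and 10
#' additionally carry the spatial random field. Continuous covariates
#' (year, age, day, AO indices, break-up dates, ice-free days) enter as RW2
#' smoothers by default; `linear` demotes chosen terms to plain slopes. For
#' females every model adds reproductive state as a fixed effect and model
#' labels use the `F` prefix instead of `M`.
#'
#' @param sex `"M"` or `"F"`.
#' @param linear optional character vector of smoother terms to treat as
#'   linear fixed effects in every candidate.
#' @return object of class `candidate_set`: named list of [model_spec()]s.
#' @export
enumerate_candidates <- function(sex = c("M", "F"), linear = character()) {
  sex <- match.arg(sex)
  terms <- list(
    "1"  = character(),
    "2a" = c("winter_ao", "spring_ao"),
    "2b" = c("spring_ao_lag1", "winter_ao"),
    "3a" = "breakup",
    "3b" = "breakup_lag1",
    "3c" = "ice_free_days",
    "4"  = character(),
    "5"  = "year",
    "6"  = "day",
    "7a" = c("winter_ao", "spring_ao", "breakup"),
    "7b" = c("winter_ao", "spring_ao", "breakup_lag1"),
    "7c" = c("winter_ao", "spring_ao", "ice_free_days"),
    "8a" = c("winter_ao", "spring_ao", "breakup", "day"),
    "8b" = c("winter_ao", "spring_ao", "breakup_lag1", "day"),
    "8c" = c("winter_ao", "spring_ao", "ice_free_days", "day"),
    "9a" = c("winter_ao", "spring_ao", "breakup", "day", "age"),
    "9b" = c("winter_ao", "spring_ao", "breakup_lag1", "day", "age"),
    "9c" = c("winter_ao", "spring_ao", "ice_free_days", "day", "age"),
    "10" = c("year", "age", "day"))
  spatial_ids <- c("4", "8a", "8b", "8c", "9a", "9b", "9c", "10")
  prefix <- if (sex == "M") "M" else "F"
  fixed <- if (sex == "F") "repro" else character()
  specs <- lapply(names(terms), function(id) {
    model_spec(name = paste0(prefix, id),
               fixed = fixed,
               smoothers = terms[[id]],
               random_intercept = TRUE,
               spatial = id %in% spatial_ids,
               linear = intersect(linear, terms[[id]]))
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(sex = sex, specs = specs), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set (%s): %d models\n", x$sex, length(x$specs)))
  for (s in x$specs) print(s)
  invisible(x)
}

#' Serializable manifest of a candidate set
#'
#' One row per candidate with its term structure; stable across runs, used
#' for golden-file checks and run manifests.
#'
#' @param candidates a [enumerate_candidates()] result.
#' @return data frame with model, fixed, smoothers, random-intercept and
#'   spatial columns.
#' @export
candidate_manifest <- function(candidates) {
  data.frame(
    model = vapply(candidates$specs, `[[`, "", "name"),
    fixed = vapply(candidates$specs,
                   function(s) paste(s$fixed, collapse = "+"), ""),
    smoothers = vapply(candidates$specs,
                       function(s) paste(s$smoothers, collapse = "+"), ""),
    random_intercept = vapply(candidates$specs, `[[`, TRUE, "random_intercept"),
    spatial = vapply(candidates$specs, `[[`, TRUE, "spatial"),
    row.names = NULL)
}

#' Fit every candidate model and collect information criteria
#'
#' Fits each spec with shared settings; a failing fit is recorded as a
#' failed row (with its error message) and the suite continues. Fits are
#' deterministic given data and settings.
#'
#' @param candidates a [enumerate_candidates()] result, or a plain list of
#'   [model_spec()]s.
#' @param data prepared sex-specific capture data frame.
#' @param settings a [fit_settings()].
#' @param keep_fits retain the full fit objects in the result.
#' @return object of class `comparison_table` (ranked, see
#'   [rank_models()]), with attribute `fits` when `keep_fits`.
#' @export
fit_all <- function(candidates, data, settings = fit_settings(),
                    keep_fits = FALSE) {
  specs <- if (inherits(candidates, "candidate_set")) candidates$specs
           else candidates
  rows <- list()
  fits <- list()
  for (spec in specs) {
    res <- tryCatch({
      fit <- fit_model(spec, data, settings)
      dic <- compute_dic(fit)
      waic <- compute_waic(fit)
      if (keep_fits) fits[[spec$name]] <- fit
      data.frame(model = spec$name, dic = dic$dic, p_d = dic$p_d,
                 waic = waic$waic, p_waic = waic$p_waic,
                 ok = TRUE, error = "")
    }, error = function(e) {
      data.frame(model = spec$name, dic = NA_real_, p_d = NA_real_,
                 waic = NA_real_, p_waic = NA_real_,
                 ok = FALSE, error = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- rank_models(do.call(rbind, rows))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Rank a model-comparison table
#'
#' Sorts by WAIC (ties broken by DIC), assigns ranks and differences to the
#' best model. Failed fits sort last with `NA` rank.
#'
#' @param table data frame with at least `model`, `dic`, `waic` columns.
#' @return the table sorted, with `rank`, `delta_waic` and `delta_dic`
#'   columns, classed `comparison_table`.
#' @export
rank_models <- function(table) {
  stopifnot(all(c("model", "dic", "waic") %in% names(table)))
  if (!"ok" %in% names(table)) table$ok <- !is.na(table$waic)
  if (!any(table$ok)) stop("no successful fits to rank", call. = FALSE)
  table <- table[order(!table$ok, table$waic, table$dic, table$model), ,
                 drop = FALSE]
  table$rank <- NA_integer_
  table$rank[table$ok] <- seq_len(sum(table$ok))
  best <- table[which(table$ok)[1], ]
  table$delta_waic <- table$waic - best$waic
  table$delta_dic <- table$dic - best$dic
  rownames(table) <- NULL
  class(table) <- c("comparison_table", "data.frame")
  table
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("model comparison (%d candidates, best: %s)\n",
              nrow(x), x$model[1]))
  df <- as.data.frame(x)
  df$error <- NULL
  print(format(df, digits = 5), row.names = FALSE)
  invisible(x)
}
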