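#' Read long-format ratings from CSV
#'
#' Expects a header `ratee,item,rater,score`. Scores must be 0 or 1 and
#' (ratee, item, rater) triples must be unique; violations fail with the
#' offending line number.
#'
#' @param path CSV path.
#' @return Validated data frame with the four columns.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("ratee", "item", "rater", "score")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("ratings file must have header ratee,item,rater,score.",
         call. = FALSE)
  }
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(sc) | !(sc %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary score at line %d (value \"%s\").",
                 bad[1] + 1L, df$score[bad[1]]), call. = FALSE)
  }
  df$score <- as.integer(sc)
  key <- paste(df$ratee, df$item, df$rater)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (ratee, item, rater) triple at line %d: %s.",
                 dup[1] + 1L, key[dup[1]]), call. = FALSE)
  }
  df
}

#' Write long-format ratings to CSV
#'
#' @param ratings Data frame with columns `ratee, item, rater, score`, or a
#'   `sim_ratings` object (its truth side-tables are written alongside with
#'   a `_truth` suffix).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  if (inherits(ratings, "sim_ratings")) {
    truth <- ratings$truth
    tpath <- sub("(\\.csv)?$", "_truth.csv", path)[1]
    utils::write.csv(cbind(data.frame(ratee = seq_len(nrow(truth$alpha))),
                           as.data.frame(truth$alpha)),
                     tpath, row.names = FALSE)
    ratings <- ratings$ratings
  }
  utils::write.csv(ratings[, c("ratee", "item", "rater", "score")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a fit summary as JSON
#'
#' Serializes EAPs, posterior SDs, R-hat values, mastery probabilities,
#' classified profiles, and the id maps.
#'
#' @param fit A `cdm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cdm_fit"))
  out <- list(
    model = fit$model, cdm = fit$cdm,
    parameters = lapply(seq_along(fit$eap), function(p)
      list(name = names(fit$eap)[p], eap = unname(fit$eap[p]),
           sd = unname(fit$sd[p]), rhat = unname(fit$rhat[p]))),
    mastery = unname(apply(fit$mastery, 1, as.list)),
    profiles = unname(apply(fit$profiles, 1, paste, collapse = "")),
    ids = fit$data$levels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fills in default model, prior, and schedule fields for anything the file
#' leaves unspecified; `seed` has no default and must be present for
#' simulation or replication runs.
#'
#' @param path YAML path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(model = "facets", cdm = "saturated",
                   design = "complete", iterations = 10000L,
                   burnin = 5000L, thin = 10L, chains = 2L)
  utils::modifyList(defaults, cfg)
}
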