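# Generating structures for the parameter-recovery simulation studies: a
# 10-item / 5-attribute Q-matrix (five single-attribute items, five
# two-attribute items), the item kernels used to generate data, and the
# ten rater severities (which sum to zero by construction).

#' Q-matrix of the recovery simulation studies
#'
#' Ten dichotomous items measuring five attributes: items 1-5 each load on a
#' single attribute, items 6-10 each on a pair of adjacent attributes.
#'
#' @return A `qmatrix` with 10 rows and 5 columns.
#' @export
sim_qmatrix <- function() {
  q <- rbind(
    c(1, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0),
    c(0, 0, 1, 0, 0),
    c(0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 1),
    c(1, 1, 0, 0, 0),
    c(0, 1, 1, 0, 0),
    c(0, 0, 1, 1, 0),
    c(0, 0, 0, 1, 1),
    c(1, 0, 0, 0, 1))
  as_qmatrix(q)
}

#' Generating item parameters of the recovery simulation studies
#'
#' Intercepts, main effects and (for the two-attribute items) two-way
#' interaction weights of the ten simulation items. Each two-attribute item
#' carries a single main-effect value applied to both of its required
#' attributes; this is the reading under which the implied guessing
#' probabilities span \[0.08, 0.20\] and the slip probabilities span
#' \[0.07, 0.19\] (2 dp).
#'
#' @param cdm `"saturated"` returns the LCDM kernels; `"dina"` collapses each
#'   item to its DINA restriction with the same endpoints (intercept kept,
#'   conjunction weight equal to the full-mastery kernel minus the
#'   intercept).
#' @return List of 10 [item_params()] objects.
#' @export
sim_item_params <- function(cdm = c("saturated", "dina")) {
  cdm <- match.arg(cdm)
  l0 <- c(-2.00, -1.40, -1.79, -1.37, -1.85, -2.42, -1.57, -1.95, -2.07, -1.69)
  l1 <- c(3.72, 2.82, 3.41, 2.91, 3.38, 1.26, 1.04, 1.18, 1.00, 0.96)
  l2 <- c(NA, NA, NA, NA, NA, 2.16, 2.14, 1.98, 2.05, 2.12)
  pairs <- list(NULL, NULL, NULL, NULL, NULL,
                c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))
  out <- vector("list", 10L)
  for (j in 1:10) {
    if (cdm == "dina") {
      full <- if (is.na(l2[j])) l1[j] else 2 * l1[j] + l2[j]
      out[[j]] <- dina_params(l0[j], full)
    } else if (is.null(pairs[[j]])) {
      out[[j]] <- item_params(l0[j], main_effects = l1[j])
    } else {
      ints <- stats::setNames(l2[j], paste(pairs[[j]], collapse = ","))
      out[[j]] <- item_params(l0[j], main_effects = l1[j], interactions = ints)
    }
  }
  out
}

#' Generating rater severities of the recovery simulation studies
#'
#' Severities for the ten raters of Study-style facets data; they sum to
#' zero, matching the zero-mean identification constraint used in fitting.
#'
#' @return Numeric vector of length 10.
#' @export
sim_rater_severities <- function() {
  c(0.57, 0.59, 0.70, 1.83, -0.50, -0.56, -0.10, -1.05, 0.55, -2.03)
}

#' Q-matrix of the essay-checklist fixture
#'
#' The 52-criterion, six-attribute loading structure used by the synthetic
#' essay-checklist fixture (content, organization, grammar, vocabulary,
#' academic conventions, mechanics).
#'
#' @return A `qmatrix` with 52 rows and 6 columns.
#' @export
checklist_qmatrix <- function() {
  q <- rbind(
    c(1,1,1,1,1,0), c(1,0,0,0,0,0), c(1,0,0,0,0,0), c(0,1,1,1,0,0),
    c(0,1,1,1,0,0), c(1,0,1,1,1,0), c(1,1,1,1,0,0), c(1,1,0,0,0,0),
    c(1,1,0,0,0,0), c(1,1,0,0,0,0), c(1,0,0,1,0,0), c(1,1,0,1,0,0),
    c(1,0,0,0,0,0), c(0,1,0,0,1,0), c(0,1,0,0,0,0), c(0,1,0,0,0,0),
    c(0,1,0,0,0,0), c(0,1,0,0,0,0), c(0,1,0,0,0,0), c(0,1,0,0,0,0),
    c(0,1,1,1,0,0), c(0,1,1,1,0,0), c(0,1,1,1,0,0), c(0,1,1,1,0,0),
    c(0,1,0,0,0,0), c(0,0,1,0,0,0), c(0,0,1,0,0,0), c(0,0,1,0,0,0),
    c(0,0,1,0,0,0), c(0,0,1,0,0,0), c(0,0,1,0,0,1), c(0,0,1,0,0,1),
    c(0,0,1,0,0,0), c(0,0,1,0,0,0), c(0,0,1,0,0,0), c(0,0,1,1,0,0),
    c(0,0,1,0,0,0), c(0,0,1,0,0,0), c(0,0,1,1,0,0), c(0,0,1,1,0,0),
    c(0,0,0,1,0,0), c(0,0,0,1,0,0), c(0,0,0,1,0,0), c(0,0,0,1,0,0),
    c(0,0,1,1,0,0), c(0,0,0,1,0,1), c(0,0,0,1,0,1), c(0,0,1,0,0,1),
    c(0,0,0,0,0,1), c(0,0,0,0,0,1), c(0,0,1,1,1,0), c(0,0,1,1,1,0))
  as_qmatrix(q)
}
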