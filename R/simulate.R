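# Synthetic-data generators: dichotomous ratings under the facets model
# (severity inside the logit) and the HRM (shared latent ideal category per
# ratee-item response, noisy rating stage per rater).

# kernel matrix over all 2^K classes: C x J
.kernel_matrix <- function(item_params, qmatrix) {
  pat <- attribute_patterns(ncol(qmatrix))
  J <- nrow(qmatrix)
  out <- matrix(0, nrow(pat), J)
  for (j in seq_len(J)) {
    out[, j] <- apply(pat, 1, function(a)
      lcdm_kernel(item_params[[j]], a, qmatrix[j, ]))
  }
  out
}

.check_sim_args <- function(qmatrix, item_params, design, profiles, rho) {
  stopifnot(inherits(design, "rating_design"))
  if (length(item_params) != nrow(qmatrix)) {
    stop("need one item_params per Q-matrix row.", call. = FALSE)
  }
  if (!is.null(profiles) && nrow(profiles$alpha) != design$N) {
    stop("profiles and design disagree on the number of ratees.",
         call. = FALSE)
  }
}

#' Simulate dichotomous ratings under the facets model
#'
#' Each permitted (ratee, item, rater) triple receives an independent
#' Bernoulli score with success probability `plogis(kernel - eta_r)`; the
#' generating attribute profiles (and underlying continuous abilities) are
#' returned as a truth side-table.
#'
#' @param qmatrix A `qmatrix`.
#' @param item_params List of [item_params()], one per item.
#' @param eta Numeric vector of rater severities, one per rater.
#' @param design A [rating_design()].
#' @param profiles Optional profile list from [sim_profiles()]; drawn with
#'   correlation `rho` if omitted.
#' @param rho Inter-attribute correlation used when drawing profiles.
#' @param seed Optional integer seed.
#' @return Object of class `sim_ratings`: list with `ratings` (long-format
#'   data frame `ratee, item, rater, score`), `truth` (profiles, class
#'   indices, generating parameters), `qmatrix`, `design`, `model`.
#' @export
simulate_facets <- function(qmatrix, item_params, eta, design,
                            profiles = NULL, rho = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_sim_args(qmatrix, item_params, design, profiles, rho)
  if (length(eta) != design$R) {
    stop("need one severity per rater.", call. = FALSE)
  }
  if (is.null(profiles)) {
    profiles <- sim_profiles(design$N, ncol(qmatrix), rho)
  }
  J <- nrow(qmatrix)
  ker <- .kernel_matrix(item_params, qmatrix)
  pairs <- which(design$assignment, arr.ind = TRUE)
  ii <- rep(pairs[, 1], each = J)
  rr <- rep(pairs[, 2], each = J)
  jj <- rep(seq_len(J), times = nrow(pairs))
  p <- stats::plogis(ker[cbind(profiles$class[ii], jj)] - eta[rr])
  score <- stats::rbinom(length(p), 1L, p)
  ord <- order(ii, jj, rr)
  structure(list(
    ratings = data.frame(ratee = ii, item = jj, rater = rr,
                         score = score)[ord, , drop = FALSE],
    truth = list(alpha = profiles$alpha, theta = profiles$theta,
                 class = profiles$class, eta = eta,
                 item_params = item_params),
    qmatrix = qmatrix, design = design, model = "facets"),
    class = "sim_ratings")
}

#' Simulate dichotomous ratings under the HRM
#'
#' Two-stage generation: one latent ideal category `xi` is drawn per
#' (ratee, item) response from the latent-category LCDM, then every rater
#' assigned to that ratee scores the shared `xi` through their own
#' signal-detection rating stage ([hrm_rating_prob()]). Raters of the same
#' response are conditionally independent given `xi` but marginally
#' correlated through it.
#'
#' @inheritParams simulate_facets
#' @param phi Numeric vector of rater severities.
#' @param psi Numeric vector of positive rater variabilities.
#' @param xi `"shared"` draws one latent category per (ratee, item) response
#'   and lets every rater score it — the hierarchical rater premise, under
#'   which raters of a response are marginally correlated and extra raters
#'   saturate quickly. `"per_rating"` redraws the category independently for
#'   every rating, so each additional rater contributes an independent
#'   realization; this is the regime under which profile recovery keeps
#'   improving with the rater count, and is what the recovery-study harness
#'   uses.
#' @return A `sim_ratings` object; `truth` additionally carries the `xi`
#'   draws (an N x J matrix for `"shared"`, one value per score row for
#'   `"per_rating"`).
#' @export
simulate_hrm <- function(qmatrix, item_params, phi, psi, design,
                         profiles = NULL, rho = 0.5, seed = NULL,
                         xi = c("shared", "per_rating")) {
  xi <- match.arg(xi)
  if (!is.null(seed)) set.seed(seed)
  .check_sim_args(qmatrix, item_params, design, profiles, rho)
  if (length(phi) != design$R || length(psi) != design$R) {
    stop("need one phi and one psi per rater.", call. = FALSE)
  }
  if (any(psi <= 0)) stop("psi must be strictly positive.", call. = FALSE)
  if (is.null(profiles)) {
    profiles <- sim_profiles(design$N, ncol(qmatrix), rho)
  }
  N <- design$N; J <- nrow(qmatrix)
  ker <- .kernel_matrix(item_params, qmatrix)
  pairs <- which(design$assignment, arr.ind = TRUE)
  ii <- rep(pairs[, 1], each = J)
  rr <- rep(pairs[, 2], each = J)
  jj <- rep(seq_len(J), times = nrow(pairs))
  if (xi == "shared") {
    pxi <- stats::plogis(ker[profiles$class, , drop = FALSE])  # N x J
    xi_mat <- matrix(stats::rbinom(N * J, 1L, as.vector(pxi)), N, J)
    x <- xi_mat[cbind(ii, jj)]
  } else {
    x <- stats::rbinom(length(ii), 1L,
                       stats::plogis(ker[cbind(profiles$class[ii], jj)]))
    xi_mat <- NULL
  }
  p1 <- stats::plogis((2 * (x - phi[rr]) - 1) / (2 * psi[rr]^2))
  score <- stats::rbinom(length(p1), 1L, p1)
  ord <- order(ii, jj, rr)
  structure(list(
    ratings = data.frame(ratee = ii, item = jj, rater = rr,
                         score = score)[ord, , drop = FALSE],
    truth = list(alpha = profiles$alpha, theta = profiles$theta,
                 class = profiles$class,
                 xi = if (xi == "shared") xi_mat else x[ord],
                 xi_mode = xi, phi = phi, psi = psi,
                 item_params = item_params),
    qmatrix = qmatrix, design = design, model = "hrm"),
    class = "sim_ratings")
}

#' Synthetic essay-checklist fixture
#'
#' Emulates the shape of a checklist-scored essay assessment: 287 ratees,
#' the 52-criterion six-attribute [checklist_qmatrix()], and nine raters
#' with each essay judged by one or two of them. Scores are generated under
#' an HRM-DINA: DINA item kernels with synthetic guessing/slip levels and a
#' rater pool whose severities and variabilities span the severe-and-
#' consistent to lenient-and-erratic range. The assignment chains raters
#' through shared essays so the rater graph is connected. All generating
#' values are retained in `truth`; the fixture is synthetic and stands in
#' for no real dataset.
#'
#' @param seed Integer seed.
#' @return A `sim_ratings` object (model `"hrm"`, DINA kernels).
#' @export
checklist_fixture <- function(seed = 1) {
  set.seed(seed)
  q <- checklist_qmatrix()
  J <- nrow(q)
  N <- 287L
  R <- 9L
  g <- stats::runif(J, 0.03, 0.45)
  s <- stats::runif(J, 0.03, 0.50)
  ip <- lapply(seq_len(J), function(j)
    dina_params(stats::qlogis(g[j]), stats::qlogis(1 - s[j]) -
                  stats::qlogis(g[j])))
  phi <- c(0.40, 0.02, 0.01, 0.02, 0.01, 0.02, 0.24, 0.04, 0.02)
  psi <- c(0.37, 0.84, 0.69, 0.70, 0.53, 0.52, 0.76, 1.28, 0.49)
  A <- matrix(FALSE, N, R)
  first <- (seq_len(N) - 1L) %% R + 1L
  A[cbind(seq_len(N), first)] <- TRUE
  # first 9 essays get the chained second rater (guarantees connectivity);
  # roughly half of the rest get a random second rater
  second <- first %% R + 1L
  dbl <- c(seq_len(R), which(stats::runif(N) < 0.5 & seq_len(N) > R))
  A[cbind(dbl, second[dbl])] <- TRUE
  design <- structure(list(assignment = A, kind = "random", N = N, R = R),
                      class = "rating_design")
  simulate_hrm(q, ip, phi, psi, design, rho = 0.5)
}

#' @export
print.sim_ratings <- function(x, ...) {
  cat(sprintf("<sim_ratings: %s model, %d ratees x %d items, %d raters, %d scores>\n",
              x$model, x$design$N, nrow(x$qmatrix), x$design$R,
              nrow(x$ratings)))
  invisible(x)
}
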