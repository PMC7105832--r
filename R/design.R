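#' Generate correlated binary attribute profiles
#'
#' Draws continuous abilities \eqn{\theta_i \sim MVN(0, \Sigma)} with unit
#' variances and a common inter-attribute correlation `rho`, then
#' dichotomizes attribute k at the standard normal quantile
#' \eqn{\Phi^{-1}(k / (K + 1))}: mastery (\eqn{\alpha_{ik} = 1}) when
#' \eqn{\theta_{ik} \ge} the threshold (ties, a measure-zero event, count as
#' mastery). Marginal mastery rates therefore decline from attribute 1 to
#' attribute K: \eqn{P(\alpha_{ik} = 1) = 1 - k/(K+1)}.
#'
#' @param N Number of ratees.
#' @param K Number of attributes.
#' @param rho Common inter-attribute correlation, in \[0, 1).
#' @param seed Optional integer seed (set before drawing).
#' @return List with `alpha` (N x K integer matrix), `theta` (N x K),
#'   `thresholds` (length K), and `class` (1-based profile index per ratee).
#' @export
sim_profiles <- function(N, K, rho = 0.5, seed = NULL) {
  stopifnot(N >= 1, K >= 1)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1).", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- matrix(rho, K, K)
  diag(sigma) <- 1
  cf <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance not positive definite.",
                                          call. = FALSE))
  theta <- matrix(stats::rnorm(N * K), N, K) %*% cf
  thresholds <- stats::qnorm(seq_len(K) / (K + 1))
  alpha <- matrix(0L, N, K)
  for (k in seq_len(K)) alpha[, k] <- as.integer(theta[, k] >= thresholds[k])
  list(alpha = alpha, theta = theta, thresholds = thresholds,
       class = profile_index(alpha))
}

.unbalanced_sizes_500_10 <- c(50, 68, 44, 58, 35, 51, 50, 55, 40, 49)

# Rater triple for block b of R raters: {b, b+1, b+2} cyclically.
.block_raters <- function(b, R) ((b - 1L + 0:2) %% R) + 1L

#' Construct a rater-assignment design
#'
#' Builds the ratee-by-rater assignment matrix for four rating designs:
#' `"complete"` (every rater judges every ratee), `"balanced"` (each ratee
#' judged by three raters assigned in rotating blocks of `N/R` ratees so
#' that every rater judges `3N/R` ratees), `"unbalanced"` (same rotating
#' blocks with unequal block sizes; for N = 500, R = 10 the canonical block
#' sizes 50, 68, 44, 58, 35, 51, 50, 55, 40, 49 are used, giving rater
#' totals 139, 167, 162, 170, 137, 144, 136, 156, 145, 144), and `"random"`
#' (20 anchor ratees judged by all raters, the rest by three raters drawn
#' uniformly without replacement). All designs are checked for connectivity
#' of the rater graph through shared ratees.
#'
#' @param kind One of `"complete"`, `"balanced"`, `"unbalanced"`, `"random"`.
#' @param N Number of ratees.
#' @param R Number of raters.
#' @param seed Optional seed (only the random design draws).
#' @return Object of class `rating_design`: list with `assignment` (N x R
#'   logical), `kind`, `N`, `R`.
#' @export
rating_design <- function(kind = c("complete", "balanced", "unbalanced",
                                   "random"),
                          N, R, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(N >= 1, R >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(FALSE, N, R)
  if (kind == "complete") {
    A[] <- TRUE
  } else {
    if (R < 3) stop("incomplete designs need at least 3 raters.", call. = FALSE)
    if (kind == "balanced") {
      if (N %% R != 0) {
        stop(sprintf("balanced design needs N divisible by R (got N=%d, R=%d).",
                     N, R), call. = FALSE)
      }
      sizes <- rep(N %/% R, R)
    } else if (kind == "unbalanced") {
      if (N == 500 && R == 10) {
        sizes <- .unbalanced_sizes_500_10
      } else {
        # proportional jitter around equal blocks, deterministic
        jit <- rep_len(.unbalanced_sizes_500_10 / 50, R)
        sizes <- floor(N * jit / sum(jit))
        rem <- N - sum(sizes)
        if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      }
    }
    if (kind %in% c("balanced", "unbalanced")) {
      stopifnot(sum(sizes) == N)
      start <- cumsum(c(0L, sizes[-length(sizes)]))
      for (b in seq_len(R)) {
        if (sizes[b] == 0) next
        rows <- (start[b] + 1L):(start[b] + sizes[b])
        A[rows, .block_raters(b, R)] <- TRUE
      }
    } else { # random
      anchors <- seq_len(min(20L, N))
      A[anchors, ] <- TRUE
      rest <- setdiff(seq_len(N), anchors)
      for (i in rest) A[i, sample.int(R, 3L)] <- TRUE
    }
  }
  d <- structure(list(assignment = A, kind = kind, N = N, R = R),
                 class = "rating_design")
  chk <- design_connected(d)
  if (!isTRUE(chk)) {
    stop(sprintf("design '%s' (N=%d, R=%d) is invalid: %s", kind, N, R, chk),
         call. = FALSE)
  }
  d
}

#' Check rating-design validity and connectivity
#'
#' Every ratee must have at least one rater, and the raters must form a
#' single connected component in the bipartite rater-ratee graph (otherwise
#' severities in disconnected blocks are not on a common scale).
#'
#' @param design A `rating_design`.
#' @return `TRUE` if valid, otherwise a character diagnostic.
#' @export
design_connected <- function(design) {
  A <- design$assignment
  if (any(rowSums(A) == 0)) {
    return(sprintf("ratee(s) without any rater: %s",
                   paste(utils::head(which(rowSums(A) == 0), 5),
                         collapse = ", ")))
  }
  R <- ncol(A)
  parent <- seq_len(R)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(A))) {
    rs <- which(A[i, ])
    if (length(rs) > 1) {
      r0 <- find(rs[1])
      for (r in rs[-1]) parent[find(r)] <- r0
    }
  }
  roots <- vapply(seq_len(R), find, integer(1))
  if (length(unique(roots)) > 1) {
    return("rater graph is disconnected (severities not on a common scale)")
  }
  TRUE
}

#' @export
print.rating_design <- function(x, ...) {
  cat(sprintf("<rating_design: %s, %d ratees x %d raters, %d pairs>\n",
              x$kind, x$N, x$R, sum(x$assignment)))
  invisible(x)
}
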