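#' Enumerate all attribute profiles
#'
#' Lists the \eqn{2^K} binary mastery profiles over \eqn{K} attributes in
#' canonical binary-counting order: profile number \eqn{c} (1-based) is the
#' binary expansion of \eqn{c - 1} with attribute 1 as the most significant
#' bit. This row order is the latent-class indexing used throughout the
#' samplers and is stable across runs and platforms.
#'
#' @param K Number of attributes; an integer between 1 and 15 (the class
#'   space has \eqn{2^K} elements, so larger K is refused).
#' @return Integer matrix with \eqn{2^K} rows and `K` columns, entries 0/1.
#' @examples
#' attribute_patterns(2)
#' @export
attribute_patterns <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K != round(K) ||
      K < 1 || K > 15) {
    stop("K must be a single integer in 1..15 (2^K latent classes).",
         call. = FALSE)
  }
  K <- as.integer(K)
  C <- 2L^K
  pat <- matrix(0L, C, K)
  for (k in seq_len(K)) {
    bit <- bitwShiftL(1L, K - k)
    pat[, k] <- as.integer(bitwAnd(0:(C - 1L), bit) > 0L)
  }
  colnames(pat) <- paste0("A", seq_len(K))
  pat
}

#' Index of a profile in the canonical enumeration
#'
#' @param alpha Binary vector (or matrix, one profile per row) of length K.
#' @return 1-based class index into [attribute_patterns()].
#' @export
profile_index <- function(alpha) {
  if (is.matrix(alpha)) {
    K <- ncol(alpha)
    return(as.integer(alpha %*% 2^((K - 1):0)) + 1L)
  }
  K <- length(alpha)
  as.integer(sum(alpha * 2^((K - 1):0))) + 1L
}

#' Item parameters for an LCDM kernel
#'
#' Container for one item's log-linear kernel: an intercept, main effects for
#' the item's required attributes, and interaction weights for subsets of the
#' required attributes. Main effects must be positive (the monotonicity
#' constraint used in estimation). A single unnamed main effect is shared
#' across all required attributes; a vector is matched positionally to the
#' required attributes (in attribute order), or by attribute index if named.
#'
#' @param intercept Real intercept \eqn{\lambda_{j0}}; the logit of success
#'   for a ratee mastering none of the required attributes.
#' @param main_effects Positive numeric vector of main effects
#'   \eqn{\lambda_{jk}} (see above for matching rules).
#' @param interactions Named numeric vector of interaction weights; names are
#'   comma-separated sorted attribute indices, e.g. `c("1,2" = 2.16)`.
#' @param model `"saturated"` or `"dina"`. For DINA, use [dina_params()].
#' @return Object of class `item_params`.
#' @seealso [dina_params()], [lcdm_kernel()], [lcdm_prob()]
#' @export
item_params <- function(intercept, main_effects = numeric(0),
                        interactions = numeric(0),
                        model = c("saturated", "dina")) {
  model <- match.arg(model)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  main_effects <- as.numeric(main_effects)
  if (model == "saturated") {
    if (length(main_effects) && any(main_effects <= 0)) {
      stop("main effects must be strictly positive (monotonicity constraint).",
           call. = FALSE)
    }
  } else {
    if (length(main_effects)) {
      stop("a DINA item has no free main effects; use dina_params().",
           call. = FALSE)
    }
    if (length(interactions) != 1L) {
      stop("a DINA item has exactly one free effect (the conjunction weight).",
           call. = FALSE)
    }
  }
  if (length(interactions)) {
    if (model == "saturated" && is.null(names(interactions))) {
      stop("interactions must be named by their attribute subsets, e.g. \"1,2\".",
           call. = FALSE)
    }
  }
  structure(list(intercept = intercept, main_effects = main_effects,
                 interactions = interactions, model = model),
            class = "item_params")
}

#' DINA item parameters
#'
#' The DINA restriction of the LCDM keeps only the intercept and the single
#' highest-order interaction over all attributes the item requires: success
#' probability takes just two values, depending on whether the ratee masters
#' every required attribute.
#'
#' @param intercept Logit of success without full mastery (guessing logit).
#' @param delta Conjunction weight added at full mastery; must be positive.
#' @return Object of class `item_params` with `model = "dina"`.
#' @export
dina_params <- function(intercept, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta <= 0) {
    stop("the DINA conjunction weight must be positive.", call. = FALSE)
  }
  item_params(intercept, interactions = c(all = delta), model = "dina")
}

.parse_subset <- function(nm) sort(as.integer(strsplit(nm, ",")[[1]]))

# Resolve an item's main effects against its q-row: returns a vector over
# `req` (the required attribute indices).
.resolve_mains <- function(params, req) {
  me <- params$main_effects
  if (!length(me)) return(numeric(length(req)) + NA_real_)
  if (!is.null(names(me)) && any(nzchar(names(me)))) {
    idx <- as.integer(names(me))
    if (!all(idx %in% req)) {
      stop("main effect refers to an attribute the item does not require.",
           call. = FALSE)
    }
    out <- numeric(length(req))
    out[match(idx, req)] <- me
    return(out)
  }
  if (length(me) == 1L) return(rep(me, length(req)))
  if (length(me) != length(req)) {
    stop("main_effects length does not match the item's required attributes.",
         call. = FALSE)
  }
  me
}

#' LCDM linear predictor (log-linear kernel)
#'
#' Evaluates \eqn{\lambda_{j0} + \sum_k \lambda_{jk}\alpha_k q_{jk} +
#' \sum_{k<v} \lambda_{jkv}\alpha_k\alpha_v q_{jk} q_{jv} + \dots} for one
#' item. Attributes the item does not require contribute nothing; an
#' interaction referencing a non-required attribute is an error.
#'
#' @param params An [item_params()] object.
#' @param alpha Binary attribute profile (length K).
#' @param q_row Binary Q-matrix row for the item (length K).
#' @return The linear predictor (a real number).
#' @examples
#' it <- item_params(-2, main_effects = 3.72)
#' lcdm_kernel(it, alpha = c(1, 0), q_row = c(1, 0))
#' @export
lcdm_kernel <- function(params, alpha, q_row) {
  stopifnot(inherits(params, "item_params"))
  alpha <- as.numeric(alpha)
  q_row <- as.numeric(q_row)
  if (length(alpha) != length(q_row)) {
    stop("alpha and q_row must have the same length.", call. = FALSE)
  }
  req <- which(q_row == 1)
  if (params$model == "dina") {
    return(params$intercept + params$interactions[[1L]] * prod(alpha[req]))
  }
  val <- params$intercept
  if (length(req)) {
    mains <- .resolve_mains(params, req)
    if (!anyNA(mains)) val <- val + sum(mains * alpha[req])
  }
  ints <- params$interactions
  if (length(ints)) {
    for (s in seq_along(ints)) {
      sub <- .parse_subset(names(ints)[s])
      if (!all(sub %in% req)) {
        stop(sprintf(
          "interaction \"%s\" references an attribute not required by the item.",
          names(ints)[s]), call. = FALSE)
      }
      val <- val + ints[[s]] * prod(alpha[sub])
    }
  }
  unname(val)
}

#' LCDM success probability
#'
#' Logistic transform of the [lcdm_kernel()] linear predictor: the
#' probability of a score of 1 on the item given the attribute profile.
#' Strictly inside (0, 1) and non-decreasing in each mastered attribute when
#' all main effects are positive.
#'
#' @inheritParams lcdm_kernel
#' @return Probability in (0, 1).
#' @export
lcdm_prob <- function(params, alpha, q_row) {
  stats::plogis(lcdm_kernel(params, alpha, q_row))
}

#' DINA success probability
#'
#' Conjunctive success probability: `plogis(intercept + delta)` when the
#' profile masters every attribute the item requires, `plogis(intercept)`
#' otherwise. Refuses saturated parameter objects.
#'
#' @inheritParams lcdm_kernel
#' @return Probability in (0, 1).
#' @export
dina_prob <- function(params, alpha, q_row) {
  stopifnot(inherits(params, "item_params"))
  if (params$model != "dina") {
    stop("dina_prob() requires DINA-constrained parameters; see dina_params().",
         call. = FALSE)
  }
  lcdm_prob(params, alpha, q_row)
}

#' Guessing and slip reparameterization
#'
#' Expresses an item's kernel as a guessing probability (success without
#' mastering all required attributes, evaluated at the all-zero profile) and
#' a slip probability (failure despite full required mastery).
#'
#' @inheritParams lcdm_kernel
#' @return List with elements `guessing` and `slip`, both in (0, 1).
#' @export
guess_slip <- function(params, q_row) {
  stopifnot(inherits(params, "item_params"))
  g <- stats::plogis(params$intercept)
  s <- 1 - lcdm_prob(params, alpha = as.numeric(q_row == 1), q_row = q_row)
  list(guessing = unname(g), slip = unname(s))
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<item_params: %s>\n", x$model))
  cat("  intercept:", format(x$intercept), "\n")
  if (length(x$main_effects)) {
    cat("  main effects:", paste(format(x$main_effects), collapse = " "), "\n")
  }
  if (length(x$interactions)) {
    cat("  interactions:",
        paste(sprintf("[%s]=%s", names(x$interactions),
                      format(unname(x$interactions))), collapse = " "), "\n")
  }
  invisible(x)
}
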