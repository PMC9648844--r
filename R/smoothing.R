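# Relational label smoothing: soft classification targets that spread part of
# the target weight uniformly over the superclass of objects sharing an
# attribute value with the true class, creating controllable perceptual biases
# in the pretrained vision module.

#' Specify a relational label smoothing condition
#'
#' The training target is `y = sigma * y_r + (1 - sigma) * y_0`, where `y_0`
#' is the one-hot target and `y_r` spreads weight uniformly over the other
#' members of the superclass sharing an attribute value with the true class.
#' With several attributes, `y_r` is the (weighted) average of the
#' per-attribute relational components.
#'
#' @param attributes Character subset of `c("color", "scale", "shape")`; may be
#'   empty only when `sigma = 0`.
#' @param sigma Smoothing factor in \[0, 1\].
#' @param weights Optional nonnegative per-attribute mixing weights (normalised
#'   to sum to 1); default equal weights.
#' @return An object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(attributes = character(), sigma = 0, weights = NULL) {
  attributes <- as.character(attributes)
  assert_that(all(attributes %in% class_attributes()),
              "attributes must be a subset of color/scale/shape")
  assert_that(!anyDuplicated(attributes), "duplicate attributes in spec")
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0 && sigma <= 1,
              "sigma must lie in [0, 1]")
  assert_that(sigma == 0 || length(attributes) > 0,
              "attribute set must be nonempty when sigma > 0")
  if (is.null(weights)) {
    weights <- rep(1 / max(length(attributes), 1), length(attributes))
  }
  assert_that(length(weights) == length(attributes) && all(weights >= 0),
              "weights must be nonnegative, one per attribute")
  if (length(weights) > 0) {
    assert_that(sum(weights) > 0, "at least one weight must be positive")
    weights <- weights / sum(weights)
  }
  structure(list(attributes = attributes, sigma = sigma,
                 weights = stats::setNames(weights, attributes)),
            class = "smoothing_spec")
}

#' Named pretraining conditions
#'
#' Shorthand for the standard bias conditions: `default` (no smoothing),
#' single-attribute `color` / `scale` / `shape` (sigma 0.6), `all`
#' (sigma 0.8), and the mixed pairs `color-scale` / `color-shape` /
#' `scale-shape` (default sigma 0.6, equal weights; see
#' [calibrate_mixed_bias()] for tuned versions).
#'
#' @param condition Condition name.
#' @param sigma Optional override of the condition's default smoothing factor.
#' @param weights Optional mixing weights for mixed conditions.
#' @return A [smoothing_spec()].
#' @export
bias_condition <- function(condition = c("default", "color", "scale", "shape", "all",
                                         "color-scale", "color-shape", "scale-shape"),
                           sigma = NULL, weights = NULL) {
  condition <- match.arg(condition)
  attrs <- switch(condition,
                  default = character(),
                  all = class_attributes(),
                  strsplit(condition, "-", fixed = TRUE)[[1]])
  if (is.null(sigma)) {
    sigma <- switch(condition, default = 0, all = 0.8, 0.6)
  }
  smoothing_spec(attrs, sigma, weights)
}

# 0/1 superclass membership matrix excluding the diagonal: M[i, j] = 1 iff
# classes i-1 and j-1 share the value of `attribute` and i != j.
superclass_matrix <- function(attribute) {
  vals <- class_values(0:63)
  v <- switch(attribute, color = vals$color_value, scale = vals$scale_value,
              shape = vals$shape_value,
              stop_refgame("unknown attribute: ", attribute))
  M <- outer(v, v, "==") * 1
  diag(M) <- 0
  M
}

#' Relational smoothing targets
#'
#' Computes the soft target vector(s) `y = sigma * y_r + (1 - sigma) * y_0`
#' for the given true class(es). Each single-attribute relational component
#' puts weight `1/(n-1)` on the `n - 1 = 15` other members of the true class's
#' superclass; multi-attribute components are averaged with the spec's weights.
#'
#' @param class_index Integer vector of true classes in 0..63.
#' @param spec A [smoothing_spec()].
#' @return A `length(class_index) x 64` matrix; each row is a probability
#'   vector.
#' @export
relational_target <- function(class_index, spec) {
  assert_that(inherits(spec, "smoothing_spec"), "spec must be a smoothing_spec")
  ci <- class_values(class_index)$class_index  # validates range
  n <- length(ci)
  Y0 <- matrix(0, n, 64)
  Y0[cbind(seq_len(n), ci + 1L)] <- 1
  if (spec$sigma == 0) return(Y0)
  Yr <- matrix(0, n, 64)
  for (a in spec$attributes) {
    M <- superclass_matrix(a)
    sz <- rowSums(M)  # n - 1 within each superclass (15 for every attribute)
    Yr <- Yr + spec$weights[[a]] * (M / sz)[ci + 1L, , drop = FALSE]
  }
  spec$sigma * Yr + (1 - spec$sigma) * Y0
}

#' @export
print.smoothing_spec <- function(x, ...) {
  if (length(x$attributes) == 0) {
    cat("<smoothing_spec> default (no smoothing)\n")
  } else {
    cat(sprintf("<smoothing_spec> attributes: %s | sigma = %g | weights: %s\n",
                paste(x$attributes, collapse = ", "), x$sigma,
                paste(sprintf("%.3g", x$weights), collapse = ", ")))
  }
  invisible(x)
}
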