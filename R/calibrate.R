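# Grid-search calibration of mixed-bias smoothing specs: choose the smoothing
# factor and attribute weighting whose pretrained representations give strong,
# balanced RSA for the two enforced attributes while leaving the third
# attribute's RSA low.

#' Calibrate a mixed-bias smoothing specification
#'
#' For each grid point (smoothing factor sigma, weight w on the first
#' attribute of the pair) a vision module is pretrained and its per-attribute
#' RSA profile measured. The selected point maximizes the minimum RSA over
#' the two enforced attributes among points whose unenforced-attribute RSA
#' stays below `unenforced_max`; if no point satisfies the cap, the
#' unconstrained maximizer is returned with a warning. A single-point grid is
#' returned as-is (with a warning when its sigma is 0, since no bias can be
#' enforced then).
#'
#' @param attribute_pair Character vector of exactly two distinct attributes
#'   from `c("color", "scale", "shape")`.
#' @param grid data.frame with columns `sigma` (in \[0,1\]) and `weight`
#'   (weight of the first attribute, in \[0,1\]; the second gets `1 - weight`).
#' @param split Train/test item split used for pretraining.
#' @param hp Pretraining hyperparameters ([pretrain_hp()]).
#' @param rsa_N Example images per class for the RSA profiles.
#' @param unenforced_max Cap on the unenforced attribute's RSA.
#' @param seed Optional integer seed.
#' @return The selected [smoothing_spec()], with the evaluated grid (a
#'   data.frame of profiles) attached as attribute `grid_results`.
#' @export
calibrate_mixed_bias <- function(attribute_pair, grid, split, hp = pretrain_hp(),
                                 rsa_N = 10L, unenforced_max = 0.2, seed = NULL) {
  attribute_pair <- as.character(attribute_pair)
  assert_that(length(attribute_pair) == 2L && !anyDuplicated(attribute_pair) &&
                all(attribute_pair %in% class_attributes()),
              "attribute_pair must be two distinct attributes")
  assert_that(is.data.frame(grid) && nrow(grid) >= 1L &&
                all(c("sigma", "weight") %in% names(grid)),
              "grid must be a nonempty data.frame with columns sigma and weight")
  make_spec <- function(sigma, w) {
    if (sigma == 0) return(smoothing_spec(character(), 0))
    smoothing_spec(attribute_pair, sigma, c(w, 1 - w))
  }
  if (nrow(grid) == 1L) {
    if (grid$sigma[1] == 0) {
      warning("single grid point has sigma = 0: bias targets unmet")
    }
    return(make_spec(grid$sigma[1], grid$weight[1]))
  }
  unenforced <- setdiff(class_attributes(), attribute_pair)
  res <- grid
  res$min_enforced <- NA_real_
  res$unenforced_rsa <- NA_real_
  for (i in seq_len(nrow(grid))) {
    spec <- make_spec(grid$sigma[i], grid$weight[i])
    hp_i <- hp
    hp_i$seed <- derive_seed(seed, i)
    vm <- pretrain_vision(split, spec, hp_i)
    prof <- rsa_bias_profile(vm, N = rsa_N, seed = derive_seed(seed, 10000L + i))
    res$min_enforced[i] <- min(prof[attribute_pair])
    res$unenforced_rsa[i] <- prof[unenforced]
  }
  feasible <- which(res$unenforced_rsa <= unenforced_max)
  if (length(feasible) == 0) {
    warning("no grid point keeps the unenforced attribute's RSA below the cap")
    feasible <- seq_len(nrow(res))
  }
  best <- feasible[which.max(res$min_enforced[feasible])]
  if (res$min_enforced[best] <= res$unenforced_rsa[best] || grid$sigma[best] == 0) {
    warning("selected grid point does not achieve the bias targets")
  }
  spec <- make_spec(grid$sigma[best], grid$weight[best])
  attr(spec, "grid_results") <- res
  spec
}
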