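# Evolutionary analysis: symmetrize pairwise sender/receiver rewards into a
# population payoff matrix over bias types, and identify evolutionary stable
# types. Type t is an ESS iff for every mutant t' != t either
# r(t,t) > r(t',t), or r(t',t) = r(t,t) and r(t,t') > r(t',t').

#' Symmetrize role-asymmetric game rewards into a payoff matrix
#'
#' The payoff between types t and t' is the mean of the run-mean reward of a
#' t-sender with a t'-receiver and that of a t'-sender with a t-receiver
#' (diagonal cells use same-type pairs directly). Run-level rewards are kept
#' per cell for bootstrap comparisons.
#'
#' @param role_rewards A data.frame with columns `sender_type`,
#'   `receiver_type` and `reward` (one row per run). Both role orders must be
#'   present for every pair of types.
#' @return An object of class `payoff_matrix`: a list with `types`, the
#'   symmetric `matrix`, and per-cell run-level `samples`.
#' @export
symmetrize <- function(role_rewards) {
  need <- c("sender_type", "receiver_type", "reward")
  assert_that(is.data.frame(role_rewards) && all(need %in% names(role_rewards)),
              "role_rewards needs columns sender_type, receiver_type, reward")
  types <- sort(unique(c(as.character(role_rewards$sender_type),
                         as.character(role_rewards$receiver_type))))
  nt <- length(types)
  M <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  samples <- stats::setNames(lapply(types, function(.) {
    stats::setNames(vector("list", nt), types)
  }), types)
  cell <- function(s, r) {
    role_rewards$reward[role_rewards$sender_type == s & role_rewards$receiver_type == r]
  }
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      a <- cell(types[i], types[j])
      b <- cell(types[j], types[i])
      assert_that(length(a) > 0 && length(b) > 0,
                  sprintf("missing runs for the pair (%s, %s)", types[i], types[j]))
      M[i, j] <- M[j, i] <- (mean(a) + mean(b)) / 2
      pooled <- if (i == j) a else c(a, b)
      samples[[i]][[j]] <- pooled
      samples[[j]][[i]] <- pooled
    }
  }
  structure(list(types = types, matrix = M, samples = samples),
            class = "payoff_matrix")
}

as_payoff <- function(payoff) {
  if (inherits(payoff, "payoff_matrix")) return(payoff)
  assert_that(is.matrix(payoff) && nrow(payoff) == ncol(payoff),
              "payoff must be a square matrix or a payoff_matrix")
  types <- rownames(payoff) %||% as.character(seq_len(nrow(payoff)))
  dimnames(payoff) <- list(types, types)
  list(types = types, matrix = payoff, samples = NULL)
}

#' Find evolutionary stable types in a payoff matrix
#'
#' Checks, for every resident type t and every mutant t', the strict
#' condition `r(t,t) > r(t',t)`; on a tie (within `tol`), the tie-breaking
#' condition `r(t,t') > r(t',t')`. Rows index the focal (row) player's type:
#' `payoff[a, b]` is the reward of a type-a agent interacting with a type-b
#' agent. With `significance = TRUE` (requires per-cell run samples from
#' [symmetrize()]), a comparison only counts as strict when the bootstrap CI
#' of the column-wise payoff difference excludes zero.
#'
#' @param payoff A `payoff_matrix` from [symmetrize()] or a plain symmetric
#'   matrix (rows/cols named by type).
#' @param tol Equality tolerance on point estimates (default 1e-9).
#' @param significance Require bootstrap-CI-supported strict inequalities.
#' @param level,reps,seed Bootstrap settings for the significance mode.
#' @return An object of class `ess_report`: list with `ess_types` and a
#'   per-comparison `conditions` data.frame (columns `type`, `mutant`,
#'   `branch`, `satisfied`).
#' @export
find_ess <- function(payoff, tol = 1e-9, significance = FALSE,
                     level = 0.95, reps = 2000L, seed = NULL) {
  po <- as_payoff(payoff)
  M <- po$matrix
  types <- po$types
  nt <- length(types)
  if (significance) {
    assert_that(!is.null(po$samples),
                "significance mode needs run-level samples (use symmetrize())")
  }
  diff_ci <- function(x, y, k) {
    d <- with_local_seed(derive_seed(seed, k), {
      vapply(seq_len(reps), function(i) {
        mean(sample(x, length(x), replace = TRUE)) -
          mean(sample(y, length(y), replace = TRUE))
      }, numeric(1))
    })
    stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7)
  }
  rows <- list()
  ess <- logical(nt)
  k <- 0L
  for (i in seq_len(nt)) {
    ok <- TRUE
    for (j in seq_len(nt)) {
      if (i == j) next
      k <- k + 1L
      strict <- M[i, i] > M[j, i] + tol
      tie <- abs(M[i, i] - M[j, i]) <= tol
      if (strict && significance) {
        ci <- diff_ci(po$samples[[i]][[i]], po$samples[[j]][[i]], k)
        strict <- ci[1] > 0
        tie <- !strict
      }
      if (strict) {
        branch <- "strict"; sat <- TRUE
      } else if (tie) {
        sat <- M[i, j] > M[j, j] + tol
        if (sat && significance) {
          ci <- diff_ci(po$samples[[i]][[j]], po$samples[[j]][[j]], k + 100000L)
          sat <- ci[1] > 0
        }
        branch <- "tie-break"
      } else {
        branch <- "strict"; sat <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(type = types[i], mutant = types[j],
                                              branch = branch, satisfied = sat)
      if (!sat) ok <- FALSE
    }
    ess[i] <- ok
  }
  structure(list(ess_types = types[ess],
                 conditions = do.call(rbind, rows),
                 significance = significance),
            class = "ess_report")
}

#' @export
print.ess_report <- function(x, ...) {
  cat("<ess_report>", if (x$significance) "(CI-based)" else "(point estimates)", "\n")
  cat("  ESS types:", if (length(x$ess_types)) paste(x$ess_types, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("<payoff_matrix> over types:", paste(x$types, collapse = ", "), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Round-robin tournament between bias types
#'
#' Trains and evaluates a fresh sender-receiver pair (fixed vision modules,
#' new language modules) for every ordered sender-type x receiver-type
#' combination and run, collects the greedy test rewards and symmetrizes them
#' into a payoff matrix.
#'
#' @param visions Named list of pretrained [vision_module()]s, one per type.
#' @param split Train/test item split for the games.
#' @param gc A [game_config()] (set `relevant_attributes` for the
#'   irrelevant-attribute variants).
#' @param sc A [scenario_config()]; its `seed` is overridden per run.
#' @param runs_per_pair Independent runs per ordered combination.
#' @param seed Master integer seed.
#' @return A `payoff_matrix` with the raw `role_rewards` attached as an
#'   attribute.
#' @export
run_tournament <- function(visions, split, gc = game_config(),
                           sc = scenario_config("fixed_vision_emergence"),
                           runs_per_pair = 1L, seed = NULL) {
  assert_that(is.list(visions) && !is.null(names(visions)) && length(visions) >= 2L,
              "visions must be a named list of at least two vision modules")
  types <- names(visions)
  rows <- list()
  idx <- 0L
  for (ts in types) {
    for (tr in types) {
      for (run in seq_len(runs_per_pair)) {
        idx <- idx + 1L
        rs <- derive_seed(seed, idx)
        sc_run <- sc
        sc_run$seed <- rs
        snd <- sender_agent(visions[[ts]], gc$vocab_size, gc$message_length,
                            seed = derive_seed(rs, 1L))
        rcv <- receiver_agent(visions[[tr]], gc$vocab_size, gc$message_length,
                              seed = derive_seed(rs, 2L))
        fit <- train_agents(snd, rcv, split, gc, sc_run)
        rows[[idx]] <- data.frame(sender_type = ts, receiver_type = tr,
                                  run = run, reward = fit$test_reward)
      }
    }
  }
  role_rewards <- do.call(rbind, rows)
  out <- symmetrize(role_rewards)
  attr(out, "role_rewards") <- role_rewards
  out
}
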