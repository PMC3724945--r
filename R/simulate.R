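# Seeded stochastic trajectory sampling and empirical estimators that
# cross-validate the exact Markov analytics.
#
# One RNG stream per call (Mersenne-Twister via the R generator, isolated
# with withr so user RNG state is untouched); within a step the nodes are
# drawn in node order, making trajectories bit-reproducible for a given
# seed across platforms.

# Precompiled one-step sampler. Only genuinely probabilistic updates (ties
# with an interior tie probability) consume RNG draws, in node order.
make_stepper <- function(net) {
  adj <- signed_adjacency(net)
  rep <- grn_representation(net)
  p <- frac_num(net$tie_prob)
  keep <- net$rule %in% c("IMR", "INMR")
  clamp_pos <- match(names(net$clamped), net$nodes)
  clamp_val <- unname(net$clamped)
  unclamped <- setdiff(seq_along(net$nodes), clamp_pos)
  function(values) {
    u <- as.vector(values %*% adj)
    bit <- ifelse(u > 0L, 1L, 0L)
    tied <- unclamped[u[unclamped] == 0L]
    if (length(tied) > 0L) {
      ph <- p[tied]
      if (keep) ph <- ifelse(values[tied] > 0L, ph, 1 - ph)
      det_hi <- ph >= 1; det_lo <- ph <= 0
      bit[tied[det_hi]] <- 1L
      bit[tied[det_lo]] <- 0L
      live <- tied[!det_hi & !det_lo]
      if (length(live) > 0L) {
        bit[live] <- as.integer(stats::runif(length(live)) < ph[!det_hi & !det_lo])
      }
    }
    out <- bits_to_values(bit, rep)
    if (length(clamp_pos) > 0L) out[clamp_pos] <- clamp_val
    out
  }
}

#' Sample a trajectory of the synchronous stochastic dynamics
#'
#' @param net A [grn].
#' @param init Initial configuration (vector in the rule's representation,
#'   or a configuration string).
#' @param steps Number of update steps.
#' @param seed Integer seed; trajectories are reproducible given the seed.
#' @return An object of class `grn_trajectory`: a list with `states`
#'   (character vector of length `steps + 1`), `values` (integer matrix),
#'   `seed` and `net`.
#' @export
sample_trajectory <- function(net, init, steps, seed = 1L) {
  stopifnot(inherits(net, "grn"), steps >= 0)
  rep <- grn_representation(net)
  if (is.character(init)) init <- parse_configuration(init, rep)
  check_representation(net, init)
  values <- matrix(0L, steps + 1L, length(init))
  values[1L, ] <- as.integer(init)
  step <- make_stepper(net)
  withr::with_seed(seed, {
    for (t in seq_len(steps)) {
      values[t + 1L, ] <- step(values[t, ])
    }
  })
  structure(
    list(states = apply(values, 1L, format_configuration, representation = rep),
         values = values, seed = seed, net = net),
    class = "grn_trajectory"
  )
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("<grn_trajectory> %d steps, seed %d\n",
              nrow(x$values) - 1L, x$seed))
  cat(paste(utils::head(x$states, 10L), collapse = " -> "))
  if (length(x$states) > 10L) cat(" -> ...")
  cat("\n")
  invisible(x)
}

#' Tidy a trajectory to one row per step
#'
#' @param x A `grn_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `step` (0-based) and `configuration`.
#' @method tidy grn_trajectory
#' @export
tidy.grn_trajectory <- function(x, ...) {
  tibble::tibble(step = seq_along(x$states) - 1L, configuration = x$states)
}

#' Estimate mean first-return times by simulation
#'
#' Runs repeated trajectories from `state` and records the first return.
#' Runs that do not return within `horizon` steps are censored and counted
#' separately, never silently dropped.
#'
#' @param net A [grn].
#' @param state Configuration whose return time is estimated.
#' @param n_runs Number of independent runs.
#' @param horizon Maximum steps per run.
#' @param seed Integer seed.
#' @return A tibble with `mean`, `stderr`, `n_returned`, `n_censored`.
#' @export
estimate_return_times <- function(net, state, n_runs = 1000L, horizon = 1000L,
                                  seed = 1L) {
  rep <- grn_representation(net)
  if (is.character(state)) state <- parse_configuration(state, rep)
  check_representation(net, state)
  times <- integer(0)
  censored <- 0L
  step <- make_stepper(net)
  withr::with_seed(seed, {
    for (r in seq_len(n_runs)) {
      values <- as.integer(state)
      hit <- NA_integer_
      for (t in seq_len(horizon)) {
        values <- step(values)
        if (all(values == state)) { hit <- t; break }
      }
      if (is.na(hit)) censored <- censored + 1L else times <- c(times, hit)
    }
  })
  m <- if (length(times) > 0L) mean(times) else NA_real_
  se <- if (length(times) > 1L) stats::sd(times) / sqrt(length(times)) else NA_real_
  tibble::tibble(mean = m, stderr = se,
                 n_returned = length(times), n_censored = censored)
}

#' Estimate absorption behaviour by simulation
#'
#' Runs trajectories from `init` until they enter an ergodic set of the
#' chain and reports per-attractor absorption frequencies and the mean
#' number of steps spent before absorption. Runs exceeding `horizon` are
#' censored.
#'
#' @param net A [grn]; its chain should classify as absorbing (extended).
#' @param init Initial configuration.
#' @param n_runs,horizon,seed Simulation controls.
#' @return A list with `frequencies` (tibble: `attractor`, `n`, `freq`),
#'   `mean_time`, `stderr_time`, `n_censored`.
#' @export
estimate_absorption <- function(net, init, n_runs = 1000L, horizon = 1000L,
                                seed = 1L) {
  rep <- grn_representation(net)
  if (is.character(init)) init <- parse_configuration(init, rep)
  check_representation(net, init)
  tm <- transition_model(net)
  es <- ergodic_sets(tm)
  free_pos <- match(tm$free, net$nodes)
  set_of <- stats::setNames(rep(seq_len(nrow(es)), times = es$size),
                            unlist(es$states))
  label_of <- vapply(es$states, `[[`, "", 1L)
  hits <- integer(0)
  times <- integer(0)
  censored <- 0L
  step <- make_stepper(net)
  withr::with_seed(seed, {
    for (r in seq_len(n_runs)) {
      values <- as.integer(init)
      absorbed <- NA_integer_
      lab <- format_configuration(values[free_pos], rep)
      if (!is.na(set_of[lab])) absorbed <- 0L
      t <- 0L
      while (is.na(absorbed) && t < horizon) {
        values <- step(values)
        t <- t + 1L
        lab <- format_configuration(values[free_pos], rep)
        if (!is.na(set_of[lab])) absorbed <- t
      }
      if (is.na(absorbed)) {
        censored <- censored + 1L
      } else {
        hits <- c(hits, set_of[[lab]])
        times <- c(times, absorbed)
      }
    }
  })
  freq <- tibble::tibble(attractor = label_of[sort(unique(hits))],
                         n = as.integer(table(hits)))
  freq$freq <- freq$n / sum(freq$n)
  list(
    frequencies = freq,
    mean_time = if (length(times) > 0L) mean(times) else NA_real_,
    stderr_time = if (length(times) > 1L) stats::sd(times) / sqrt(length(times))
      else NA_real_,
    n_censored = censored
  )
}
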