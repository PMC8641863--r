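# Exact stochastic simulation (Gillespie direct method) of compiled models,
# and ensemble statistics across independent replicates.

#' @useDynLib fflnoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ssa_init_state <- function(crn, level) {
  x <- stats::setNames(numeric(nrow(crn$species)), crn$species$name)
  x["S"] <- round(level)
  x[grepl("_i$", names(x))] <- crn$params$total
  x
}

.protocol_seg_rates <- function(crn, protocol) {
  protocol$segments$level * (crn$input$d - crn$input$b)
}

#' Simulate one exact trajectory of a compiled model
#'
#' Direct-method Gillespie simulation through the piecewise-constant input
#' protocol.  Reproducible: the same seed yields the same trajectory.
#'
#' @param crn an `ffl_crn`.
#' @param protocol an `ffl_protocol`.
#' @param seed integer RNG seed.
#' @param sample_times times at which the state is recorded (defaults to a
#'   regular grid of 10 points per plateau).
#' @param init integer initial state; defaults to all molecules inactive
#'   and S at the first plateau level.
#' @return An object of class `ffl_ssa_traj`: `times`, `state` (time by
#'   species matrix), `seed`, `model_id`.
#' @export
ssa_simulate <- function(crn, protocol, seed, sample_times = NULL,
                         init = NULL) {
  stopifnot(inherits(crn, "ffl_crn"), inherits(protocol, "ffl_protocol"))
  seg <- protocol$segments
  if (is.null(sample_times))
    sample_times <- sort(unique(unlist(lapply(seq_len(nrow(seg)), function(k)
      seq(seg$t0[k], seg$t1[k], length.out = 11)[-1]))))
  if (is.null(init)) init <- .ssa_init_state(crn, seg$level[1])
  stopifnot(all(init == round(init)), all(init >= 0))
  set.seed(seed)
  st <- ssa_run_cpp(
    stoich = matrix(as.integer(round(crn$N)), nrow(crn$N), ncol(crn$N)),
    expo = matrix(as.integer(crn$E), nrow(crn$E), ncol(crn$E)),
    rates = crn$rates, x0 = as.numeric(init),
    input_rx = crn$input_rx - 1L,
    seg_rates = .protocol_seg_rates(crn, protocol),
    seg_ends = seg$t1, sample_times = sample_times)
  state <- t(st)
  colnames(state) <- crn$species$name
  structure(list(model_id = crn$model_id, times = sample_times,
                 state = state, seed = seed, protocol = protocol),
            class = "ffl_ssa_traj")
}

#' @export
print.ffl_ssa_traj <- function(x, ...) {
  cat("<ffl_ssa_traj> ", x$model_id, ": ", length(x$times),
      " samples, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ensemble statistics from independent SSA replicates
#'
#' Runs `n` independent trajectories (replicate `i` uses seed
#' `base_seed + i - 1`), records the state at the end of each plateau
#' after a burn-in of 90% of the plateau, and returns per-plateau,
#' per-species means, variances and Monte-Carlo standard errors computed
#' across replicates.
#'
#' @param crn an `ffl_crn`.
#' @param protocol an `ffl_protocol`.
#' @param n number of replicates (>= 2).
#' @param base_seed integer seed of the first replicate.
#' @return An object of class `ffl_ensemble`: `stats` is a data frame with
#'   columns `segment`, `level`, `phase`, `species`, `mean`, `var`,
#'   `se_mean`, `se_var`; `n` and `base_seed` record the design.
#' @export
ssa_ensemble <- function(crn, protocol, n = 200, base_seed = 1) {
  stopifnot(n >= 2)
  seg <- protocol$segments
  ends <- seg$t1 - 1e-9  # state at plateau end
  reps <- lapply(seq_len(n), function(i)
    ssa_simulate(crn, protocol, seed = base_seed + i - 1L,
                 sample_times = ends)$state)
  arr <- simplify2array(reps)  # plateau x species x replicate
  stats_list <- list()
  for (k in seq_len(nrow(seg))) for (s in seq_len(ncol(arr))) {
    v <- arr[k, s, ]
    m2 <- stats::var(v)
    stats_list[[length(stats_list) + 1L]] <- data.frame(
      segment = k, level = seg$level[k], phase = seg$phase[k],
      species = crn$species$name[s],
      mean = mean(v), var = m2,
      se_mean = stats::sd(v) / sqrt(n),
      se_var = m2 * sqrt(2 / (n - 1)),
      stringsAsFactors = FALSE)
  }
  structure(list(model_id = crn$model_id, stats = do.call(rbind, stats_list),
                 n = n, base_seed = base_seed, protocol = protocol),
            class = "ffl_ensemble")
}

#' @export
print.ffl_ensemble <- function(x, ...) {
  cat("<ffl_ensemble> ", x$model_id, ": ", x$n,
      " replicates, base seed ", x$base_seed, "\n", sep = "")
  invisible(x)
}
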