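# Linear noise approximation: deterministic means from the macroscopic rate
# equations plus Gaussian fluctuations whose covariance solves a Lyapunov
# (stationary) or differential Lyapunov (time-dependent) equation.
#
# Conserved pools make the Jacobian singular on the full state space, so
# covariances are propagated on the stoichiometric subspace spanned by an
# orthonormal basis B of the column space of the stoichiometry matrix;
# conserved directions carry exactly zero variance.

#' Macroscopic drift, Jacobian and diffusion of a compiled network
#'
#' `drift()` is the macroscopic rate-equation right-hand side
#' `N %*% v(x)`; `lna_jacobian()` its analytic derivative (propensities are
#' monomials, so the derivative is exact); `diffusion()` the fluctuation
#' matrix `N diag(v) N^T` of the linear noise approximation.
#'
#' @param crn an `ffl_crn`.
#' @param x nonnegative real state vector.
#' @return A vector (`drift`) or matrix (`lna_jacobian`, `diffusion`).
#' @examples
#' crn <- build_model(catalog_entry("c1-OR"))
#' drift(crn, lna_stationary(crn, 1)$mean)  # ~ 0 at the fixed point
#' @export
drift <- function(crn, x) {
  drop(crn$N %*% propensities(crn, x))
}

#' @rdname drift
#' @export
lna_jacobian <- function(crn, x) {
  stopifnot(length(x) == nrow(crn$species))
  nsp <- nrow(crn$E); nrx <- ncol(crn$E)
  M <- matrix(0, nrx, nsp)
  for (j in seq_len(nrx)) {
    e <- crn$E[, j]
    nz <- which(e > 0)
    for (i in nz) {
      ei <- e; ei[i] <- ei[i] - 1L   # d/dx_i of the monomial
      nzi <- which(ei > 0)
      M[j, i] <- crn$rates[j] * e[i] *
        (if (length(nzi)) prod(x[nzi]^ei[nzi]) else 1)
    }
  }
  crn$N %*% M
}

#' @rdname drift
#' @export
diffusion <- function(crn, x) {
  v <- propensities(crn, x)
  crn$N %*% (t(crn$N) * v)
}

# solve J S + S J' = -D for S (small dense systems; Kronecker form)
.lyap_solve <- function(J, D) {
  r <- nrow(J)
  I <- diag(r)
  A <- kronecker(I, J) + kronecker(J, I)
  S <- matrix(solve(A, -as.vector(D)), r, r)
  (S + t(S)) / 2
}

.set_input_level <- function(crn, input_mean) {
  # basal production rate a = mean * (d - b); the packaged mechanisms are
  # normalised to d - b = 1
  crn$rates[crn$input_rx] <- input_mean * (crn$input$d - crn$input$b)
  crn
}

.default_init <- function(crn, input_mean) {
  x <- stats::setNames(numeric(nrow(crn$species)), crn$species$name)
  x["S"] <- input_mean
  x[grepl("_i$", names(x))] <- crn$params$total
  x
}

.ode_deriv_mean <- function(t, y, crn) list(drift(crn, pmax(y, 0)))

#' Stationary moments at a fixed input level
#'
#' Relaxes the macroscopic rate equations to their fixed point (numerical
#' integration followed by Newton refinement restricted to the
#' stoichiometric subspace), then solves the stationary Lyapunov equation
#' for the covariance on that subspace.  Conserved combinations are pinned
#' to zero variance exactly.
#'
#' @param crn an `ffl_crn`.
#' @param input_mean plateau mean of the input S.
#' @param tol residual tolerance on the drift at the fixed point.
#' @return A list with `mean` (named vector), `cov` (matrix), `input_mean`,
#'   and `stable` (all subspace eigenvalues of the Jacobian negative).
#' @examples
#' st <- lna_stationary(build_model(catalog_entry("c1-OR")), 6)
#' st$mean["Z_a"]
#' @export
lna_stationary <- function(crn, input_mean, tol = 1e-10) {
  stopifnot(inherits(crn, "ffl_crn"), input_mean > 0)
  crn <- .set_input_level(crn, input_mean)
  x <- .default_init(crn, input_mean)
  sol <- deSolve::ode(y = x, times = c(0, 20, 60), func = .ode_deriv_mean,
                      parms = crn, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  x <- sol[nrow(sol), -1]
  B <- crn$B
  for (it in seq_len(60)) {
    f <- drift(crn, x)
    if (max(abs(f)) < tol) break
    Jr <- t(B) %*% lna_jacobian(crn, x) %*% B
    step <- drop(B %*% solve(Jr, -t(B) %*% f))
    # damp steps that would leave the positive orthant
    lam <- 1
    while (any(x + lam * step < -1e-9) && lam > 1e-4) lam <- lam / 2
    x <- pmax(x + lam * step, 0)
  }
  if (max(abs(drift(crn, x))) > 1e-6)
    stop("stationary solve did not converge for ", crn$model_id,
         " at input mean ", input_mean)
  J <- lna_jacobian(crn, x)
  Jr <- t(B) %*% J %*% B
  ev <- eigen(Jr, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  if (!stable)
    warning("non-stable Jacobian at the fixed point of ", crn$model_id)
  Dr <- t(B) %*% diffusion(crn, x) %*% B
  Sr <- .lyap_solve(Jr, Dr)
  S <- B %*% Sr %*% t(B)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(crn$species$name, crn$species$name)
  list(mean = stats::setNames(x, crn$species$name), cov = S,
       input_mean = input_mean, stable = stable)
}

.vech <- function(S) S[lower.tri(S, diag = TRUE)]
.unvech <- function(v, r) {
  S <- matrix(0, r, r)
  S[lower.tri(S, diag = TRUE)] <- v
  S <- S + t(S) - diag(diag(S))
  S
}

#' Integrate means and covariances through an input protocol
#'
#' Jointly integrates the macroscopic means and the differential Lyapunov
#' equation for the subspace covariance through the piecewise-constant
#' staircase, continuing (not resetting) the state at plateau boundaries.
#' The run starts from the stationary state of the first plateau.
#'
#' @param crn an `ffl_crn`.
#' @param protocol an `ffl_protocol` (see [staircase()]).
#' @param rtol,atol integration tolerances.
#' @param n_out output time points per plateau.
#' @return An object of class `ffl_lna_result`: `times`, matrices `mean`
#'   and `sd` (time by species), and `plateaus`, a list with the full
#'   moment state at the end of each plateau (`level`, `phase`, `t`,
#'   `mean`, `cov`).
#' @export
lna_integrate <- function(crn, protocol, rtol = 1e-8, atol = 1e-8,
                          n_out = 21) {
  stopifnot(inherits(crn, "ffl_crn"), inherits(protocol, "ffl_protocol"))
  B <- crn$B
  r <- ncol(B)
  nsp <- nrow(crn$species)
  seg <- protocol$segments

  st0 <- lna_stationary(crn, seg$level[1])
  y <- c(st0$mean, .vech(t(B) %*% st0$cov %*% B))

  deriv <- function(t, y, crn) {
    x <- pmax(y[seq_len(nsp)], 0)
    Sr <- .unvech(y[-seq_len(nsp)], r)
    v <- propensities(crn, x)
    dx <- drop(crn$N %*% v)
    J <- lna_jacobian(crn, x)
    Jr <- t(B) %*% J %*% B
    Dr <- t(B) %*% (crn$N %*% (t(crn$N) * v)) %*% B
    dS <- Jr %*% Sr + Sr %*% t(Jr) + Dr
    list(c(dx, .vech((dS + t(dS)) / 2)))
  }

  times_all <- c(); mu_all <- NULL; sd_all <- NULL
  plateaus <- vector("list", nrow(seg))
  for (k in seq_len(nrow(seg))) {
    crn_k <- .set_input_level(crn, seg$level[k])
    tk <- seq(seg$t0[k], seg$t1[k], length.out = n_out)
    sol <- deSolve::ode(y = y, times = tk, func = deriv, parms = crn_k,
                        method = "lsoda", rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    mu_k <- sol[, 1 + seq_len(nsp), drop = FALSE]
    var_k <- t(apply(sol[, -(seq_len(nsp + 1)), drop = FALSE], 1, function(v) {
      S <- B %*% .unvech(v, r) %*% t(B)
      pmax(diag(S), 0)
    }))
    keep <- if (k == 1) seq_len(n_out) else -1L  # drop duplicated boundary
    times_all <- c(times_all, tk[keep])
    mu_all <- rbind(mu_all, mu_k[keep, , drop = FALSE])
    sd_all <- rbind(sd_all, sqrt(var_k[keep, , drop = FALSE]))
    Sfull <- B %*% .unvech(y[-seq_len(nsp)], r) %*% t(B)
    dimnames(Sfull) <- list(crn$species$name, crn$species$name)
    plateaus[[k]] <- list(level = seg$level[k], phase = seg$phase[k],
                          t = seg$t1[k],
                          mean = stats::setNames(y[seq_len(nsp)],
                                                 crn$species$name),
                          cov = Sfull)
  }
  colnames(mu_all) <- colnames(sd_all) <- crn$species$name
  structure(list(model_id = crn$model_id, protocol = protocol,
                 times = times_all, mean = mu_all, sd = sd_all,
                 plateaus = plateaus),
            class = "ffl_lna_result")
}

#' @export
print.ffl_lna_result <- function(x, ...) {
  cat("<ffl_lna_result> ", x$model_id, ": ", length(x$times),
      " time points, ", length(x$plateaus), " plateaus\n", sep = "")
  invisible(x)
}

#' Tidy per-plateau statistics from an LNA result
#'
#' @param result an `ffl_lna_result`.
#' @return Data frame with one row per plateau and species: `level`,
#'   `phase`, `species`, `mean`, `var`.
#' @export
lna_plateau_stats <- function(result) {
  do.call(rbind, lapply(result$plateaus, function(p) {
    data.frame(level = p$level, phase = p$phase, t = p$t,
               species = names(p$mean), mean = unname(p$mean),
               var = pmax(diag(p$cov), 0), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
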