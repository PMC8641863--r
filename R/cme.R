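# Exact stationary solution of the chemical master equation on a truncated
# state space, for shrunken model instances.  Conservation laws reduce the
# lattice: each node contributes its active (and intermediate) counts with
# the inactive form implied; the input S is truncated at a cap.

#' Exact stationary CME solution of a small model instance
#'
#' Enumerates the conservation-reduced state lattice (S capped at `s_cap`,
#' each node's forms summing to the conserved total), assembles the sparse
#' generator with reactions leaving the truncation reflected (rate set to
#' zero), and solves the stationary linear system exactly.  Intended for
#' shrunken instances (small totals, capped input).
#'
#' @param crn an `ffl_crn` (use a small `total` in [ffl_params()]).
#' @param s_cap truncation bound for S copy numbers.
#' @param input_mean plateau mean at which the input is held.
#' @param max_states guard on the truncated lattice size.
#' @return A list: `mean` and `cov` (exact stationary moments over all
#'   species), `boundary_mass` (stationary probability on states with
#'   `S == s_cap`, the truncation-quality diagnostic), `n_states`, and
#'   `p` (the stationary probability vector).
#' @examples
#' crn <- build_model(catalog_entry("c1-OR"), params = ffl_params(total = 3))
#' sol <- cme_stationary_small(crn, s_cap = 25, input_mean = 2)
#' sol$mean["Z_a"]
#' @export
cme_stationary_small <- function(crn, s_cap, input_mean,
                                 max_states = 2e5) {
  stopifnot(inherits(crn, "ffl_crn"), s_cap >= 1)
  crn <- .set_input_level(crn, input_mean)
  sp <- crn$species$name
  nsp <- length(sp)

  # per-block admissible form counts
  blocks <- list(matrix(0:s_cap, ncol = 1, dimnames = list(NULL, "S")))
  for (cl in crn$conservation) {
    forms <- names(cl$species)
    tot <- cl$total
    if (length(forms) == 2L) {
      g <- cbind(tot - 0:tot, 0:tot)
    } else {
      g <- as.matrix(expand.grid(m = 0:tot, a = 0:tot))
      g <- g[rowSums(g) <= tot, , drop = FALSE]
      g <- cbind(tot - rowSums(g), g)
    }
    colnames(g) <- forms
    blocks[[length(blocks) + 1L]] <- g
  }
  sizes <- vapply(blocks, nrow, integer(1))
  n_states <- prod(sizes)
  if (n_states > max_states)
    stop("truncated state space too large: ", n_states, " states")

  # full state matrix by mixed-radix expansion of block indices
  idx <- as.matrix(do.call(expand.grid, lapply(sizes, seq_len)))
  states <- matrix(0, n_states, nsp, dimnames = list(NULL, sp))
  for (b in seq_along(blocks))
    states[, colnames(blocks[[b]])] <- blocks[[b]][idx[, b], , drop = FALSE]

  # block-local lookup of a state's linear index
  radix <- cumprod(c(1, sizes[-length(sizes)]))
  block_key <- lapply(blocks, function(g) {
    key <- apply(g, 1, paste, collapse = ",")
    stats::setNames(seq_len(nrow(g)), key)
  })
  state_index <- function(M) {
    ix <- rep(1, nrow(M))
    ok <- rep(TRUE, nrow(M))
    for (b in seq_along(blocks)) {
      key <- apply(M[, colnames(blocks[[b]]), drop = FALSE], 1,
                   paste, collapse = ",")
      j <- block_key[[b]][key]
      ok <- ok & !is.na(j)
      ix <- ix + (ifelse(is.na(j), 1, j) - 1) * radix[b]
      ok[M[, "S"] > s_cap | M[, "S"] < 0] <- FALSE
    }
    ix[!ok] <- NA_integer_
    ix
  }

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_out <- numeric(n_states)
  for (r in seq_len(ncol(crn$N))) {
    e <- crn$E[, r]
    v <- rep(if (r == crn$input_rx) crn$rates[crn$input_rx] else crn$rates[r],
             n_states)
    for (i in which(e > 0)) v <- v * states[, i]^e[i]
    nz <- which(v > 0)
    if (!length(nz)) next
    tgt <- sweep(states[nz, , drop = FALSE], 2, crn$N[, r], `+`)
    ti <- state_index(tgt)
    keep <- !is.na(ti)        # reflecting truncation at the S cap
    nzk <- nz[keep]
    ii <- c(ii, ti[keep]); jj <- c(jj, nzk); vv <- c(vv, v[nzk])
    diag_out[nzk] <- diag_out[nzk] + v[nzk]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n_states)),
                            j = c(jj, seq_len(n_states)),
                            x = c(vv, -diag_out),
                            dims = c(n_states, n_states))
  # replace one balance equation by the normalisation constraint
  A[n_states, ] <- 1
  rhs <- c(rep(0, n_states - 1), 1)
  p <- as.numeric(Matrix::solve(A, rhs))
  p[p < 0 & p > -1e-12] <- 0
  stopifnot(all(p >= -1e-9), abs(sum(p) - 1) < 1e-8)
  p <- p / sum(p)

  mu <- drop(p %*% states)
  ctr <- sweep(states, 2, mu)
  cov <- t(ctr) %*% (ctr * p)
  list(mean = stats::setNames(mu, sp), cov = cov,
       boundary_mass = sum(p[states[, "S"] == s_cap]),
       n_states = n_states, p = p, states = states)
}
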