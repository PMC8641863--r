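# Compile a catalog entry into a concrete mass-action chemical reaction
# network.  Every regulated node N holds a conserved pool of `total`
# molecules distributed over an inactive form N_i, an active form N_a and,
# in the two-step modification scheme, an intermediate N_m.  Regulators act
# catalytically: an activator converts target molecules towards the active
# form, an inhibitor towards the inactive form, at a rate proportional to
# the regulator's active copy number normalised by its own scale (the
# conserved total for protein regulators, `s_ref` for the input S).

.node_layer <- function(node) {
  switch(substr(node, 1, 1), X = "X", Y = "Y", Z = "Z",
         stop("unknown node: ", node))
}

.layer_rate <- function(layer, params)
  switch(layer, X = params$k1, Y = params$k2, Z = params$k3)

.reg_activity <- function(from, params) {
  if (from == "S") list(species = "S", omega = params$s_ref)
  else list(species = paste0(from, "_a"), omega = params$p_ref)
}

#' Compile a catalog entry into a mass-action reaction network
#'
#' @param entry an `ffl_entry` from the catalog (see
#'   [enumerate_catalog()]).
#' @param scheme `"one-step"` (direct inactive <-> active conversion) or
#'   `"two-step"` (conversion through an intermediate form, both forward
#'   steps driven by the same regulators; the spontaneous and
#'   inhibitor-driven reverse path runs through the intermediate as well).
#' @param params an [ffl_params()] object.
#' @param input an [calibrate_input()] mechanism; its basal production
#'   rate is the quantity stepped by the protocol.
#' @return An object of class `ffl_crn` holding the species table, the
#'   reaction list, the stoichiometry and reactant-exponent matrices, the
#'   conservation laws, and the resolved AND-gate attenuation factor.
#' @examples
#' crn <- build_model(catalog_entry("c1-OR"))
#' crn$species$name
#' @export
build_model <- function(entry, scheme = c("one-step", "two-step"),
                        params = ffl_params(),
                        input = calibrate_input(1.83, mean = 1)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(entry, "ffl_entry"), inherits(params, "ffl_params"),
            inherits(input, "ffl_input"))
  and_factor <- params$and_factor
  if (any(entry$gates == "AND") && is.null(and_factor))
    and_factor <- calibrate_and_factor(entry, scheme, params, input)
  .assemble_crn(entry, scheme, params, input,
                and_factor = if (is.null(and_factor)) NA_real_ else and_factor)
}

# deterministic assembly with a fully resolved AND factor
.assemble_crn <- function(entry, scheme, params, input, and_factor) {
  two_step <- scheme == "two-step"
  nodes <- setdiff(entry$nodes, "S")
  forms <- if (two_step) c("i", "m", "a") else c("i", "a")

  species <- data.frame(name = "S", layer = "input", form = "free",
                        stringsAsFactors = FALSE)
  for (n in nodes)
    species <- rbind(species, data.frame(
      name = paste0(n, "_", forms), layer = .node_layer(n),
      form = c(inactive = "inactive", m = "intermediate",
               a = "active")[match(forms, c("i", "m", "a"))],
      stringsAsFactors = FALSE))
  sp <- species$name
  idx <- stats::setNames(seq_along(sp), sp)

  rx <- list()
  add_rx <- function(name, rate, expo, from = NULL, to = NULL) {
    stoich <- stats::setNames(numeric(length(sp)), sp)
    if (!is.null(from)) stoich[from] <- stoich[from] - 1
    if (!is.null(to)) stoich[to] <- stoich[to] + 1
    rx[[length(rx) + 1L]] <<- list(name = name, rate = rate,
                                   expo = idx[expo], stoich = stoich)
  }

  # input submodel: 0 -> S (a, protocol-driven), S -> 2S (b S), S -> 0 (d S)
  add_rx("S:production", input$a, character(0), to = "S")
  input_rx <- length(rx)
  add_rx("S:autocatalysis", input$b, "S", to = "S")
  add_rx("S:decay", input$d, character(0), from = "S")  # reactant S enters the propensity

  # one catalytic conversion (or a two-step pair) of node n towards the
  # active (sign +1) or inactive (sign -1) form
  add_conversion <- function(n, sign, rate1, rate2, expo, tag) {
    if (!two_step) {
      if (sign > 0)
        add_rx(paste0(n, ":act", tag), rate1, expo,
               from = paste0(n, "_i"), to = paste0(n, "_a"))
      else
        add_rx(paste0(n, ":inact", tag), rate1, expo,
               from = paste0(n, "_a"), to = paste0(n, "_i"))
    } else {
      if (sign > 0) {
        add_rx(paste0(n, ":act1", tag), rate1, expo,
               from = paste0(n, "_i"), to = paste0(n, "_m"))
        add_rx(paste0(n, ":act2", tag), rate2, expo,
               from = paste0(n, "_m"), to = paste0(n, "_a"))
      } else {
        add_rx(paste0(n, ":inact1", tag), rate1, expo,
               from = paste0(n, "_a"), to = paste0(n, "_m"))
        add_rx(paste0(n, ":inact2", tag), rate2, expo,
               from = paste0(n, "_m"), to = paste0(n, "_i"))
      }
    }
  }

  for (n in nodes) {
    kl <- .layer_rate(.node_layer(n), params)
    targ <- function(f) paste0(n, "_", f)
    # constitutive conversions (expo = target form only, added inside
    # add_conversion through the reactant; rates kl forward, ka reverse)
    add_conversion(n, +1, kl, kl, character(0), ":basal")
    add_conversion(n, -1, params$ka, params$ka, character(0), ":basal")

    regs <- entry$edges[entry$edges$to == n, , drop = FALSE]
    if (nrow(regs) == 0L) next
    gate <- if (n %in% names(entry$gates)) entry$gates[[n]] else "OR"
    if (gate == "AND" && nrow(regs) >= 2L) {
      stopifnot(length(unique(regs$sign)) == 1L)
      acts <- lapply(regs$from, .reg_activity, params = params)
      omega_prod <- prod(vapply(acts, `[[`, numeric(1), "omega"))
      expo <- vapply(acts, `[[`, character(1), "species")
      af <- and_factor^(nrow(regs) - 1L)
      add_conversion(n, regs$sign[1],
                     af * params$kp / omega_prod,
                     af * params$kpp / omega_prod,
                     expo, paste0("<-AND(", paste(regs$from, collapse = ","), ")"))
    } else {
      for (j in seq_len(nrow(regs))) {
        act <- .reg_activity(regs$from[j], params)
        add_conversion(n, regs$sign[j],
                       params$kp / act$omega, params$kpp / act$omega,
                       act$species, paste0("<-", regs$from[j]))
      }
    }
  }

  nsp <- length(sp); nrx <- length(rx)
  N <- matrix(0, nsp, nrx, dimnames = list(sp, vapply(rx, `[[`, character(1), "name")))
  E <- matrix(0L, nsp, nrx, dimnames = dimnames(N))
  for (j in seq_len(nrx)) {
    N[, j] <- rx[[j]]$stoich
    E[rx[[j]]$expo, j] <- 1L
    # reactant of a conversion also enters the propensity
  }
  # reactants enter the mass-action propensity alongside catalytic modifiers
  for (j in seq_len(nrx)) {
    reac <- which(N[, j] < 0)
    E[reac, j] <- E[reac, j] + 1L
  }
  rates <- vapply(rx, `[[`, numeric(1), "rate")

  cons <- lapply(nodes, function(n) {
    list(node = n, species = idx[paste0(n, "_", forms)],
         total = params$total)
  })
  for (cl in cons) {
    v <- numeric(nsp); v[cl$species] <- 1
    stopifnot(max(abs(drop(v %*% N))) == 0)
  }

  qrN <- qr(N)
  B <- qr.Q(qrN)[, seq_len(qrN$rank), drop = FALSE]

  structure(list(
    model_id = entry$model_id, entry = entry, scheme = scheme,
    params = params, input = input, and_factor = and_factor,
    species = species, reactions = rx,
    N = N, E = E, rates = rates, input_rx = input_rx,
    conservation = cons, B = B), class = "ffl_crn")
}

#' @export
print.ffl_crn <- function(x, ...) {
  cat("<ffl_crn> ", x$model_id, " [", x$scheme, "]  ",
      nrow(x$species), " species, ", length(x$reactions), " reactions, ",
      length(x$conservation), " conservation laws (total ",
      x$params$total, ")\n", sep = "")
  if (!is.na(x$and_factor))
    cat("  AND attenuation factor: ", signif(x$and_factor, 6), "\n", sep = "")
  invisible(x)
}

#' Conservation laws of a compiled network
#'
#' Each regulated node contributes one law: the sum of its forms is
#' constant and equals the parameter `total`.  The indicator vector of
#' every law lies in the left null space of the stoichiometry matrix.
#'
#' @param crn an `ffl_crn`.
#' @return A list of lists with elements `node`, `species` (names) and
#'   `total`.
#' @export
conservation_laws <- function(crn) {
  stopifnot(inherits(crn, "ffl_crn"))
  lapply(crn$conservation, function(cl)
    list(node = cl$node, species = names(cl$species), total = cl$total))
}

#' Stoichiometry matrix and mass-action propensities
#'
#' @param crn an `ffl_crn`.
#' @param state nonnegative state vector (length = number of species,
#'   order as in `crn$species`).
#' @return `stoichiometry()` returns the species-by-reaction net-change
#'   matrix; `propensities()` the vector of mass-action propensities at
#'   `state`.
#' @examples
#' crn <- build_model(catalog_entry("c1-OR"))
#' stoichiometry(crn)[, "X:act<-S"]
#' @export
stoichiometry <- function(crn) {
  stopifnot(inherits(crn, "ffl_crn"))
  crn$N
}

#' @rdname stoichiometry
#' @export
propensities <- function(crn, state) {
  stopifnot(inherits(crn, "ffl_crn"), length(state) == nrow(crn$species))
  if (any(state < 0)) stop("negative state entries")
  v <- crn$rates
  for (j in seq_along(v)) {
    e <- crn$E[, j]
    nz <- which(e > 0)
    if (length(nz)) v[j] <- v[j] * prod(state[nz]^e[nz])
  }
  stats::setNames(v, colnames(crn$N))
}

#' Calibrate the AND-gate attenuation factor of a model
#'
#' The study's parameterisation attenuates the joint effect of AND-gated
#' regulators so that AND and OR variants of the same topology produce the
#' same mean output at input mean 1.  The attenuation factor is found by
#' root-solving: the stationary mean of the active output of the AND model
#' at input mean 1 is matched to that of its all-OR twin.
#'
#' @inheritParams build_model
#' @param tol relative tolerance on the matched mean.
#' @return The fitted attenuation factor (scalar).
#' @export
calibrate_and_factor <- function(entry, scheme = "one-step",
                                 params = ffl_params(),
                                 input = calibrate_input(1.83, mean = 1),
                                 tol = 1e-8) {
  or_entry <- entry
  or_entry$gates[] <- "OR"
  or_crn <- .assemble_crn(or_entry, scheme, params, input, NA_real_)
  target <- lna_stationary(or_crn, input_mean = 1)$mean[["Z_a"]]
  gap <- function(log_af) {
    crn <- .assemble_crn(entry, scheme, params, input, exp(log_af))
    lna_stationary(crn, input_mean = 1)$mean[["Z_a"]] - target
  }
  root <- stats::uniroot(gap, lower = log(1e-2), upper = log(1e3),
                         extendInt = "yes", tol = tol)
  exp(root$root)
}
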