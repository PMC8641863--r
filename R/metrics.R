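# Noise and signal-transduction measures: percent coefficient of
# variation, Fano factor, input-output slope, catalog rankings, layer-wise
# noise profiles and the saturation guard.

#' Percent coefficient of variation and Fano factor
#'
#' `cv_percent()` returns `100 * sd / mean`, the signal-to-noise measure
#' reported for every species; `fano_factor()` returns `variance / mean`
#' (1 for a Poisson process, below 1 for the sub-Poissonian conserved
#' pools, above 1 for the super-Poissonian input).
#'
#' @param mean,variance moments of a copy-number distribution
#'   (`mean > 0`, `variance >= 0`); vectorised.
#' @return Numeric vector.
#' @examples
#' cv_percent(4, 1)            # 25
#' cv_percent(6, 6)            # Poisson at mean 6: 100/sqrt(6)
#' fano_factor(6, 10.98)       # calibrated input: 1.83
#' @export
cv_percent <- function(mean, variance) {
  if (any(mean <= 0)) stop("cv_percent requires positive means")
  if (any(variance < 0)) stop("negative variance")
  100 * sqrt(variance) / mean
}

#' @rdname cv_percent
#' @export
fano_factor <- function(mean, variance) {
  if (any(mean <= 0)) stop("fano_factor requires positive means")
  variance / mean
}

#' Input-output slope
#'
#' Ordinary least-squares slope of mean output against mean input across
#' plateau levels: the signal-transduction measure.  Positive slopes mean
#' faithful transduction, negative slopes signal inversion, near-zero
#' slopes a non-transducing network.
#'
#' @param input_means,output_means equal-length numeric vectors (>= 2
#'   distinct input values).
#' @return The regression slope (scalar).
#' @examples
#' io_slope(2:6, 5 * (2:6))   # 5
#' @export
io_slope <- function(input_means, output_means) {
  if (length(input_means) != length(output_means) || length(input_means) < 2)
    stop("need equal-length vectors with at least two points")
  if (length(unique(input_means)) < 2) stop("degenerate input levels")
  unname(stats::coef(stats::lm(output_means ~ input_means))[2])
}

#' Per-plateau summary of one model
#'
#' Computes stationary LNA moments of a compiled model at each input
#' level and derives the output noise measures and the input-output
#' slope (up-phase levels only; the down phase of the staircase revisits
#' the same stationary states).
#'
#' @param crn an `ffl_crn`.
#' @param levels input plateau means (the staircase's distinct levels,
#'   baseline first).
#' @param slope_levels levels used for the slope regression (the five
#'   up-phase plateaus).
#' @return A list: `stats` (data frame: level, species, mean, var, cv,
#'   fano), `output` (data frame per level for the active output Z_a),
#'   `slope`, `model_id`, `scheme`.
#' @export
model_summary <- function(crn, levels = c(1, 2, 3, 4, 5, 6),
                          slope_levels = c(2, 3, 4, 5, 6)) {
  stopifnot(inherits(crn, "ffl_crn"))
  rows <- lapply(levels, function(lv) {
    st <- lna_stationary(crn, lv)
    data.frame(level = lv, species = names(st$mean),
               mean = unname(st$mean), var = pmax(diag(st$cov), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  stats$cv <- ifelse(stats$mean > 0, 100 * sqrt(stats$var) / stats$mean, NA)
  stats$fano <- ifelse(stats$mean > 0, stats$var / stats$mean, NA)
  out <- stats[stats$species == "Z_a", ]
  sl <- io_slope(slope_levels,
                 out$mean[match(slope_levels, out$level)])
  list(model_id = crn$model_id, scheme = crn$scheme,
       stats = stats, output = out, slope = sl)
}

#' Rank models by output noise at a reference input
#'
#' @param summaries data frame with one row per model holding at least
#'   `model_id`, `cv6` (output %CV at the reference input) and `slope`
#'   (as produced by [run_catalog()]).
#' @return A list: `table` (sorted by ascending %CV), `correlation`
#'   (Pearson correlation between %CV and slope across models, negative
#'   when better noise reducers are also better transducers), `best_cv`
#'   and `best_slope` model ids.
#' @export
rank_models <- function(summaries) {
  need <- c("model_id", "cv6", "slope")
  stopifnot(all(need %in% names(summaries)))
  tab <- summaries[order(summaries$cv6), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       correlation = stats::cor(summaries$cv6, summaries$slope),
       best_cv = tab$model_id[1],
       best_slope = summaries$model_id[which.max(summaries$slope)])
}

#' Layer-wise noise profile of a model
#'
#' %CV of every active species (and the input S) at a reference input
#' level, ordered from the input down the layers.  Good noise reducers
#' show monotonically decreasing noise down the cascade; in poor noise
#' reducers the minimum often sits at the middle layer.
#'
#' @param crn an `ffl_crn`.
#' @param at_input reference input mean.
#' @return Data frame: `species`, `layer`, `cv`.
#' @export
layer_cv_profile <- function(crn, at_input = 6) {
  st <- lna_stationary(crn, at_input)
  keep <- crn$species$name == "S" | grepl("_a$", crn$species$name)
  sp <- crn$species[keep, ]
  ord <- order(match(sp$layer, c("input", "X", "Y", "Z")))
  sp <- sp[ord, ]
  data.frame(species = sp$name, layer = sp$layer,
             cv = cv_percent(st$mean[sp$name],
                             pmax(diag(st$cov)[sp$name], 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Saturation guard
#'
#' Flags species whose mean active fraction leaves the working band at any
#' plateau: the study's parameterisation requires that no network pins its
#' molecules fully active or fully inactive.
#'
#' @param stats a per-level species table as returned in
#'   `model_summary()$stats`.
#' @param total conserved total per node.
#' @param band admissible active-fraction range.
#' @return A list: `pass` (logical) and `violations` (data frame of
#'   offending species/levels).
#' @export
saturation_check <- function(stats, total = 60, band = c(0.02, 0.98)) {
  if (is.null(stats) || !nrow(stats)) stop("empty result")
  act <- stats[grepl("_a$", stats$species), , drop = FALSE]
  frac <- act$mean / total
  bad <- act[frac <= band[1] | frac >= band[2], , drop = FALSE]
  list(pass = nrow(bad) == 0, violations = bad)
}
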