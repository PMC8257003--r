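#' Group language value
#'
#' The language value of a group of agents is the arithmetic mean of the
#' members' language values (each the mode of that agent's Beta belief).
#' An empty group has no language value and yields `NA`.
#'
#' @param values Numeric vector of agent language values in \[0, 1\].
#' @return Mean in \[0, 1\], or `NA_real_` for an empty group.
#' @export
group_language_value <- function(values) {
  if (length(values) == 0L) return(NA_real_)
  mean(values)
}

#' Signed difference between unbiased and biased agents
#'
#' `mean(unbiased) - mean(biased)`: how far the languages of the two groups
#' have drifted apart. Positive values mean the unbiased group uses more of
#' variant "1". Equal to the mean of all pairwise (unbiased - biased)
#' differences, at a fraction of the cost. `NA` if either group is empty.
#'
#' @param values Numeric vector of agent language values.
#' @param biased Logical vector marking the intrinsically biased agents.
#' @return Signed difference, or `NA_real_`.
#' @export
diff_unbiased_biased <- function(values, biased) {
  stopifnot(length(values) == length(biased))
  if (!any(biased) || all(biased)) return(NA_real_)
  mean(values[!biased]) - mean(values[biased])
}

#' Between-community heterogeneity of language values
#'
#' Dialect differentiation across the network's structural communities:
#' the sample standard deviation (denominator `m - 1`) of the
#' per-community mean language values. A single community gives 0 (no
#' dispersion). Following the study design, the statistic is not computed
#' for networks of 10 or fewer agents (too few agents per community) and
#' `NA` is returned.
#'
#' @param values Numeric vector of agent language values.
#' @param partition A [detect_communities()] result (or an integer
#'   membership vector).
#' @param min_n Networks with at most this many agents return `NA`
#'   (default 10).
#' @return Standard deviation, 0 for one community, or `NA_real_`.
#' @export
heterogeneity <- function(values, partition, min_n = 10) {
  membership <- if (inherits(partition, "community_partition"))
    partition$membership else as.integer(partition)
  stopifnot(length(values) == length(membership), !anyNA(membership))
  if (length(values) <= min_n) return(NA_real_)
  comm_means <- tapply(values, membership, mean)
  if (length(comm_means) < 2L) return(0)
  stats::sd(comm_means)
}

#' Stabilization time of a group language-value series
#'
#' Detects when a group's language stops changing, using a sliding window
#' of width `omega = n_iterations / 10`: for every window start `g` the
#' scaled slope \eqn{t(e_g) = (e_{g+\omega} - e_g)/\omega \times 10000} is
#' rounded to the nearest integer (half away from zero); the stabilization
#' tick is the first `g` whose rounded slope is zero and stays zero for the
#' following 50 windows. A rounded slope of zero corresponds to a raw slope
#' within \eqn{\pm 5\times 10^{-5}} per iteration. If no such `g` exists
#' the sentinel `n_iterations` is returned with `stabilized = FALSE`.
#'
#' @param series Numeric vector of per-iteration group mean language
#'   values, element `i` being iteration `i - 1`; must cover iterations
#'   `0..n_iterations`.
#' @param n_iterations Number of iterations the series spans; the window is
#'   `n_iterations / 10` and at least `omega + 51` windows are required.
#' @return A list of class `"stabilization_report"`: `stab_tick`,
#'   `stabilized`, `omega`, and the integer vector `rounded_slopes` (one
#'   per window start `g = 0, 1, ...`).
#' @examples
#' stabilization_time(rep(0.5, 501), 500)$stab_tick  # 0: never moves
#' @export
stabilization_time <- function(series, n_iterations) {
  if (length(series) != n_iterations + 1L)
    stop("'series' must hold one value per iteration 0..n_iterations",
         call. = FALSE)
  omega <- n_iterations / 10
  if (omega != round(omega))
    stop("'n_iterations' must be a multiple of 10", call. = FALSE)
  omega <- as.integer(omega)
  n_windows <- n_iterations - omega + 1L  # window starts g = 0..I-omega
  if (n_windows < 51L)
    stop("series too short: need at least omega + 51 windows", call. = FALSE)
  g <- seq_len(n_windows) - 1L
  slopes <- (series[g + omega + 1L] - series[g + 1L]) / omega * 10000
  rounded <- as.integer(sign(slopes) * floor(abs(slopes) + 0.5))
  zero <- rounded == 0L
  # first g with zeros at g..g+50 (51 consecutive zero windows)
  run <- stats::filter(as.numeric(zero), rep(1, 51), sides = 1)
  hit <- which(run == 51)  # position of the window g+50
  if (length(hit) == 0L) {
    return(structure(list(stab_tick = n_iterations, stabilized = FALSE,
                          omega = omega, rounded_slopes = rounded),
                     class = "stabilization_report"))
  }
  structure(list(stab_tick = as.integer(hit[1] - 51L), stabilized = TRUE,
                 omega = omega, rounded_slopes = rounded),
            class = "stabilization_report")
}

#' @export
print.stabilization_report <- function(x, ...) {
  if (x$stabilized)
    cat(sprintf("stabilized at iteration %d (window %d)\n", x$stab_tick,
                x$omega))
  else
    cat(sprintf("not stabilized within the run (sentinel %d, window %d)\n",
                x$stab_tick, x$omega))
  invisible(x)
}

#' Inter-replication standard deviation
#'
#' Variation of the final whole-population language value across the
#' independent replications of one condition: the sample standard
#' deviation of the replication-level values. `NA` for fewer than two
#' replications.
#'
#' @param final_values Numeric vector, one final `langval_all` per
#'   replication.
#' @return Sample standard deviation, or `NA_real_`.
#' @export
inter_replication_sd <- function(final_values) {
  if (length(final_values) < 2L) return(NA_real_)
  stats::sd(final_values)
}
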