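#' Parameter-grid specification
#'
#' Describes a replicated sweep: every argument that varies may be given as
#' a vector, and the grid is the cartesian product of all supplied values,
#' each cell run `reps` times with seeds derived from `base_seed` and the
#' cell's condition key (so any single cell is re-runnable in isolation).
#'
#' @param size_net,network,mu0,lambda0,learners,prop_biased,placement,
#'   top_fraction,init_k0,init_n0,n_iterations,update_mode Condition
#'   parameters as in [sim_config()]; vectors allowed.
#' @param reps Number of independent replications per condition.
#' @param base_seed Integer base seed for the whole grid.
#' @return A list of class `"grid_spec"` with a `conditions` data frame
#'   (one row per condition).
#' @export
grid_spec <- function(size_net = 150, network = "scale-free",
                      mu0 = 0.1, lambda0 = 0.6, learners = "SAM",
                      prop_biased = 0.1, placement = "random",
                      top_fraction = 0.10, init_k0 = 4, init_n0 = 4,
                      n_iterations = 500, update_mode = "asynchronous",
                      reps = 50, base_seed = 1L) {
  conditions <- expand.grid(
    size_net = size_net, network = network, mu0 = mu0, lambda0 = lambda0,
    learners = learners, prop_biased = prop_biased, placement = placement,
    top_fraction = top_fraction, init_k0 = init_k0, init_n0 = init_n0,
    n_iterations = n_iterations, update_mode = update_mode,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  structure(list(conditions = conditions, reps = as.integer(reps),
                 base_seed = as.integer(base_seed)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d conditions x %d replications (base seed %d)\n",
              nrow(x$conditions), x$reps, x$base_seed))
  invisible(x)
}

condition_key <- function(cond) {
  paste(names(cond), vapply(cond, function(v) format(v, digits = 15),
                            character(1)),
        sep = "=", collapse = "|")
}

#' Named grid presets
#'
#' Ready-made sweep designs:
#' \describe{
#'   \item{`figure8`}{The systematic bias-effects design: 150 SAM agents,
#'     initial language `k0 = n0 = 4`, biased agents at `mu0 = 0.1` placed
#'     at random, 500 iterations, 50 replications per cell; sweep over
#'     `lambda0` and `prop_biased` values supplied via `...` (defaults: a
#'     coarse 5 x 5 grid).}
#'   \item{`main-smoke`}{A scaled-down echo of the main study: sizes 10 and
#'     50, all three network classes, strong (`lambda0 = 0.1`) and weak
#'     (`lambda0 = 0.6`) bias, `prop_biased` 0 / 0.1 / 0.5, 1000
#'     iterations, 10 replications.}
#'   \item{`systematic-smoke`}{The systematic design at reduced resolution:
#'     `lambda0` and `prop_biased` in steps of 0.25, 5 replications.}
#' }
#'
#' @param name Preset name.
#' @param base_seed Integer base seed.
#' @param ... Overrides forwarded to [grid_spec()] (e.g., `lambda0`,
#'   `prop_biased`, `reps`, `network`).
#' @return A `grid_spec`.
#' @export
grid_preset <- function(name = c("figure8", "main-smoke", "systematic-smoke"),
                        base_seed = 1L, ...) {
  name <- match.arg(name)
  override <- list(...)
  defaults <- switch(name,
    "figure8" = list(size_net = 150, network = "scale-free", mu0 = 0.1,
                     lambda0 = c(0.1, 0.3, 0.5, 0.7, 0.9), learners = "SAM",
                     prop_biased = c(0, 0.25, 0.5, 0.75, 1),
                     placement = "random", init_k0 = 4, init_n0 = 4,
                     n_iterations = 500, reps = 50),
    "main-smoke" = list(size_net = c(10, 50),
                        network = c("random", "small-world", "scale-free"),
                        mu0 = 0.1, lambda0 = c(0.1, 0.6), learners = "SAM",
                        prop_biased = c(0, 0.1, 0.5), placement = "random",
                        init_k0 = 4, init_n0 = 4, n_iterations = 1000,
                        reps = 10),
    "systematic-smoke" = list(size_net = 150, network = "scale-free",
                              mu0 = 0.1,
                              lambda0 = seq(0, 1, by = 0.25),
                              learners = "SAM",
                              prop_biased = seq(0, 1, by = 0.25),
                              placement = "random", init_k0 = 4,
                              init_n0 = 4, n_iterations = 500, reps = 5))
  args <- utils::modifyList(defaults, override)
  args$base_seed <- base_seed
  do.call(grid_spec, args)
}

#' Run a replicated parameter grid
#'
#' Runs every (condition, replication) cell of the grid and collects one
#' row of outcome statistics per cell. Replication `r` of a condition uses
#' the seed `derive_seed(base_seed, paste(condition_key, r))`, so cells are
#' independent and individually re-runnable. When `out_csv` is given, rows
#' are appended to the file as they complete (crash-safe). A failing cell
#' is recorded with its error message in the `status` column and never
#' aborts the grid.
#'
#' @param spec A [grid_spec()].
#' @param out_csv Optional path of an incrementally written CSV.
#' @param quiet Suppress per-condition progress messages.
#' @return A data frame with one row per (condition, replication): the
#'   condition parameters, `rep`, `seed`, the outcome statistics of
#'   [run_simulation()], and `status`.
#' @export
run_grid <- function(spec, out_csv = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  conds <- spec$conditions
  rows <- vector("list", nrow(conds) * spec$reps)
  idx <- 0L
  header_written <- FALSE
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, , drop = FALSE]
    key <- condition_key(as.list(cond))
    if (!quiet)
      message(sprintf("condition %d/%d: %s", ci, nrow(conds), key))
    for (r in seq_len(spec$reps)) {
      seed <- derive_seed(spec$base_seed, paste(key, r))
      row <- cbind(cond, condition = ci, rep = r, seed = seed,
                   row.names = NULL)
      res <- tryCatch({
        cfg <- sim_config(size_net = cond$size_net, network = cond$network,
                          mu0 = cond$mu0, lambda0 = cond$lambda0,
                          learners = cond$learners,
                          prop_biased = cond$prop_biased,
                          placement = cond$placement,
                          top_fraction = cond$top_fraction,
                          init_k0 = cond$init_k0, init_n0 = cond$init_n0,
                          n_iterations = cond$n_iterations,
                          update_mode = cond$update_mode, seed = seed)
        m <- run_simulation(cfg)$metrics
        data.frame(langval_all = m$langval_all,
                   langval_biased = m$langval_biased,
                   langval_control = m$langval_control,
                   diff = m$diff, heterogeneity = m$heterogeneity,
                   stab_biased = m$stab_biased,
                   stab_biased_ok = m$stab_biased_ok,
                   stab_control = m$stab_control,
                   stab_control_ok = m$stab_control_ok,
                   status = "ok")
      }, error = function(e) {
        data.frame(langval_all = NA_real_, langval_biased = NA_real_,
                   langval_control = NA_real_, diff = NA_real_,
                   heterogeneity = NA_real_, stab_biased = NA_integer_,
                   stab_biased_ok = NA, stab_control = NA_integer_,
                   stab_control_ok = NA,
                   status = paste("error:", conditionMessage(e)))
      })
      row <- cbind(row, res, row.names = NULL)
      idx <- idx + 1L
      rows[[idx]] <- row
      if (!is.null(out_csv)) {
        utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                           col.names = !header_written,
                           append = header_written)
        header_written <- TRUE
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate grid results by condition
#'
#' Averages the replications of each condition: the mean and the
#' inter-replication standard deviation of the final whole-population
#' language value, and means of the other outcome statistics.
#'
#' @param results A [run_grid()] result (rows with `status != "ok"` are
#'   dropped).
#' @return A data frame with one row per condition.
#' @export
summarize_conditions <- function(results) {
  stopifnot(nrow(results) > 0)
  ok <- results[results$status == "ok", , drop = FALSE]
  cond_cols <- intersect(names(ok),
                         c("size_net", "network", "mu0", "lambda0",
                           "learners", "prop_biased", "placement",
                           "top_fraction", "init_k0", "init_n0",
                           "n_iterations", "update_mode"))
  key <- do.call(paste, c(ok[cond_cols], sep = "\r"))
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- !duplicated(key)
  out <- ok[first, cond_cols, drop = FALSE]
  ord <- match(unique(key), sort(unique(key)))
  # tapply sorts by key; realign to first-appearance order
  realign <- function(v) v[ord]
  out$n_reps <- realign(agg(ok$langval_all, length))
  out$mean_langval_all <- realign(agg(ok$langval_all, mean))
  out$sd_langval_all <- realign(as.numeric(tapply(ok$langval_all, key,
                                                  inter_replication_sd)))
  for (nm in c("langval_biased", "langval_control", "diff", "heterogeneity",
               "stab_biased", "stab_control")) {
    out[[paste0("mean_", nm)]] <-
      realign(agg(ok[[nm]], function(v) mean(v, na.rm = TRUE)))
  }
  rownames(out) <- NULL
  out
}

#' Isolines of the aggregated language value over the bias plane
#'
#' For a condition summary covering a rectangular `lambda0 x prop_biased`
#' grid, extracts for each level `L` the frontier of the sub-level set
#' `{mean_langval_all <= L}`: within every `lambda0` column, the cell with
#' the smallest `prop_biased` whose aggregated language value is at most
#' `L` (all cells with more biased agents also fall below `L` when the
#' surface is monotone). These frontiers trace how much bias strength
#' trades off against bias prevalence to reach a given language value.
#'
#' @param summary A [summarize_conditions()] result with `lambda0`,
#'   `prop_biased` and `mean_langval_all` columns.
#' @param levels Numeric vector of language-value levels.
#' @return A data frame with columns `level`, `lambda0`, `prop_biased`,
#'   `mean_langval_all`; levels attained nowhere contribute no rows.
#' @export
isolines <- function(summary, levels) {
  stopifnot(all(c("lambda0", "prop_biased", "mean_langval_all") %in%
                  names(summary)))
  out <- list()
  for (L in levels) {
    sub <- summary[summary$mean_langval_all <= L, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (lam in sort(unique(sub$lambda0))) {
      col <- sub[sub$lambda0 == lam, , drop = FALSE]
      cell <- col[which.min(col$prop_biased), , drop = FALSE]
      out[[length(out) + 1L]] <-
        data.frame(level = L, lambda0 = lam,
                   prop_biased = cell$prop_biased,
                   mean_langval_all = cell$mean_langval_all)
    }
  }
  if (length(out) == 0)
    return(data.frame(level = numeric(0), lambda0 = numeric(0),
                      prop_biased = numeric(0),
                      mean_langval_all = numeric(0)))
  do.call(rbind, out)
}

#' Rank-sum comparisons with Bonferroni correction
#'
#' Two-sided unpaired Wilcoxon rank-sum tests for a family of comparisons,
#' with Bonferroni multiplication by the family size (capped at 1). The
#' exact null distribution is used when both sides have at most 10 values
#' and there are no ties; the normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b Lists of numeric vectors, one element per comparison.
#' @param labels Optional comparison labels.
#' @return A data frame with `label`, `n_a`, `n_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `tested` (FALSE for degenerate inputs).
#' @export
ranksum_bonferroni <- function(a, b, labels = NULL) {
  if (is.numeric(a)) a <- list(a)
  if (is.numeric(b)) b <- list(b)
  stopifnot(length(a) == length(b))
  m <- length(a)
  if (is.null(labels)) labels <- paste0("cmp", seq_len(m))
  rows <- lapply(seq_len(m), function(i) {
    x <- a[[i]]; y <- b[[i]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(label = labels[i], n_a = length(x), n_b = length(y),
                        statistic = NA_real_, p_raw = NA_real_,
                        tested = FALSE))
    }
    use_exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
    data.frame(label = labels[i], n_a = length(x), n_b = length(y),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               tested = TRUE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out[c("label", "n_a", "n_b", "statistic", "p_raw", "p_adjusted", "tested")]
}
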