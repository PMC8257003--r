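#' @useDynLib lingnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Derive a child seed from a master seed and a label
#'
#' Deterministic 31-bit hash used to give every stochastic component
#' (network generation, role assignment, the interaction loop, community
#' detection) and every grid cell its own reproducible seed, so any one
#' component or cell can be re-run in isolation.
#'
#' @param seed Integer master seed.
#' @param label Character label of the component or grid cell.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  if (h < 0) h <- h + 2147483647
  for (b in utf8ToInt(paste0("#", label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Simulation configuration
#'
#' Bundles one full experimental condition: the network (class, size,
#' generator parameters), the bias specification and its prevalence and
#' placement, the production strategy, the initial language, the number of
#' iterations, the updating mode and the master seed. Unbiased agents
#' always carry the near-flat prior with mode 0.5 and strength 0.9; biased
#' agents carry `(mu0, lambda0)`.
#'
#' @param size_net Number of agents.
#' @param network Network class: `"scale-free"`, `"small-world"` or
#'   `"random"`.
#' @param network_params Named list of generator overrides (see
#'   [generate_network()]).
#' @param mu0,lambda0 Bias location and strength of the biased agents (see
#'   [bias_profile()]).
#' @param learners Production strategy shared by all agents: `"SAM"` or
#'   `"MAP"`.
#' @param prop_biased Fraction of agents that are intrinsically biased.
#' @param placement Placement of biased agents: `"random"` or
#'   `"influencers"` (see [assign_bias_roles()]).
#' @param top_fraction Influencer fraction under influencer placement.
#' @param init_k0,init_n0 The initial language: all agents hear the same
#'   `init_n0` utterances of which `init_k0` are "1" at iteration 0
#'   (`0, 0` means no pre-existing language).
#' @param n_iterations Number of interaction iterations.
#' @param update_mode `"asynchronous"` (listeners update immediately) or
#'   `"synchronous"` (all posteriors updated once per iteration).
#' @param record_every Stride used when exporting the group series to CSV;
#'   internally the series is always kept at per-iteration resolution, as
#'   stabilization detection requires.
#' @param seed Integer master seed; fully determines the run.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(size_net = 150,
                       network = c("scale-free", "small-world", "random"),
                       network_params = list(),
                       mu0 = 0.1, lambda0 = 0.6,
                       learners = c("SAM", "MAP"),
                       prop_biased = 0.1,
                       placement = c("random", "influencers"),
                       top_fraction = 0.10,
                       init_k0 = 4, init_n0 = 4,
                       n_iterations = 500,
                       update_mode = c("asynchronous", "synchronous"),
                       record_every = if (size_net <= 150) 1L else 10L,
                       seed = 1L) {
  network <- match.arg(network)
  learners <- match.arg(learners)
  placement <- match.arg(placement)
  update_mode <- match.arg(update_mode)
  bias_profile(mu0, lambda0)  # validate
  if (prop_biased < 0 || prop_biased > 1)
    stop("'prop_biased' must be in [0, 1]", call. = FALSE)
  if (init_k0 < 0 || init_n0 < 0 || init_k0 > init_n0)
    stop("initial language needs 0 <= k0 <= n0", call. = FALSE)
  if (n_iterations < 0) stop("'n_iterations' must be >= 0", call. = FALSE)
  structure(list(size_net = as.integer(size_net), network = network,
                 network_params = network_params, mu0 = mu0,
                 lambda0 = lambda0, learners = learners,
                 prop_biased = prop_biased, placement = placement,
                 top_fraction = top_fraction, init_k0 = as.integer(init_k0),
                 init_n0 = as.integer(init_n0),
                 n_iterations = as.integer(n_iterations),
                 update_mode = update_mode,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d %s agents on a %s network\n", x$size_net, x$learners,
              x$network))
  cat(sprintf("  biased: %.0f%% at (mu0 = %g, lambda0 = %g), placement %s\n",
              100 * x$prop_biased, x$mu0, x$lambda0, x$placement))
  cat(sprintf("  initial language k0 = %d / n0 = %d; %d iterations (%s); seed %d\n",
              x$init_k0, x$init_n0, x$n_iterations, x$update_mode, x$seed))
  invisible(x)
}

# CSR adjacency (0-based) for the compiled loop.
adjacency_csr <- function(net) {
  n <- igraph::vcount(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  lens <- lengths(adj)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(adj, use.names = FALSE)) - 1L)
}

#' Initialize the agent population on a network
#'
#' Builds per-agent state vectors: biased agents receive the prior induced
#' by `(mu0, lambda0)` (or are marked fixed when `lambda0 = 0`), unbiased
#' agents the near-flat prior with mode 0.5 and strength 0.9. The
#' production strategy is shared by the whole run.
#'
#' @param config A [sim_config()].
#' @param roles A [assign_bias_roles()] result for the same network size.
#' @return A list with numeric vectors `alpha`, `beta`, logicals `fixed`,
#'   `biased`, and `fixed_value` (the constant language value of fixed
#'   agents, `NA` elsewhere).
#' @export
initialize_population <- function(config, roles) {
  n <- config$size_net
  if (roles$n != n)
    stop("role assignment does not match the network size", call. = FALSE)
  biased <- rep(FALSE, n)
  biased[roles$biased] <- TRUE
  unb <- prior_from_bias(bias_profile(0.5, 0.9))
  alpha <- rep(unb[["alpha"]], n)
  beta <- rep(unb[["beta"]], n)
  fixed <- rep(FALSE, n)
  fixed_value <- rep(NA_real_, n)
  if (any(biased)) {
    pr <- prior_from_bias(bias_profile(config$mu0, config$lambda0))
    if (is.list(pr) && isTRUE(pr$fixed)) {
      fixed[biased] <- TRUE
      fixed_value[biased] <- pr$value
      alpha[biased] <- 1; beta[biased] <- 1  # unused placeholders
    } else {
      alpha[biased] <- pr[["alpha"]]
      beta[biased] <- pr[["beta"]]
    }
  }
  list(alpha = alpha, beta = beta, fixed = fixed, biased = biased,
       fixed_value = fixed_value)
}

#' Expose all agents to the initial language
#'
#' Updates every non-fixed agent's Beta belief with the shared batch of
#' `k0` "1"-utterances out of `n0`, modeling a pre-existing community
#' convention heard at iteration 0. Fixed agents ignore it.
#'
#' @param pop A population from [initialize_population()].
#' @param k0,n0 The shared utterance batch (`0 <= k0 <= n0`).
#' @return The updated population list.
#' @export
expose_initial_language <- function(pop, k0, n0) {
  if (k0 < 0 || n0 < 0 || k0 > n0)
    stop("initial language needs 0 <= k0 <= n0", call. = FALSE)
  live <- !pop$fixed
  pop$alpha[live] <- pop$alpha[live] + k0
  pop$beta[live] <- pop$beta[live] + (n0 - k0)
  pop
}

#' Run one simulation
#'
#' Generates the network (unless one is supplied), assigns bias roles,
#' initializes the population, applies the initial language (iteration 0),
#' runs `n_iterations` of the broadcast interaction loop, detects Louvain
#' communities, and computes the outcome statistics. Everything is fully
#' determined by `config$seed`: child seeds for network generation, role
#' assignment, the interaction loop and community detection are derived
#' from it with [derive_seed()].
#'
#' @param config A [sim_config()].
#' @param network Optional pre-built igraph network (e.g., from
#'   [net_read_edgelist()]); must have `config$size_net` vertices.
#' @return An object of class `"lingnet_run"`: a list with
#'   \describe{
#'     \item{series}{`(n_iterations + 1) x 3` matrix of per-iteration mean
#'       language values for the whole population and the biased/unbiased
#'       groups (row 1 is iteration 0, after exposure).}
#'     \item{final_states}{data frame of per-agent role, shape parameters,
#'       language value and community.}
#'     \item{metrics}{list of final outcome statistics: `langval_all`,
#'       `langval_biased`, `langval_control`, `diff`
#'       (unbiased minus biased), `heterogeneity` (`NA` for networks of at
#'       most 10 agents), `stab_biased`, `stab_control` with
#'       stabilized-flags.}
#'     \item{network, roles, partition, config}{the run's ingredients.}
#'   }
#' @examples
#' run <- run_simulation(sim_config(size_net = 30, n_iterations = 50, seed = 1))
#' run$metrics$langval_all
#' @export
run_simulation <- function(config, network = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(network)) {
    network <- generate_network(config$network, config$size_net,
                                config$network_params,
                                seed = derive_seed(config$seed, "network"))
  } else if (igraph::vcount(network) != config$size_net) {
    stop("supplied network does not have 'size_net' vertices", call. = FALSE)
  }
  roles <- assign_bias_roles(network, config$prop_biased, config$placement,
                             config$top_fraction,
                             seed = derive_seed(config$seed, "roles"))
  pop <- initialize_population(config, roles)
  pop <- expose_initial_language(pop, config$init_k0, config$init_n0)

  csr <- adjacency_csr(network)
  set.seed(derive_seed(config$seed, "engine"))
  eng <- .engine_run(csr$ptr, csr$idx, pop$alpha, pop$beta, pop$fixed,
                     ifelse(is.na(pop$fixed_value), 0, pop$fixed_value),
                     pop$biased, if (config$learners == "SAM") 0L else 1L,
                     config$n_iterations,
                     config$update_mode == "synchronous")

  partition <- detect_communities(network,
                                  seed = derive_seed(config$seed, "louvain"))

  values <- agent_values(eng$alpha, eng$beta, pop$fixed, pop$fixed_value)
  final_states <- data.frame(
    agent = seq_len(config$size_net),
    role = ifelse(pop$biased, "biased", "unbiased"),
    fixed = pop$fixed,
    alpha = ifelse(pop$fixed, NA_real_, eng$alpha),
    beta = ifelse(pop$fixed, NA_real_, eng$beta),
    language_value = values,
    community = partition$membership)

  metrics <- run_metrics(values, pop$biased, partition, eng$series,
                         config$n_iterations)

  structure(list(series = eng$series, final_states = final_states,
                 metrics = metrics, network = network, roles = roles,
                 partition = partition, config = config),
            class = "lingnet_run")
}

# Per-agent language values from engine output.
agent_values <- function(alpha, beta, fixed, fixed_value) {
  v <- beta_mode(pmax(alpha, 1), pmax(beta, 1))
  v[fixed] <- fixed_value[fixed]
  v
}

# Final outcome statistics of a run.
run_metrics <- function(values, biased, partition, series, n_iterations) {
  omega <- floor(n_iterations / 10)
  stab <- function(col) {
    s <- series[, col]
    if (all(is.na(s)) || n_iterations < 10 ||
        length(s) < omega + 51L)
      return(list(tick = NA_integer_, stabilized = NA))
    r <- stabilization_time(s, n_iterations)
    list(tick = r$stab_tick, stabilized = r$stabilized)
  }
  sb <- stab("biased"); sc <- stab("unbiased")
  list(
    langval_all = group_language_value(values),
    langval_biased = group_language_value(values[biased]),
    langval_control = group_language_value(values[!biased]),
    diff = diff_unbiased_biased(values, biased),
    heterogeneity = heterogeneity(values, partition),
    stab_biased = sb$tick, stab_biased_ok = sb$stabilized,
    stab_control = sc$tick, stab_control_ok = sc$stabilized)
}

#' @export
print.lingnet_run <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("lingnet run: %d %s agents, %s network, %d iterations\n",
              x$config$size_net, x$config$learners, x$config$network,
              x$config$n_iterations))
  cat(sprintf("  final language value: all %.3f | biased %s | unbiased %s\n",
              m$langval_all,
              ifelse(is.na(m$langval_biased), "-", sprintf("%.3f", m$langval_biased)),
              ifelse(is.na(m$langval_control), "-", sprintf("%.3f", m$langval_control))))
  cat(sprintf("  heterogeneity across %d communities: %s\n",
              x$partition$n_communities,
              ifelse(is.na(m$heterogeneity), "not computed",
                     sprintf("%.4f", m$heterogeneity))))
  invisible(x)
}

#' @export
summary.lingnet_run <- function(object, ...) {
  m <- object$metrics
  cat("Outcome statistics\n")
  for (nm in c("langval_all", "langval_biased", "langval_control", "diff",
               "heterogeneity"))
    cat(sprintf("  %-16s %s\n", nm,
                ifelse(is.na(m[[nm]]), "NA", sprintf("%.5f", m[[nm]]))))
  cat(sprintf("  %-16s %s%s\n", "stab_biased",
              ifelse(is.na(m$stab_biased), "NA", m$stab_biased),
              ifelse(isTRUE(m$stab_biased_ok), "", " (not stabilized)")))
  cat(sprintf("  %-16s %s%s\n", "stab_control",
              ifelse(is.na(m$stab_control), "NA", m$stab_control),
              ifelse(isTRUE(m$stab_control_ok), "", " (not stabilized)")))
  invisible(m)
}

#' Plot the group language-value trajectories of a run
#'
#' @param x A `lingnet_run`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lingnet_run <- function(x, ...) {
  it <- seq_len(nrow(x$series)) - 1L
  graphics::matplot(it, x$series, type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "forestgreen"),
                    xlab = "iteration", ylab = "mean language value",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = colnames(x$series), lty = 1, lwd = 2,
                   col = c("black", "firebrick", "forestgreen"), bty = "n")
  invisible(x)
}

#' Export a run to CSV files
#'
#' Writes the group language-value series (thinned to
#' `config$record_every`), the per-agent final states, and a plain-text
#' manifest of the full configuration and seed.
#'
#' @param run A `lingnet_run`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stride <- max(1L, run$config$record_every)
  rows <- unique(c(seq(1L, nrow(run$series), by = stride), nrow(run$series)))
  series <- data.frame(iteration = rows - 1L, run$series[rows, , drop = FALSE])
  p1 <- file.path(dir, paste0(prefix, "_series.csv"))
  p2 <- file.path(dir, paste0(prefix, "_agents.csv"))
  p3 <- file.path(dir, paste0(prefix, "_manifest.yaml"))
  utils::write.csv(series, p1, row.names = FALSE)
  utils::write.csv(run$final_states, p2, row.names = FALSE)
  cfg <- unclass(run$config)
  cfg$network_params <- NULL
  yaml::write_yaml(c(cfg, run$config$network_params,
                     list(metrics = lapply(run$metrics, function(v)
                       if (is.na(v)) "NA" else v))), p3)
  invisible(c(p1, p2, p3))
}
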