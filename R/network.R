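#' Network configuration for the cerebellar rate model
#'
#' Builds the parameter set describing the cerebellar cortical microcircuit:
#' population sizes (mossy fibers, granule, Golgi, basket/stellate and
#' Purkinje cells), the sigmoidal activation constants, the learning rate of
#' the climbing-fiber-gated plasticity rule, and the per-projection
#' convergence counts (number of presynaptic partners per postsynaptic cell).
#'
#' The default population sizes (755 granule cells, 5 Golgi cells, 15
#' basket/stellate cells, 1 Purkinje cell) preserve the convergence and
#' divergence ratios of the real cerebellar circuit at a scale sufficient to
#' control the plants shipped with the package.  The number of mossy fibers
#' depends on the plant: 7 channels for the balancing robot, 5 for the DC
#' motor.
#'
#' @param plant either \code{"motor"} or \code{"robot"}; sets \code{n_mf}
#'   when it is not given explicitly.
#' @param n_mf number of mossy fibers (input channels).
#' @param n_gc number of granule cells (parallel fibers).
#' @param n_go number of Golgi cells.
#' @param n_ba number of basket/stellate cells.
#' @param n_pc number of Purkinje cells (the model output; 1).
#' @param sigma steepness of the sigmoidal activation (dimensionless).
#' @param mu midpoint of the sigmoidal activation (dimensionless).
#' @param gamma learning rate of the PF-PC plasticity rule, per sample.
#' @param convergence named list of presynaptic partner counts for the
#'   masked projections: \code{mf_gc}, \code{go_gc}, \code{pf_go},
#'   \code{pf_ba}.  Mossy fiber to Golgi, PF to Purkinje and basket to
#'   Purkinje projections are fully connected.
#'
#' @return an object of class \code{"network_config"} (a validated list).
#' @seealso [build_connectivity()], [initialize_weights()]
#' @export
#' @examples
#' cfg <- network_config("robot")
#' cfg$n_mf   # 7 input channels
network_config <- function(plant = c("robot", "motor"),
                           n_mf = NULL,
                           n_gc = 755L, n_go = 5L, n_ba = 15L, n_pc = 1L,
                           sigma = 8, mu = 0.5, gamma = 0.008,
                           convergence = list(mf_gc = 4L, go_gc = 3L,
                                              pf_go = 150L, pf_ba = 50L)) {
  plant <- match.arg(plant)
  if (is.null(n_mf)) n_mf <- if (plant == "robot") 7L else 5L
  cfg <- list(plant = plant,
              n_mf = as.integer(n_mf), n_gc = as.integer(n_gc),
              n_go = as.integer(n_go), n_ba = as.integer(n_ba),
              n_pc = as.integer(n_pc),
              sigma = sigma, mu = mu, gamma = gamma,
              convergence = lapply(convergence, as.integer))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  counts <- c(n_mf = cfg$n_mf, n_gc = cfg$n_gc, n_go = cfg$n_go,
              n_ba = cfg$n_ba, n_pc = cfg$n_pc)
  if (any(counts < 1L))
    stop("all population counts must be positive, got: ",
         paste(names(counts)[counts < 1L], collapse = ", "))
  if (!is.numeric(cfg$gamma) || cfg$gamma <= 0)
    stop("learning rate 'gamma' must be > 0")
  if (!is.numeric(cfg$sigma) || cfg$sigma <= 0)
    stop("activation steepness 'sigma' must be > 0")
  need <- c("mf_gc", "go_gc", "pf_go", "pf_ba")
  miss <- setdiff(need, names(cfg$convergence))
  if (length(miss))
    stop("missing convergence counts: ", paste(miss, collapse = ", "))
  pre <- c(mf_gc = cfg$n_mf, go_gc = cfg$n_go,
           pf_go = cfg$n_gc, pf_ba = cfg$n_gc)
  for (p in need) {
    k <- cfg$convergence[[p]]
    if (k < 1L) stop("convergence count for ", p, " must be positive")
    if (k > pre[[p]])
      stop("convergence count for ", p, " (", k,
           ") exceeds its presynaptic population (", pre[[p]], ")")
  }
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("Cerebellar network configuration (", x$plant, " plant)\n", sep = "")
  cat(sprintf("  populations: %d MF, %d GC, %d GO, %d BA, %d PC\n",
              x$n_mf, x$n_gc, x$n_go, x$n_ba, x$n_pc))
  cat(sprintf("  activation: sigma = %g, mu = %g; learning rate gamma = %g\n",
              x$sigma, x$mu, x$gamma))
  cv <- x$convergence
  cat(sprintf("  convergence: MF>GC %d, GO>GC %d, PF>GO %d, PF>BA %d (MF>GO, PF>PC, BA>PC full)\n",
              cv$mf_gc, cv$go_gc, cv$pf_go, cv$pf_ba))
  invisible(x)
}

# one 0/1 mask (pre x post) with exactly k ones per column, partners drawn
# uniformly without replacement
draw_mask <- function(n_pre, n_post, k) {
  m <- matrix(0, n_pre, n_post)
  for (j in seq_len(n_post)) m[sample.int(n_pre, k), j] <- 1
  m
}

#' Build the masked connectivity of the cerebellar network
#'
#' Draws the binary masking matrices that embed the convergence ratios of
#' the circuit: each postsynaptic cell receives exactly the configured
#' number of presynaptic partners, drawn uniformly without replacement.
#' The mossy fiber to Golgi projection is fully connected (the tabulated
#' convergence exceeds the available mossy fibers), as are PF to Purkinje
#' and basket to Purkinje.
#'
#' A single master seed is expanded deterministically into independent
#' per-projection draws, so masks are reproducible projection by projection.
#'
#' @param config a [network_config()] object.
#' @param seed integer master seed.
#' @return an object of class \code{"connectivity_masks"}: list of 0/1
#'   matrices \code{m_mf_gc}, \code{m_go_gc}, \code{m_mf_go},
#'   \code{m_pf_go}, \code{m_pf_ba} (presynaptic rows, postsynaptic
#'   columns).
#' @export
#' @examples
#' masks <- build_connectivity(network_config("robot"), seed = 1)
#' colSums(masks$m_mf_gc)[1:5]  # every granule cell receives 4 mossy fibers
build_connectivity <- function(config, seed) {
  validate_network_config(config)
  sub <- derive_seeds(seed, 4L)
  cv <- config$convergence
  set.seed(sub[1L])
  m_mf_gc <- draw_mask(config$n_mf, config$n_gc, cv$mf_gc)
  set.seed(sub[2L])
  m_go_gc <- draw_mask(config$n_go, config$n_gc, cv$go_gc)
  set.seed(sub[3L])
  m_pf_go <- draw_mask(config$n_gc, config$n_go, cv$pf_go)
  set.seed(sub[4L])
  m_pf_ba <- draw_mask(config$n_gc, config$n_ba, cv$pf_ba)
  m_mf_go <- matrix(1, config$n_mf, config$n_go)  # full connectivity
  structure(list(m_mf_gc = m_mf_gc, m_go_gc = m_go_gc, m_mf_go = m_mf_go,
                 m_pf_go = m_pf_go, m_pf_ba = m_pf_ba),
            class = "connectivity_masks")
}

# rejection sampling of Normal(mean, 1) into (lo, hi); upper bound inclusive
# when 'inc_hi' (continuous law, so boundaries carry no mass either way)
rtrunc_norm <- function(n, mean, lo, hi) {
  out <- numeric(n)
  need <- n
  got <- 0L
  while (need > 0L) {
    x <- rnorm(max(need * 3L, 16L), mean = mean, sd = 1)
    x <- x[x > lo & x <= hi]
    take <- min(length(x), need)
    if (take > 0L) {
      out[(got + 1L):(got + take)] <- x[seq_len(take)]
      got <- got + take
      need <- need - take
    }
  }
  out
}

#' Initialize the synaptic weights of the cerebellar network
#'
#' Excitatory weights are sampled from a Normal(0.5, 1) restricted to
#' (0, 1] and inhibitory weights from a Normal(-0.5, 1) restricted to
#' (-1, 0), by rejection (not clipping, which would pile mass on the
#' bounds).  Entries where the connectivity mask is zero are exactly zero.
#' The PF to Purkinje vector \code{w_pf_pc} is the only weight set later
#' modified by learning.
#'
#' @param config a [network_config()] object.
#' @param masks a [build_connectivity()] result.
#' @param seed integer master seed (expanded into per-matrix draws).
#' @return an object of class \code{"synapse_weights"}: matrices
#'   \code{w_mf_gc}, \code{w_go_gc}, \code{w_mf_go}, \code{w_pf_go},
#'   \code{w_pf_ba}, \code{w_ba_pc} and the plastic vector \code{w_pf_pc}
#'   of length \code{n_gc}.
#' @export
initialize_weights <- function(config, masks, seed) {
  validate_network_config(config)
  sub <- derive_seeds(seed, 7L)
  fill <- function(mask, mean, lo, hi, s) {
    set.seed(s)
    w <- matrix(0, nrow(mask), ncol(mask))
    idx <- which(mask == 1)
    w[idx] <- rtrunc_norm(length(idx), mean, lo, hi)
    w
  }
  exc <- function(mask, s) fill(mask, 0.5, 0, 1, s)
  inh <- function(mask, s) fill(mask, -0.5, -1, 0, s)
  w_mf_gc <- exc(masks$m_mf_gc, sub[1L])
  w_go_gc <- inh(masks$m_go_gc, sub[2L])
  w_mf_go <- exc(masks$m_mf_go, sub[3L])
  w_pf_go <- exc(masks$m_pf_go, sub[4L])
  w_pf_ba <- exc(masks$m_pf_ba, sub[5L])
  set.seed(sub[6L])
  w_ba_pc <- matrix(rtrunc_norm(config$n_ba, -0.5, -1, 0), ncol = 1)
  set.seed(sub[7L])
  w_pf_pc <- rtrunc_norm(config$n_gc, 0.5, 0, 1)
  structure(list(w_mf_gc = w_mf_gc, w_go_gc = w_go_gc, w_mf_go = w_mf_go,
                 w_pf_go = w_pf_go, w_pf_ba = w_pf_ba, w_ba_pc = w_ba_pc,
                 w_pf_pc = w_pf_pc),
            class = "synapse_weights")
}

#' Sigmoidal rate activation
#'
#' The activation shared by every population in the model:
#' \code{1 / (1 + exp(-sigma * (x - mu)))}, mapping a synaptic drive to a
#' firing rate in (0, 1).
#'
#' @param x synaptic drive (any numeric vector).
#' @param sigma steepness (default 8).
#' @param mu midpoint (default 0.5); \code{sigmoid_rate(mu) == 0.5}.
#' @return rates in (0, 1), same shape as \code{x}.
#' @export
#' @examples
#' sigmoid_rate(0.5)  # 0.5, the midpoint
#' sigmoid_rate(0)    # ~0.018, the quiescent rate
sigmoid_rate <- function(x, sigma = 8, mu = 0.5) {
  1 / (1 + exp(-sigma * (x - mu)))
}

#' Guard the Purkinje cell against over-inhibition
#'
#' With hundreds of excitatory parallel-fiber inputs against a handful of
#' basket/stellate inhibitory inputs, a freshly initialized Purkinje cell
#' sits far outside the dynamic range of its activation.  The guard
#' rescales the basket-to-Purkinje weight column by a single scalar so that
#' the baseline Purkinje drive -- computed with every presynaptic rate at
#' 0.5 -- lies inside \[0.3, 0.7\] (the rescale targets 0.5 exactly whenever
#' the baseline is outside that band).  The scalar is returned so runs can
#' log it.
#'
#' @param weights a [initialize_weights()] result.
#' @param target baseline drive aimed at when rescaling (default 0.5).
#' @return list with elements \code{weights} (guarded) and \code{scale}
#'   (the applied scalar, 1 when no rescale was needed).
#' @export
purkinje_guard <- function(weights, target = 0.5) {
  base <- 0.5 * sum(weights$w_pf_pc) + 0.5 * sum(weights$w_ba_pc)
  scale <- 1
  if (base < 0.3 || base > 0.7) {
    # solve 0.5*sum(w_pf_pc) + s * 0.5*sum(w_ba_pc) = target
    denom <- 0.5 * sum(weights$w_ba_pc)
    if (denom == 0) stop("cannot guard Purkinje baseline: no basket input")
    scale <- (target - 0.5 * sum(weights$w_pf_pc)) / denom
    weights$w_ba_pc <- weights$w_ba_pc * scale
  }
  list(weights = weights, scale = scale)
}

#' Initial state of the cerebellar network
#'
#' The granule-Golgi recurrent loop is resolved with a one-sample delay:
#' the granule drive uses the previous sample's Golgi rates.  The initial
#' previous-sample Golgi rate is set to 0.5, the same operating baseline
#' assumed by [purkinje_guard()].
#'
#' @param config a [network_config()] object.
#' @return an object of class \code{"network_state"}.
#' @export
network_state <- function(config) {
  structure(list(y_mf = rep(sigmoid_rate(0, config$sigma, config$mu), config$n_mf),
                 y_pf = rep(0.5, config$n_gc),
                 y_go = rep(0.5, config$n_go),
                 y_ba = rep(0.5, config$n_ba),
                 y_pc = 0,
                 y_go_prev = rep(0.5, config$n_go)),
            class = "network_state")
}

#' One rate-dynamics step of the cerebellar network
#'
#' Evaluates the circuit for one 10-ms control sample, in order: granule
#' drive from mossy fibers and the previous sample's Golgi rates (masked
#' weights), parallel-fiber rates, Golgi drive from mossy fibers and the
#' current parallel fibers, Golgi rates, basket drive and rates, and the
#' Purkinje drive (full PF and basket convergence) whose rate is shifted by
#' -0.5 into (-0.5, 0.5) so it can be subtracted from the motor command.
#'
#' @param state a \code{"network_state"} (holds the previous Golgi rates).
#' @param weights a \code{"synapse_weights"} set.
#' @param masks a \code{"connectivity_masks"} set.
#' @param y_mf mossy-fiber rate vector for this sample.
#' @param config a [network_config()] object.
#' @return the updated \code{"network_state"}; element \code{y_pc} is the
#'   Purkinje output in (-0.5, 0.5) and \code{y_go_prev} holds this
#'   sample's Golgi rates for the next call.
#' @export
network_step <- function(state, weights, masks, y_mf, config) {
  sg <- config$sigma; mu <- config$mu
  x_gc <- drop(y_mf %*% (masks$m_mf_gc * weights$w_mf_gc)) +
          drop(state$y_go_prev %*% (masks$m_go_gc * weights$w_go_gc))
  if (!all(is.finite(x_gc))) stop("non-finite granule drive")
  y_pf <- sigmoid_rate(x_gc, sg, mu)
  x_go <- drop(y_mf %*% (masks$m_mf_go * weights$w_mf_go)) +
          drop(y_pf %*% (masks$m_pf_go * weights$w_pf_go))
  y_go <- sigmoid_rate(x_go, sg, mu)
  x_ba <- drop(y_pf %*% (masks$m_pf_ba * weights$w_pf_ba))
  y_ba <- sigmoid_rate(x_ba, sg, mu)
  x_pc <- sum(y_pf * weights$w_pf_pc) + sum(y_ba * weights$w_ba_pc)
  if (!is.finite(x_pc)) stop("non-finite Purkinje drive")
  y_pc <- sigmoid_rate(x_pc, sg, mu) - 0.5
  structure(list(y_mf = y_mf, y_pf = y_pf, y_go = y_go, y_ba = y_ba,
                 y_pc = y_pc, y_go_prev = y_go),
            class = "network_state")
}

#' Climbing-fiber-gated plasticity at parallel fiber-Purkinje synapses
#'
#' Applies the learning rule \code{dW = -gamma * (y_pf - 0.5) * cf} to the
#' plastic PF-PC weight vector, then clips it into \[eps, 1\] to keep the
#' synapses excitatory.  When the zero-centred parallel-fiber rate and the
#' climbing-fiber value share a sign the weight is depressed (LTD);
#' opposite signs potentiate it (LTP).  No other weight set is touched.
#'
#' @param weights a \code{"synapse_weights"} set.
#' @param y_pf parallel-fiber rate vector of the current sample.
#' @param cf_value scalar climbing-fiber teaching signal.
#' @param gamma learning rate per sample.
#' @param eps lower clip bound keeping weights strictly positive.
#' @return the weights with \code{w_pf_pc} updated.
#' @export
#' @examples
#' toy <- make_toy_network()
#' w1 <- apply_cf_learning(toy$weights, y_pf = rep(1, 3), cf_value = 0.5,
#'                         gamma = 0.008)
#' w1$w_pf_pc - toy$weights$w_pf_pc   # -0.002: depression
apply_cf_learning <- function(weights, y_pf, cf_value, gamma = 0.008,
                              eps = 1e-6) {
  if (!is.finite(cf_value)) stop("non-finite climbing-fiber value")
  w <- weights$w_pf_pc - gamma * (y_pf - 0.5) * cf_value
  weights$w_pf_pc <- pmin(pmax(w, eps), 1)
  weights
}

#' Hand-settable miniature network fixture
#'
#' Builds a fully connected toy network (default 2 mossy fibers, 3 granule,
#' 1 Golgi, 1 basket, 1 Purkinje cell) with all excitatory weights at 0.5
#' and inhibitory at -0.5, for worked examples and step-by-step checks of
#' the rate equations.
#'
#' @param n_mf,n_gc,n_go,n_ba,n_pc population sizes (each >= 1).
#' @return list with \code{config}, \code{masks} (all-ones) and
#'   \code{weights}; every weight entry can be overwritten directly.
#' @export
make_toy_network <- function(n_mf = 2L, n_gc = 3L, n_go = 1L, n_ba = 1L,
                             n_pc = 1L) {
  config <- network_config("motor", n_mf = n_mf, n_gc = n_gc, n_go = n_go,
                           n_ba = n_ba, n_pc = n_pc,
                           convergence = list(mf_gc = n_mf, go_gc = n_go,
                                              pf_go = n_gc, pf_ba = n_gc))
  ones <- function(a, b) matrix(1, a, b)
  masks <- structure(list(m_mf_gc = ones(n_mf, n_gc),
                          m_go_gc = ones(n_go, n_gc),
                          m_mf_go = ones(n_mf, n_go),
                          m_pf_go = ones(n_gc, n_go),
                          m_pf_ba = ones(n_gc, n_ba)),
                     class = "connectivity_masks")
  weights <- structure(list(w_mf_gc = 0.5 * masks$m_mf_gc,
                            w_go_gc = -0.5 * masks$m_go_gc,
                            w_mf_go = 0.5 * masks$m_mf_go,
                            w_pf_go = 0.5 * masks$m_pf_go,
                            w_pf_ba = 0.5 * masks$m_pf_ba,
                            w_ba_pc = matrix(-0.5, n_ba, 1),
                            w_pf_pc = rep(0.5, n_gc)),
                       class = "synapse_weights")
  list(config = config, masks = masks, weights = weights)
}
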