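#' Normal parameter distribution
#'
#' @param mean,sd mean and standard deviation, in the units of the target
#'   parameter (`sd >= 0`; `sd = 0` denotes a point mass, usable for sampling
#'   and quadrature but not for density evaluation).
#' @param truncate_at_zero if `TRUE`, samples are redrawn until nonnegative
#'   and the density is renormalized on `[0, Inf)`. Off by default: the
#'   distributions here are not truncated, so a large `sd` on a physically
#'   nonnegative parameter can produce negative draws.
#' @return A `dist_spec` object.
#' @export
dist_normal <- function(mean, sd, truncate_at_zero = FALSE) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L, sd >= 0)
  structure(list(kind = "normal", mean = mean, sd = sd,
                 truncate = isTRUE(truncate_at_zero)),
            class = "dist_spec")
}

#' Two-component normal mixture distribution
#'
#' Models a population with two subpopulations (for example strongly and
#' weakly adapting neurons): with probability `weight` a value is drawn from
#' `N(mean1, sd1^2)`, otherwise from `N(mean2, sd2^2)`.
#'
#' @param mean1,sd1 first component.
#' @param mean2,sd2 second component.
#' @param weight mixing proportion of component 1, in `[0, 1]`.
#' @inheritParams dist_normal
#' @return A `dist_spec` object.
#' @export
dist_mixture <- function(mean1, sd1, mean2, sd2, weight,
                         truncate_at_zero = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, weight >= 0, weight <= 1)
  structure(list(kind = "mixture", mean1 = mean1, sd1 = sd1,
                 mean2 = mean2, sd2 = sd2, weight = weight,
                 truncate = isTRUE(truncate_at_zero)),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$kind == "normal")
    cat(sprintf("normal(mean = %g, sd = %g)%s\n", x$mean, x$sd,
                if (x$truncate) " truncated at 0" else ""))
  else
    cat(sprintf("mixture: %g * N(%g, %g^2) + %g * N(%g, %g^2)%s\n",
                x$weight, x$mean1, x$sd1, 1 - x$weight, x$mean2, x$sd2,
                if (x$truncate) " truncated at 0" else ""))
  invisible(x)
}

dist_mean <- function(spec) {
  if (spec$kind == "normal") spec$mean
  else spec$weight * spec$mean1 + (1 - spec$weight) * spec$mean2
}

dist_range <- function(spec, span = 8) {
  if (spec$kind == "normal")
    spec$mean + c(-1, 1) * span * max(spec$sd, .Machine$double.eps)
  else
    range(spec$mean1 + c(-1, 1) * span * spec$sd1,
          spec$mean2 + c(-1, 1) * span * spec$sd2)
}

#' Probability density of a parameter distribution
#'
#' @param spec a `dist_spec`.
#' @param x values at which to evaluate the density.
#' @return Numeric vector of densities.
#' @export
het_density <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  degenerate <- if (spec$kind == "normal") spec$sd == 0 else
    (spec$sd1 == 0 || spec$sd2 == 0)
  if (degenerate)
    stop("degenerate distribution: point mass has no density", call. = FALSE)
  d <- if (spec$kind == "normal") {
    stats::dnorm(x, spec$mean, spec$sd)
  } else {
    spec$weight * stats::dnorm(x, spec$mean1, spec$sd1) +
      (1 - spec$weight) * stats::dnorm(x, spec$mean2, spec$sd2)
  }
  if (spec$truncate) {
    mass <- if (spec$kind == "normal") {
      stats::pnorm(0, spec$mean, spec$sd, lower.tail = FALSE)
    } else {
      spec$weight * stats::pnorm(0, spec$mean1, spec$sd1, lower.tail = FALSE) +
        (1 - spec$weight) * stats::pnorm(0, spec$mean2, spec$sd2,
                                         lower.tail = FALSE)
    }
    d <- ifelse(x < 0, 0, d / mass)
  }
  d
}

#' Draw reproducible samples from a parameter distribution
#'
#' @param spec a `dist_spec`.
#' @param n number of draws.
#' @param seed optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of length `n`.
#' @export
het_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  draw <- function(m) {
    if (spec$kind == "normal") {
      stats::rnorm(m, spec$mean, spec$sd)
    } else {
      pick <- stats::runif(m) < spec$weight
      ifelse(pick, stats::rnorm(m, spec$mean1, spec$sd1),
             stats::rnorm(m, spec$mean2, spec$sd2))
    }
  }
  x <- draw(n)
  if (spec$truncate) {
    while (any(bad <- x < 0)) x[bad] <- draw(sum(bad))
  }
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Quadrature nodes and weights for integrating against a distribution
#'
#' Deterministic mode uses Gauss-Hermite nodes mapped to `(mean, sd)` and is
#' available for one-dimensional normal specs only (the smooth choice needed
#' by root-finding); Monte-Carlo mode draws `M` i.i.d. samples with uniform
#' weights `1/M` and works for any spec.
#'
#' @param spec a `dist_spec`.
#' @param M number of nodes.
#' @param mode `"hermite"` or `"montecarlo"`.
#' @param seed integer seed for Monte-Carlo draws.
#' @return A list with components `nodes` and `weights` (weights sum to 1).
#' @export
het_quadrature <- function(spec, M, mode = c("hermite", "montecarlo", "dense"),
                           seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), M >= 1)
  mode <- match.arg(mode)
  if (mode == "dense") {
    rng <- dist_range(spec)
    nodes <- seq(rng[1], rng[2], length.out = M)
    w <- het_density(spec, nodes)
    w[c(1, M)] <- w[c(1, M)] / 2         # trapezoid end weights
    return(list(nodes = nodes, weights = w / sum(w)))
  }
  if (mode == "hermite") {
    if (spec$kind != "normal" || spec$truncate)
      stop("unsupported mode: Gauss-Hermite quadrature requires an ",
           "untruncated normal spec", call. = FALSE)
    if (M == 1L) return(list(nodes = spec$mean, weights = 1))
    gh <- pracma::gaussHermite(M)
    list(nodes = spec$mean + sqrt(2) * spec$sd * gh$x,
         weights = gh$w / sqrt(pi))
  } else {
    list(nodes = het_sample(spec, M, seed = seed), weights = rep(1 / M, M))
  }
}

#' Heterogeneity specification over named model parameters
#'
#' Binds distributions to dimensional parameter names. Parameters not listed
#' are homogeneous at their `izh_params` values. Heterogeneous parameters
#' are assumed independent of one another.
#'
#' @param ... named `dist_spec` objects; valid names are `I_app`, `g_syn`,
#'   `W_jump`, `tau_W`.
#' @return A `het_spec` object (named list of `dist_spec`).
#' @export
#' @examples
#' het_spec(I_app = dist_normal(4500, 1000))
het_spec <- function(...) {
  specs <- list(...)
  allowed <- c("I_app", "g_syn", "W_jump", "tau_W")
  if (length(specs) == 0) stop("empty heterogeneity spec", call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == ""))
    stop("all distributions must be named after a model parameter",
         call. = FALSE)
  bad <- setdiff(names(specs), allowed)
  if (length(bad))
    stop("unknown heterogeneous parameter(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(allowed, collapse = ", "), call. = FALSE)
  if (!all(vapply(specs, inherits, TRUE, "dist_spec")))
    stop("all components must be dist_spec objects", call. = FALSE)
  structure(specs, class = "het_spec")
}

# scale factor taking a dimensional heterogeneous parameter to its
# dimensionless counterpart (division); tau_W maps to the dimensionless
# adaptation time constant 1/a
het_dimless_scale <- function(name, p) {
  sc <- attr(nondimensionalize(p), "scales")
  switch(name,
         I_app  = sc$current_pA,
         g_syn  = sc$conductance_nS,
         W_jump = sc$current_pA,
         tau_W  = sc$time_ms,
         stop("unknown parameter ", name, call. = FALSE))
}

# dimensionless field of izh_params_nd that a heterogeneous parameter feeds
het_nd_field <- function(name) {
  switch(name, I_app = "I", g_syn = "g", W_jump = "w_jump", tau_W = "tau_w",
         stop("unknown parameter ", name, call. = FALSE))
}

#' Build a dimensionless parameter grid from a heterogeneity specification
#'
#' Draws or constructs `M` nodes in the heterogeneous-parameter space and
#' converts them to dimensionless units. With a single heterogeneous normal
#' parameter the `"hermite"` mode gives deterministic Gauss-Hermite nodes;
#' otherwise Monte-Carlo sampling is used (and `mode = "hermite"` is an
#' error for mixtures or multiple parameters).
#'
#' The `"dense"` mode lays a deterministic uniform grid over the
#' distribution's `+-8` standard-deviation span with trapezoid
#' density weights; it resolves the square-root onset of the conditional
#' firing rate far better than a few Gauss-Hermite nodes, which matters
#' whenever eigenvalues or root-finding are involved.
#'
#' @param het a `het_spec`.
#' @param p the base `izh_params` (supplies homogeneous values and scales).
#' @param M number of grid nodes.
#' @param mode `"hermite"`, `"montecarlo"` or `"dense"`.
#' @param seed integer seed for Monte-Carlo mode.
#' @return A `beta_grid` object: data frame with one dimensionless column per
#'   heterogeneous parameter (`I`, `g`, `w_jump`, `tau_w`) plus a `weight`
#'   column summing to 1. Attributes record the parameter names, seed, and
#'   the dimensional node values.
#' @export
beta_grid <- function(het, p, M = 1000,
                      mode = c("montecarlo", "hermite", "dense"),
                      seed = NULL) {
  stopifnot(inherits(het, "het_spec"), inherits(p, "izh_params"))
  mode <- match.arg(mode)
  nm <- names(het)
  if (mode != "montecarlo" && length(nm) > 1L)
    stop("unsupported mode: deterministic grids are one-dimensional",
         call. = FALSE)
  dim_nodes <- list()
  if (mode != "montecarlo") {
    q <- het_quadrature(het[[1]], M, mode = mode)
    dim_nodes[[nm]] <- q$nodes
    weights <- q$weights
  } else {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    for (k in nm) dim_nodes[[k]] <- het_sample(het[[k]], M)
    weights <- rep(1 / M, M)
  }
  out <- data.frame(row.names = seq_len(M))
  for (k in nm)
    out[[het_nd_field(k)]] <- dim_nodes[[k]] / het_dimless_scale(k, p)
  out$weight <- weights
  structure(out, class = c("beta_grid", "data.frame"),
            het_params = nm, mode = mode, seed = seed,
            dim_nodes = as.data.frame(dim_nodes))
}
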