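#' Configuration for the biased-random-walk null model
#'
#' A virtual axon grows through the neuropil cube as a persistent
#' (biased) random walk: each step has fixed length and the new
#' direction is drawn from a von Mises-Fisher distribution concentrated
#' around the previous direction, giving the relatively straight
#' trajectory characteristic of growing axon collaterals. Any
#' unconsumed candidate site that comes within the capture radius is
#' scored as a synapse. Each replicate stops when the observed number
#' of synapses has been reached (or at \code{max_steps}).
#'
#' @param n_synapses_stop synapses to score per replicate (the observed
#'   per-cluster synapse count).
#' @param cube_um cube edge length in micrometres (default 500).
#' @param capture_radius_um capture distance in micrometres (default 1);
#'   must be < cube_um / 10.
#' @param n_reps number of replicates (default 10000).
#' @param step_um step length (default 1).
#' @param persistence_kappa von Mises-Fisher concentration of the
#'   turning distribution; 0 = unbiased random walk, large = nearly
#'   straight (default 20).
#' @param max_steps hard cap on steps per replicate (default 1e6).
#' @param seed integer root seed; replicates use independent child
#'   streams, so results do not depend on replicate order.
#' @return object of class \code{walk_config}.
#' @export
walk_config <- function(n_synapses_stop,
                        cube_um = 500, capture_radius_um = 1,
                        n_reps = 10000, step_um = 1,
                        persistence_kappa = 20, max_steps = 1e6,
                        seed = 1L) {
  stopifnot(n_synapses_stop >= 1, n_reps >= 1, step_um > 0,
            persistence_kappa >= 0, max_steps >= 1, cube_um > 0)
  if (capture_radius_um >= cube_um / 10) {
    stop("capture_radius_um must be < cube_um / 10")
  }
  structure(list(n_synapses_stop = as.integer(n_synapses_stop),
                 cube_um = cube_um, capture_radius_um = capture_radius_um,
                 n_reps = as.integer(n_reps), step_um = step_um,
                 persistence_kappa = persistence_kappa,
                 max_steps = as.integer(max_steps), seed = as.integer(seed)),
            class = "walk_config")
}

#' Run the random-walk null model of synaptic target composition
#'
#' For each replicate the axon starts at a uniform random interior
#' point with a uniform random direction, steps with von Mises-Fisher
#' persistent turning, reflects at the cube faces, and consumes every
#' not-yet-consumed site within the capture radius of its new position
#' (nearest first) until \code{n_synapses_stop} synapses are scored.
#' Capture is class-blind; soma and spiny-shaft sites score as spiny,
#' only \code{shaft_smooth} sites score as smooth, mirroring the
#' experimental spiny/smooth dichotomy. The result of each replicate is
#' the proportion of smooth targets among its scored synapses.
#'
#' @param field a [make_neuropil_field()] result (data.frame with
#'   \code{x, y, z, class}); sites outside the cube are rejected.
#' @param cfg a [walk_config()].
#' @return object of class \code{walk_result}: list with
#'   \code{per_rep_smooth_fraction} (NA for truncated replicates that
#'   scored no synapse), \code{per_rep_synapses},
#'   \code{per_rep_smooth}, \code{per_rep_steps}, \code{truncated_reps}
#'   and the config.
#' @export
run_walk <- function(field, cfg) {
  stopifnot(inherits(cfg, "walk_config"))
  n <- nrow(field)
  L <- cfg$cube_um
  if (n > 0 && any(field$x < 0 | field$x > L | field$y < 0 | field$y > L |
                   field$z < 0 | field$z > L)) {
    stop("field contains sites outside the cube")
  }
  P <- cbind(field$x, field$y, field$z)
  smooth <- field$class == "shaft_smooth"

  # spatial hash: cubic cells of edge = capture radius; a capture sphere
  # around any position is covered by the 27 cells around its own cell
  cs <- cfg$capture_radius_um
  cells <- new.env(hash = TRUE, parent = emptyenv())
  nc2 <- ceiling(L / cs) + 2  # padded grid side, allows -1/+1 neighbours
  if (n > 0) {
    key <- cell_key(P, cs, nc2)
    list2env(split(seq_len(n), key), envir = cells)
  }
  noff <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  noff_lin <- noff[, 1] + noff[, 2] * nc2 + noff[, 3] * nc2 * nc2

  alive <- rep(TRUE, n)
  frac <- rep(NA_real_, cfg$n_reps)
  nsyn <- integer(cfg$n_reps)
  nsm <- integer(cfg$n_reps)
  steps <- integer(cfg$n_reps)
  truncated <- 0L

  r2 <- cs^2
  for (rep_i in seq_len(cfg$n_reps)) {
    res <- with_seed(child_seed(cfg$seed, paste0("walk_rep_", rep_i)), {
      pos <- stats::runif(3, 0, L)   # unfolded position; folded for lookup
      dir <- rand_unit3()
      consumed <- integer(0)
      got <- 0L; got_sm <- 0L; st <- 0L
      chunk <- 32L
      while (got < cfg$n_synapses_stop && st < cfg$max_steps) {
        S <- min(chunk, cfg$max_steps - st)
        # trajectory is independent of captures: generate S steps at once
        D <- matrix(0, S, 3)
        for (j in seq_len(S)) {
          dir <- vmf_turn(dir, cfg$persistence_kappa)
          D[j, ] <- dir
        }
        traj <- matrix(pos, S, 3, byrow = TRUE) +
          apply(D * cfg$step_um, 2, cumsum)
        if (S == 1L) traj <- matrix(pos + D[1, ] * cfg$step_um, 1, 3)
        pos <- traj[S, ]
        # reflect into the cube: triangular fold of each coordinate
        q <- traj %% (2 * L)
        Fp <- ifelse(q > L, 2 * L - q, q)
        if (n > 0L) {
          base <- floor(Fp / cs)
          lin <- (base[, 1] + 1) + (base[, 2] + 1) * nc2 +
                 (base[, 3] + 1) * nc2 * nc2
          keys <- as.character(rep(lin, times = 27L) +
                                 rep(noff_lin, each = S))
          cl <- mget(keys, envir = cells, ifnotfound = vector("list", 1L))
          len <- lengths(cl)
          if (any(len > 0L)) {
            cand <- unlist(cl, use.names = FALSE)
            step_of <- rep.int(rep(seq_len(S), times = 27L), len)
            keep <- alive[cand]
            cand <- cand[keep]; step_of <- step_of[keep]
            if (length(cand)) {
              d2 <- (P[cand, 1] - Fp[step_of, 1])^2 +
                    (P[cand, 2] - Fp[step_of, 2])^2 +
                    (P[cand, 3] - Fp[step_of, 3])^2
              sel <- d2 <= r2
              if (any(sel)) {
                cand <- cand[sel]; step_of <- step_of[sel]; d2 <- d2[sel]
                ord <- order(step_of, d2, cand)
                for (ii in ord) {
                  tg <- cand[ii]
                  if (!alive[tg]) next   # same target near several steps
                  alive[tg] <- FALSE
                  consumed <- c(consumed, tg)
                  got <- got + 1L
                  if (smooth[tg]) got_sm <- got_sm + 1L
                  if (got >= cfg$n_synapses_stop) {
                    # replicate ends mid-chunk: truncate the step count
                    st <- st + step_of[ii] - S
                    break
                  }
                }
              }
            }
          }
        }
        st <- st + S
        chunk <- min(1024L, chunk * 2L)
      }
      list(got = got, got_sm = got_sm, st = st, consumed = consumed)
    })
    alive[res$consumed] <- TRUE  # targets regenerate between replicates
    nsyn[rep_i] <- res$got
    nsm[rep_i] <- res$got_sm
    steps[rep_i] <- res$st
    if (res$got < cfg$n_synapses_stop) truncated <- truncated + 1L
    if (res$got > 0L) frac[rep_i] <- res$got_sm / res$got
  }
  structure(list(per_rep_smooth_fraction = frac,
                 per_rep_synapses = nsyn,
                 per_rep_smooth = nsm,
                 per_rep_steps = steps,
                 truncated_reps = truncated,
                 config = cfg),
            class = "walk_result")
}

# linearised cell hash keys for an n x 3 coordinate matrix on a padded
# grid of side nc2 cells
cell_key <- function(P, cs, nc2) {
  as.character((floor(P[, 1] / cs) + 1) + (floor(P[, 2] / cs) + 1) * nc2 +
                 (floor(P[, 3] / cs) + 1) * nc2 * nc2)
}

# uniform random unit 3-vector
rand_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    s <- sqrt(sum(v^2))
    if (s > 1e-12) return(v / s)
  }
}

# draw a direction from a von Mises-Fisher distribution with mean
# direction `mu` (unit 3-vector) and concentration `kappa` (Wood 1994)
vmf_turn <- function(mu, kappa) {
  if (kappa <= 0) return(rand_unit3())
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- min(1, max(-1, w))
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal basis perpendicular to mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(1 - w^2)
  w * mu + s * (cos(phi) * e1 + sin(phi) * e2)
}

#' Compare observed between-cluster variance with the walk null
#'
#' Tests whether the variance of observed per-cluster smooth-target
#' fractions is of the same magnitude as expected under the random-walk
#' null: the null distribution of the variance is built by repeatedly
#' drawing \code{length(observed)} replicate fractions from the
#' simulation without replacement and taking their variance; the
#' Monte Carlo p-value is two-sided (with add-one correction).
#'
#' @param observed numeric vector of per-cluster smooth fractions
#'   (length >= 2).
#' @param result a [run_walk()] result with >= 100 usable replicates.
#' @param n_null number of null resamples (default 2000).
#' @param seed integer seed for the resampling.
#' @return list with \code{observed_var}, \code{null_summary} (mean,
#'   sd, quantiles of the null variances), \code{mc_p}, \code{n_null}.
#' @export
variance_comparison <- function(observed, result, n_null = 2000, seed = 1L) {
  stopifnot(inherits(result, "walk_result"))
  k <- length(observed)
  if (k < 2L) stop("need at least 2 observed clusters")
  fr <- result$per_rep_smooth_fraction
  fr <- fr[!is.na(fr)]
  if (length(fr) < 100L) stop("need at least 100 usable replicates")
  if (length(fr) < k) stop("fewer usable replicates than observed clusters")
  obs_var <- stats::var(observed)
  null_var <- with_seed(child_seed(seed, "variance_null"), {
    vapply(seq_len(n_null),
           function(i) stats::var(fr[sample.int(length(fr), k)]),
           numeric(1))
  })
  p_le <- (1 + sum(null_var <= obs_var)) / (n_null + 1)
  p_ge <- (1 + sum(null_var >= obs_var)) / (n_null + 1)
  list(observed_var = obs_var,
       null_summary = c(mean = mean(null_var), sd = stats::sd(null_var),
                        stats::quantile(null_var, c(0.025, 0.5, 0.975))),
       mc_p = min(1, 2 * min(p_le, p_ge)),
       n_null = n_null)
}
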