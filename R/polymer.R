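## Kremer-Grest bead-spring chromosome model in reduced Lennard-Jones units:
## lengths in sigma (monomer diameter = 1 Mb of chromatin), energies in kBT,
## times in tau. Temperature is fixed at kBT = 1.

#' Bonded and nonbonded potentials (reduced units)
#'
#' `fene_energy(r) = -0.5 k R0^2 ln(1 - (r/R0)^2)` for r < R0 (divergence
#' error at r >= R0); `bend_energy(theta) = k_theta (1 - cos theta)` with
#' `theta` the angle between adjacent bond vectors (0 = straight);
#' `lj_energy(r, eps) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, zero at
#' r = sigma and minimal (-eps) at r = 2^(1/6) sigma;
#' `wca_energy` is the purely repulsive cut-and-shifted form truncated at
#' `2^(1/6) sigma`. Matching analytic force magnitudes (`-dU/dr`) are
#' provided as `*_force`.
#'
#' @param r separation, sigma units.
#' @param theta bond angle, radians.
#' @param eps pair interaction strength, kBT.
#' @param k,r0,k_theta,sigma potential parameters.
#' @return energy in kBT (or force in kBT/sigma).
#' @export
fene_energy <- function(r, k = 30, r0 = 1.5) {
  if (any(r <= 0)) stop("FENE requires r > 0", call. = FALSE)
  if (any(r >= r0))
    stop("FENE divergence: r >= R0 (bond overstretched)", call. = FALSE)
  -0.5 * k * r0^2 * log(1 - (r / r0)^2)
}

#' @rdname fene_energy
#' @export
fene_force <- function(r, k = 30, r0 = 1.5) {
  if (any(r >= r0))
    stop("FENE divergence: r >= R0 (bond overstretched)", call. = FALSE)
  -k * r / (1 - (r / r0)^2)
}

#' @rdname fene_energy
#' @export
bend_energy <- function(theta, k_theta = 1) k_theta * (1 - cos(theta))

#' @rdname fene_energy
#' @export
lj_energy <- function(r, eps, sigma = 1) {
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6)
}

#' @rdname fene_energy
#' @export
lj_force <- function(r, eps, sigma = 1) {
  sr6 <- (sigma / r)^6
  24 * eps * (2 * sr6^2 - sr6) / r
}

#' @rdname fene_energy
#' @export
wca_energy <- function(r, eps = 1, sigma = 1) {
  ifelse(r < 2^(1 / 6) * sigma, lj_energy(r, eps, sigma) + eps, 0)
}

#' Map a binned ChIP-like signal to per-monomer attraction strengths
#'
#' One signal value per monomer (1 Mb bin). The relative interaction
#' strengths between monomers equal the signal ratios exactly; the level
#' (E1..E4) sets only the absolute scale:
#' `eps_i = level_scale * signal_i / mean(signal[signal > 0])`. Zero-signal
#' bins give `eps_i = 0`, i.e. purely repulsive (unbound) monomers.
#'
#' @param signal numeric vector, or a `chrom/start/end/value` track
#'   data.frame from [gen_chip_track()] / [read_bedgraph()].
#' @param level `"E1"`, `"E2"`, `"E3"` or `"E4"` (low to very high).
#' @param scale_map named numeric: the absolute kBT scale per level.
#' @return list of class `epsilon_track`: `eps` (kBT per monomer), `bound`
#'   mask, `level`, `signal`.
#' @export
chip_to_epsilon <- function(signal, level = c("E1", "E2", "E3", "E4"),
                            scale_map = c(E1 = 0.5, E2 = 1.0, E3 = 1.5,
                                          E4 = 2.0)) {
  level <- match.arg(level)
  v <- if (is.data.frame(signal)) signal$value else as.numeric(signal)
  assert_that(all(v >= 0), "ChIP-like signal must be nonnegative")
  eps <- numeric(length(v))
  if (any(v > 0)) eps <- scale_map[[level]] * v / mean(v[v > 0])
  structure(list(eps = eps, bound = v > 0, level = level, signal = v),
            class = "epsilon_track")
}

#' Build a rigid confinement shell of static wall monomers
#'
#' The shell volume is fixed by the monomer volume fraction:
#' `V_shell = n_monomers * (pi/6) sigma^3 / phi`, and the semi-axes `(a, a, c)`
#' solve that volume at the shape's aspect ratio (`c/a` = 1, 0.5 or 1/3;
#' the oblate shapes keep the sphere's volume). Wall monomers (diameter
#' sigma, zero dynamics) are placed near-equidistantly on the surface by an
#' area-weighted Fibonacci lattice; the wall is checked for leaks (spacing
#' must not exceed sigma).
#'
#' @param shape `"sphere"`, `"oblate_0.5"` or `"oblate_0.33"`.
#' @param n_monomers number of mobile monomers the shell will hold.
#' @param phi target monomer volume fraction (0 < phi < 0.4).
#' @param n_wall wall monomer count; `NULL` auto-sizes to a surface density
#'   of at least 1.2 monomers per sigma^2 and a leak-free spacing.
#' @return list of class `shell_spec`: `shape`, `semi_axes` (a, b, c),
#'   `wall` (matrix of wall monomer coordinates), `phi`, `volume`,
#'   `n_monomers`, `max_spacing`.
#' @export
build_shell <- function(shape = c("sphere", "oblate_0.5", "oblate_0.33"),
                        n_monomers = 258L, phi = 0.10, n_wall = NULL) {
  shape <- match.arg(shape)
  assert_that(phi > 0 && phi < 0.4, "phi must lie in (0, 0.4)")
  q <- switch(shape, sphere = 1, oblate_0.5 = 0.5, oblate_0.33 = 1 / 3)
  V <- n_monomers * (pi / 6) / phi
  a <- (3 * V / (4 * pi * q))^(1 / 3)
  cc <- q * a
  # oblate spheroid surface area (analytic)
  area <- if (q == 1) 4 * pi * a^2 else {
    e <- sqrt(1 - q^2)
    2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
  }
  auto <- is.null(n_wall)
  n <- if (auto) ceiling(1.2 * area) else n_wall
  for (iter in 1:6) {
    wall <- fibonacci_spheroid(n, a, cc)
    spacing <- max_nn_spacing(wall)
    if (spacing <= 1) break
    if (!auto)
      stop("leaky wall: spacing ", signif(spacing, 3),
           " sigma > 1 sigma; increase n_wall", call. = FALSE)
    n <- ceiling(n * 1.3)
  }
  if (spacing > 1)
    stop("could not build a leak-free wall (spacing ", signif(spacing, 3),
         " sigma)", call. = FALSE)
  structure(list(shape = shape, semi_axes = c(a = a, b = a, c = cc),
                 wall = wall, phi = phi, volume = V,
                 n_monomers = n_monomers, max_spacing = spacing),
            class = "shell_spec")
}

# Fibonacci lattice on the unit sphere mapped to the spheroid surface.
fibonacci_spheroid <- function(n, a, c) {
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  th <- 2 * pi * i / golden
  cbind(x = a * r * cos(th), y = a * r * sin(th), z = c * z)
}

# Largest nearest-neighbor distance in a point set (leak check).
max_nn_spacing <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(Inf)
  worst <- 0
  # block-wise to bound memory
  bs <- 500L
  for (s in seq(1, n, by = bs)) {
    idx <- s:min(s + bs - 1, n)
    d2 <- outer(pts[idx, 1], pts[, 1], "-")^2 +
          outer(pts[idx, 2], pts[, 2], "-")^2 +
          outer(pts[idx, 3], pts[, 3], "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Initialize a confined polymer system
#'
#' Chains are grown as self-avoiding random walks (bond length 0.97 sigma,
#' no two monomers closer than 0.8 sigma) strictly inside the shell, then
#' relaxed by a short soft-potential push-off run so that dynamics can start
#' from an overlap-free state. Reproducible for a fixed seed.
#'
#' @param chain_lengths monomers per chain; must sum to `length(eps$eps)`.
#' @param eps an `epsilon_track`.
#' @param shell a `shell_spec`.
#' @param seed RNG seed.
#' @param pushoff_steps soft push-off steps (two amplitude stages).
#' @return list of class `polymer_system`: positions, velocities, eps,
#'   chain_lengths, shell, seed.
#' @export
init_system <- function(chain_lengths, eps, shell, seed = 1L,
                        pushoff_steps = 2000L) {
  stopifnot(inherits(eps, "epsilon_track"), inherits(shell, "shell_spec"))
  assert_that(sum(chain_lengths) == length(eps$eps),
              "chain lengths must sum to the epsilon track length")
  ax <- shell$semi_axes
  eff <- pmax(ax - 1, 0.5)  # monomer centers stay ~1 sigma off wall centers
  inside <- function(p) sum((p / eff)^2) < 1
  n_tot <- sum(chain_lengths)
  pos <- matrix(NA_real_, n_tot, 3)
  with_seed(seed, {
    at <- 0L
    for (len in chain_lengths) {
      for (restart in 1:50) {
        ok <- TRUE
        # chain start
        repeat {
          p <- (runif(3) * 2 - 1) * eff
          if (inside(p)) break
        }
        pos[at + 1L, ] <- p
        if (len > 1) for (k in 2:len) {
          placed <- FALSE
          for (try in 1:200) {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
            p <- pos[at + k - 1L, ] + 0.97 * u
            if (!inside(p)) next
            prev <- pos[seq_len(at + k - 2L), , drop = FALSE]
            if (nrow(prev) > 0) {
              d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 +
                (prev[, 3] - p[3])^2
              if (min(d2) < 0.8^2) next
            }
            pos[at + k, ] <- p
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok)
        stop("self-avoiding growth failed; the shell is too crowded ",
             "(consider a lower phi)", call. = FALSE)
      at <- at + len
    }
  })
  vel <- with_seed(derive_seed(seed, 2),
                   matrix(rnorm(3 * n_tot), n_tot, 3))
  sys <- structure(list(positions = pos, velocities = vel, eps = eps,
                        chain_lengths = as.integer(chain_lengths),
                        shell = shell, seed = as.integer(seed)),
                   class = "polymer_system")
  if (pushoff_steps > 0) {
    for (stage in c(10, 60)) {
      res <- cpp_run_langevin(sys$positions, sys$velocities, sys$eps$eps,
                              sys$chain_lengths, sys$shell$wall,
                              sys$shell$semi_axes,
                              30, 1.5, 1, 2.5, 0.005, 1, 1,
                              as.integer(pushoff_steps / 2), 0L,
                              derive_seed(seed, 3 + stage), TRUE, stage)
      sys$positions <- res$positions
      sys$velocities <- res$velocities
    }
  }
  sys
}

#' Run Langevin dynamics on a polymer system
#'
#' BAOAB-splitting Langevin integration at kBT = 1 with friction `gamma`
#' (1/tau) and time step `dt` (tau). Forces: FENE + WCA bonds, bending
#' penalty, Lennard-Jones pairs (attractive with geometric-mean
#' `eps_ij = sqrt(eps_i eps_j)` truncated at `lj_cut` for bound-bound pairs;
#' purely repulsive WCA otherwise and against the static wall monomers).
#' Frames are sampled every `sample_every` steps with energy and constraint
#' diagnostics (shell violations, bond statistics). Bit-identical for a
#' fixed seed.
#'
#' @param system a `polymer_system`.
#' @param n_steps integration steps.
#' @param dt time step, tau.
#' @param gamma friction, 1/tau.
#' @param sample_every sampling stride (0 = no frames).
#' @param lj_cut attractive LJ cutoff, sigma.
#' @param seed RNG seed (defaults to the system seed).
#' @return list of class `polymer_trajectory`: `frames` (n x 3 x n_frames),
#'   energies, `mean_bond`, `mean_cos`, `max_shell`, `n_outside`, and the
#'   advanced `system`.
#' @export
run_langevin <- function(system, n_steps, dt = 0.01, gamma = 1,
                         sample_every = 1000L, lj_cut = 2.5, seed = NULL) {
  stopifnot(inherits(system, "polymer_system"))
  seed <- seed %||% derive_seed(system$seed, 101)
  res <- cpp_run_langevin(system$positions, system$velocities,
                          system$eps$eps, system$chain_lengths,
                          system$shell$wall, system$shell$semi_axes,
                          30, 1.5, 1, lj_cut, dt, gamma, 1,
                          as.integer(n_steps), as.integer(sample_every),
                          seed, FALSE, 0)
  system$positions <- res$positions
  system$velocities <- res$velocities
  structure(list(frames = res$frames, e_bond = res$e_bond,
                 e_angle = res$e_angle, e_pair = res$e_pair,
                 mean_bond = res$mean_bond, mean_cos = res$mean_cos,
                 max_shell = res$max_shell, n_outside = res$n_outside,
                 dt = dt, sample_every = sample_every, system = system),
            class = "polymer_trajectory")
}

#' Chain statistics from a trajectory
#'
#' Mean bond length, mean cosine of the bond angle, the worm-like-chain Kuhn
#' length estimate `l_k = l_b (1 + <cos theta>) / (1 - <cos theta>)`, and the
#' achieved monomer volume fraction.
#'
#' @param traj a `polymer_trajectory` (>= 10 sampled frames required).
#' @param discard_fraction leading fraction of frames dropped as
#'   equilibration.
#' @return list: `bond_mean`, `cos_mean`, `kuhn_length`, `phi`, `n_frames`.
#' @export
chain_diagnostics <- function(traj, discard_fraction = 0) {
  stopifnot(inherits(traj, "polymer_trajectory"))
  nf <- length(traj$mean_bond)
  assert_that(nf >= 10, "need at least 10 sampled frames")
  use <- seq(floor(discard_fraction * nf) + 1, nf)
  lb <- mean(traj$mean_bond[use])
  cm <- mean(traj$mean_cos[use])
  shell <- traj$system$shell
  list(bond_mean = lb, cos_mean = cm,
       kuhn_length = lb * (1 + cm) / (1 - cm),
       phi = traj$system$shell$n_monomers * (pi / 6) / shell$volume,
       n_frames = length(use))
}

#' Write a trajectory in XYZ format (sigma units)
#'
#' One block per sampled frame: monomer count, comment line, then
#' `id x y z` rows.
#'
#' @param traj a `polymer_trajectory`.
#' @param path output path.
#' @export
write_xyz <- function(traj, path) {
  fr <- traj$frames
  stopifnot(length(dim(fr)) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(fr)[1]
  for (f in seq_len(dim(fr)[3])) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    writeLines(sprintf("%d %.8g %.8g %.8g", seq_len(n),
                       fr[, 1, f], fr[, 2, f], fr[, 3, f]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file path.
#' @return array n x 3 x n_frames.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    m <- do.call(rbind, lapply(strsplit(block, " +"), function(p)
      as.numeric(p[2:4])))
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  arr <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  arr
}
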