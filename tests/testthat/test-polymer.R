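test_that("ChIP signal maps to epsilon preserving ratios exactly", {
  et <- chip_to_epsilon(c(2, 4, 0), level = "E2")
  expect_equal(et$eps[1] / et$eps[2], 0.5)
  expect_equal(et$eps[3], 0)
  expect_equal(et$bound, c(TRUE, TRUE, FALSE))
  # constant positive signal -> uniform eps at the level scale
  eu <- chip_to_epsilon(rep(3, 5), level = "E3")
  expect_equal(eu$eps, rep(1.5, 5))
  # E4 is exactly 4x E1 under the default map
  e1 <- chip_to_epsilon(c(1, 2, 0, 5), "E1")
  e4 <- chip_to_epsilon(c(1, 2, 0, 5), "E4")
  expect_equal(e4$eps, 4 * e1$eps)
  expect_error(chip_to_epsilon(c(1, -2)), "nonnegative")
})

test_that("shell sizing solves the volume-fraction equation", {
  sh <- build_shell("sphere", 258L, 0.10)
  r_analytic <- (3 * 258 * (pi / 6) / (4 * pi * 0.1))^(1 / 3)
  expect_equal(unname(sh$semi_axes[["a"]]), r_analytic, tolerance = 1e-12)
  expect_equal(unname(sh$semi_axes[["a"]]), 6.86, tolerance = 0.01)
  expect_equal(258 * (pi / 6) / sh$volume, 0.10, tolerance = 1e-12)
  # oblate 0.5 holds the same volume: (4/3) pi a^2 c = V, c = a/2
  sh2 <- build_shell("oblate_0.5", 258L, 0.10)
  expect_equal(sh2$volume, sh$volume)
  expect_equal(unname(sh2$semi_axes[["a"]]), 8.64, tolerance = 0.01)
  expect_equal(unname(sh2$semi_axes[["c"]]), 4.32, tolerance = 0.01)
  sh3 <- build_shell("oblate_0.33")
  expect_equal(unname(sh3$semi_axes[["c"]] / sh3$semi_axes[["a"]]), 1 / 3,
               tolerance = 1e-12)
  expect_error(build_shell("sphere", phi = 0.6), "phi")
  expect_error(build_shell("banana"), "arg")
})

test_that("walls are dense, leak-checked, and on the surface", {
  sh <- build_shell("sphere", 258L, 0.10)
  expect_gte(nrow(sh$wall), 1.2 * 4 * pi * sh$semi_axes[["a"]]^2 - 1)
  expect_lte(sh$max_spacing, 1)
  r <- sqrt(rowSums(sh$wall^2))
  expect_lt(max(abs(r - sh$semi_axes[["a"]])), 1e-9)
  # undersized explicit wall errors
  expect_error(build_shell("sphere", n_wall = 50L), "leaky|n_wall")
})

test_that("potentials evaluate to the printed formulas", {
  expect_equal(fene_energy(1.0), -0.5 * 30 * 1.5^2 * log(1 - (1 / 1.5)^2))
  expect_equal(fene_energy(1.0), 19.84, tolerance = 0.005)
  expect_error(fene_energy(1.5), "divergence")
  expect_error(fene_energy(-1), "r > 0")
  expect_equal(bend_energy(0), 0)
  expect_equal(bend_energy(pi / 2), 1)
  expect_equal(lj_energy(1, 2.5), 0)
  expect_equal(lj_energy(2^(1 / 6), 2.5), -2.5)
  # force is -dU/dr (numeric derivative check) and zero at the LJ minimum
  h <- 1e-6
  expect_equal(fene_force(1), -(fene_energy(1 + h) - fene_energy(1 - h)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(lj_force(2^(1 / 6), 1), 0, tolerance = 1e-12)
  expect_equal(lj_force(1.1, 0.7),
               -(lj_energy(1.1 + h, 0.7) - lj_energy(1.1 - h, 0.7)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(wca_energy(2), 0)
  expect_equal(wca_energy(2^(1 / 6) - 1e-9), 0, tolerance = 1e-6)
})

test_that("initialization produces valid bonded chains inside the shell", {
  sh <- build_shell("sphere", 100L, 0.10)
  et <- chip_to_epsilon(rep(1, 100), "E1")
  sys <- init_system(c(60L, 40L), et, sh, seed = 5)
  # bonds within (0.8, 1.2) sigma after push-off
  for (b in list(1:59, 61:99)) {
    d <- sqrt(rowSums((sys$positions[b + 1L, ] - sys$positions[b, ])^2))
    expect_true(all(d > 0.8 & d < 1.2))
  }
  # all monomers strictly inside the shell
  u <- rowSums(sweep(sys$positions, 2, sh$semi_axes, "/")^2)
  expect_true(all(u < 1))
  # same seed reproduces coordinates exactly
  sys2 <- init_system(c(60L, 40L), et, sh, seed = 5)
  expect_identical(sys$positions, sys2$positions)
  expect_error(init_system(c(60L, 50L), et, sh), "sum")
})

test_that("free-chain statistics match the FENE+WCA and bending oracles", {
  # ideal chain, no confinement: mean bond length ~ 1D minimum of the
  # FENE+WCA bond potential; <cos theta> ~ Boltzmann average coth(1) - 1
  # (local angles are free of excluded volume by construction)
  et <- chip_to_epsilon(rep(0, 60), "E1")
  sh <- build_shell("sphere", 60L, 0.10)
  pos <- cbind(cumsum(rep(0.97, 60)) - 30 * 0.97, 0, 0)
  sys <- structure(list(positions = pos,
                        velocities = matrix(0, 60, 3),
                        eps = et, chain_lengths = 60L, shell = sh,
                        seed = 1L),
                   class = "polymer_system")
  sys$shell$wall <- matrix(numeric(0), 0, 3)  # no confinement
  traj <- run_langevin(sys, 60000, sample_every = 500, seed = 99)
  use <- 40:120
  bond_min <- optimize(function(r) fene_energy(r) + wca_energy(r),
                       c(0.5, 1.2))$minimum
  expect_equal(mean(traj$mean_bond[use]), bond_min, tolerance = 0.03)
  cos_oracle <- 1 / tanh(1) - 1            # 0.3130
  # residual distal excluded volume biases <cos> up by ~0.04 (vignette)
  expect_lt(abs(mean(traj$mean_cos[use]) - cos_oracle), 0.07)
})

test_that("rigid confinement keeps every monomer inside at every frame", {
  sh <- build_shell("oblate_0.5", 80L, 0.10)
  et <- chip_to_epsilon(rep(c(1, 0), 40), "E4")
  sys <- init_system(c(80L), et, sh, seed = 3)
  traj <- run_langevin(sys, 20000, sample_every = 1000)
  expect_true(all(traj$n_outside == 0))
  expect_true(all(traj$max_shell < 1))
})

test_that("trajectories are bit-identical for a fixed seed", {
  sh <- build_shell("sphere", 40L, 0.10)
  et <- chip_to_epsilon(rep(1, 40), "E2")
  sys <- init_system(c(40L), et, sh, seed = 8)
  t1 <- run_langevin(sys, 2000, sample_every = 500, seed = 123)
  t2 <- run_langevin(sys, 2000, sample_every = 500, seed = 123)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_langevin(sys, 2000, sample_every = 500, seed = 124)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("attraction strength increases the largest contact cluster", {
  # contact clusters: single-linkage components at a fixed 1.5 sigma cut
  sh <- build_shell("sphere", 120L, 0.10)
  sig <- rep(c(1, 0), 60)
  biggest <- vapply(c("E1", "E4"), function(lv) {
    sizes <- c()
    for (s in 1:2) {
      et <- chip_to_epsilon(sig, lv)
      sys <- init_system(c(120L), et, sh, seed = s)
      traj <- run_langevin(sys, 30000, sample_every = 10000)
      pos <- traj$frames[et$eps > 0, , 3]
      comp <- cutree(hclust(dist(pos), method = "single"), h = 1.5)
      sizes <- c(sizes, max(tabulate(comp)))
    }
    mean(sizes)
  }, 1)
  expect_gt(biggest[["E4"]], biggest[["E1"]])
})

test_that("chain diagnostics compute the worm-like-chain mapping", {
  sh <- build_shell("sphere", 50L, 0.10)
  et <- chip_to_epsilon(rep(0, 50), "E1")
  sys <- init_system(c(50L), et, sh, seed = 2)
  traj <- run_langevin(sys, 12000, sample_every = 1000)
  di <- chain_diagnostics(traj)
  expect_equal(di$kuhn_length,
               di$bond_mean * (1 + di$cos_mean) / (1 - di$cos_mean))
  expect_equal(di$phi, 0.10, tolerance = 1e-12)
  short <- run_langevin(sys, 3000, sample_every = 1000)
  expect_error(chain_diagnostics(short), "10")
})

test_that("XYZ trajectories round-trip", {
  sh <- build_shell("sphere", 20L, 0.10)
  et <- chip_to_epsilon(rep(1, 20), "E1")
  sys <- init_system(c(20L), et, sh, seed = 1)
  traj <- run_langevin(sys, 2000, sample_every = 1000)
  path <- tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  back <- read_xyz(path)
  expect_equal(back, unclass(traj$frames), tolerance = 1e-7,
               ignore_attr = TRUE)
})
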