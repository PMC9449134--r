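test_that("spheroid seeding fills the integer ball and splits clones by ratio", {
  set.seed(1)
  st <- initialize_spheroid(simulation_config(lattice_edge = 31,
                                              seeding_ratio = 1))
  expect_equal(sum(st$counts), 515)        # integer points with x^2+y^2+z^2 <= 25
  expect_equal(st$counts[["B"]], 0)
  expect_equal(st$time, 0)
  # occupancy tallies match counts and the ball is centred
  idx <- which(st$occupancy == 1, arr.ind = TRUE)
  c0 <- floor(31 / 2) + 1
  d2 <- rowSums((idx - c0)^2)
  expect_true(all(d2 <= 25))
  expect_equal(max(d2), 25)

  st0 <- initialize_spheroid(simulation_config(lattice_edge = 31,
                                               seed_radius = 0))
  expect_equal(sum(st0$counts), 1)
  expect_equal(st0$occupancy[c0, c0, c0], 1L)

  st5 <- initialize_spheroid(simulation_config(lattice_edge = 31,
                                               seeding_ratio = 0.5))
  expect_equal(sum(st5$counts), 515)
  expect_gt(st5$counts[["A"]], 0)
  expect_gt(st5$counts[["B"]], 0)

  # ball touching the frame is a configuration error
  expect_error(initialize_spheroid(simulation_config(lattice_edge = 11,
                                                     seed_radius = 5)),
               "configuration error")
})

test_that("effective motility follows M_i = m_i + r_j * I_ij with clamping", {
  mod <- interaction_model(matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(effective_motility("A", 1, c(0.5, 0.5), mod), 2)
  # mono-culture: other proportion 0 returns the base rate
  expect_equal(effective_motility("A", 1, c(1, 0), mod), 1)
  # zero interaction is the identity
  expect_equal(effective_motility("B", 3.7, c(0.4, 0.6),
                                  interaction_model()), 3.7)
  neg <- interaction_model(matrix(c(0, -20, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(effective_motility("A", 1, c(0.5, 0.5), neg), 0)
  expect_error(effective_motility("A", -1, c(1, 0), mod), "non-negative")
})

test_that("propensity enumeration gives the SSA total rate", {
  st <- state_from_sites(15, c(8, 8, 8))
  tab <- enumerate_propensities(st, phenotype_params(1, 5))
  expect_equal(attr(tab, "total_rate"), 6.1)     # 1.0 + 5.0 + 0.1
  expect_equal(sort(unique(tab$process)), c("death", "division", "movement"))

  empty <- state_from_sites(15, matrix(numeric(0), ncol = 3))
  expect_equal(attr(enumerate_propensities(empty, phenotype_params(1, 5)),
                    "total_rate"), 0)

  # two-cell co-culture: totals follow the analytic table
  st2 <- state_from_sites(15, rbind(c(3, 3, 3), c(12, 12, 12)), c(1L, 2L))
  tab2 <- enumerate_propensities(st2, list(phenotype_params(1, 0),
                                           phenotype_params(2, 0)))
  expect_equal(attr(tab2, "total_rate"), 3.3)   # 1.1 + 2.2
  expect_equal(tab2$rate_total[tab2$clone == "A" & tab2$process == "division"],
               1.0)
  tab3 <- enumerate_propensities(st2, list(phenotype_params(1, 1),
                                           phenotype_params(2, 0)))
  expect_equal(attr(tab3, "total_rate"), 4.3)
})

test_that("movement relocates one step into the Moore neighbourhood, uniformly", {
  L <- 9; c0 <- 5
  st <- state_from_sites(L, c(c0, c0, c0))
  set.seed(7)
  out <- execute_move(st, c(c0, c0, c0))
  expect_true(attr(out, "success"))
  expect_equal(sum(out$counts), 1)
  new <- which(out$occupancy == 1, arr.ind = TRUE)
  expect_equal(max(abs(new - c0)), 1)     # Chebyshev distance 1

  # fully enclosed cell cannot move: null event
  shell <- as.matrix(expand.grid(x = (c0 - 1):(c0 + 1), y = (c0 - 1):(c0 + 1),
                                 z = (c0 - 1):(c0 + 1)))
  stb <- state_from_sites(L, shell)
  outb <- execute_move(stb, c(c0, c0, c0))
  expect_false(attr(outb, "success"))
  expect_identical(outb$occupancy, stb$occupancy)

  # uniformity over the 26 targets, 26 000 seeded single moves
  set.seed(11)
  dest <- integer(26000)
  for (i in 1:26000) {
    o <- execute_move(st, c(c0, c0, c0))
    dest[i] <- which(o$occupancy == 1)
  }
  tab <- table(dest)
  expect_equal(length(tab), 26)
  expected <- 26000 / 26
  sigma <- sqrt(26000 * (1 / 26) * (25 / 26))
  expect_true(all(abs(tab - expected) <= 3 * sigma))
})

test_that("division places a daughter or pushes a run of cells along a ray", {
  L <- 9; c0 <- 5
  st <- state_from_sites(L, c(c0, c0, c0))
  set.seed(3)
  out <- execute_division(st, c(c0, c0, c0))
  expect_true(attr(out, "success"))
  expect_equal(out$counts[["A"]], 2)
  pts <- which(out$occupancy == 1, arr.ind = TRUE)
  expect_true(all(abs(pts - c0) <= 1))

  # full Moore shell, aggression 1: blocked, count unchanged
  cube <- as.matrix(expand.grid(x = (c0 - 1):(c0 + 1), y = (c0 - 1):(c0 + 1),
                                z = (c0 - 1):(c0 + 1)))
  stb <- state_from_sites(L, cube)
  outb <- execute_division(stb, c(c0, c0, c0), aggression = 1)
  expect_false(attr(outb, "success"))
  expect_identical(outb$occupancy, stb$occupancy)

  # aggression push: centre enclosed to Chebyshev radius 3 except one site
  # on the +x ray; labels along the ray must shift outward in order
  L2 <- 17; cc <- 9
  cube3 <- as.matrix(expand.grid(x = (cc - 3):(cc + 3), y = (cc - 3):(cc + 3),
                                 z = (cc - 3):(cc + 3)))
  occ <- array(0L, dim = c(L2, L2, L2))
  occ[cube3] <- 1L
  occ[cc + 3, cc, cc] <- 0L                       # the only reachable hole
  occ[cc + 1, cc, cc] <- 2L                       # distinct labels on the ray
  occ[cc + 2, cc, cc] <- 1L
  stp <- spheroidABC:::new_lattice_state(occ)
  n_before <- sum(stp$counts)
  set.seed(5)
  outp <- execute_division(stp, c(cc, cc, cc), aggression = 3)
  expect_true(attr(outp, "success"))
  expect_equal(sum(outp$counts), n_before + 1)
  # run shifted outward by one: old labels at +1,+2 now at +2,+3
  expect_equal(outp$occupancy[cc + 3, cc, cc], 1L)
  expect_equal(outp$occupancy[cc + 2, cc, cc], 2L)
  # daughter of the dividing clone fills the vacated neighbour
  expect_equal(outp$occupancy[cc + 1, cc, cc], 1L)
  expect_equal(outp$counts[["A"]], stp$counts[["A"]] + 1)
  expect_equal(outp$counts[["B"]], stp$counts[["B"]])
})

test_that("death vacates the site immediately", {
  st <- state_from_sites(9, c(5, 5, 5))
  out <- execute_death(st, c(5, 5, 5))
  expect_equal(sum(out$counts), 0)
  expect_equal(attr(enumerate_propensities(out, phenotype_params(1, 5)),
                    "total_rate"), 0)

  cube <- as.matrix(expand.grid(x = 4:6, y = 4:6, z = 4:6))
  stf <- state_from_sites(9, cube)
  outf <- execute_death(stf, c(5, 5, 5))
  expect_equal(sum(outf$occupancy == 0) - sum(stf$occupancy == 0), 1)
})

test_that("advance respects time bounds and conserves counts event by event", {
  st <- state_from_sites(15, c(8, 8, 8))
  ph <- phenotype_params(1, 5)
  set.seed(2)
  same <- advance(st, ph, until = st$time)
  expect_identical(same$occupancy, st$occupancy)

  # conservation: final count = initial + realized divisions - deaths
  for (seed in 1:5) {
    set.seed(seed)
    st0 <- initialize_spheroid(simulation_config(lattice_edge = 30,
                                                 seed_radius = 3))
    out <- advance(st0, phenotype_params(1.5, 3), until = 1.5)
    tl <- attr(out, "tally")
    expect_equal(sum(out$counts),
                 sum(st0$counts) + tl$divisions_realized - tl$deaths)
    idx_counts <- c(sum(out$occupancy == 1L), sum(out$occupancy == 2L))
    expect_equal(unname(out$counts), idx_counts)
  }
})

test_that("identical seeds give bit-identical snapshot stacks", {
  cfg <- simulation_config(lattice_edge = 36, end_time = 2, rng_seed = 99,
                           seeding_ratio = 0.5)
  pars <- list(phenotype_params(0.8, 2), phenotype_params(0.5, 4))
  s1 <- run_simulation(cfg, pars)
  s2 <- run_simulation(cfg, pars)
  expect_identical(lapply(s1, identity), lapply(s2, identity))
})

test_that("2D collapse marks a pixel iff some z-column holds that clone", {
  st <- state_from_sites(12, c(3, 4, 7))
  m <- collapse_to_2d(st)
  expect_equal(sum(m$A), 1)
  expect_equal(m$A[3, 4], 1L)

  st2 <- state_from_sites(12, rbind(c(3, 4, 2), c(3, 4, 9)))
  expect_equal(sum(collapse_to_2d(st2)$A), 1)

  # random sparse occupancy vs. brute-force projection oracle
  set.seed(21)
  sites <- unique(cbind(sample(12, 60, TRUE), sample(12, 60, TRUE),
                        sample(12, 60, TRUE)))
  st3 <- state_from_sites(12, sites)
  mask <- collapse_to_2d(st3)$A
  oracle <- matrix(0L, 12, 12)
  for (i in seq_len(nrow(sites))) oracle[sites[i, 1], sites[i, 2]] <- 1L
  expect_identical(mask, oracle)
})

test_that("simulation snapshots follow the configured schedule", {
  cfg <- simulation_config(lattice_edge = 30, end_time = 3,
                           snapshot_interval = 1, rng_seed = 4)
  snaps <- run_simulation(cfg, phenotype_params(0.5, 1))
  expect_length(snaps, 4)
  expect_equal(vapply(snaps, `[[`, numeric(1), "time"), 0:3)

  # inert phenotype: death is 10% of a zero division rate, so nothing moves
  frozen <- run_simulation(cfg, phenotype_params(0, 0))
  expect_identical(frozen[[1]]$masks, frozen[[4]]$masks)
  expect_equal(frozen[[4]]$counts[["A"]], 515)

  # net growth: birth exceeds death by construction
  finals <- vapply(1:10, function(s) {
    cfgs <- simulation_config(lattice_edge = 30, end_time = 3, rng_seed = s)
    sum(run_simulation(cfgs, phenotype_params(1, 0))[[4]]$counts)
  }, numeric(1))
  expect_gt(mean(finals), 515)
})

test_that("frame contact warns and a full lattice aborts with a diagnostic", {
  cfg <- simulation_config(lattice_edge = 14, seed_radius = 5, end_time = 2,
                           rng_seed = 8)
  expect_warning(run_simulation(cfg, phenotype_params(0.5, 20)),
                 "lattice frame")
  cfg2 <- simulation_config(lattice_edge = 13, seed_radius = 5, end_time = 30,
                            rng_seed = 8)
  expect_error(
    suppressWarnings(run_simulation(cfg2, phenotype_params(5, 0,
                                                           aggression = 6))),
    "overflow")
})

test_that("zero interaction leaves co-culture dynamics indistinguishable from mono-culture", {
  # same rates for both clones, I = 0: the total population of a 50:50
  # co-culture must match the mono-culture law (KS over replicates)
  tot <- function(ratio, seed) {
    cfg <- simulation_config(lattice_edge = 36, end_time = 2,
                             seeding_ratio = ratio, rng_seed = seed)
    pars <- list(phenotype_params(1, 3), phenotype_params(1, 3))
    sum(run_simulation(cfg, pars)[[3]]$counts)
  }
  co <- vapply(1:12, function(s) tot(0.5, 1000 + s), numeric(1))
  mono <- vapply(1:12, function(s) tot(1, 2000 + s), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(co, mono))$p.value, 0.01)
})

test_that("local interaction neighbourhoods reduce to proportions around each cell", {
  # two cells of different clones adjacent, third far away: radius-2
  # neighbourhood of the first sees only the neighbour
  st <- state_from_sites(15, rbind(c(5, 5, 5), c(6, 5, 5), c(13, 13, 13)),
                         c(1L, 2L, 1L))
  lp <- spheroidABC:::cpp_local_proportions(st$occupancy, 15,
                                            spheroidABC:::site_linear0(st, c(5, 5, 5)), 2)
  expect_true(lp$any_neighbours)
  expect_equal(lp$proportions, c(0, 1))
  # a local-neighbourhood simulation runs and conserves cells
  set.seed(31)
  st2 <- initialize_spheroid(simulation_config(lattice_edge = 24,
                                               seed_radius = 3,
                                               seeding_ratio = 0.5))
  mod <- interaction_model(matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE),
                           neighborhood = 2)
  out <- advance(st2, list(phenotype_params(0.5, 1), phenotype_params(0.5, 1)),
                 mod, until = 0.5)
  tl <- attr(out, "tally")
  expect_equal(sum(out$counts),
               sum(st2$counts) + tl$divisions_realized - tl$deaths)
})
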