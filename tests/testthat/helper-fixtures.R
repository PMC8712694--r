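# Shared fixtures, built once per test run and cached. Everything is
# generated in code; the synthetic generator's presets define the study
# conditions (200 frames, ~5,500 atoms, seeded).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fx_model <- function() cached("model", function() build_hexamer())

fx_regions <- function() cached("regions", function()
  define_regions(fx_model(), fx_model()$topology))

# Full-scale scripted opening run, noiseless, with water.
fx_open_run <- function() cached("open_run", function() {
  m <- fx_model()
  sc <- preset_gating_script("open", n_frames = 200L, noise_sigma = 0,
                             seed = 1L)
  w <- populate_water(fx_regions(), 200L,
                      bubble_interval = sc$bubble_interval, seed = 2L)
  run <- script_gating_trajectory(m, sc, waters = w)
  run$script <- sc
  run
})

# Same script with per-atom jitter (sigma = 0.3 A), protein only.
fx_noisy_run <- function() cached("noisy_run", function() {
  m <- fx_model()
  sc <- preset_gating_script("open", n_frames = 200L, noise_sigma = 0.3,
                             seed = 1L)
  run <- script_gating_trajectory(m, sc)
  run$script <- sc
  run
})

# Short noiseless run without water, for geometry-only checks.
fx_short_run <- function() cached("short_run", function() {
  sc <- preset_gating_script("open", n_frames = 40L, noise_sigma = 0,
                             seed = 1L)
  run <- script_gating_trajectory(fx_model(), sc)
  run$script <- sc
  run
})

# A ring of n carbon atoms at distance `ring_r` from (cx, cy), at height z.
ring_structure <- function(n = 6L, ring_r = 5.0, z = 0, cx = 0, cy = 0,
                           vdw_elem = "C") {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  xyz <- cbind(cx + ring_r * cos(th), cy + ring_r * sin(th), rep(z, n))
  atoms <- atom_table(seq_len(n), rep("CA", n), rep("ALA", n), seq_len(n),
                      rep("A", n), element = rep(vdw_elem, n))
  channel_structure(atoms, xyz)
}

# Uniform-density water-only trajectory in a cylinder (radius R, z0..z1).
uniform_water_traj <- function(n_waters = 400L, n_frames = 50L, R = 6,
                               z0 = 0, z1 = 30, seed = 11L) {
  co <- withr::with_seed(seed, {
    a <- array(0, c(n_waters, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      r <- sqrt(stats::runif(n_waters)) * R
      th <- stats::runif(n_waters, 0, 2 * pi)
      a[, , f] <- cbind(r * cos(th), r * sin(th),
                        stats::runif(n_waters, z0, z1))
    }
    a
  })
  atoms <- atom_table(seq_len(n_waters), rep("OH2", n_waters),
                      rep("HOH", n_waters), seq_len(n_waters),
                      rep("W", n_waters), element = rep("O", n_waters))
  pore_trajectory(atoms, co, 0.1)
}

kB_T300 <- 0.0019872 * 300
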