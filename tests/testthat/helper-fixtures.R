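# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# perfect annulus mask: ring of radius r, tube half-width hw, in a sq frame
annulus_mask <- function(r = 10, hw = 3, side = 4 * r + 2 * hw + 8) {
  c0 <- (side + 1) / 2
  xs <- matrix(seq_len(side), side, side, byrow = TRUE)
  ys <- matrix(seq_len(side), side, side)
  abs(sqrt((xs - c0)^2 + (ys - c0)^2) - r) <= hw
}

# horizontal bar mask: length n px, thickness 1 px
bar_mask <- function(n = 10, side = n + 20) {
  m <- matrix(FALSE, side, side)
  m[side %/% 2, 10 + seq_len(n)] <- TRUE
  m
}

# noiseless, unblurred wildtype-like cell (exact truths)
cell_noiseless <- function() fixture("cell_noiseless", function()
  render_cell(strain_preset("wildtype", noise_model = "none",
                            psf_sigma_um = 0, dna_arm_bias = 0)))

# blurred + noisy wildtype-like cell
cell_noisy <- function() fixture("cell_noisy", function()
  render_cell(strain_preset("wildtype", noise_model = "poisson+gaussian",
                            dna_arm_bias = 0, seed = 42L)))

# figure-eight dimer, light noise
cell_fig8 <- function() fixture("cell_fig8", function()
  render_cell(strain_preset("mukB_del_dimer", noise_model = "poisson",
                            seed = 7L)))

# 50-cell noisy wildtype population, analyzed once
population50 <- function() fixture("population50", function() {
  pop <- render_population(
    rep(list(strain_preset("wildtype", noise_model = "poisson+gaussian")), 50),
    layout = "grid", seed = 11L)
  list(pop = pop,
       results = analyze_stack(pop$stack, strain_label = "wildtype"))
})

# match analyzed rows to ground truths by cell position (segmentation label
# order need not follow the generator's cell order)
match_truth_rows <- function(res, truths) {
  ctrs <- t(vapply(truths, function(t) t$cell_center_px, numeric(2)))
  vapply(seq_len(nrow(res)), function(i) {
    which.min((ctrs[, 1] - res$com_x[i])^2 + (ctrs[, 2] - res$com_y[i])^2)
  }, integer(1))
}

# cell mask covering the rendered cell footprint (from ground truth)
truth_cell_mask <- function(rc) {
  d <- dim(rc$stack$channels$dna)[1:2]
  disk <- function(cx, cy, r) {
    xs <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    ys <- matrix(seq_len(d[1]), d[1], d[2])
    (xs - cx)^2 + (ys - cy)^2 <= r^2
  }
  disk(rc$truth$cell_center_px[1], rc$truth$cell_center_px[2],
       rc$truth$cell_radius_px)
}
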