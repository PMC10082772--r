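# Shared fixtures. The desk-profile fit is expensive (minutes), so it is
# trained once per test run and cached for every test that needs it.

.cache <- new.env(parent = emptyenv())

# Small phantom for fast unit tests.
tiny_phantom_spec <- function(...) {
  phantom_spec(rows = 96, cols = 96, n_layers = 3, seed = 7, ...)
}

desk_dataset <- function() {
  if (is.null(.cache$ds))
    .cache$ds <- make_dataset(8, 2, 10, phantom_spec(), seed = 1, m = 100)
  .cache$ds
}

# The scaled-down study conditions: U-Net^{-r,-t} at n = 4, desk profile
# (30 epochs x 100 steps, batch 16, 64x64 patches), fixed seed.
desk_fit <- function() {
  if (is.null(.cache$fit))
    .cache$fit <- blindspot(
      desk_dataset(),
      net = net_spec(n = 4, residual = FALSE, top_skip = FALSE, seed = 1),
      control = train_config("desk", seed = 1))
  .cache$fit
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
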