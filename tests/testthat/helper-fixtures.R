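# Shared fixtures, memoized so expensive objects are built once per session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

samp_default <- function() fixture("s724", function() make_sampling(724L))
samp_small <- function() fixture("s96", function() make_sampling(96L))
samp_dense <- function() fixture("s10k", function() make_sampling(10000L))
samp_peaks <- function() fixture("ico2562", function()
  make_sampling(2562L, "icosphere"))

# small noisy phantom reused by metrics / io / cli tests
small_phantom <- function() fixture("ph300", function()
  generate_phantom(300L, snr = 20, seed = 42L))

expect_norm_lt <- function(x, bound) {
  expect_lt(max(abs(x)), bound)
}
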