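# Shared small fixtures, built once per test run.

fix_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fix_env)) assign(name, builder(), envir = fix_env)
  get(name, envir = fix_env)
}

fix_model <- function() fixture("model", function() spectral_model())
fix_times <- function() fixture("times", function() echo_times())

# 32x32, 3-coil phantom for fast operator tests
fix_phantom_small <- function() fixture("ph32", function()
  make_phantom(phantom_config(shape = c(32L, 32L), n_coils = 3L, seed = 2L)))

# 64x64, 4-coil phantom for calibration / field-map tests
fix_phantom_mid <- function() fixture("ph64", function()
  make_phantom(phantom_config(shape = c(64L, 64L), n_coils = 4L, seed = 3L)))

rand_species <- function(n, seed = 11L) {
  wfsrecon:::with_local_seed(seed, species_images(
    wfsrecon:::crandn(c(n, n)), wfsrecon:::crandn(c(n, n)),
    wfsrecon:::crandn(c(n, n))))
}

species_nrmse <- function(a, b) {
  max(wfsrecon:::nrmse(a$w, b$w), wfsrecon:::nrmse(a$f, b$f),
      wfsrecon:::nrmse(a$s, b$s))
}

dot_test <- function(E, seed = 7L) {
  d <- E$dims
  wfsrecon:::with_local_seed(seed, {
    x <- species_images(wfsrecon:::crandn(c(d$nx, d$ny)),
                        wfsrecon:::crandn(c(d$nx, d$ny)),
                        wfsrecon:::crandn(c(d$nx, d$ny)))
    y <- wfsrecon:::crandn(c(d$nx, d$ny, d$n_coils, d$n_echoes, 2L))
    Ex <- E$forward(x)
    Ey <- E$adjoint(y)
    ip1 <- sum(Conj(Ex) * y)
    ip2 <- sum(Conj(x$w) * Ey$w + Conj(x$f) * Ey$f + Conj(x$s) * Ey$s)
    Mod(ip1 - ip2) / (sqrt(sum(Mod(Ex)^2)) * sqrt(sum(Mod(y)^2)))
  })
}
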